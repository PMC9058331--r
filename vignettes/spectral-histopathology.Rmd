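---
title: "Methods: FTIR spectral histopathology with spectropath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FTIR spectral histopathology with spectropath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectropath)
```

`spectropath` analyses FTIR hyperspectral images of colonic tissue to
classify samples into four diagnostic groups — normal mucosa, adenoma,
adenoma with epithelial misplacement (pseudo-invasion) and adenocarcinoma —
with particular interest in the epithelial-misplacement-versus-cancer
differential. This vignette is the package's own account of its models,
parameters and design decisions. Every empirical statement here is one the
test suite or `scripts/acceptance.R` computes.

## Data model

A sample is a `hyper_cube`: a (row, column, band) absorbance array with a
strictly increasing, uniformly spaced wavenumber axis (cm⁻¹), a pixel pitch
(default 1.1 µm, matching a 128×128 focal-plane-array acquisition of a
140×140 µm tile) and a pathology label. Coordinates are 0-based, row 0 at
the top; absorbance is the only stored quantity. Cubes flatten to a
`spectra_table` (one labelled spectrum per pixel), the working currency of
every downstream stage. Cubes and tables round-trip through a validated
binary container and tables additionally through plain CSV; the container is
checked key-by-key on read so a malformed file fails naming the missing
dataset, never silently.

The analysis axis is the spectral fingerprint region, 1000–1800 cm⁻¹. The
instrument class being emulated states a 4 cm⁻¹ spectral *resolution*; since
the sampling interval is not separately specified, the synthetic axis uses
4 cm⁻¹ sampling (201 points), and all input paths accept any uniform
spacing.

## EMSC: digital de-paraffinization, baseline removal, normalisation

Each observed spectrum $y$ is modelled as

$$y = b\,r + \textstyle\sum_i c_i p_i + \sum_{j=0}^{d} d_j P_j(t) + \varepsilon,$$

where $r$ is a reference spectrum, $p_i$ are paraffin interference
components, and $P_j$ are Legendre polynomials on the axis mapped affinely
to $[-1, 1]$. The fit is ordinary least squares through a QR factorisation
assembled once per basis; full column rank is asserted, and rank-deficiency
errors name the collinear columns. The corrected spectrum is
$(y - \sum_i c_i p_i - \sum_j d_j P_j)/b$, which de-paraffinizes,
baseline-corrects and normalises in one step; re-fitting a corrected
spectrum returns scale 1 and zero interference/baseline coefficients to
solver tolerance (idempotence, asserted at 1e-8 in tests).

Choices and defaults:

* **Baseline basis** — Legendre polynomials, default degree 4. Orthogonal
  polynomials keep the design well conditioned; degree 4 comfortably spans
  the smooth scatter baselines the generator draws (degree 2) while staying
  far from the width of real absorbance bands.
* **Reference spectrum** — the channel-wise mean of the dataset's truncated
  spectra (`compute_reference()`), the standard EMSC normalisation target.
  Preprocessing runs once, upstream of cross-validation; only the
  classifier chain is fold-scoped. The reference defines a normalisation
  target rather than class information — it is a label-free average — so
  computing it on the full dataset does not leak pathology labels into
  training.
* **Paraffin basis** — component zero is the mean of measured (here:
  simulated) paraffin spectra, plus principal directions of the mean-centred
  spectra; default 2 directions. One caution the tests encode: when paraffin
  variation is *exactly* two-dimensional (two bands, no noise), the mean
  already lies in the span of the two directions and the three columns are
  collinear — use mean + 1 direction there. With measurement noise, mean + 2
  directions is well posed.
* **Quality criteria** — EMSC scale in [0.2, 5], residual RMS at most 10×
  the cohort median, baseline-corrected amide-I height (max in
  1634–1674 cm⁻¹) at least 0.05 absorbance. No published criteria exist for
  this step, so the bounds are config-exposed (`quality_criteria()`) and the
  filter logs counts per rejection rule. Degenerate all-zero spectra fit
  with scale 0 and are quality-rejected, never raised as errors.

A notable interaction, relevant to interpreting all downstream effect sizes:
the scale coefficient $b$ absorbs whatever component of a pathology signal
is parallel to the reference. Band-amplitude modulations therefore survive
EMSC only in their component orthogonal to the reference, and group
separations after correction are substantially smaller than raw band
arithmetic suggests. This mirrors how EMSC-normalised pipelines behave on
real data.

## Segmentation

`kmeans_segment()` is Lloyd's algorithm with k-means++ seeding on Euclidean
distance over corrected spectra, best of `restarts` (default 10 for direct
calls, 5 in the pipeline) by within-cluster sum of squares; `max_iter` 300,
convergence at relative WCSS change below 1e-6. The objective is asserted
non-increasing at every iteration, and empty clusters are re-seeded from the
farthest point. No per-spectrum rescaling is applied on top of EMSC —
correction already normalises, and double-normalisation would distort band
ratios.

`scan_k()` scores k = 2..8 by mean silhouette width on a fixed-seed
subsample of at most 2000 spectra and recommends the maximiser, returning
all candidates: on real images the final k is a pathologist's call, not a
score's. Silhouette prefers the coarsest well-separated split, so when class
separations are very lopsided (two classes much closer to each other than to
a third) the recommendation can undershoot the true class count; the
acceptance construction for this check therefore uses mutually equidistant
classes. A constant image has no defined silhouette and recommends k = 1
with a warning.

Cluster→tissue-class labelling is explicit (`label_clusters()`,
many-to-one allowed); for synthetic data `majority_label_clusters()`
automates it from ground truth, standing in for expert validation.
`extract_class_spectra()` implements the extraction modes the classifier
uses: epithelium = {nuclear, cytoplasmic}, nuclear-only, and
epithelium-plus-stroma variants. Digital stains use a fixed palette
(deterministic per cluster index); centroid dendrograms use Ward linkage
("ward.D2") on Euclidean centroid distances — the linkage is a package
choice, made once — and serialise to Newick.

## Classification: PCA → ANOVA → LDA with LOSOCV

`pcalda()` chains three standard steps on training spectra:

1. **PCA** by SVD of mean-centred spectra, keeping up to 50 components
   (cap; the rank bound usually binds first at cohort scale). Loadings are
   sign-fixed (largest-magnitude entry positive) for determinism.
2. **ANOVA selection**: each component's scores get a fixed-effects one-way
   F-test across pathology groups; components with p < 0.05 are kept,
   at most 25, smallest p first. The test is applied to component *scores*
   (one value per spectrum per component) — the only reading that yields
   per-group samples. If nothing reaches significance the single smallest-p
   component is kept so the model stays defined; the fit is flagged.
3. **LDA** with equal class priors (balanced designs are the norm here;
   configurable) and pooled within-class covariance regularised by
   ridge ε = 1e-6 · trace(Σ)/d by default — a guard against near-singular
   covariance at up to 25 dimensions. Posteriors come from the
   Gaussian-equal-covariance model; discriminant directions (≤ classes − 1)
   feed the LD scatter and histogram plots.

`losocv()` holds out one sample at a time — all of its spectra — and refits
PCA, selection and LDA on the remaining samples only, asserting in every
fold that no training record carries the held-out sample's id. Whether the
published analyses fold-scoped their PCA is unstated in this literature;
fold-scoping is the leak-free default, and `global_pca = TRUE` reproduces
the leaky variant for comparison. Per-spectrum predictions aggregate to a
sample call by **majority vote**: a class with more than 50% of the spectra
wins decisively; otherwise the plurality class is returned flagged
non-decisive, plurality ties broken by highest mean posterior.

**Leave-one-out balance correction.** Holding a sample out leaves its own
group with fewer training spectra than the others. The variance of that
group's fitted mean is correspondingly larger, and the LDA discriminant's
quadratic term $-\tfrac12 \mu_g' \Sigma^{-1} \mu_g$ then systematically
disfavours the held-out class. The per-spectrum effect is small, but it is
*shared across all spectra of the sample*, so majority voting amplifies it;
on null cohorts (no pathology signal) it can push sample-level accuracy far
below chance. `losocv(balance_groups = TRUE)` (default) therefore
subsamples every fold's training groups to the smallest group's spectrum
count with fold-scoped seeding, restoring exchangeability under the null.
An optional per-sample `subsample` cap exists for tractability at clinical
scale (~10⁵ spectra per sample); synthetic scale needs none.

Two "accuracy" readings are always reported, since either may be meant by
an accuracy headline: overall accuracy (correct fraction, trace/total) and
balanced accuracy (mean of average one-vs-rest sensitivity and
specificity). ROC curves are computed at the spectrum level by default
(pooled held-out positive-class posteriors across folds; LD score
optional), with a sample-level vote-fraction ROC also available; AUC is the
concordance probability with ties counting one half. Multi-class ROC is
offered only as clearly-labelled one-vs-rest curves.

## The synthetic tissue generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, with full ground truth (tissue-class maps and per-pixel
contamination coefficients). Defaults are the study conditions: 10 samples
per group × 4 groups, one 128×128 tile per sample at 1.1 µm pitch,
axis 1000–1800 cm⁻¹ step 4.

* **Pure class spectra** are sums of Gaussian bands at the canonical
  assignments: sugars 1040, DNA 1078/1238, protein 1160, amide II 1546,
  amide I 1654, phospholipids 1726 cm⁻¹, with class-specific amplitudes
  (DNA bands dominate the nuclear class, sugars the mucin class, amide
  bands everything). 1380 and 1468 cm⁻¹ are reserved for paraffin and never
  appear in tissue profiles. A band's value at its centre equals its
  amplitude.
* **Pathology signal** is amplitude modulation of the DNA and sugar bands
  of epithelial (and mucin) classes, scaled by `effect_size`: DNA gain per
  unit effect 0 / 0.25 / 0.32 / 0.60 and sugar loss 0 / 0.18 / 0.22 / 0.45
  for normal / adenoma / epithelial misplacement / cancer. Epithelial
  misplacement deliberately sits close to adenoma — the clinically
  confusable pair — but is distinct, and additionally carries an elevated
  mucin amplitude (submucosal mucus pools) and a submucosa background. No
  quantitative group effect sizes exist to copy from clinical data, so
  `effect_size` is a free simulation parameter and every test states the
  value it uses (strong = 3, moderate = 2 with noise 0.04, null = 0).
* **Tissue architecture**: non-cancer tiles get elliptical glands — mucin
  lumen, cytoplasmic interior, nuclear rim — on lamina propria (normal,
  adenoma) or submucosa (epithelial misplacement); cancer tiles get
  irregular (angularly wobbled) epithelial blobs in stroma whose nuclear
  and cytoplasmic pixels interleave at random, the architecture-loss
  signature, and contain no mucin. Glands that cannot fit reduce in number
  with a warning, never an error.
* **Exchangeability at zero effect**, by construction: gland geometry is
  identical across pathologies, and cancer's interleave probability equals
  the nuclear fraction its own gland geometry would have produced — so the
  nuclear:cytoplasmic mixture of extracted epithelium carries no pathology
  signal at `effect_size = 0`, and null cohorts really are null.
* **Contamination**: observed = scatter × pure + paraffin + baseline +
  noise, with scatter ~ U(0.7, 1.3), an independent U(0.1, 0.5) amplitude
  per paraffin band (1380, width 10, relative height 1.0; 1468, width 9,
  height 1.4), a Legendre baseline of degree 2 with N(0, 0.02) coefficients,
  and i.i.d. Gaussian channel noise, default SD 0.005 absorbance. All drawn
  coefficients are returned as ground truth, which is what makes the EMSC
  exact-recovery and noise-robustness checks possible.

What the generator does **not** emulate: resonant Mie scattering and other
radiative-transfer effects, correlated detector noise, atmospheric (water
vapour/CO₂) lines, per-sample biological random effects, haemosiderin or
desmoplastic stroma chemistry, and multi-tile mosaics (a config option
concatenates tiles spatially, but defaults are single-tile). Passing tests
on this generator therefore validate the *pipeline's mechanics* — exact
EMSC recovery under its stated model, segmentation fidelity at stated
separations, selection calibration, leak-free cross-validation, vote
aggregation — not clinical performance. Clinical performance figures
reported in the literature for this differential come from in-house FFPE
cohorts that are not publicly deposited, so they serve only as qualitative
trend references (e.g. majority votes outperforming single-spectrum calls),
and the package makes no claim to reproduce them.

## Problem sizes and numerical choices

The validation suite runs cohorts of 10 samples per group on 16×16-pixel
tiles (40 LOSOCV folds on a few thousand extracted epithelial spectra) and
segmentation checks on 64×64 images — sizes chosen so the full suite
completes in about a minute on one core while still exercising 40-fold
cross-validation end to end. Tie-breaks are deterministic throughout
(first-index argmax in K-means and LDA, sign-fixed loadings and scalings,
fixed stain palette); all stochastic steps take explicit seeds and restore
the caller's RNG state. Tolerances: EMSC against the normal-equations
oracle at 1e-8 (coefficients) and 1e-6 relative L2 (recovery); PCA
reconstruction 1e-8; AUC against pairwise concordance 1e-12.

## Known limitations

* Proprietary instrument files are out of scope; data enter through the
  package's own containers (or in-memory arrays).
* K-means with Euclidean distance inherits the usual failure modes
  (unequal cluster sizes, non-spherical clusters); `scan_k` mitigates but
  the final k and labelling are human decisions on real data.
* The ANOVA screen tests components marginally; jointly informative but
  marginally null component sets are invisible to it.
* LDA assumes shared within-class covariance; the ridge guards
  conditioning, not model mismatch.
* Majority voting reports a decisive flag but no uncertainty; vote
  fractions are exposed for calibration-minded users.
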