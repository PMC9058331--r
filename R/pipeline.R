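# End-to-end run on a synthetic cohort: simulate -> EMSC-correct ->
# quality-filter -> segment -> label clusters from ground truth -> extract
# epithelium -> cross-validate. This is the harness the package's own
# validation (and the acceptance script) drives.

#' Run the full synthetic pipeline
#'
#' Generates a cohort, flattens and EMSC-corrects every cube (paraffin basis
#' from simulated paraffin spectra, dataset-mean reference, Legendre
#' baseline), quality-filters, segments each image with K-means at the
#' sample's true class count, labels clusters by ground-truth majority,
#' extracts the requested tissue classes and runs [losocv()].
#'
#' @param config A [cohort_config()].
#' @param extraction `"epithelium"` (nuclear + cytoplasmic), `"nuclear"`, or
#'   a character vector of [tissue_classes()].
#' @param groups Optional subset of [pathology_levels()] for the CV model.
#' @param baseline_degree EMSC Legendre baseline degree (default 4).
#' @param n_paraffin_components Paraffin principal directions in the EMSC
#'   basis (default 2).
#' @param k Clusters per image; default: the number of distinct ground-truth
#'   classes in that image.
#' @param restarts K-means restarts per image (default 5).
#' @param quality Apply [quality_filter()] (default TRUE).
#' @param ... Passed to [losocv()] (e.g. `alpha`, `max_keep`, `global_pca`).
#' @return List: `cv` ([losocv()] result), `extracted` (combined
#'   [spectra_table()]), `segmentations` (per-sample cluster maps),
#'   `quality_log` (summed rejection log), `cohort` manifest.
#' @export
run_pipeline <- function(config = cohort_config(),
                         extraction = "epithelium",
                         groups = NULL,
                         baseline_degree = 4,
                         n_paraffin_components = 2,
                         k = NULL, restarts = 5,
                         quality = TRUE, ...) {
  classes <- switch(extraction[1],
                    epithelium = epithelium_classes(),
                    nuclear = "nuclear",
                    extraction)
  cohort <- generate_cohort(config)
  axis <- config$axis

  tables <- lapply(cohort$cubes, flatten_cube)

  paraffin <- simulate_paraffin_spectra(200, config$contamination, axis,
                                        seed = config$seed + 101L)
  interference <- build_paraffin_basis(paraffin, n_paraffin_components)
  reference <- colMeans(do.call(rbind, lapply(tables, `[[`, "spectra")))
  basis <- emsc_basis(axis, reference, interference,
                      baseline_degree = baseline_degree)

  fits <- lapply(tables, fit_emsc_table, basis = basis)
  criteria <- default_quality_criteria(
    structure(data.frame(residual_rms = unlist(lapply(fits, `[[`, "residual_rms"))),
              class = c("emsc_fits", "data.frame")))

  quality_log <- c(scale = 0, residual = 0, amide1 = 0, rejected = 0,
                   passed = 0)
  segmentations <- list(); extracted <- list()
  for (sid in names(tables)) {
    corrected <- apply_emsc_table(tables[[sid]], fits[[sid]], basis)
    if (quality) {
      qf <- quality_filter(corrected, fits[[sid]], criteria)
      corrected <- qf$passed
      quality_log <- quality_log + qf$log
    }
    truth_map <- cohort$label_maps[[sid]]
    k_s <- k %||% length(unique(as.vector(truth_map)))
    cm <- kmeans_segment(corrected, k_s, seed = config$seed + 7L,
                         restarts = restarts)
    cm <- majority_label_clusters(cm, truth_map)
    segmentations[[sid]] <- cm
    ext <- extract_class_spectra(corrected, cm, classes)
    if (n_spectra(ext) > 0) extracted[[sid]] <- ext
  }
  extracted <- bind_spectra(extracted)
  cv <- losocv(extracted, groups = groups, seed = config$seed, ...)
  list(cv = cv, extracted = extracted, segmentations = segmentations,
       quality_log = quality_log, cohort = cohort$manifest)
}
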