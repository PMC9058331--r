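# Synthetic FTIR tissue cohorts with known ground truth. Pure class spectra
# are sums of Gaussian absorbance bands at the canonical fingerprint
# assignments (1040 sugars, 1078/1238 DNA, 1160 proteins, 1546 amide II,
# 1654 amide I, 1726 phospholipids); observed pixel spectra add paraffin
# interference (1380, 1468), multiplicative scatter, a smooth Legendre
# baseline and white noise. Pathology is encoded as amplitude modulation of
# the DNA and sugar bands.

#' Gaussian absorbance band specification
#'
#' @param center Band centre in cm^-1 (within or near 1000-1800).
#' @param width Gaussian standard deviation in cm^-1 (> 0).
#' @param amplitude Apex absorbance (>= 0); the band evaluates to exactly
#'   `amplitude` at `center`.
#' @return A one-row data.frame; several can be `rbind`ed into a peak table.
#' @export
peak_spec <- function(center, width, amplitude) {
  stopifnot(is.numeric(center), length(center) == 1,
            is.numeric(width), length(width) == 1, width > 0,
            is.numeric(amplitude), length(amplitude) == 1, amplitude >= 0)
  if (center < 900 || center > 1900) {
    stop("band centre should lie within or near the 1000-1800 cm^-1 region",
         call. = FALSE)
  }
  data.frame(center = center, width = width, amplitude = amplitude)
}

#' Tissue-class spectral profile
#'
#' A set of Gaussian bands plus optional per-pathology multiplicative
#' modulation factors applied to named bands (keyed by band centre).
#'
#' @param tissue_class One of [tissue_classes()].
#' @param peaks data.frame with columns `center`, `width`, `amplitude`
#'   (rows from [peak_spec()]).
#' @param pathology_modulation Named list (names from [pathology_levels()])
#'   of named numeric vectors: band centre (as character) -> factor > 0.
#'   Every modulated band must exist in `peaks`.
#' @return Object of class `"class_profile"`.
#' @export
class_profile <- function(tissue_class, peaks,
                          pathology_modulation = list()) {
  stopifnot(tissue_class %in% tissue_classes())
  if (nrow(peaks)) {
    stopifnot(all(peaks$width > 0), all(peaks$amplitude >= 0))
  }
  centers <- as.character(peaks$center)
  for (p in names(pathology_modulation)) {
    assert_pathology(p)
    m <- pathology_modulation[[p]]
    if (any(m <= 0)) stop("modulation factors must be > 0", call. = FALSE)
    unknown <- setdiff(names(m), centers)
    if (length(unknown)) {
      stop("modulated band(s) not present in profile: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(tissue_class = tissue_class, peaks = peaks,
                 pathology_modulation = pathology_modulation),
            class = "class_profile")
}

# Per-unit-effect modulation strengths of the pathology signal. DNA band
# amplitudes rise with neoplastic progression; sugar (mucin secretion)
# falls. Epithelial misplacement sits close to adenoma (the clinically
# confusable pair) but is distinct, and carries an elevated mucin amplitude
# of its own (submucosal mucus pools).
path_dna_gain <- c(normal = 0, adenoma = 0.25,
                   epithelial_misplacement = 0.32, cancer = 0.6)
path_sugar_loss <- c(normal = 0, adenoma = 0.18,
                     epithelial_misplacement = 0.22, cancer = 0.45)

modulation_factors <- function(effect_size, dna_keys, sugar_keys) {
  out <- list()
  for (p in pathology_levels()) {
    f <- c(
      stats::setNames(rep(1 + effect_size * path_dna_gain[[p]],
                          length(dna_keys)), dna_keys),
      stats::setNames(rep(max(1 - effect_size * path_sugar_loss[[p]], 0.05),
                          length(sugar_keys)), sugar_keys)
    )
    out[[p]] <- f
  }
  out
}

#' Default tissue-class spectral profiles
#'
#' Band sets per histology class built from the canonical fingerprint
#' assignments; 1380 and 1468 cm^-1 are reserved for paraffin contamination
#' and never appear in tissue profiles. `effect_size` scales the
#' per-pathology amplitude modulation of the DNA (1078, 1238) and sugar
#' (1040) bands of the epithelial and mucin classes; at `effect_size = 0`
#' all pathology groups share identical pure spectra.
#'
#' @param effect_size Non-negative separation multiplier (default 1).
#' @return Named list of [class_profile()]s, one per tissue class.
#' @export
default_tissue_profiles <- function(effect_size = 1) {
  stopifnot(is.numeric(effect_size), length(effect_size) == 1,
            effect_size >= 0)
  pk <- function(...) do.call(rbind, list(...))
  epi_mod <- modulation_factors(effect_size,
                                dna_keys = c("1078", "1238"),
                                sugar_keys = "1040")
  # mucin: sugar band rises for epithelial misplacement (mucus pools),
  # falls with progression otherwise
  mucin_mod <- modulation_factors(effect_size, dna_keys = character(0),
                                  sugar_keys = "1040")
  mucin_mod$epithelial_misplacement["1040"] <- 1 + 0.3 * effect_size

  list(
    nuclear = class_profile("nuclear", pk(
      peak_spec(1040, 12, 0.10), peak_spec(1078, 12, 0.45),
      peak_spec(1160, 12, 0.15), peak_spec(1238, 14, 0.40),
      peak_spec(1546, 16, 0.55), peak_spec(1654, 18, 0.85),
      peak_spec(1726, 12, 0.10)), epi_mod),
    cytoplasmic = class_profile("cytoplasmic", pk(
      peak_spec(1040, 12, 0.35), peak_spec(1078, 12, 0.12),
      peak_spec(1160, 12, 0.25), peak_spec(1238, 14, 0.10),
      peak_spec(1546, 16, 0.60), peak_spec(1654, 18, 0.95),
      peak_spec(1726, 12, 0.15)), epi_mod),
    mucin = class_profile("mucin", pk(
      peak_spec(1040, 14, 0.80), peak_spec(1078, 12, 0.30),
      peak_spec(1160, 12, 0.35), peak_spec(1546, 16, 0.25),
      peak_spec(1654, 18, 0.45)), mucin_mod),
    lamina_propria = class_profile("lamina_propria", pk(
      peak_spec(1040, 12, 0.12), peak_spec(1078, 12, 0.10),
      peak_spec(1160, 12, 0.20), peak_spec(1238, 14, 0.28),
      peak_spec(1546, 16, 0.65), peak_spec(1654, 18, 1.00))),
    submucosa = class_profile("submucosa", pk(
      peak_spec(1040, 12, 0.08), peak_spec(1160, 12, 0.28),
      peak_spec(1238, 14, 0.33), peak_spec(1546, 16, 0.60),
      peak_spec(1654, 18, 0.90), peak_spec(1726, 12, 0.08))),
    stroma = class_profile("stroma", pk(
      peak_spec(1078, 12, 0.08), peak_spec(1160, 12, 0.22),
      peak_spec(1238, 14, 0.30), peak_spec(1546, 16, 0.70),
      peak_spec(1654, 18, 1.05), peak_spec(1726, 12, 0.12))),
    background = class_profile("background",
                               data.frame(center = numeric(0),
                                          width = numeric(0),
                                          amplitude = numeric(0)))
  )
}

gaussian_bands <- function(peaks, axis, factors = NULL) {
  ax <- as.numeric(unclass(axis))
  s <- numeric(length(ax))
  if (!nrow(peaks)) return(s)
  for (i in seq_len(nrow(peaks))) {
    f <- 1
    if (!is.null(factors)) {
      key <- as.character(peaks$center[i])
      if (key %in% names(factors)) f <- factors[[key]]
    }
    s <- s + peaks$amplitude[i] * f *
      exp(-0.5 * ((ax - peaks$center[i]) / peaks$width[i])^2)
  }
  s
}

#' Render a noise-free pure class spectrum
#'
#' Sum over the profile's Gaussian bands, each scaled by the pathology's
#' modulation factor (1 where none is defined). Deterministic and
#' non-negative.
#'
#' @param profile A [class_profile()].
#' @param pathology One of [pathology_levels()].
#' @param axis A [wn_axis()].
#' @return Numeric absorbance vector on `axis`.
#' @export
render_pure_spectrum <- function(profile, pathology, axis) {
  stopifnot(inherits(profile, "class_profile"))
  assert_pathology(pathology)
  gaussian_bands(profile$peaks, axis,
                 factors = profile$pathology_modulation[[pathology]])
}

#' Contamination model for observed spectra
#'
#' Describes how a pure tissue spectrum becomes an observed FFPE measurement:
#' multiplicative scatter, additive paraffin bands (one amplitude drawn per
#' band), a smooth Legendre-polynomial baseline and white Gaussian noise.
#'
#' @param paraffin_peaks data.frame of paraffin band shapes (defaults:
#'   1380 and 1468 cm^-1).
#' @param paraffin_amplitude_range Interval the per-band paraffin amplitudes
#'   are drawn from (uniform).
#' @param scatter_scale_range Interval around 1 for the multiplicative
#'   scatter scale (uniform); lower bound must be > 0.
#' @param baseline_degree Legendre baseline degree (>= 0).
#' @param baseline_coeff_scale Standard deviation(s) of the Gaussian baseline
#'   coefficients, recycled over degrees 0..`baseline_degree`.
#' @param noise_sd Additive white-noise standard deviation (absorbance units).
#' @return Object of class `"contamination_model"`.
#' @export
contamination_model <- function(paraffin_peaks = rbind(peak_spec(1380, 10, 1.0),
                                                       peak_spec(1468, 9, 1.4)),
                                paraffin_amplitude_range = c(0.1, 0.5),
                                scatter_scale_range = c(0.7, 1.3),
                                baseline_degree = 2,
                                baseline_coeff_scale = 0.02,
                                noise_sd = 0.005) {
  stopifnot(length(paraffin_amplitude_range) == 2,
            diff(paraffin_amplitude_range) >= 0,
            paraffin_amplitude_range[1] >= 0,
            length(scatter_scale_range) == 2,
            scatter_scale_range[1] > 0,
            diff(scatter_scale_range) >= 0,
            baseline_degree >= 0, all(baseline_coeff_scale >= 0),
            noise_sd >= 0)
  structure(list(paraffin_peaks = paraffin_peaks,
                 paraffin_amplitude_range = paraffin_amplitude_range,
                 scatter_scale_range = scatter_scale_range,
                 baseline_degree = as.integer(baseline_degree),
                 baseline_coeff_scale = baseline_coeff_scale,
                 noise_sd = noise_sd),
            class = "contamination_model")
}

paraffin_components <- function(model, axis) {
  sapply(seq_len(nrow(model$paraffin_peaks)), function(i) {
    gaussian_bands(model$paraffin_peaks[i, , drop = FALSE], axis)
  })
}

baseline_sds <- function(model) {
  rep_len(model$baseline_coeff_scale, model$baseline_degree + 1L)
}

# Contaminate a matrix of pure spectra (one per row) in one vectorized pass.
# Draws use the current RNG state. Returns observed matrix plus the drawn
# ground-truth coefficients.
contaminate_matrix <- function(pure, model, axis) {
  stopifnot(inherits(model, "contamination_model"))
  pure <- rbind(pure)
  n <- nrow(pure); p <- ncol(pure)
  stopifnot(p == length(axis))
  P <- paraffin_components(model, axis)           # p x n_bands
  L <- legendre_basis(axis, model$baseline_degree) # p x (deg+1)
  scatter <- stats::runif(n, model$scatter_scale_range[1],
                          model$scatter_scale_range[2])
  amps <- matrix(stats::runif(n * ncol(P), model$paraffin_amplitude_range[1],
                              model$paraffin_amplitude_range[2]),
                 nrow = n)
  sds <- baseline_sds(model)
  base_coeffs <- matrix(stats::rnorm(n * length(sds), 0,
                                     rep(sds, each = n)), nrow = n)
  observed <- pure * scatter + amps %*% t(P) + base_coeffs %*% t(L)
  if (model$noise_sd > 0) {
    observed <- observed + matrix(stats::rnorm(n * p, 0, model$noise_sd),
                                  nrow = n)
  }
  colnames(amps) <- paste0("paraffin_", model$paraffin_peaks$center)
  colnames(base_coeffs) <- paste0("baseline_", seq_len(ncol(L)) - 1L)
  list(observed = observed,
       truth = data.frame(scatter = scatter, amps, base_coeffs,
                          check.names = FALSE))
}

#' Contaminate a pure spectrum
#'
#' observed = scatter x pure + sum(paraffin bands) + Legendre baseline +
#' Gaussian noise. Random draws use R's current RNG state; call `set.seed()`
#' first for reproducibility. The drawn coefficients are returned as ground
#' truth.
#'
#' @param spectrum Pure absorbance vector on `axis`.
#' @param model A [contamination_model()].
#' @param axis The [wn_axis()] the spectrum lives on.
#' @return List with `observed` (numeric vector) and `truth` (one-row
#'   data.frame: scatter scale, per-band paraffin amplitudes, baseline
#'   coefficients).
#' @export
contaminate <- function(spectrum, model, axis) {
  stopifnot(is.numeric(spectrum), length(spectrum) == length(axis))
  res <- contaminate_matrix(matrix(spectrum, nrow = 1), model, axis)
  list(observed = drop(res$observed), truth = res$truth)
}

#' Cohort configuration
#'
#' Study conditions for a synthetic cohort: by default ten samples per
#' diagnostic group on 128 x 128 pixel tiles at 1.1 um pitch, fingerprint
#' axis 1000-1800 cm^-1 every 4 cm^-1.
#'
#' @param samples_per_group Samples per pathology group (>= 1, default 10).
#' @param tile_shape Integer c(rows, cols), each >= 8 (default 128 x 128).
#' @param glands_per_image Integer range c(min, max) of glands per tile.
#' @param effect_size Pathology separation multiplier (see
#'   [default_tissue_profiles()]).
#' @param contamination A [contamination_model()].
#' @param axis A [wn_axis()].
#' @param pixel_size Pixel pitch in micrometres.
#' @param seed Integer RNG seed; a fixed seed makes [generate_cohort()]
#'   byte-identical across runs.
#' @return Object of class `"cohort_config"`.
#' @export
cohort_config <- function(samples_per_group = 10,
                          tile_shape = c(128, 128),
                          glands_per_image = c(2, 4),
                          effect_size = 1,
                          contamination = contamination_model(),
                          axis = default_axis(),
                          pixel_size = 1.1,
                          seed = 1) {
  stopifnot(samples_per_group >= 1,
            length(tile_shape) == 2, all(tile_shape >= 8),
            length(glands_per_image) == 2,
            glands_per_image[1] >= 0,
            glands_per_image[2] >= glands_per_image[1],
            effect_size >= 0,
            inherits(contamination, "contamination_model"),
            pixel_size > 0,
            is.numeric(seed), length(seed) == 1)
  structure(list(samples_per_group = as.integer(samples_per_group),
                 tile_shape = as.integer(tile_shape),
                 glands_per_image = as.integer(glands_per_image),
                 effect_size = effect_size,
                 contamination = contamination,
                 axis = wn_axis(axis),
                 pixel_size = pixel_size,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Fill elliptical gland classes into `map` (character matrix, modified copy
# returned). d <= 1 inside the gland; lumen/interior/rim split by elliptical
# radius. `wobble` > 0 perturbs the boundary angularly (irregular cancer
# blobs).
draw_glands <- function(map, n_glands, wobble = 0) {
  nr <- nrow(map); nc <- ncol(map)
  m <- min(nr, nc)
  r_min <- max(3, 0.10 * m)
  r_max <- max(r_min + 0.5, 0.22 * m)
  placed <- 0L
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (g in seq_len(n_glands)) {
    a <- stats::runif(1, r_min, r_max)
    b <- stats::runif(1, r_min, r_max)
    margin <- max(a, b) * (1 + wobble)
    if (nr - 2 * margin < 1 || nc - 2 * margin < 1) next
    cy <- stats::runif(1, 1 + margin, nr - margin)
    cx <- stats::runif(1, 1 + margin, nc - margin)
    theta <- stats::runif(1, 0, pi)
    phi <- stats::runif(1, 0, 2 * pi)
    u <- (rows - cy) * cos(theta) + (cols - cx) * sin(theta)
    v <- -(rows - cy) * sin(theta) + (cols - cx) * cos(theta)
    d <- sqrt((u / a)^2 + (v / b)^2)
    if (wobble > 0) {
      ang <- atan2(v, u)
      d <- d / (1 + wobble * sin(3 * ang + phi))
    }
    inside <- d <= 1
    if (!any(inside)) next
    map[inside & d < 0.45] <- "mucin"
    map[inside & d >= 0.45 & d < 0.78] <- "cytoplasmic"
    map[inside & d >= 0.78] <- "nuclear"
    placed <- placed + 1L
  }
  attr(map, "placed") <- placed
  map
}

#' Generate a ground-truth tissue-class label map
#'
#' Non-cancer pathologies get elliptical glands (mucin lumen, cytoplasmic
#' interior, nuclear rim) on a connective background (lamina propria for
#' normal/adenoma, submucosa for epithelial misplacement). Cancer gets
#' irregular epithelial blobs in stroma whose nuclear and cytoplasmic pixels
#' are interleaved at random (architecture loss) and which contain no mucin;
#' the interleave fraction equals the nuclear fraction the same gland
#' geometry would have produced, so the nuclear:cytoplasmic mixture carries
#' no pathology signal by construction.
#'
#' Glands that cannot fit are silently reduced in number with a warning,
#' never an error. Random draws use the current RNG state.
#'
#' @param tile_shape Integer c(rows, cols), each >= 8.
#' @param pathology One of [pathology_levels()].
#' @param glands Number of glands to attempt.
#' @return Character matrix of tissue classes.
#' @export
generate_label_map <- function(tile_shape, pathology, glands) {
  assert_pathology(pathology)
  stopifnot(length(tile_shape) == 2, all(tile_shape >= 8), glands >= 0)
  nr <- tile_shape[1]; nc <- tile_shape[2]
  background <- switch(pathology,
                       normal = "lamina_propria",
                       adenoma = "lamina_propria",
                       epithelial_misplacement = "submucosa",
                       cancer = "stroma")
  map <- matrix(background, nr, nc)
  wobble <- if (pathology == "cancer") 0.25 else 0
  map <- draw_glands(map, glands, wobble = wobble)
  placed <- attr(map, "placed")
  attr(map, "placed") <- NULL
  if (placed < glands) {
    warning(sprintf("only %d of %d glands fit a %d x %d tile",
                    placed, glands, nr, nc), call. = FALSE)
  }
  if (pathology == "cancer") {
    gland_px <- map %in% c("mucin", "cytoplasmic", "nuclear")
    n_nuc <- sum(map == "nuclear"); n_cyt <- sum(map == "cytoplasmic")
    p_nuc <- if (n_nuc + n_cyt > 0) n_nuc / (n_nuc + n_cyt) else 0.5
    n_epi <- sum(gland_px)
    if (n_epi > 0) {
      map[gland_px] <- ifelse(stats::runif(n_epi) < p_nuc,
                              "nuclear", "cytoplasmic")
    }
  }
  map
}

#' Generate a synthetic cohort with ground truth
#'
#' Produces `4 * samples_per_group` hyperspectral cubes (one tile per
#' sample), the ground-truth tissue-class map per sample, and the drawn
#' contamination coefficients per pixel. Deterministic under the config
#' seed: two runs with the same config are byte-identical.
#'
#' @param config A [cohort_config()].
#' @return List with elements `cubes` (named list of [hyper_cube()]),
#'   `label_maps` (named list of character matrices), `truth` (data.frame of
#'   per-pixel contamination coefficients keyed by sample_id/row/col),
#'   `manifest` (data.frame sample_id, pathology) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  profiles <- default_tissue_profiles(config$effect_size)
  axis <- config$axis
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)

  cubes <- list(); label_maps <- list(); truths <- list()
  manifest <- NULL
  nr <- config$tile_shape[1]; nc <- config$tile_shape[2]
  for (pathology in pathology_levels()) {
    # pure spectrum per tissue class for this pathology
    pure <- sapply(tissue_classes(), function(cl) {
      render_pure_spectrum(profiles[[cl]], pathology, axis)
    })                                             # p x n_classes
    for (i in seq_len(config$samples_per_group)) {
      sid <- sprintf("%s_%02d", pathology, i)
      glands <- sample(seq(config$glands_per_image[1],
                           config$glands_per_image[2]), 1)
      map <- generate_label_map(c(nr, nc), pathology, glands)
      pure_px <- t(pure[, map, drop = FALSE])      # (nr*nc) x p, column-major
      cont <- contaminate_matrix(pure_px, config$contamination, axis)
      data <- array(cont$observed, dim = c(nr, nc, length(axis)))
      cubes[[sid]] <- hyper_cube(sid, pathology, axis, data,
                                 pixel_size = config$pixel_size)
      label_maps[[sid]] <- map
      truths[[sid]] <- data.frame(
        sample_id = sid,
        row = rep(seq_len(nr) - 1L, nc),
        col = rep(seq_len(nc) - 1L, each = nr),
        tissue_class = as.vector(map),
        cont$truth, check.names = FALSE
      )
      manifest <- rbind(manifest,
                        data.frame(sample_id = sid, pathology = pathology))
    }
  }
  list(cubes = cubes, label_maps = label_maps,
       truth = do.call(rbind, truths), manifest = manifest, config = config)
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Simulate measured paraffin spectra
#'
#' Draws `n` pure-paraffin spectra from a contamination model (independent
#' amplitude per band, plus the model's noise), for building an EMSC
#' paraffin interference basis when no measured paraffin block is available.
#'
#' @param n Number of spectra.
#' @param model A [contamination_model()].
#' @param axis A [wn_axis()].
#' @param seed Optional integer seed (local to this call).
#' @return Numeric matrix, one spectrum per row.
#' @export
simulate_paraffin_spectra <- function(n, model, axis, seed = NULL) {
  stopifnot(n >= 1, inherits(model, "contamination_model"))
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_seed(old_seed), add = TRUE)
    set.seed(seed)
  }
  P <- paraffin_components(model, axis)
  amps <- matrix(stats::runif(n * ncol(P), model$paraffin_amplitude_range[1],
                              model$paraffin_amplitude_range[2]), nrow = n)
  X <- amps %*% t(P)
  if (model$noise_sd > 0) {
    X <- X + matrix(stats::rnorm(n * ncol(X), 0, model$noise_sd), nrow = n)
  }
  X
}
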