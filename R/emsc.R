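# Modified extended multiplicative signal correction (EMSC): each observed
# spectrum is decomposed by ordinary least squares into a scaled reference,
# paraffin interference components and a Legendre-polynomial baseline;
# correction subtracts interference and baseline and divides by the scale,
# which simultaneously de-paraffinizes, baseline-corrects and normalises.

#' Legendre polynomial basis on a wavenumber axis
#'
#' Legendre polynomials P_0..P_degree evaluated on the axis affinely mapped
#' to \[-1, 1\] (Bonnet recurrence). Orthogonal baseline terms keep the EMSC
#' design well conditioned.
#'
#' @param axis A [wn_axis()].
#' @param degree Highest polynomial degree (>= 0).
#' @return Matrix with `length(axis)` rows and `degree + 1` columns.
#' @export
legendre_basis <- function(axis, degree) {
  stopifnot(degree >= 0)
  ax <- as.numeric(unclass(axis))
  t <- 2 * (ax - min(ax)) / (max(ax) - min(ax)) - 1
  L <- matrix(0, length(t), degree + 1L)
  L[, 1] <- 1
  if (degree >= 1) L[, 2] <- t
  if (degree >= 2) {
    for (k in 2:degree) {
      L[, k + 1] <- ((2 * k - 1) * t * L[, k] - (k - 1) * L[, k - 1]) / k
    }
  }
  colnames(L) <- paste0("legendre_", 0:degree)
  L
}

#' Truncate to the fingerprint region
#'
#' Restricts a cube or spectra table to the axis points w with
#' `low <= w <= high` (defaults 1000-1800 cm^-1); metadata are preserved.
#'
#' @param x A [hyper_cube()] or [spectra_table()].
#' @param low,high Closed interval in cm^-1 (`low < high`); must intersect
#'   the axis.
#' @return Object of the same kind on the restricted axis.
#' @export
truncate_fingerprint <- function(x, low = 1000, high = 1800) {
  UseMethod("truncate_fingerprint")
}

fingerprint_idx <- function(axis, low, high) {
  if (!(low < high)) stop("low must be < high", call. = FALSE)
  keep <- which(unclass(axis) >= low - 1e-9 & unclass(axis) <= high + 1e-9)
  if (length(keep) < 2) {
    stop(sprintf("[%g, %g] keeps fewer than 2 axis points", low, high),
         call. = FALSE)
  }
  keep
}

#' @export
truncate_fingerprint.hyper_cube <- function(x, low = 1000, high = 1800) {
  keep <- fingerprint_idx(x$axis, low, high)
  hyper_cube(x$sample_id, x$pathology, unclass(x$axis)[keep],
             x$data[, , keep, drop = FALSE], x$pixel_size)
}

#' @export
truncate_fingerprint.spectra_table <- function(x, low = 1000, high = 1800) {
  keep <- fingerprint_idx(x$axis, low, high)
  spectra_table(unclass(x$axis)[keep], x$meta,
                x$spectra[, keep, drop = FALSE], tile_shape = x$tile_shape)
}

#' EMSC reference spectrum
#'
#' Channel-wise mean spectrum of all records in the table — the standard
#' EMSC normalisation target.
#'
#' @param table A non-empty [spectra_table()].
#' @return Numeric vector on the table's axis.
#' @export
compute_reference <- function(table) {
  stopifnot(inherits(table, "spectra_table"))
  if (n_spectra(table) == 0) stop("cannot compute a reference from an empty table",
                                  call. = FALSE)
  colMeans(table$spectra)
}

#' Build a paraffin interference basis
#'
#' Component zero is the mean of the supplied paraffin spectra; the remaining
#' `n_components` columns are the leading principal directions of the
#' mean-centred spectra (orthonormal). Directions whose singular value is
#' numerically zero are flagged with a warning.
#'
#' @param paraffin A [spectra_table()] or numeric matrix (one paraffin
#'   spectrum per row) on the working axis.
#' @param n_components Number of principal directions (< spectrum count).
#' @return Matrix, one interference component per column
#'   (`paraffin_mean`, `paraffin_pc1`, ...).
#' @export
build_paraffin_basis <- function(paraffin, n_components = 2) {
  X <- if (inherits(paraffin, "spectra_table")) paraffin$spectra else as.matrix(paraffin)
  n <- nrow(X)
  if (n_components >= n) {
    stop("n_components must be smaller than the number of paraffin spectra",
         call. = FALSE)
  }
  m <- colMeans(X)
  out <- matrix(m, ncol = 1)
  colnames(out) <- "paraffin_mean"
  if (n_components > 0) {
    sv <- svd(sweep(X, 2, m), nu = 0, nv = n_components)
    tiny <- sv$d[seq_len(n_components)] <= max(sv$d[1], .Machine$double.eps) * 1e-8
    if (any(tiny)) {
      warning(sprintf("paraffin direction(s) %s are numerically degenerate (zero variance)",
                      paste(which(tiny), collapse = ", ")), call. = FALSE)
    }
    dirs <- sv$v
    colnames(dirs) <- paste0("paraffin_pc", seq_len(n_components))
    out <- cbind(out, dirs)
  }
  out
}

#' EMSC design basis
#'
#' Assembles and QR-factorises the least-squares design
#' \[reference | interference components | Legendre baseline terms\];
#' full column rank is asserted, and rank deficiency errors name the
#' collinear columns.
#'
#' @param axis A [wn_axis()].
#' @param reference Reference spectrum on `axis` (see [compute_reference()]).
#' @param interference Optional matrix of interference components (one per
#'   column), e.g. from [build_paraffin_basis()].
#' @param baseline_degree Legendre baseline degree (default 4).
#' @return Object of class `"emsc_basis"`.
#' @export
emsc_basis <- function(axis, reference, interference = NULL,
                       baseline_degree = 4) {
  axis <- wn_axis(axis)
  stopifnot(length(reference) == length(axis), baseline_degree >= 0)
  design <- cbind(reference = reference)
  if (!is.null(interference)) {
    interference <- as.matrix(interference)
    stopifnot(nrow(interference) == length(axis))
    if (is.null(colnames(interference))) {
      colnames(interference) <- paste0("interference_", seq_len(ncol(interference)))
    }
    design <- cbind(design, interference)
  }
  design <- cbind(design, legendre_basis(axis, baseline_degree))
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("EMSC design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n_int <- if (is.null(interference)) 0L else ncol(interference)
  structure(list(axis = axis, reference = reference,
                 interference = interference,
                 baseline_degree = as.integer(baseline_degree),
                 design = design, qr = qrd,
                 n_interference = n_int),
            class = "emsc_basis")
}

#' @export
print.emsc_basis <- function(x, ...) {
  cat(sprintf("<emsc_basis> %d channels; %d interference component(s); Legendre degree %d\n",
              length(x$axis), x$n_interference, x$baseline_degree))
  invisible(x)
}

coef_split <- function(basis, coefs) {
  # coefs: m x n matrix (columns = spectra)
  coefs <- unname(coefs)
  n_int <- basis$n_interference
  list(scale = coefs[1, ],
       interference = coefs[seq_len(n_int) + 1L, , drop = FALSE],
       baseline = coefs[(2L + n_int):nrow(coefs), , drop = FALSE])
}

#' Fit the EMSC model to one spectrum
#'
#' Ordinary least squares of `observed` on the basis design; the unique
#' solution's coefficients (scale, interference, baseline) and residual RMS
#' are returned.
#'
#' @param observed Numeric spectrum on the basis axis.
#' @param basis An [emsc_basis()].
#' @return Object of class `"emsc_fit"` with fields `scale`,
#'   `interference_coeffs`, `baseline_coeffs`, `residual_rms`.
#' @export
fit_emsc <- function(observed, basis) {
  stopifnot(inherits(basis, "emsc_basis"),
            is.numeric(observed), length(observed) == length(basis$axis))
  fits <- fit_emsc_matrix(matrix(observed, ncol = 1), basis)
  structure(list(scale = fits$scale[1],
                 interference_coeffs = fits$interference[, 1],
                 baseline_coeffs = fits$baseline[, 1],
                 residual_rms = fits$residual_rms[1]),
            class = "emsc_fit")
}

#' @export
print.emsc_fit <- function(x, ...) {
  cat(sprintf("<emsc_fit> scale %.4g; residual RMS %.4g\n",
              x$scale, x$residual_rms))
  if (length(x$interference_coeffs)) {
    cat("  interference:", paste(sprintf("%.4g", x$interference_coeffs),
                                 collapse = ", "), "\n")
  }
  cat("  baseline:", paste(sprintf("%.4g", x$baseline_coeffs),
                           collapse = ", "), "\n")
  invisible(x)
}

# observed: p x n matrix, one spectrum per column
fit_emsc_matrix <- function(observed, basis) {
  coefs <- qr.coef(basis$qr, observed)
  resid <- observed - basis$design %*% coefs
  rms <- sqrt(colMeans(resid^2))
  out <- coef_split(basis, coefs)
  out$residual_rms <- rms
  out
}

#' Fit the EMSC model to every spectrum of a table
#'
#' @param table A [spectra_table()] on the basis axis.
#' @param basis An [emsc_basis()].
#' @return Object of class `"emsc_fits"`: a data.frame with one row per
#'   record — `scale`, one column per interference component, one per
#'   baseline term, and `residual_rms`.
#' @export
fit_emsc_table <- function(table, basis) {
  stopifnot(inherits(table, "spectra_table"), inherits(basis, "emsc_basis"))
  if (!isTRUE(all.equal(unclass(table$axis), unclass(basis$axis)))) {
    stop("table and basis axes differ", call. = FALSE)
  }
  f <- fit_emsc_matrix(t(table$spectra), basis)
  int <- t(f$interference)
  if (ncol(int)) {
    colnames(int) <- colnames(basis$interference)
  }
  bl <- t(f$baseline)
  colnames(bl) <- paste0("baseline_", seq_len(ncol(bl)) - 1L)
  df <- data.frame(scale = f$scale, int, bl, residual_rms = f$residual_rms,
                   check.names = FALSE)
  class(df) <- c("emsc_fits", "data.frame")
  df
}

#' Apply an EMSC correction
#'
#' corrected = (observed - interference terms - baseline terms) / scale.
#' Fitting the corrected spectrum again yields scale 1 and zero interference
#' and baseline coefficients (idempotence, to solver tolerance). A scale
#' whose magnitude falls below `min_scale` signals a quality reject: the
#' corrected spectrum is all-`NA` with attribute `rejected = TRUE`, never an
#' exception.
#'
#' @param observed Numeric spectrum on the basis axis.
#' @param fit An [fit_emsc()] result for that spectrum.
#' @param basis The [emsc_basis()] used for the fit.
#' @param min_scale Guard on `|scale|` (default 0.05).
#' @return Corrected numeric spectrum.
#' @export
apply_emsc <- function(observed, fit, basis, min_scale = 0.05) {
  stopifnot(inherits(fit, "emsc_fit"))
  if (abs(fit$scale) < min_scale) {
    out <- rep(NA_real_, length(observed))
    attr(out, "rejected") <- TRUE
    return(out)
  }
  removed <- numeric(length(observed))
  if (basis$n_interference > 0) {
    removed <- removed + basis$interference %*% fit$interference_coeffs
  }
  L <- legendre_basis(basis$axis, basis$baseline_degree)
  removed <- removed + L %*% fit$baseline_coeffs
  drop(observed - removed) / fit$scale
}

#' Apply EMSC corrections to a whole table
#'
#' @param table A [spectra_table()] of observed spectra on the basis axis.
#' @param fits An [fit_emsc_table()] result for `table`.
#' @param basis The [emsc_basis()] used.
#' @param min_scale Guard on `|scale|`; rows below it become all-`NA`
#'   (rejected by [quality_filter()] downstream).
#' @return A [spectra_table()] of corrected spectra (same records).
#' @export
apply_emsc_table <- function(table, fits, basis, min_scale = 0.05) {
  stopifnot(inherits(table, "spectra_table"), inherits(fits, "emsc_fits"),
            nrow(fits) == n_spectra(table))
  n_int <- basis$n_interference
  removed <- matrix(0, n_spectra(table), length(basis$axis))
  if (n_int > 0) {
    B <- as.matrix(fits[, colnames(basis$interference), drop = FALSE])
    removed <- removed + B %*% t(basis$interference)
  }
  L <- legendre_basis(basis$axis, basis$baseline_degree)
  Cf <- as.matrix(fits[, paste0("baseline_", seq_len(ncol(L)) - 1L),
                       drop = FALSE])
  removed <- removed + Cf %*% t(L)
  corrected <- (table$spectra - removed) / fits$scale
  corrected[abs(fits$scale) < min_scale, ] <- NA_real_
  out <- table
  out$spectra <- corrected
  out
}

#' Quality criteria for EMSC-corrected spectra
#'
#' A record passes when its EMSC scale lies in `[min_scale, max_scale]`, its
#' residual RMS is at most `max_residual_rms`, and its baseline-corrected
#' amide-I height (maximum corrected absorbance within `amide1_window`) is
#' at least `min_amide1_height`. Defaults follow
#' [default_quality_criteria()].
#'
#' @param min_scale,max_scale EMSC scale bounds (0 < min < max).
#' @param max_residual_rms Residual RMS bound (absorbance units).
#' @param min_amide1_height Minimum corrected absorbance near 1654 cm^-1.
#' @param amide1_window Window around the amide-I band, cm^-1.
#' @return Object of class `"quality_criteria"`.
#' @export
quality_criteria <- function(min_scale = 0.2, max_scale = 5,
                             max_residual_rms = Inf,
                             min_amide1_height = 0.05,
                             amide1_window = c(1634, 1674)) {
  stopifnot(min_scale > 0, min_scale < max_scale,
            max_residual_rms >= 0, min_amide1_height >= 0)
  structure(list(min_scale = min_scale, max_scale = max_scale,
                 max_residual_rms = max_residual_rms,
                 min_amide1_height = min_amide1_height,
                 amide1_window = amide1_window),
            class = "quality_criteria")
}

#' Default quality criteria from fitted spectra
#'
#' Scale in \[0.2, 5\], residual RMS at most 10x the cohort median, amide-I
#' height at least 0.05 absorbance.
#'
#' @param fits An [fit_emsc_table()] result for the cohort.
#' @return A [quality_criteria()].
#' @export
default_quality_criteria <- function(fits) {
  quality_criteria(max_residual_rms = 10 * stats::median(fits$residual_rms))
}

#' Filter spectra by quality
#'
#' Partitions a corrected table into passing and rejected records and logs
#' rejection counts per rule ("scale", "residual", "amide1"). Degenerate
#' all-zero input spectra fail the scale rule (scale 0), never raise.
#'
#' @param table The EMSC-corrected [spectra_table()] (from
#'   [apply_emsc_table()]).
#' @param fits The matching [fit_emsc_table()] result.
#' @param criteria A [quality_criteria()].
#' @return List with `passed` and `rejected` ([spectra_table()]s partitioning
#'   the input) and `log` (named counts per rejection rule; a record may
#'   count under several rules).
#' @export
quality_filter <- function(table, fits, criteria) {
  stopifnot(inherits(table, "spectra_table"), inherits(fits, "emsc_fits"),
            inherits(criteria, "quality_criteria"),
            nrow(fits) == n_spectra(table))
  ax <- unclass(table$axis)
  win <- ax >= criteria$amide1_window[1] & ax <= criteria$amide1_window[2]
  amide1 <- if (any(win)) {
    apply(table$spectra[, win, drop = FALSE], 1, max)
  } else {
    rep(NA_real_, n_spectra(table))
  }
  bad_scale <- !(fits$scale >= criteria$min_scale &
                   fits$scale <= criteria$max_scale)
  bad_resid <- !(fits$residual_rms <= criteria$max_residual_rms)
  bad_amide <- !(!is.na(amide1) & amide1 >= criteria$min_amide1_height)
  reject <- bad_scale | bad_resid | bad_amide
  list(
    passed = subset_spectra(table, !reject),
    rejected = subset_spectra(table, reject),
    log = c(scale = sum(bad_scale), residual = sum(bad_resid),
            amide1 = sum(bad_amide), rejected = sum(reject),
            passed = sum(!reject))
  )
}
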