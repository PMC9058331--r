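#' Pathology labels
#'
#' The four diagnostic groups handled by the package: normal colonic mucosa,
#' adenomatous polyp with low-grade dysplasia, adenomatous polyp with
#' epithelial misplacement (pseudo-invasion), and adenocarcinoma.
#'
#' @return Character vector of the four pathology labels, in progression order.
#' @export
pathology_levels <- function() {
  c("normal", "adenoma", "epithelial_misplacement", "cancer")
}

#' Tissue classes
#'
#' Closed set of histology classes a pixel may be assigned to. "Epithelium"
#' is defined as the union of the nuclear and cytoplasmic classes, see
#' [epithelium_classes()].
#'
#' @return Character vector of tissue class names.
#' @export
tissue_classes <- function() {
  c("nuclear", "cytoplasmic", "mucin", "lamina_propria",
    "submucosa", "stroma", "background")
}

#' @rdname tissue_classes
#' @export
epithelium_classes <- function() c("nuclear", "cytoplasmic")

#' Wavenumber axis
#'
#' A validated, strictly increasing, uniformly spaced wavenumber axis in
#' reciprocal centimetres. Uniform spacing is asserted (to a 1e-9 relative
#' tolerance), never silently assumed.
#'
#' @param values Numeric vector of wavenumbers (cm^-1), length >= 2,
#'   all positive, strictly increasing, uniformly spaced.
#' @return Numeric vector of class `"wn_axis"`.
#' @export
wn_axis <- function(values) {
  values <- as.numeric(unclass(values))
  if (length(values) < 2) {
    stop("a wavenumber axis needs at least 2 points", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("wavenumber values must be finite and > 0", call. = FALSE)
  }
  d <- diff(values)
  if (any(d <= 0)) {
    stop("wavenumber axis must be strictly increasing", call. = FALSE)
  }
  if ((max(d) - min(d)) > 1e-9 * abs(mean(d))) {
    stop("wavenumber axis spacing is not uniform (relative tolerance 1e-9)",
         call. = FALSE)
  }
  structure(values, class = "wn_axis")
}

#' Default fingerprint-region axis
#'
#' 1000 to 1800 cm^-1 sampled every 4 cm^-1 (201 points), matching the
#' fingerprint region and instrument resolution the package emulates.
#'
#' @param low,high Interval endpoints in cm^-1.
#' @param by Sampling interval in cm^-1.
#' @return A [wn_axis()].
#' @export
default_axis <- function(low = 1000, high = 1800, by = 4) {
  wn_axis(seq(low, high, by = by))
}

#' @export
print.wn_axis <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("<wn_axis> %d points, %.6g to %.6g cm^-1, spacing %.6g cm^-1\n",
              length(v), v[1], v[length(v)], v[2] - v[1]))
  invisible(x)
}

assert_pathology <- function(pathology) {
  if (!(is.character(pathology) && length(pathology) == 1 &&
        pathology %in% pathology_levels())) {
    stop("pathology must be one of: ",
         paste(pathology_levels(), collapse = ", "), call. = FALSE)
  }
  pathology
}

#' Hyperspectral absorbance cube
#'
#' One sample's absorbance image cube: a (row, column, band) array with its
#' wavenumber axis, pixel pitch and pathology label. Rows and columns are
#' 0-based with row 0 at the image top; bands are ordered ascending in
#' wavenumber. Absorbance (dimensionless) is the stored quantity.
#'
#' @param sample_id Opaque sample identifier string.
#' @param pathology One of [pathology_levels()].
#' @param axis A [wn_axis()] (coerced if plain numeric).
#' @param data 3-D numeric array indexed (row, column, band); all values
#'   finite; band count must equal `length(axis)`.
#' @param pixel_size Pixel edge length in micrometres (> 0, default 1.1).
#' @return Object of class `"hyper_cube"`.
#' @export
hyper_cube <- function(sample_id, pathology, axis, data, pixel_size = 1.1) {
  if (!is.character(sample_id) || length(sample_id) != 1 || !nzchar(sample_id)) {
    stop("sample_id must be a non-empty string", call. = FALSE)
  }
  assert_pathology(pathology)
  axis <- wn_axis(axis)
  if (!(is.array(data) && length(dim(data)) == 3)) {
    stop("data must be a 3-D array indexed (row, column, band)", call. = FALSE)
  }
  if (dim(data)[3] != length(axis)) {
    stop(sprintf("invariant violated: cube has %d bands but axis has %d points",
                 dim(data)[3], length(axis)), call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("invariant violated: cube contains non-finite absorbance values",
         call. = FALSE)
  }
  if (!(is.numeric(pixel_size) && length(pixel_size) == 1 && pixel_size > 0)) {
    stop("pixel_size must be a single value > 0", call. = FALSE)
  }
  structure(
    list(sample_id = sample_id, pathology = pathology, axis = axis,
         data = data, pixel_size = as.numeric(pixel_size)),
    class = "hyper_cube"
  )
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube> '%s' (%s): %d x %d pixels @ %.3g um, %d bands (%.6g-%.6g cm^-1)\n",
              x$sample_id, x$pathology, d[1], d[2], x$pixel_size, d[3],
              x$axis[1], x$axis[length(x$axis)]))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$data)

#' Flat table of labelled spectra
#'
#' A collection of spectra sharing one wavenumber axis, each carrying its
#' sample id, pathology, tissue class and 0-based pixel coordinates.
#' `(sample_id, row, col)` triplets must be unique.
#'
#' @param axis A [wn_axis()].
#' @param meta data.frame with columns `sample_id`, `pathology`,
#'   `tissue_class`, `row`, `col` (one row per spectrum).
#' @param spectra Numeric matrix, one spectrum per row; `ncol(spectra)`
#'   must equal `length(axis)`.
#' @param tile_shape Optional integer c(rows, cols) recording the image grid
#'   the records came from (kept by [flatten_cube()], used by segmentation).
#' @return Object of class `"spectra_table"`.
#' @export
spectra_table <- function(axis, meta, spectra, tile_shape = NULL) {
  axis <- wn_axis(axis)
  required <- c("sample_id", "pathology", "tissue_class", "row", "col")
  if (!is.data.frame(meta) || !all(required %in% names(meta))) {
    stop("meta must be a data.frame with columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  if (nrow(meta) != nrow(spectra)) {
    stop("meta and spectra disagree on record count", call. = FALSE)
  }
  if (nrow(spectra) > 0 && ncol(spectra) != length(axis)) {
    stop(sprintf("invariant violated: spectra have %d channels but axis has %d points",
                 ncol(spectra), length(axis)), call. = FALSE)
  }
  if (nrow(spectra) == 0 && ncol(spectra) != length(axis)) {
    spectra <- matrix(numeric(0), nrow = 0, ncol = length(axis))
  }
  bad_path <- setdiff(unique(meta$pathology), pathology_levels())
  if (length(bad_path)) {
    stop("unknown pathology label(s): ", paste(bad_path, collapse = ", "),
         call. = FALSE)
  }
  bad_cls <- setdiff(unique(meta$tissue_class), tissue_classes())
  if (length(bad_cls)) {
    stop("unknown tissue class(es): ", paste(bad_cls, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(meta$sample_id, meta$row, meta$col, sep = "\r")
  if (anyDuplicated(key)) {
    stop("invariant violated: duplicate (sample_id, row, col) records",
         call. = FALSE)
  }
  rownames(meta) <- NULL
  structure(
    list(axis = axis, meta = meta, spectra = spectra,
         tile_shape = tile_shape),
    class = "spectra_table"
  )
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("<spectra_table> %d spectra x %d channels (%.6g-%.6g cm^-1)\n",
              nrow(x$spectra), length(x$axis), x$axis[1],
              x$axis[length(x$axis)]))
  if (nrow(x$meta)) {
    cat("  samples:", length(unique(x$meta$sample_id)),
        "| pathologies:", paste(sort(unique(x$meta$pathology)), collapse = ", "),
        "\n")
    cat("  tissue classes:",
        paste(sort(unique(x$meta$tissue_class)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of spectra in a table
#' @param table A [spectra_table()].
#' @return Integer record count.
#' @export
n_spectra <- function(table) nrow(table$spectra)

#' Subset a spectra table by record index
#'
#' @param table A [spectra_table()].
#' @param idx Integer or logical index over records.
#' @return A [spectra_table()] with the selected records.
#' @export
subset_spectra <- function(table, idx) {
  spectra_table(table$axis, table$meta[idx, , drop = FALSE],
                table$spectra[idx, , drop = FALSE],
                tile_shape = table$tile_shape)
}

#' Concatenate spectra tables sharing one axis
#'
#' @param ... [spectra_table()] objects on identical axes.
#' @return A single combined [spectra_table()].
#' @export
bind_spectra <- function(...) {
  tables <- list(...)
  if (length(tables) == 1 && is.list(tables[[1]]) &&
      !inherits(tables[[1]], "spectra_table")) {
    tables <- tables[[1]]
  }
  stopifnot(length(tables) >= 1)
  ax <- tables[[1]]$axis
  for (t in tables) {
    if (!isTRUE(all.equal(unclass(t$axis), unclass(ax), tolerance = 0))) {
      stop("all tables must share one wavenumber axis", call. = FALSE)
    }
  }
  meta <- do.call(rbind, lapply(tables, function(t) t$meta))
  spec <- do.call(rbind, lapply(tables, function(t) t$spectra))
  spectra_table(ax, meta, spec)
}
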