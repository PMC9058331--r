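# On-disk containers. A cube is stored as a single binary container file
# holding named datasets ("axis", "data") and metadata attributes
# ("sample_id", "pathology", "pixel_size_um") plus a format/version tag, via
# R's native serialization; reads validate every key and error naming any
# missing one. Spectra tables round-trip either through the same binary
# container (full precision) or through plain CSV.

CUBE_FORMAT <- "spectropath-cube"
TABLE_FORMAT <- "spectropath-spectra"
FORMAT_VERSION <- 1L

#' Write / read a hyperspectral cube container
#'
#' `write_cube()` stores a [hyper_cube()] in a single binary container file
#' with named datasets `axis` and `data` and attributes `sample_id`,
#' `pathology` and `pixel_size_um`. `read_cube()` validates the container and
#' reconstructs the cube bit-exactly.
#'
#' @param cube A [hyper_cube()].
#' @param path File path to write to / read from.
#' @return `write_cube()` returns `path` invisibly; `read_cube()` returns a
#'   [hyper_cube()].
#' @export
write_cube <- function(cube, path) {
  if (!inherits(cube, "hyper_cube")) {
    # re-validate loose lists so invariant errors surface on write
    cube <- hyper_cube(cube$sample_id, cube$pathology, cube$axis, cube$data,
                       cube$pixel_size)
  }
  payload <- list(
    format = CUBE_FORMAT, version = FORMAT_VERSION,
    axis = as.numeric(unclass(cube$axis)),
    data = cube$data,
    sample_id = cube$sample_id,
    pathology = cube$pathology,
    pixel_size_um = cube$pixel_size
  )
  saveRDS(payload, path, version = 3)
  invisible(path)
}

read_container <- function(path, expected_format, keys) {
  payload <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("format error: '%s' is not a readable container (%s)",
                 path, conditionMessage(e)), call. = FALSE)
  })
  if (!is.list(payload) || !identical(payload$format, expected_format)) {
    stop(sprintf("format error: '%s' is not a %s container",
                 path, expected_format), call. = FALSE)
  }
  missing <- setdiff(keys, names(payload))
  if (length(missing)) {
    stop("format error: container is missing key(s): ",
         paste(sprintf("'%s'", missing), collapse = ", "), call. = FALSE)
  }
  payload
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  payload <- read_container(path, CUBE_FORMAT,
                            c("axis", "data", "sample_id", "pathology",
                              "pixel_size_um"))
  hyper_cube(payload$sample_id, payload$pathology, payload$axis,
             payload$data, payload$pixel_size_um)
}

#' Flatten a cube into a spectra table
#'
#' One record per (unmasked) pixel, in column-major pixel order; tissue class
#' is initialised to `"background"`. Coordinates are 0-based.
#'
#' @param cube A [hyper_cube()].
#' @param mask Optional logical matrix with the cube's spatial shape; only
#'   `TRUE` pixels are emitted.
#' @return A [spectra_table()] whose `tile_shape` records the cube's grid.
#' @export
flatten_cube <- function(cube, mask = NULL) {
  d <- dim(cube$data)
  nr <- d[1]; nc <- d[2]
  if (is.null(mask)) {
    mask <- matrix(TRUE, nr, nc)
  }
  if (!is.logical(mask) || !identical(dim(mask), c(nr, nc))) {
    stop(sprintf("invariant violated: mask shape must be %d x %d", nr, nc),
         call. = FALSE)
  }
  idx <- which(mask)                      # column-major pixel indices
  X <- matrix(cube$data, nrow = nr * nc)  # row i <-> pixel (r, c), i = r + (c-1)*nr
  rows0 <- (idx - 1L) %% nr
  cols0 <- (idx - 1L) %/% nr
  meta <- data.frame(
    sample_id = rep(cube$sample_id, length(idx)),
    pathology = rep(cube$pathology, length(idx)),
    tissue_class = rep("background", length(idx)),
    row = as.integer(rows0), col = as.integer(cols0),
    stringsAsFactors = FALSE
  )
  spectra_table(cube$axis, meta, X[idx, , drop = FALSE],
                tile_shape = c(nr, nc))
}

#' Write / read a spectra table
#'
#' Two formats are supported, chosen by `format` (default from the file
#' extension): `"bin"`, the package's binary container (full-precision round
#' trip), and `"csv"`, a plain-text table with the metadata columns followed
#' by one column per wavenumber (values preserved to at least 9 significant
#' digits; the axis is recovered from the header).
#'
#' @param table A [spectra_table()].
#' @param path File path.
#' @param format `"bin"` or `"csv"`; `NULL` picks `"csv"` for `.csv` paths
#'   and `"bin"` otherwise.
#' @return `write_spectra()` returns `path` invisibly; `read_spectra()`
#'   returns a [spectra_table()].
#' @export
write_spectra <- function(table, path, format = NULL) {
  stopifnot(inherits(table, "spectra_table"))
  format <- format %||% (if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "bin")
  format <- match.arg(format, c("bin", "csv"))
  if (format == "bin") {
    payload <- list(
      format = TABLE_FORMAT, version = FORMAT_VERSION,
      axis = as.numeric(unclass(table$axis)),
      meta = table$meta, spectra = table$spectra,
      tile_shape = table$tile_shape
    )
    saveRDS(payload, path, version = 3)
  } else {
    df <- data.frame(table$meta,
                     as.data.frame(table$spectra), check.names = FALSE)
    names(df) <- c(names(table$meta),
                   paste0("wn_", format(unclass(table$axis), digits = 15,
                                        trim = TRUE, scientific = FALSE)))
    data.table::fwrite(df, path)
  }
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "bin")
  format <- match.arg(format, c("bin", "csv"))
  if (format == "bin") {
    payload <- read_container(path, TABLE_FORMAT, c("axis", "meta", "spectra"))
    return(spectra_table(payload$axis, payload$meta, payload$spectra,
                         tile_shape = payload$tile_shape))
  }
  df <- tryCatch(
    data.table::fread(path, data.table = FALSE, fill = FALSE),
    error = function(e) stop("format error: ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("format error: ", conditionMessage(w), call. = FALSE)
  )
  required <- c("sample_id", "pathology", "tissue_class", "row", "col")
  if (!all(required %in% names(df))) {
    stop("format error: CSV is missing metadata column(s): ",
         paste(setdiff(required, names(df)), collapse = ", "), call. = FALSE)
  }
  wn_cols <- grep("^wn_", names(df), value = TRUE)
  if (length(wn_cols) < 2) {
    stop("format error: CSV header defines fewer than 2 wavenumber columns",
         call. = FALSE)
  }
  axis <- as.numeric(sub("^wn_", "", wn_cols))
  if (anyNA(axis)) {
    stop("format error: unparseable wavenumber column name(s)", call. = FALSE)
  }
  spec <- as.matrix(df[, wn_cols, drop = FALSE])
  meta <- df[, required, drop = FALSE]
  meta$sample_id <- as.character(meta$sample_id)
  meta$pathology <- as.character(meta$pathology)
  meta$tissue_class <- as.character(meta$tissue_class)
  spectra_table(axis, meta, spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
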