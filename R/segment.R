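# Per-image K-means segmentation of corrected spectra. Lloyd's algorithm
# with k-means++ seeding, best of several restarts by within-cluster sum of
# squares; the objective is asserted non-increasing at every iteration and
# empty clusters are re-seeded from the farthest point.

squared_dist <- function(X, C) {
  # n x k matrix of squared Euclidean distances
  outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- squared_dist(X, X[centers[1], , drop = FALSE])[, 1]
    for (j in 2:k) {
      d2 <- pmax(d2, 0)
      centers[j] <- if (sum(d2) > 0) {
        sample.int(n, 1, prob = d2)
      } else {
        sample.int(n, 1)
      }
      d2 <- pmin(d2, squared_dist(X, X[centers[j], , drop = FALSE])[, 1])
    }
  }
  X[centers, , drop = FALSE]
}

lloyd_once <- function(X, k, max_iter, tol) {
  C <- kmeanspp_init(X, k)
  wcss_prev <- Inf
  assign <- rep(1L, nrow(X))
  for (iter in seq_len(max_iter)) {
    d2 <- squared_dist(X, C)
    assign <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters from the farthest point
    repeat {
      empty <- setdiff(seq_len(k), unique(assign))
      if (!length(empty)) break
      cur_d2 <- d2[cbind(seq_len(nrow(X)), assign)]
      far <- which.max(cur_d2)
      C[empty[1], ] <- X[far, ]
      d2[, empty[1]] <- squared_dist(X, C[empty[1], , drop = FALSE])[, 1]
      assign <- max.col(-d2, ties.method = "first")
    }
    wcss <- sum(pmax(d2[cbind(seq_len(nrow(X)), assign)], 0))
    if (wcss > wcss_prev * (1 + 1e-9) + 1e-12) {
      stop("internal error: k-means objective increased", call. = FALSE)
    }
    for (j in seq_len(k)) {
      C[j, ] <- colMeans(X[assign == j, , drop = FALSE])
    }
    if (is.finite(wcss_prev) &&
        (wcss_prev - wcss) <= tol * max(wcss_prev, .Machine$double.eps)) {
      wcss_prev <- wcss
      break
    }
    wcss_prev <- wcss
  }
  # final assignment consistent with final centroids
  d2 <- squared_dist(X, C)
  assign <- max.col(-d2, ties.method = "first")
  for (j in seq_len(k)) {
    if (any(assign == j)) C[j, ] <- colMeans(X[assign == j, , drop = FALSE])
  }
  wcss <- sum(pmax(squared_dist(X, C)[cbind(seq_len(nrow(X)), assign)], 0))
  list(assign = assign, centers = C, wcss = wcss)
}

#' K-means segmentation of one sample's spectra
#'
#' Lloyd's algorithm with k-means++ seeding on Euclidean distance over the
#' (EMSC-corrected) spectra of a single sample; the best of `restarts` runs
#' by within-cluster sum of squares is kept. Deterministic under `seed`.
#' Cluster labels start unassigned; see [label_clusters()].
#'
#' @param table A [spectra_table()] holding exactly one sample.
#' @param k Number of clusters (1 <= k <= record count).
#' @param seed Integer seed (local to this call).
#' @param restarts Independent restarts (default 10).
#' @param max_iter Iteration cap per restart (default 300).
#' @param tol Relative WCSS change convergence tolerance (default 1e-6).
#' @return Object of class `"cluster_map"`: 0-based `assignments` image
#'   (-1 where no record exists), `k`, `centroids` (k x channels),
#'   empty `label_map`, `wcss`, `axis`, `sample_id`.
#' @export
kmeans_segment <- function(table, k, seed = 1, restarts = 10,
                           max_iter = 300, tol = 1e-6) {
  stopifnot(inherits(table, "spectra_table"))
  sid <- unique(table$meta$sample_id)
  if (length(sid) != 1) {
    stop("kmeans_segment expects spectra from exactly one sample",
         call. = FALSE)
  }
  n <- n_spectra(table)
  if (!(k >= 1 && k <= n)) {
    stop(sprintf("k must satisfy 1 <= k <= %d records", n), call. = FALSE)
  }
  X <- table$spectra
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  best <- NULL
  all_wcss <- numeric(restarts)
  for (r in seq_len(restarts)) {
    run <- lloyd_once(X, k, max_iter, tol)
    all_wcss[r] <- run$wcss
    if (is.null(best) || run$wcss < best$wcss) best <- run
  }
  shape <- table$tile_shape %||% c(max(table$meta$row) + 1L,
                                   max(table$meta$col) + 1L)
  assignments <- matrix(-1L, shape[1], shape[2])
  assignments[cbind(table$meta$row + 1L, table$meta$col + 1L)] <-
    as.integer(best$assign - 1L)
  structure(list(sample_id = sid, assignments = assignments, k = as.integer(k),
                 centroids = best$centers, label_map = character(0),
                 wcss = best$wcss, restart_wcss = all_wcss, axis = table$axis),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> '%s': %d x %d image, k = %d, WCSS = %.6g\n",
              x$sample_id, nrow(x$assignments), ncol(x$assignments), x$k,
              x$wcss))
  if (length(x$label_map)) {
    cat("  labels:", paste(sprintf("%s=%s", names(x$label_map), x$label_map),
                           collapse = ", "), "\n")
  } else {
    cat("  labels: <unassigned>\n")
  }
  invisible(x)
}

#' Scan cluster counts and recommend one
#'
#' Runs [kmeans_segment()] for every k in `k_range` and scores each
#' segmentation by mean silhouette width on a fixed-seed subsample of at
#' most `max_silhouette_n` spectra. All candidates are returned so the
#' recommendation can be overridden (cluster images are ultimately
#' validated by a pathologist, not a score). A constant image (all spectra
#' identical) has no defined silhouette: k = 1 is recommended with a
#' warning.
#'
#' @param table One sample's [spectra_table()].
#' @param k_range Candidate cluster counts (default 2..8).
#' @param seed Integer seed for clustering and subsampling.
#' @param max_silhouette_n Silhouette subsample cap (default 2000).
#' @param ... Passed to [kmeans_segment()].
#' @return List with `maps` (per-k [kmeans_segment()] results), `silhouette`
#'   (named mean widths) and `recommended` (k).
#' @export
scan_k <- function(table, k_range = 2:8, seed = 1,
                   max_silhouette_n = 2000, ...) {
  stopifnot(inherits(table, "spectra_table"), all(k_range >= 1))
  n <- n_spectra(table)
  if (max(k_range) > n) stop("max(k_range) exceeds the record count",
                             call. = FALSE)
  X <- table$spectra
  if (max(apply(X, 2, stats::var)) <= .Machine$double.eps) {
    warning("all spectra identical; silhouette undefined, recommending k = 1",
            call. = FALSE)
    return(list(maps = list(`1` = kmeans_segment(table, 1, seed = seed, ...)),
                silhouette = stats::setNames(NA_real_, "1"),
                recommended = 1L))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  sub <- if (n > max_silhouette_n) sort(sample.int(n, max_silhouette_n)) else seq_len(n)
  dsub <- stats::dist(X[sub, , drop = FALSE])
  maps <- list(); sil <- stats::setNames(numeric(length(k_range)),
                                         as.character(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    cm <- kmeans_segment(table, k, seed = seed + i, ...)
    maps[[as.character(k)]] <- cm
    cl <- cm$assignments[cbind(table$meta$row + 1L,
                               table$meta$col + 1L)][sub] + 1L
    sil[i] <- if (length(unique(cl)) < 2) {
      -Inf
    } else {
      mean(cluster::silhouette(cl, dsub)[, "sil_width"])
    }
  }
  list(maps = maps, silhouette = sil,
       recommended = k_range[which.max(sil)])
}

occurring_clusters <- function(cmap) {
  sort(unique(cmap$assignments[cmap$assignments >= 0]))
}

#' Assign histology classes to clusters
#'
#' Sets the cluster -> tissue-class labelling of a [kmeans_segment()] map.
#' Many-to-one mappings are allowed (e.g. several clusters -> cytoplasmic).
#'
#' @param cmap A `"cluster_map"`.
#' @param labels Named character vector or list: cluster index (as character,
#'   0-based) -> one of [tissue_classes()]. Must cover every occurring
#'   cluster index.
#' @return The labelled `"cluster_map"`.
#' @export
label_clusters <- function(cmap, labels) {
  stopifnot(inherits(cmap, "cluster_map"))
  labels <- unlist(labels)
  occ <- occurring_clusters(cmap)
  missing <- setdiff(as.character(occ), names(labels))
  if (length(missing)) {
    stop("labels missing for cluster(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(labels), tissue_classes())
  if (length(bad)) {
    stop("unknown tissue class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cmap$label_map <- labels
  cmap
}

#' Label clusters from a ground-truth map by majority vote
#'
#' For synthetic data: each occurring cluster is labelled with the modal
#' ground-truth tissue class of its member pixels. This automates the role
#' the expert pathologist plays for real cluster images.
#'
#' @param cmap A `"cluster_map"`.
#' @param truth_map Character matrix of ground-truth tissue classes with the
#'   map's spatial shape.
#' @return The labelled `"cluster_map"`.
#' @export
majority_label_clusters <- function(cmap, truth_map) {
  stopifnot(inherits(cmap, "cluster_map"),
            identical(dim(truth_map), dim(cmap$assignments)))
  occ <- occurring_clusters(cmap)
  labels <- vapply(occ, function(cl) {
    classes <- truth_map[cmap$assignments == cl]
    names(which.max(table(classes)))
  }, character(1))
  label_clusters(cmap, stats::setNames(labels, as.character(occ)))
}

#' Extract spectra whose cluster carries a wanted histology class
#'
#' Keeps the records whose pixel's cluster label is in `classes` and stamps
#' the tissue_class field from the cluster label. Supports the standard
#' extraction modes: epithelium = \{nuclear, cytoplasmic\}, nuclear-only,
#' and epithelium-plus-stroma variants.
#'
#' @param table The sample's [spectra_table()] (same records the map was
#'   built from).
#' @param cmap A labelled `"cluster_map"`.
#' @param classes Non-empty character vector of [tissue_classes()].
#' @return A [spectra_table()] of the selected records.
#' @export
extract_class_spectra <- function(table, cmap, classes) {
  stopifnot(inherits(table, "spectra_table"), inherits(cmap, "cluster_map"),
            length(classes) >= 1)
  if (!length(cmap$label_map)) {
    stop("cluster map is unlabelled; call label_clusters() first",
         call. = FALSE)
  }
  bad <- setdiff(classes, tissue_classes())
  if (length(bad)) stop("unknown tissue class(es): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cl <- cmap$assignments[cbind(table$meta$row + 1L, table$meta$col + 1L)]
  uncovered <- setdiff(as.character(unique(cl[cl >= 0])),
                       names(cmap$label_map))
  if (length(uncovered)) {
    stop("cluster(s) without a label: ", paste(uncovered, collapse = ", "),
         call. = FALSE)
  }
  lab <- rep(NA_character_, length(cl))
  lab[cl >= 0] <- unname(cmap$label_map[as.character(cl[cl >= 0])])
  keep <- !is.na(lab) & lab %in% classes
  out <- subset_spectra(table, keep)
  out$meta$tissue_class <- lab[keep]
  out
}

#' Digital stain of a cluster map
#'
#' Deterministic colour per cluster index (a fixed palette, extended with
#' evenly spaced hues for large k); masked pixels are black.
#'
#' @param cmap A `"cluster_map"`.
#' @param palette Optional vector of colours, one per cluster.
#' @return rows x cols x 3 numeric array of RGB values in \[0, 1\].
#' @export
render_digital_stain <- function(cmap, palette = NULL) {
  stopifnot(inherits(cmap, "cluster_map"))
  palette <- palette %||% stain_palette(cmap$k)
  stopifnot(length(palette) >= cmap$k)
  rgb <- grDevices::col2rgb(palette[seq_len(cmap$k)]) / 255
  a <- cmap$assignments
  img <- array(0, dim = c(nrow(a), ncol(a), 3))
  for (ch in 1:3) {
    plane <- matrix(0, nrow(a), ncol(a))
    plane[a >= 0] <- rgb[ch, a[a >= 0] + 1L]
    img[, , ch] <- plane
  }
  img
}

stain_palette <- function(k) {
  base <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
            "#A65628", "#F781BF", "#00CED1", "#FFD700", "#999999",
            "#8B0000", "#006400")
  if (k <= length(base)) base[seq_len(k)] else grDevices::rainbow(k)
}

#' @export
plot.cluster_map <- function(x, ...) {
  img <- render_digital_stain(x)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, ncol(x$assignments)),
                        ylim = c(0, nrow(x$assignments)), asp = 1)
  graphics::rasterImage(img, 0, 0, ncol(x$assignments), nrow(x$assignments),
                        interpolate = FALSE)
  graphics::title(main = sprintf("%s (k = %d)", x$sample_id, x$k), ...)
  invisible(x)
}

#' Dendrogram over cluster centroids
#'
#' Agglomerative tree over the k centroids (Ward linkage, Euclidean
#' distance), mirroring the cluster-heterogeneity dendrograms shown under
#' digitally stained images; serialised as Newick text with leaves
#' c0..c(k-1).
#'
#' @param cmap A `"cluster_map"` with >= 1 cluster.
#' @return List of class `"centroid_dendrogram"` with `hclust` (NULL for
#'   k = 1) and `newick`.
#' @export
centroid_dendrogram <- function(cmap) {
  stopifnot(inherits(cmap, "cluster_map"), cmap$k >= 1)
  if (cmap$k == 1) {
    return(structure(list(hclust = NULL, newick = "(c0);"),
                     class = "centroid_dendrogram"))
  }
  C <- cmap$centroids
  rownames(C) <- paste0("c", seq_len(cmap$k) - 1L)
  hc <- stats::hclust(stats::dist(C), method = "ward.D2")
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, newick = newick),
            class = "centroid_dendrogram")
}

#' @export
print.centroid_dendrogram <- function(x, ...) {
  cat("<centroid_dendrogram>", x$newick, "\n")
  invisible(x)
}

#' @export
plot.centroid_dendrogram <- function(x, ...) {
  if (is.null(x$hclust)) {
    graphics::plot.new()
    graphics::text(0.5, 0.5, "single cluster: c0")
  } else {
    graphics::plot(x$hclust, ...)
  }
  invisible(x)
}
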