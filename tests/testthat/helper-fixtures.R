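# Shared fixtures and independent oracles. Fixtures are built in code; the
# oracles are deliberately naive (normal equations, explicit sums of squares,
# pairwise concordance counts) so they stay independent of the implementation
# paths they check.

rand_cube <- function(seed = 1, nr = 4, nc = 4, nb = 201, low = 1000, by = 4) {
  set.seed(seed)
  hyper_cube(sprintf("cube_%03d", seed),
             sample(pathology_levels(), 1),
             seq(low, by = by, length.out = nb),
             array(runif(nr * nc * nb), dim = c(nr, nc, nb)),
             pixel_size = 1.1)
}

# quick spectra_table from a matrix: records laid out on a grid
make_table <- function(X, axis, sample_id = "s1", pathology = "normal",
                       tissue_class = "background", nrow_grid = NULL) {
  n <- nrow(X)
  nr <- nrow_grid %||% ceiling(sqrt(n))
  rows <- (seq_len(n) - 1L) %% nr
  cols <- (seq_len(n) - 1L) %/% nr
  spectra_table(axis,
                data.frame(sample_id = sample_id, pathology = pathology,
                           tissue_class = tissue_class,
                           row = rows, col = cols),
                X, tile_shape = c(nr, max(cols) + 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal cross-validation result for evaluating metrics/ROC in isolation
make_cv <- function(true_spec, pred_spec, sample_id_spec, classes,
                    posterior = NULL, ld = NULL,
                    true_samp = NULL, pred_samp = NULL) {
  spectra <- data.frame(sample_id = sample_id_spec,
                        fold = as.integer(factor(sample_id_spec)),
                        true = true_spec, predicted = pred_spec)
  if (is.null(posterior)) {
    posterior <- matrix(1 / length(classes), nrow(spectra), length(classes))
    colnames(posterior) <- classes
    posterior[cbind(seq_len(nrow(spectra)),
                    match(pred_spec, classes))] <- 0.9
    posterior <- posterior / rowSums(posterior)
  }
  colnames(posterior) <- paste0("posterior.", classes)
  if (is.null(ld)) {
    ld <- matrix(stats::rnorm(nrow(spectra) * (length(classes) - 1)),
                 nrow(spectra))
  }
  colnames(ld) <- paste0("ld", seq_len(ncol(ld)))
  spectra <- data.frame(spectra, posterior, ld, check.names = FALSE)
  sids <- unique(sample_id_spec)
  samples <- data.frame(sample_id = sids,
                        fold = seq_along(sids),
                        true = true_samp %||%
                          true_spec[match(sids, sample_id_spec)],
                        predicted = pred_samp %||%
                          vapply(sids, function(s) {
                            names(which.max(table(pred_spec[sample_id_spec == s])))
                          }, character(1)),
                        decisive = TRUE)
  fr <- t(vapply(sids, function(s) {
    tab <- table(factor(pred_spec[sample_id_spec == s], levels = classes))
    as.numeric(tab / sum(tab))
  }, numeric(length(classes))))
  colnames(fr) <- paste0("fraction.", classes)
  samples <- data.frame(samples, fr, check.names = FALSE)
  structure(list(spectra = spectra, samples = samples, classes = classes,
                 config = list(groups = classes, n_folds = length(sids))),
            class = "spath_cv")
}

# --- independent oracles ----------------------------------------------------

ls_oracle <- function(design, y) {
  solve(t(design) %*% design, t(design) %*% y)
}

anova_f_oracle <- function(x, g) {
  g <- factor(g)
  n <- length(x); k <- nlevels(g)
  grand <- mean(x)
  ss_between <- sum(tapply(x, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_within <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  c(f = f, p = p)
}

auc_concordance <- function(scores_pos, scores_neg) {
  cmp <- outer(scores_pos, scores_neg, function(a, b) {
    (a > b) + 0.5 * (a == b)
  })
  mean(cmp)
}

# synthetic one-sample image with given class spectra + white noise
class_image_table <- function(class_means, tile = c(24, 24), noise_sd = 0.01,
                              axis = default_axis(), seed = 1,
                              pathology = "normal") {
  set.seed(seed)
  n <- prod(tile)
  lab <- sample(colnames(class_means), n, replace = TRUE)
  X <- t(class_means[, lab]) +
    matrix(stats::rnorm(n * nrow(class_means), 0, noise_sd),
           ncol = nrow(class_means))
  tab <- make_table(X, axis, pathology = pathology, nrow_grid = tile[1])
  attr(tab, "true_labels") <- lab
  tab
}
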