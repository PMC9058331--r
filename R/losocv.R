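# Leave-one-sample-out cross-validation: every fold refits the whole
# PCA -> ANOVA -> LDA chain on the training samples' spectra only, predicts
# all spectra of the held-out sample, and records both per-spectrum calls
# and the sample-level majority vote. A no-leakage audit asserts in every
# fold that the held-out sample contributed nothing to fitting.

#' Leave-one-sample-out cross-validation of the PCA-ANOVA-LDA classifier
#'
#' @param table Extracted [spectra_table()] spanning several samples (e.g.
#'   epithelium spectra from [extract_class_spectra()]).
#' @param groups Optional subset of [pathology_levels()] to model (default:
#'   all present). Supports the standard designs: the 4-group epithelium
#'   model and 2-group (e.g. epithelial misplacement vs cancer) epithelium
#'   or nuclear-only models.
#' @param n_components,alpha,max_keep,ridge,priors Passed to [pcalda()].
#' @param global_pca If TRUE, PCA is fit once on all spectra (training and
#'   test) and reused across folds — the leaky variant, for comparison only.
#'   ANOVA selection and LDA remain fold-scoped. Default FALSE.
#' @param subsample Optional cap on spectra used per training sample
#'   (fixed-seed subsampling for tractability at clinical scale); default
#'   no subsampling.
#' @param balance_groups If TRUE (default), every fold's training groups are
#'   subsampled to the size of the smallest group (fixed-seed, fold-scoped).
#'   Holding a sample out leaves its own group with fewer training spectra
#'   than the others; the higher variance of that group's fitted mean makes
#'   the discriminant's quadratic penalty systematically disfavour the
#'   held-out class (the leave-one-out pessimistic bias), which majority
#'   voting then amplifies. Balancing removes the asymmetry.
#' @param seed Integer seed for subsampling and balancing.
#' @return Object of class `"spath_cv"`: `spectra` (per-spectrum data.frame
#'   with true/predicted classes, posteriors and LD scores), `samples`
#'   (per-sample vote fractions, majority prediction, decisive flag),
#'   `classes`, `config`.
#' @export
losocv <- function(table, groups = NULL, n_components = 50, alpha = 0.05,
                   max_keep = 25, ridge = NULL, priors = NULL,
                   global_pca = FALSE, subsample = NULL,
                   balance_groups = TRUE, seed = 1) {
  stopifnot(inherits(table, "spectra_table"))
  groups <- groups %||% intersect(pathology_levels(),
                                  unique(table$meta$pathology))
  stopifnot(length(groups) >= 2, all(groups %in% pathology_levels()))
  keep <- table$meta$pathology %in% groups
  table <- subset_spectra(table, keep)
  if (n_spectra(table) == 0) stop("no spectra in the requested groups",
                                  call. = FALSE)

  meta <- table$meta
  sample_path <- unique(meta[, c("sample_id", "pathology")])
  per_group <- table(sample_path$pathology)
  if (any(per_group < 2)) {
    stop("every group needs >= 2 samples to train after holdout; short: ",
         paste(names(per_group)[per_group < 2], collapse = ", "),
         call. = FALSE)
  }
  samples <- sample_path$sample_id
  classes <- intersect(pathology_levels(), groups)

  X <- table$spectra
  labels <- factor(meta$pathology, levels = classes)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  use <- rep(TRUE, nrow(X))
  if (!is.null(subsample)) {
    set.seed(seed)
    for (s in samples) {
      idx <- which(meta$sample_id == s)
      if (length(idx) > subsample) {
        use[idx] <- FALSE
        use[sample(idx, subsample)] <- TRUE
      }
    }
  }

  pca_all <- if (global_pca) fit_pca(X, n_components) else NULL

  spec_rows <- list(); samp_rows <- list()
  for (fi in seq_along(samples)) {
    s <- samples[fi]
    test_idx <- which(meta$sample_id == s)
    train_idx <- which(meta$sample_id != s & use)
    # no-leakage audit
    stopifnot(!any(meta$sample_id[train_idx] == s),
              length(intersect(train_idx, test_idx)) == 0)
    if (balance_groups) {
      set.seed((seed %% 1000000L) * 1000L + fi)
      sizes <- table(labels[train_idx])
      nmin <- min(sizes)
      train_idx <- unlist(lapply(classes, function(cl) {
        idx <- train_idx[labels[train_idx] == cl]
        if (length(idx) > nmin) sample(idx, nmin) else idx
      }), use.names = FALSE)
    }
    model <- pcalda(X[train_idx, , drop = FALSE], labels[train_idx],
                    n_components = n_components, alpha = alpha,
                    max_keep = max_keep, ridge = ridge, priors = priors,
                    pca = pca_all)
    pred <- predict(model, X[test_idx, , drop = FALSE])
    vote <- majority_vote(pred$class, pred$posterior)
    post <- pred$posterior
    colnames(post) <- paste0("posterior.", colnames(post))
    # LD direction count can fall below classes - 1 when few components
    # were selected; pad so folds stack
    ld <- matrix(NA_real_, length(test_idx), length(classes) - 1L)
    take <- min(ncol(pred$ld), ncol(ld))
    ld[, seq_len(take)] <- pred$ld[, seq_len(take)]
    colnames(ld) <- paste0("ld", seq_len(ncol(ld)))
    spec_rows[[fi]] <- data.frame(
      sample_id = s, fold = fi,
      true = as.character(meta$pathology[test_idx]),
      predicted = as.character(pred$class),
      post, ld, check.names = FALSE
    )
    fr <- stats::setNames(rep(0, length(classes)), classes)
    fr[names(vote$fractions)] <- vote$fractions
    samp_rows[[fi]] <- data.frame(
      sample_id = s, fold = fi,
      true = sample_path$pathology[fi],
      predicted = vote$prediction,
      decisive = vote$decisive,
      t(fr), check.names = FALSE
    )
  }
  spectra <- do.call(rbind, spec_rows)
  samples_df <- do.call(rbind, samp_rows)
  names(samples_df)[match(classes, names(samples_df))] <-
    paste0("fraction.", classes)
  structure(list(
    spectra = spectra, samples = samples_df, classes = classes,
    config = list(groups = groups, n_components = n_components,
                  alpha = alpha, max_keep = max_keep,
                  global_pca = global_pca, subsample = subsample,
                  seed = seed, n_folds = length(samples))
  ), class = "spath_cv")
}

#' @export
print.spath_cv <- function(x, ...) {
  acc_sp <- mean(x$spectra$predicted == x$spectra$true)
  acc_sa <- mean(x$samples$predicted == x$samples$true)
  cat(sprintf("<spath_cv> %d folds over %s\n", x$config$n_folds,
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  per-spectrum accuracy: %.1f%% (%d spectra)\n",
              100 * acc_sp, nrow(x$spectra)))
  cat(sprintf("  majority-vote accuracy: %.1f%% (%d samples, %d decisive)\n",
              100 * acc_sa, nrow(x$samples), sum(x$samples$decisive)))
  invisible(x)
}

#' @export
summary.spath_cv <- function(object, ...) {
  out <- list(
    spectrum = classification_metrics(confusion(object, "spectrum")),
    sample = classification_metrics(confusion(object, "sample"))
  )
  class(out) <- "summary.spath_cv"
  out
}

#' @export
print.summary.spath_cv <- function(x, ...) {
  for (lev in names(x)) {
    cat("==", lev, "level ==\n")
    print(x[[lev]])
  }
  invisible(x)
}

#' @export
plot.spath_cv <- function(x, ...) {
  df <- ld_scatter(x)
  if (!"ld2" %in% names(df)) {
    graphics::stripchart(ld1 ~ factor(true, levels = x$classes), data = df,
                         vertical = TRUE, method = "jitter", pch = 16,
                         col = grDevices::adjustcolor(
                           stain_palette(length(x$classes)), 0.5),
                         xlab = "group", ylab = "LD1", ...)
  } else {
    cols <- stain_palette(length(x$classes))[
      as.integer(factor(df$true, levels = x$classes))]
    graphics::plot(df$ld1, df$ld2, col = grDevices::adjustcolor(cols, 0.5),
                   pch = 16, xlab = "LD1", ylab = "LD2", ...)
    graphics::legend("topright", legend = x$classes,
                     col = stain_palette(length(x$classes)), pch = 16,
                     bty = "n")
  }
  invisible(x)
}
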