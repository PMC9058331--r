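# The supervised chain: PCA on spectra, one-way ANOVA to keep up to 25
# component scores that differ between pathology groups at the 5% level,
# then multiclass LDA with ridge-regularised pooled covariance. pcalda()
# fits the whole chain; predict() projects new spectra through it.

as_matrix_input <- function(x) {
  if (inherits(x, "spectra_table")) x$spectra else as.matrix(x)
}

#' Principal component analysis of spectra
#'
#' Mean-centred PCA via singular value decomposition, keeping
#' `min(n_components, rank)` components. Loadings are orthonormal and
#' sign-fixed (the largest-magnitude entry of each loading is positive) so
#' results are deterministic.
#'
#' @param x Numeric matrix (one spectrum per row) or [spectra_table()],
#'   with >= 2 records.
#' @param n_components Cap on the number of components kept (default 50).
#' @return Object of class `"spath_pca"`: `center`, `loadings`
#'   (channels x k), `explained_variance` (fractions over all components,
#'   non-increasing), `k`.
#' @export
fit_pca <- function(x, n_components = 50) {
  X <- as_matrix_input(x)
  if (nrow(X) < 2) stop("PCA needs at least 2 records", call. = FALSE)
  stopifnot(n_components >= 1)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  k <- min(n_components, max(rank, 1L))
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
    }
  }
  colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(center = center, loadings = loadings,
                 explained_variance = sv$d^2 / sum(sv$d^2),
                 singular_values = sv$d, k = k),
            class = "spath_pca")
}

#' @export
print.spath_pca <- function(x, ...) {
  cat(sprintf("<spath_pca> %d components; leading explained-variance fractions: %s\n",
              x$k, paste(sprintf("%.3f", utils::head(x$explained_variance, 5)),
                         collapse = ", ")))
  invisible(x)
}

#' Project spectra onto PCA components
#'
#' @param pca A [fit_pca()] model.
#' @param x Matrix or [spectra_table()] on the training axis.
#' @return Score matrix (records x components).
#' @export
project_pca <- function(pca, x) {
  X <- as_matrix_input(x)
  if (ncol(X) != length(pca$center)) {
    stop("spectra are not on the training axis", call. = FALSE)
  }
  sweep(X, 2, pca$center) %*% pca$loadings
}

#' Select components by one-way ANOVA across pathology groups
#'
#' Each component's scores are tested with a fixed-effects one-way ANOVA
#' F-test across the groups; components with p < `alpha` are kept, at most
#' `max_keep` of them, smallest p first.
#'
#' @param scores Matrix of component scores (records x components).
#' @param labels Pathology label per record (factor or character); >= 2
#'   groups, each with >= 2 records.
#' @param alpha Significance level (default 0.05, i.e. the 95% level).
#' @param max_keep Cap on selected components (default 25).
#' @return Object of class `"spath_selection"`: `indices` (sorted by
#'   ascending p, ties by component order), `p_values`, `f_values`,
#'   `alpha`, `max_keep`.
#' @export
anova_select <- function(scores, labels, alpha = 0.05, max_keep = 25) {
  scores <- as.matrix(scores)
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2) stop("ANOVA selection needs >= 2 groups",
                                call. = FALSE)
  if (any(table(labels) < 2)) {
    stop("every group needs >= 2 records for ANOVA", call. = FALSE)
  }
  m <- ncol(scores)
  p_values <- f_values <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    ft <- tryCatch(stats::oneway.test(scores[, j] ~ labels, var.equal = TRUE),
                   error = function(e) NULL)
    if (!is.null(ft) && is.finite(ft$statistic)) {
      f_values[j] <- unname(ft$statistic)
      p_values[j] <- unname(ft$p.value)
    }
  }
  cand <- which(!is.na(p_values) & p_values < alpha)
  cand <- cand[order(p_values[cand], cand)]
  indices <- utils::head(cand, max_keep)
  structure(list(indices = indices, p_values = p_values,
                 f_values = f_values, alpha = alpha, max_keep = max_keep),
            class = "spath_selection")
}

#' @export
print.spath_selection <- function(x, ...) {
  cat(sprintf("<spath_selection> %d of %d components at alpha = %g (cap %d)\n",
              length(x$indices), length(x$p_values), x$alpha, x$max_keep))
  if (length(x$indices)) {
    cat("  indices:", paste(x$indices, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Multiclass linear discriminant analysis
#'
#' Classic LDA on selected component scores: class means, pooled
#' within-class covariance (ridge-regularised), linear discriminant
#' functions with equal priors by default, and at most `classes - 1`
#' discriminant directions for LD score plots.
#'
#' @param scores Matrix (records x features).
#' @param labels Class label per record (>= 2 classes).
#' @param ridge Ridge added to the pooled covariance diagonal; default
#'   `1e-6 * trace(cov)/dim`. With `ridge = 0` a singular covariance is an
#'   error advising a positive ridge.
#' @param priors Named class priors (default equal; must sum to 1).
#' @return Object of class `"spath_lda"`.
#' @export
fit_lda <- function(scores, labels, ridge = NULL, priors = NULL) {
  X <- as.matrix(scores)
  labels <- droplevels(factor(labels))
  g <- nlevels(labels)
  if (g < 2) stop("LDA needs >= 2 classes", call. = FALSE)
  d <- ncol(X); n <- nrow(X)
  classes <- levels(labels)
  if (is.null(priors)) {
    priors <- stats::setNames(rep(1 / g, g), classes)
  } else {
    stopifnot(abs(sum(priors) - 1) < 1e-8)
    priors <- priors[classes]
  }
  means <- t(sapply(classes, function(cl) colMeans(X[labels == cl, , drop = FALSE])))
  if (d == 1) means <- matrix(means, ncol = 1, dimnames = list(classes, NULL))
  Sw <- matrix(0, d, d)
  for (cl in classes) {
    Xc <- sweep(X[labels == cl, , drop = FALSE], 2, means[cl, ])
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / (n - g)
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(Sw)) / d
  Sreg <- Sw + diag(ridge, d)
  cov_inv <- tryCatch(solve(Sreg), error = function(e) {
    stop("pooled within-class covariance is singular; refit with ridge > 0",
         call. = FALSE)
  })
  # discriminant directions: sphere within-class, then diagonalise the
  # between-class covariance of the sphered means
  ev <- eigen(Sreg, symmetric = TRUE)
  if (any(ev$values <= 0)) {
    stop("pooled within-class covariance is not positive definite; increase ridge",
         call. = FALSE)
  }
  W <- ev$vectors %*% diag(1 / sqrt(ev$values), d) %*% t(ev$vectors)
  grand <- colSums(means * priors)
  Ms <- sweep(means, 2, grand) %*% W
  B <- crossprod(Ms * sqrt(priors))
  eb <- eigen(B, symmetric = TRUE)
  r <- min(g - 1, d, sum(eb$values > max(eb$values[1], 0) * 1e-10))
  r <- max(r, 1L)
  scalings <- W %*% eb$vectors[, seq_len(r), drop = FALSE]
  for (j in seq_len(r)) {
    if (scalings[which.max(abs(scalings[, j])), j] < 0) {
      scalings[, j] <- -scalings[, j]
    }
  }
  colnames(scalings) <- paste0("LD", seq_len(r))
  structure(list(classes = classes, means = means, cov_pooled = Sw,
                 cov_inv = cov_inv, scalings = scalings, priors = priors,
                 ridge = ridge, grand_mean = grand),
            class = "spath_lda")
}

#' @export
print.spath_lda <- function(x, ...) {
  cat(sprintf("<spath_lda> %d classes (%s), %d feature(s), %d discriminant direction(s), ridge %.3g\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              ncol(x$means), ncol(x$scalings), x$ridge))
  invisible(x)
}

#' @export
coef.spath_lda <- function(object, ...) object$scalings

#' Predict classes from an LDA model
#'
#' Posteriors come from the Gaussian equal-covariance model
#' (softmax over the linear discriminant functions).
#'
#' @param object A [fit_lda()] model.
#' @param newdata Matrix of feature scores.
#' @param ... Unused.
#' @return List: `class` (factor), `posterior` (records x classes, rows sum
#'   to 1), `scores` (discriminant function values), `ld` (records x
#'   directions LD scores).
#' @export
predict.spath_lda <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  stopifnot(ncol(X) == ncol(object$means))
  A <- object$cov_inv %*% t(object$means)                    # d x g
  const <- -0.5 * colSums(t(object$means) * A) + log(object$priors)
  delta <- X %*% A + matrix(const, nrow(X), length(object$classes),
                            byrow = TRUE)
  colnames(delta) <- object$classes
  post <- exp(delta - apply(delta, 1, max))
  post <- post / rowSums(post)
  cls <- factor(object$classes[max.col(post, ties.method = "first")],
                levels = object$classes)
  ld <- sweep(X, 2, object$grand_mean) %*% object$scalings
  list(class = cls, posterior = post, scores = delta, ld = ld)
}

#' Fit the full PCA-ANOVA-LDA classifier
#'
#' The package's core fit: spectra are reduced by PCA, component scores are
#' screened by one-way ANOVA across pathology groups (up to `max_keep`
#' components at significance `alpha`), and the retained scores feed a
#' multiclass LDA. When no component reaches significance the single
#' smallest-p component is used so the model stays defined (flagged in the
#' result).
#'
#' @param x Training spectra: matrix (records x channels) or
#'   [spectra_table()].
#' @param labels Pathology label per record.
#' @param n_components PCA component cap before selection (default 50).
#' @param alpha ANOVA significance level (default 0.05).
#' @param max_keep Maximum selected components (default 25).
#' @param ridge,priors Passed to [fit_lda()].
#' @param pca Optional pre-fitted [fit_pca()] model to reuse (PCA is then
#'   not refit on `x`; used by the leaky "global PCA" cross-validation
#'   variant).
#' @return Object of class `"pcalda"` with elements `pca`, `selection`,
#'   `lda`, `classes`, `fallback` (TRUE when no component was significant).
#' @export
pcalda <- function(x, labels, n_components = 50, alpha = 0.05, max_keep = 25,
                   ridge = NULL, priors = NULL, pca = NULL) {
  X <- as_matrix_input(x)
  labels <- droplevels(factor(labels))
  if (is.null(pca)) pca <- fit_pca(X, n_components)
  scores <- project_pca(pca, X)
  selection <- anova_select(scores, labels, alpha = alpha,
                            max_keep = max_keep)
  fallback <- FALSE
  if (!length(selection$indices)) {
    fallback <- TRUE
    ok <- which(!is.na(selection$p_values))
    selection$indices <- if (length(ok)) ok[which.min(selection$p_values[ok])] else 1L
  }
  lda <- fit_lda(scores[, selection$indices, drop = FALSE], labels,
                 ridge = ridge, priors = priors)
  structure(list(pca = pca, selection = selection, lda = lda,
                 classes = lda$classes, fallback = fallback),
            class = "pcalda")
}

#' @export
print.pcalda <- function(x, ...) {
  cat(sprintf("<pcalda> %d PCs -> %d ANOVA-selected -> LDA over %s\n",
              x$pca$k, length(x$selection$indices),
              paste(x$classes, collapse = ", ")))
  if (x$fallback) {
    cat("  note: no component significant; using smallest-p component\n")
  }
  invisible(x)
}

#' Predict pathology per spectrum
#'
#' Projects spectra onto the training mean and loadings, restricts to the
#' selected components and applies the LDA.
#'
#' @param object A [pcalda()] model.
#' @param newdata Matrix or [spectra_table()] on the training axis.
#' @param ... Unused.
#' @return As [predict.spath_lda()].
#' @export
predict.pcalda <- function(object, newdata, ...) {
  scores <- project_pca(object$pca, newdata)
  predict(object$lda,
          scores[, object$selection$indices, drop = FALSE])
}

#' Majority vote over one sample's per-spectrum predictions
#'
#' A class holding more than 50% of the sample's spectra wins decisively.
#' Otherwise the plurality class is returned with `decisive = FALSE`; a
#' plurality tie is broken by the highest mean posterior among the tied
#' classes.
#'
#' @param classes Per-spectrum predicted classes (factor; >= 1 prediction).
#' @param posterior Optional posterior matrix (used only for tie-breaks).
#' @return List: `prediction`, `fractions` (named, sums to 1), `decisive`.
#' @export
majority_vote <- function(classes, posterior = NULL) {
  classes <- factor(classes)
  n <- length(classes)
  if (n == 0) stop("majority_vote needs at least one prediction",
                   call. = FALSE)
  fractions <- table(classes) / n
  fractions <- stats::setNames(as.numeric(fractions), names(fractions))
  top <- max(fractions)
  if (top > 0.5) {
    return(list(prediction = names(fractions)[which.max(fractions)],
                fractions = fractions, decisive = TRUE))
  }
  tied <- names(fractions)[fractions == top]
  pick <- if (length(tied) > 1 && !is.null(posterior)) {
    mp <- vapply(tied, function(cl) mean(posterior[, cl]), numeric(1))
    tied[which.max(mp)]
  } else {
    tied[1]
  }
  list(prediction = pick, fractions = fractions, decisive = FALSE)
}
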