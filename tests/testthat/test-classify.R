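# PCA, ANOVA component screening, LDA, majority voting, LOSOCV.

test_that("PCA: rank-1 data, orthonormal loadings, full-rank reconstruction", {
  set.seed(4)
  # rank-1: points on a line through the mean
  line <- outer(rnorm(30), runif(10))
  p1 <- fit_pca(line, 5)
  expect_equal(p1$explained_variance[1], 1.0, tolerance = 1e-10)

  X <- matrix(rnorm(20 * 201), 20)
  pca <- fit_pca(X, 50)
  expect_equal(crossprod(pca$loadings),
               diag(ncol(pca$loadings)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lte(pca$k, 19)          # rank of 20 mean-centred rows
  scores <- project_pca(pca, X)
  recon <- scores %*% t(pca$loadings) + rep(pca$center, each = 20)
  expect_equal(recon, X, tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  expect_lte(sum(pca$explained_variance), 1 + 1e-12)

  expect_error(fit_pca(X[1, , drop = FALSE]), "at least 2")
})

test_that("PCA agrees with prcomp up to component signs", {
  set.seed(9)
  X <- matrix(rnorm(40 * 30), 40)
  pca <- fit_pca(X, 10)
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  s1 <- project_pca(pca, X)
  s2 <- pr$x[, 1:10]
  expect_equal(abs(s1), abs(s2), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("ANOVA selection finds shifted components and respects the cap", {
  set.seed(12)
  g <- rep(c("normal", "cancer"), each = 200)
  scores <- matrix(rnorm(400 * 30), 400)
  scores[, 1] <- (g == "cancer") * 10 + rnorm(400)
  sel <- anova_select(scores, g)
  expect_true(1 %in% sel$indices)
  expect_lt(sel$p_values[1], 1e-10)
  expect_equal(sel$indices[1], 1)   # smallest p first

  strong <- matrix(rep((g == "cancer") * 5, 30), 400) +
    matrix(rnorm(400 * 30), 400)
  sel30 <- anova_select(strong, g, max_keep = 25)
  expect_length(sel30$indices, 25)

  expect_error(anova_select(scores, rep("normal", 400)), ">= 2 groups")
  expect_error(anova_select(scores[1:3, ], c("normal", "cancer", "cancer")),
               ">= 2 records")
})

test_that("ANOVA F statistics match a brute-force sums-of-squares oracle", {
  set.seed(5)
  for (i in 1:25) {
    n_g <- sample(2:4, 1)
    g <- rep(paste0("g", seq_len(n_g)), times = sample(3:8, n_g, replace = TRUE))
    x <- rnorm(length(g)) + rep(runif(n_g, 0, 2), times = table(factor(g))[
      paste0("g", seq_len(n_g))])
    sel <- anova_select(cbind(x), ifelse(g == "g1", "normal", "cancer"))
    # use the package's per-component F against the naive oracle
    want <- anova_f_oracle(x, ifelse(g == "g1", "normal", "cancer"))
    expect_equal(sel$f_values[1], unname(want["f"]), tolerance = 1e-10)
    expect_equal(sel$p_values[1], unname(want["p"]), tolerance = 1e-10)
  }
})

test_that("LDA separates two Gaussians near the Bayes boundary", {
  set.seed(21)
  n <- 500
  X <- rbind(cbind(rnorm(n, -5), rnorm(n)), cbind(rnorm(n, 5), rnorm(n)))
  y <- rep(c("epithelial_misplacement", "cancer"), each = n)
  lda <- fit_lda(X, y)
  Xt <- rbind(cbind(rnorm(n, -5), rnorm(n)), cbind(rnorm(n, 5), rnorm(n)))
  pred <- predict(lda, Xt)
  expect_gt(mean(pred$class == y), 0.99)
  # discriminant direction is essentially the x-axis
  d <- lda$scalings[, 1] / sqrt(sum(lda$scalings[, 1]^2))
  expect_gt(abs(d[1]), 1 - 1e-4)

  # 2-class equivalence: direction parallel to Sigma^-1 (mu1 - mu2)
  want <- lda$cov_inv %*% (lda$means[1, ] - lda$means[2, ])
  cosine <- abs(sum(want * lda$scalings[, 1])) /
    sqrt(sum(want^2) * sum(lda$scalings[, 1]^2))
  expect_gt(cosine, 1 - 1e-8)
})

test_that("LDA agrees with an established reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(33)
  X <- matrix(rnorm(300 * 4), 300)
  X[101:200, 1] <- X[101:200, 1] + 2
  X[201:300, 2] <- X[201:300, 2] + 2
  y <- rep(c("normal", "adenoma", "cancer"), each = 100)
  mine <- fit_lda(X, y, ridge = 0)
  ref <- MASS::lda(X, grouping = factor(y, levels = mine$classes),
                   prior = rep(1 / 3, 3))
  Xt <- matrix(rnorm(200 * 4), 200)
  pm <- predict(mine, Xt)
  pr <- predict(ref, Xt)
  expect_gt(mean(as.character(pm$class) == as.character(pr$class)), 0.995)
  expect_equal(unname(pm$posterior[, mine$classes]),
               unname(pr$posterior[, mine$classes]), tolerance = 1e-6)
})

test_that("identical class distributions classify at chance", {
  set.seed(44)
  X <- matrix(rnorm(400 * 5), 400)
  y <- rep(c("normal", "cancer"), each = 200)
  lda <- fit_lda(X, y)
  Xt <- matrix(rnorm(2000 * 5), 2000)
  acc <- mean(predict(lda, Xt)$class == sample(c("normal", "cancer"), 2000,
                                               replace = TRUE))
  expect_gt(acc, 0.5 - 1.96 * sqrt(0.25 / 2000) - 0.02)
  expect_lt(acc, 0.5 + 1.96 * sqrt(0.25 / 2000) + 0.02)
})

test_that("LDA degenerate cases: 1-D threshold and singular covariance", {
  set.seed(3)
  x <- c(rnorm(100, 0), rnorm(100, 4))
  y <- rep(c("normal", "cancer"), each = 100)
  lda <- fit_lda(cbind(x), y)
  pred <- predict(lda, cbind(seq(-2, 6, by = 0.1)))
  flips <- sum(diff(as.integer(pred$class)) != 0)
  expect_equal(flips, 1)   # a single threshold on the component

  Xs <- cbind(x, x)        # perfectly collinear features
  expect_error(fit_lda(Xs, y, ridge = 0), "ridge > 0")
  expect_s3_class(fit_lda(Xs, y), "spath_lda")  # default ridge saves it
})

test_that("posteriors are normalised, symmetric and favour class means", {
  set.seed(15)
  X <- rbind(matrix(rnorm(200, 0), 100), matrix(rnorm(200, 3), 100))
  y <- rep(c("normal", "cancer"), each = 100)
  lda <- fit_lda(X, y)
  pred <- predict(lda, X)
  expect_equal(rowSums(pred$posterior), rep(1, 200), tolerance = 1e-12)

  mid <- matrix((lda$means[1, ] + lda$means[2, ]) / 2, 1)
  expect_equal(unname(drop(predict(lda, mid)$posterior)), c(0.5, 0.5),
               tolerance = 1e-8)
  m1 <- predict(lda, matrix(lda$means[1, ], 1))
  expect_equal(as.character(m1$class), lda$classes[1])
  expect_gt(m1$posterior[1, lda$classes[1]], 0.5)
})

test_that("majority vote applies the >50% rule with plurality fallback", {
  v <- majority_vote(factor(rep(c("A", "B"), c(51, 49))))
  expect_equal(v$prediction, "A")
  expect_true(v$decisive)
  expect_equal(sum(v$fractions), 1)

  cls <- factor(rep(c("a", "b", "c", "d"), c(40, 30, 20, 10)))
  v4 <- majority_vote(cls)
  expect_equal(v4$prediction, "a")
  expect_false(v4$decisive)

  v1 <- majority_vote(factor(rep("cancer", 7)))
  expect_true(v1$decisive)
  expect_equal(unname(v1$fractions["cancer"]), 1)

  post <- rbind(c(0.6, 0.4), c(0.45, 0.55))
  colnames(post) <- c("A", "B")
  tie <- majority_vote(factor(c("A", "B")), post)
  expect_equal(tie$prediction, "A")   # higher mean posterior among the tied
  expect_false(tie$decisive)

  expect_error(majority_vote(factor(character(0))), "at least one")
})

make_cohort_table <- function(effect, seed, noise = 0.005,
                              samples_per_group = 2, tile = c(12, 12)) {
  cfg <- cohort_config(samples_per_group = samples_per_group,
                       tile_shape = tile, effect_size = effect,
                       contamination = contamination_model(
                         paraffin_amplitude_range = c(0, 0),
                         scatter_scale_range = c(1, 1),
                         baseline_degree = 0, baseline_coeff_scale = 0,
                         noise_sd = noise),
                       seed = seed)
  cht <- generate_cohort(cfg)
  tabs <- lapply(names(cht$cubes), function(sid) {
    tab <- flatten_cube(cht$cubes[[sid]])
    map <- cht$label_maps[[sid]]
    keep <- map[cbind(tab$meta$row + 1, tab$meta$col + 1)] %in%
      epithelium_classes()
    subset_spectra(tab, keep)
  })
  bind_spectra(tabs)
}

test_that("LOSOCV tests each sample exactly once with fold-scoped fitting", {
  tab <- make_cohort_table(effect = 2, seed = 6)
  cv <- losocv(tab, seed = 1)
  expect_equal(cv$config$n_folds, 8)
  expect_equal(sort(cv$samples$sample_id), sort(unique(tab$meta$sample_id)))
  expect_false(anyDuplicated(cv$samples$sample_id) > 0)
  # vote fractions sum to 1 per sample
  fr <- as.matrix(cv$samples[, paste0("fraction.", cv$classes)])
  expect_equal(unname(rowSums(fr)), rep(1, 8), tolerance = 1e-12)
  # every spectrum of each sample is predicted in its own fold
  expect_equal(unname(table(cv$spectra$sample_id)[cv$samples$sample_id]),
               unname(table(tab$meta$sample_id)[cv$samples$sample_id]))

  short <- subset_spectra(tab, tab$meta$sample_id != "normal_02")
  expect_error(losocv(short, seed = 1), ">= 2 samples")
})

test_that("majority-vote accuracy is monotone in the effect size", {
  accs <- sapply(c(0, 1, 3), function(e) {
    cv <- losocv(make_cohort_table(effect = e, seed = 14,
                                   samples_per_group = 3), seed = 2)
    mean(cv$samples$predicted == cv$samples$true)
  })
  expect_true(all(diff(accs) >= 0))
  expect_equal(accs[3], 1)
})

test_that("the leaky global-PCA variant runs and is flagged in the config", {
  tab <- make_cohort_table(effect = 2, seed = 8)
  cv <- losocv(tab, global_pca = TRUE, seed = 3)
  expect_true(cv$config$global_pca)
  expect_equal(cv$config$n_folds, 8)
})

test_that("subsampling caps the per-sample training load deterministically", {
  tab <- make_cohort_table(effect = 2, seed = 10)
  cv1 <- losocv(tab, subsample = 20, seed = 5)
  cv2 <- losocv(tab, subsample = 20, seed = 5)
  expect_identical(cv1$spectra, cv2$spectra)
  # all test spectra are still predicted
  expect_equal(nrow(cv1$spectra), n_spectra(tab))
})
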