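# EMSC correction: truncation, bases, least-squares fits against a
# normal-equations oracle, exact recovery, idempotence, quality filtering.

test_that("fingerprint truncation keeps exactly the closed interval", {
  full <- wn_axis(seq(1000, 3800, by = 4))
  cube <- hyper_cube("s", "normal", full,
                     array(runif(2 * 2 * length(full)),
                           dim = c(2, 2, length(full))))
  tr <- truncate_fingerprint(cube)
  expect_length(tr$axis, 201)              # (1800 - 1000)/4 + 1
  expect_equal(range(unclass(tr$axis)), c(1000, 1800))
  expect_equal(tr$data[1, 2, ], cube$data[1, 2, 1:201])
  expect_identical(tr$sample_id, cube$sample_id)

  tab <- flatten_cube(cube)
  same <- truncate_fingerprint(truncate_fingerprint(tab))
  expect_equal(same$spectra, truncate_fingerprint(tab)$spectra)

  expect_error(truncate_fingerprint(cube, low = 2000, high = 1000),
               "low must be")
  expect_error(truncate_fingerprint(cube, low = 5000, high = 6000),
               "fewer than 2")
})

test_that("Legendre basis matches the closed forms on the mapped axis", {
  ax <- default_axis()
  L <- legendre_basis(ax, 3)
  t <- 2 * (unclass(ax) - 1000) / 800 - 1
  expect_equal(L[, 1], rep(1, 201))
  expect_equal(L[, 2], t)
  expect_equal(L[, 3], (3 * t^2 - 1) / 2)
  expect_equal(L[, 4], (5 * t^3 - 3 * t) / 2)
})

test_that("the reference spectrum is the channel-wise mean", {
  ax <- c(1000, 1004, 1008)
  tab <- make_table(rbind(c(0, 2, 4), c(2, 2, 0)), ax)
  expect_equal(compute_reference(tab), c(1, 2, 2))
  single <- make_table(rbind(c(5, 6, 7)), ax)
  expect_equal(compute_reference(single), c(5, 6, 7))
  empty <- subset_spectra(tab, c(FALSE, FALSE))
  expect_error(compute_reference(empty), "empty")
})

test_that("paraffin basis: mean component, degenerate flag, span recovery", {
  ax <- default_axis()
  model <- contamination_model(noise_sd = 0)
  one <- spectropath:::paraffin_components(model, ax) %*% c(0.3, 0.2)
  copies <- matrix(rep(drop(one), 50), nrow = 50, byrow = TRUE)
  expect_warning(b1 <- build_paraffin_basis(copies, 1), "degenerate")
  expect_equal(b1[, "paraffin_mean"], drop(one))

  # two independent band amplitudes: directions span the generating subspace
  sim <- simulate_paraffin_spectra(100, model, ax, seed = 5)
  b2 <- build_paraffin_basis(sim, 2)
  P <- spectropath:::paraffin_components(model, ax)
  qp <- qr.Q(qr(P))
  qd <- qr.Q(qr(b2[, c("paraffin_pc1", "paraffin_pc2")]))
  principal_cos <- svd(t(qp) %*% qd)$d
  expect_true(all(acos(pmin(principal_cos, 1)) < 1e-6))
  # orthonormal directions
  expect_equal(crossprod(b2[, 2:3]), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)

  b0 <- build_paraffin_basis(sim, 0)
  expect_equal(colnames(b0), "paraffin_mean")
  expect_error(build_paraffin_basis(sim[1:3, ], 3), "smaller")
})

test_that("EMSC fit recovers constructed coefficients and flags rank deficiency", {
  ax <- default_axis()
  pure <- render_pure_spectrum(default_tissue_profiles()$nuclear, "normal", ax)
  para <- spectropath:::paraffin_components(contamination_model(), ax)[, 1]
  basis <- emsc_basis(ax, pure, cbind(paraffin = para), baseline_degree = 1)
  L <- legendre_basis(ax, 1)

  fit0 <- fit_emsc(pure, basis)
  expect_equal(fit0$scale, 1, tolerance = 1e-10)
  expect_equal(unname(fit0$interference_coeffs), 0, tolerance = 1e-10)
  expect_equal(unname(fit0$baseline_coeffs), c(0, 0), tolerance = 1e-10)
  expect_equal(fit0$residual_rms, 0, tolerance = 1e-12)

  obs <- 2 * pure + 0.5 * para + 0.1 * L[, 1] + 0.2 * L[, 2]
  fit <- fit_emsc(obs, basis)
  expect_equal(fit$scale, 2, tolerance = 1e-8)
  expect_equal(unname(fit$interference_coeffs), 0.5, tolerance = 1e-8)
  expect_equal(unname(fit$baseline_coeffs), c(0.1, 0.2), tolerance = 1e-8)
  expect_equal(apply_emsc(obs, fit, basis), pure, tolerance = 1e-8)

  # spectrum orthogonal to all design columns: zero coefficients
  Q <- qr.Q(qr(basis$design), complete = TRUE)
  ortho <- Q[, ncol(basis$design) + 1]
  fo <- fit_emsc(ortho, basis)
  expect_equal(fo$scale, 0, tolerance = 1e-10)
  expect_equal(fo$residual_rms, sqrt(mean(ortho^2)), tolerance = 1e-10)

  expect_error(emsc_basis(ax, pure, cbind(dup = pure), baseline_degree = 1),
               "rank deficient.*dup|rank deficient.*reference")
})

test_that("EMSC matches a brute-force normal-equations oracle on random instances", {
  set.seed(31)
  ax <- default_axis()
  worst <- 0
  for (i in 1:100) {
    ref <- abs(stats::rnorm(201)) + 0.5
    interf <- matrix(stats::rnorm(201 * 2), ncol = 2)
    deg <- sample(0:4, 1)
    basis <- emsc_basis(ax, ref, interf, baseline_degree = deg)
    y <- stats::rnorm(201)
    fit <- fit_emsc(y, basis)
    got <- c(fit$scale, fit$interference_coeffs, fit$baseline_coeffs)
    want <- drop(ls_oracle(basis$design, y))
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-8)
})

test_that("noiseless synthetic contamination is corrected back exactly", {
  ax <- default_axis()
  pure <- render_pure_spectrum(default_tissue_profiles()$cytoplasmic,
                               "adenoma", ax)
  model <- contamination_model(noise_sd = 0, baseline_degree = 2)
  # with exactly two noiseless paraffin bands the mean already lies in the
  # span of the principal directions, so mean + 1 direction spans the band
  # space and keeps the design full rank
  interference <- build_paraffin_basis(
    simulate_paraffin_spectra(100, model, ax, seed = 3), 1)
  basis <- emsc_basis(ax, pure, interference, baseline_degree = 4)
  set.seed(17)
  for (i in 1:20) {
    obs <- contaminate(pure, model, ax)$observed
    fit <- fit_emsc(obs, basis)
    corr <- apply_emsc(obs, fit, basis)
    expect_lt(sqrt(sum((corr - pure)^2)) / sqrt(sum(pure^2)), 1e-6)
  }
})

test_that("coefficient error shrinks with the noise level", {
  ax <- default_axis()
  pure <- render_pure_spectrum(default_tissue_profiles()$nuclear, "normal", ax)
  base_model <- function(sd) {
    contamination_model(noise_sd = sd, baseline_degree = 2)
  }
  interference <- build_paraffin_basis(
    simulate_paraffin_spectra(100, base_model(0), ax, seed = 3), 1)
  basis <- emsc_basis(ax, pure, interference, baseline_degree = 4)
  err <- sapply(c(1e-2, 1e-3, 1e-4), function(sd) {
    set.seed(7)
    mean(replicate(30, {
      r <- contaminate(pure, base_model(sd), ax)
      fit <- fit_emsc(r$observed, basis)
      abs(fit$scale - r$truth$scatter)
    }))
  })
  expect_true(all(diff(err) < 0))
})

test_that("correction is idempotent to solver tolerance", {
  ax <- default_axis()
  pure <- render_pure_spectrum(default_tissue_profiles()$mucin, "normal", ax)
  model <- contamination_model(noise_sd = 0.01)
  interference <- build_paraffin_basis(
    simulate_paraffin_spectra(100, model, ax, seed = 4), 2)
  basis <- emsc_basis(ax, pure, interference, baseline_degree = 4)
  set.seed(23)
  obs <- contaminate(pure, model, ax)$observed
  c1 <- apply_emsc(obs, fit_emsc(obs, basis), basis)
  c2 <- apply_emsc(c1, fit_emsc(c1, basis), basis)
  expect_equal(c2, c1, tolerance = 1e-8)
})

test_that("quality filter partitions records and logs reasons", {
  ax <- default_axis()
  pure <- render_pure_spectrum(default_tissue_profiles()$nuclear, "normal", ax)
  X <- rbind(pure, 2 * pure, 0.001 * pure, rep(0, 201))
  tab <- make_table(X, ax)
  basis <- emsc_basis(ax, pure, baseline_degree = 2)
  fits <- fit_emsc_table(tab, basis)
  corrected <- apply_emsc_table(tab, fits, basis)

  # vacuous criteria pass every record with a defined correction
  lax <- quality_criteria(min_scale = 1e-9, max_scale = Inf,
                          max_residual_rms = Inf, min_amide1_height = 0)
  clean <- subset_spectra(tab, c(TRUE, TRUE, FALSE, FALSE))
  fits_clean <- fit_emsc_table(clean, basis)
  corr_clean <- apply_emsc_table(clean, fits_clean, basis)
  expect_equal(n_spectra(quality_filter(corr_clean, fits_clean, lax)$passed), 2)

  crit <- quality_criteria(min_scale = 0.05, max_scale = 5,
                           max_residual_rms = Inf, min_amide1_height = 0.05)
  qf <- quality_filter(corrected, fits, crit)
  expect_equal(n_spectra(qf$passed), 2)           # pure and 2x pure
  expect_equal(unname(qf$log["scale"]), 2)        # 0.001x and the flat zero
  expect_equal(n_spectra(qf$passed) + n_spectra(qf$rejected), 4)

  # conservation under random criteria
  set.seed(8)
  for (i in 1:10) {
    crit_i <- quality_criteria(min_scale = runif(1, 0.01, 0.5),
                               max_scale = runif(1, 1, 6),
                               max_residual_rms = runif(1, 0, 0.1),
                               min_amide1_height = runif(1, 0, 0.5))
    qf_i <- quality_filter(corrected, fits, crit_i)
    expect_equal(n_spectra(qf_i$passed) + n_spectra(qf_i$rejected), 4)
    expect_equal(unname(qf_i$log["passed"] + qf_i$log["rejected"]), 4)
  }
})
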