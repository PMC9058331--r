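# Synthetic generator: pure spectra, contamination, label maps, cohorts.

test_that("rendered pure spectra follow the Gaussian band model", {
  ax <- default_axis()
  prof <- class_profile("nuclear", peak_spec(1656, 15, 1.0))
  s <- render_pure_spectrum(prof, "normal", ax)
  expect_equal(which.max(s), which.min(abs(unclass(ax) - 1656)))
  expect_equal(max(s), 1.0)   # apex value equals the amplitude (on-grid centre)
  off <- render_pure_spectrum(class_profile("nuclear", peak_spec(1654, 15, 1.0)),
                              "normal", ax)
  expect_equal(which(off == max(off)),
               which(abs(unclass(ax) - 1654) == min(abs(unclass(ax) - 1654))))
  expect_true(all(s >= 0))

  empty <- class_profile("background",
                         data.frame(center = numeric(0), width = numeric(0),
                                    amplitude = numeric(0)))
  expect_equal(render_pure_spectrum(empty, "normal", ax), rep(0, 201))

  two <- class_profile("nuclear", rbind(peak_spec(1656, 15, 1.0),
                                        peak_spec(1656, 15, 1.0)))
  expect_equal(render_pure_spectrum(two, "normal", ax), 2 * s)

  expect_error(render_pure_spectrum(prof, "polyp", ax), "pathology")
})

test_that("pure spectra are linear in band amplitudes", {
  ax <- default_axis()
  p1 <- class_profile("mucin", peak_spec(1040, 14, 0.3))
  p2 <- class_profile("mucin", peak_spec(1040, 14, 0.9))
  expect_equal(render_pure_spectrum(p2, "normal", ax),
               3 * render_pure_spectrum(p1, "normal", ax), tolerance = 1e-12)
})

test_that("pathology modulation vanishes at zero effect size and grows with it", {
  ax <- default_axis()
  dists <- sapply(c(0, 1, 2), function(e) {
    prof <- default_tissue_profiles(e)
    M <- sapply(pathology_levels(), function(p) {
      render_pure_spectrum(prof$nuclear, p, ax)
    })
    max(dist(t(M)))
  })
  expect_equal(dists[1], 0)
  expect_true(dists[2] > 0)
  expect_true(dists[3] > dists[2])
})

test_that("contamination reduces to identity / pure scaling when configured so", {
  ax <- default_axis()
  pure <- render_pure_spectrum(default_tissue_profiles()$nuclear, "normal", ax)
  ident <- contamination_model(paraffin_amplitude_range = c(0, 0),
                               scatter_scale_range = c(1, 1),
                               baseline_degree = 0, baseline_coeff_scale = 0,
                               noise_sd = 0)
  expect_equal(contaminate(pure, ident, ax)$observed, pure)

  twice <- contamination_model(paraffin_amplitude_range = c(0, 0),
                               scatter_scale_range = c(2, 2),
                               baseline_degree = 0, baseline_coeff_scale = 0,
                               noise_sd = 0)
  expect_equal(contaminate(pure, twice, ax)$observed, 2 * pure)
})

test_that("contamination is deterministic under a fixed seed and reports truth", {
  ax <- default_axis()
  pure <- render_pure_spectrum(default_tissue_profiles()$cytoplasmic,
                               "adenoma", ax)
  model <- contamination_model()
  set.seed(99); a <- contaminate(pure, model, ax)
  set.seed(99); b <- contaminate(pure, model, ax)
  expect_identical(a, b)
  expect_true(a$truth$scatter >= 0.7 && a$truth$scatter <= 1.3)
  expect_named(a$truth,
               c("scatter", "paraffin_1380", "paraffin_1468",
                 "baseline_0", "baseline_1", "baseline_2"))
})

test_that("label maps carry the advertised class inventory per pathology", {
  set.seed(11)
  m <- generate_label_map(c(64, 64), "normal", 2)
  expect_setequal(unique(as.vector(m)),
                  c("nuclear", "cytoplasmic", "mucin", "lamina_propria"))
  m2 <- generate_label_map(c(64, 64), "epithelial_misplacement", 3)
  expect_true("submucosa" %in% m2)
  expect_false("lamina_propria" %in% m2)

  mc <- generate_label_map(c(64, 64), "cancer", 3)
  expect_false("mucin" %in% mc)
  expect_setequal(unique(as.vector(mc)), c("nuclear", "cytoplasmic", "stroma"))

  m0 <- generate_label_map(c(32, 32), "adenoma", 0)
  expect_true(all(m0 == "lamina_propria"))
})

test_that("class inventory holds across pathologies and seeds", {
  want <- list(
    normal = c("nuclear", "cytoplasmic", "mucin", "lamina_propria"),
    adenoma = c("nuclear", "cytoplasmic", "mucin", "lamina_propria"),
    epithelial_misplacement = c("nuclear", "cytoplasmic", "mucin", "submucosa"),
    cancer = c("nuclear", "cytoplasmic", "stroma")
  )
  for (seed in 1:5) {
    set.seed(seed)
    for (p in pathology_levels()) {
      m <- generate_label_map(c(48, 48), p, 3)
      expect_setequal(unique(as.vector(m)), want[[p]])
    }
  }
})

test_that("oversized glands degrade to fewer with a warning, never an error", {
  # cancer blobs need a wobble margin a minimal 8x8 tile cannot provide
  set.seed(2)
  expect_warning(m <- generate_label_map(c(8, 8), "cancer", 3), "glands fit")
  expect_true(all(m == "stroma"))
})

test_that("cohorts have the right shape, unique ids and determinism", {
  cfg <- cohort_config(samples_per_group = 1, tile_shape = c(16, 16), seed = 4)
  cht <- generate_cohort(cfg)
  expect_length(cht$cubes, 4)
  expect_equal(unname(sapply(cht$cubes, function(c) prod(dim(c$data)[1:2]))),
               rep(256, 4))
  expect_false(anyDuplicated(names(cht$cubes)) > 0)
  expect_equal(sort(unique(cht$manifest$pathology)), sort(pathology_levels()))

  cht2 <- generate_cohort(cfg)
  expect_identical(lapply(cht$cubes, `[[`, "data"),
                   lapply(cht2$cubes, `[[`, "data"))
  expect_identical(cht$label_maps, cht2$label_maps)
  expect_identical(cht$truth, cht2$truth)
})

test_that("a default-sized cohort has ten samples in each of the four groups", {
  cfg <- cohort_config(tile_shape = c(12, 12), seed = 9)  # default samples_per_group
  cht <- generate_cohort(cfg)
  expect_length(cht$cubes, 40)
  expect_equal(as.integer(table(cht$manifest$pathology)), rep(10L, 4))
})

test_that("pixel spectra equal contaminate(render(class at pixel)) in the noiseless limit", {
  ident <- contamination_model(paraffin_amplitude_range = c(0, 0),
                               scatter_scale_range = c(1, 1),
                               baseline_degree = 0, baseline_coeff_scale = 0,
                               noise_sd = 0)
  cfg <- cohort_config(samples_per_group = 1, tile_shape = c(12, 12),
                       contamination = ident, effect_size = 1, seed = 12)
  cht <- generate_cohort(cfg)
  prof <- default_tissue_profiles(1)
  cube <- cht$cubes[[1]]
  map <- cht$label_maps[[1]]
  for (px in list(c(1, 1), c(4, 6), c(12, 12))) {
    want <- render_pure_spectrum(prof[[map[px[1], px[2]]]], cube$pathology,
                                 cube$axis)
    expect_equal(cube$data[px[1], px[2], ], want, tolerance = 1e-12)
  }
})
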