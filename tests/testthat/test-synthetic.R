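test_that("generate_transect honors bands, seeds, and determinism", {
  # no bands, no noise: constant at the background color
  tr <- synthetic_truth(bands = list(), noise_sd = 0)
  g <- generate_transect(100, tr)
  expect_true(all(abs(sweep(g$series$colors, 2,
                            tr$background_color)) < 1e-12))
  expect_equal(g$truth$pat_true, 0)

  # one 60-wide band in 200 positions
  g2 <- generate_transect(200, synthetic_truth(noise_sd = 0), seed = 1)
  expect_equal(g2$truth$pat_true, 0.30)

  # same seed, same series
  a <- generate_transect(200, synthetic_truth(), seed = 9)
  b <- generate_transect(200, synthetic_truth(), seed = 9)
  expect_identical(a$series$colors, b$series$colors)

  expect_error(generate_transect(30, synthetic_truth()), ">= 40")
  expect_error(generate_transect(100, synthetic_truth(
    bands = list(c(50, 150)))), "exceeds")
})

test_that("generated transects recover their ground truth", {
  # recovery at the generator's default noise (sd 0.02): pattern fraction
  # and color angles; Ran at a lighter noise level (sd 0.01) where the
  # extreme-pixel median estimator's selection bias is negligible
  truth02 <- synthetic_truth(noise_sd = 0.02)
  truth01 <- synthetic_truth(noise_sd = 0.01)
  ran_true <- sqrt(sum((truth02$background_color -
                          truth02$pattern_color)^2))
  cbk_true <- angle_to_gray(truth02$background_color)
  cpa_true <- angle_to_gray(truth02$pattern_color)
  err <- t(sapply(1:100, function(s) {
    g <- generate_transect(200, truth02, seed = s)
    rec <- compute_traits(g$series)
    g1 <- generate_transect(200, truth01, seed = 10000 + s)
    c(pat = abs(rec$pat - g$truth$pat_true),
      cbk = abs(rec$cbk - cbk_true),
      cpa = abs(rec$cpa - cpa_true),
      ran = abs(compute_traits(g1$series)$ran - ran_true))
  }))
  med <- apply(err, 2, median)
  expect_lte(med[["pat"]], 0.05)
  expect_lte(med[["ran"]], 0.05)
  expect_lte(med[["cbk"]], 3)
  expect_lte(med[["cpa"]], 3)
})

test_that("logistic band edges soften the pattern boundary", {
  hard <- generate_transect(200, synthetic_truth(noise_sd = 0))$series
  soft <- generate_transect(200, synthetic_truth(noise_sd = 0,
                                                 edge_width = 3))$series
  d_hard <- darkness(hard$colors)
  d_soft <- darkness(soft$colors)
  expect_gt(max(abs(diff(d_hard))), 0.5)   # hard edge: one sharp jump
  expect_lt(max(abs(diff(d_soft))), 0.5 * max(abs(diff(d_hard))))
})

test_that("the illumination gradient brightens tailward positions", {
  g <- generate_transect(200, synthetic_truth(bands = list(), noise_sd = 0,
                                              illumination_slope = 0.1))
  d <- darkness(g$series$colors)
  expect_lt(d[200], d[1])
})

test_that("rendered fly images round-trip exactly through PNG", {
  d <- withr::local_tempdir()
  res <- generate_fly_image("flyA", seed = 4, out_dir = d,
                            membrane = c(80, 90))
  img <- read_image(file.path(d, "flyA.png"))
  expect_identical(img, res$image)

  lm <- read_landmarks(file.path(d, "flyA_landmarks.csv"))
  ser_mem <- extract_transect(res$image,
                              c(lm$x1[1], lm$y1[1]), c(lm$x2[1], lm$y2[1]))
  ser_disk <- extract_transect(img,
                               c(lm$x1[1], lm$y1[1]), c(lm$x2[1], lm$y2[1]))
  expect_identical(ser_mem$colors, ser_disk$colors)

  masks <- read_mask_intervals(file.path(d, "flyA_masks.csv"))
  expect_equal(masks$start, 80)
  truth <- jsonlite::fromJSON(file.path(d, "flyA_truth.json"))
  expect_equal(truth$thorax$pat_true, res$truth$thorax$pat_true)
})

test_that("membrane masking reproduces the membrane-free measurement", {
  # same seed: identical cuticle pixels; the membrane only replaces the
  # masked rows, so traits on the masked transect must match the
  # membrane-free image measured with the same positions excluded
  res_mem <- generate_fly_image("f", seed = 6, noise_sd = 0.01,
                                membrane = c(80, 90))
  res_free <- generate_fly_image("f", seed = 6, noise_sd = 0.01)
  ser_mem <- extract_transect(res_mem$image, c(85, 145), c(85, 285))
  ser_free <- extract_transect(res_free$image, c(85, 145), c(85, 285))
  ser_mem <- apply_mask(ser_mem, list(c(80, 90)))
  ser_free <- apply_mask(ser_free, list(c(80, 90)))
  expect_equal(compute_traits(ser_mem, snip_window = 30),
               compute_traits(ser_free, snip_window = 30))
})

test_that("darker pattern colors produce darker rendered flies", {
  r1 <- generate_fly_image("a", seed = 2, noise_sd = 0.01)
  r2 <- generate_fly_image("b", seed = 2, noise_sd = 0.01,
                           pattern_color = c(0.15, 0.08, 0.05))
  t1 <- compute_traits(extract_transect(r1$image, c(85, 145), c(85, 285)))
  t2 <- compute_traits(extract_transect(r2$image, c(85, 145), c(85, 285)))
  expect_gt(t2$odk, t1$odk)
})

test_that("population generation applies the thermal effect on darkness", {
  # cold-reared flies carry a darker pattern color: Odk(17) > Odk(28) in
  # at least 95% of seeded replicates
  wins <- sapply(1:100, function(s) {
    pop <- generate_population(n_per_group = 2, strains = "CanS",
                               sexes = "F", temperatures = c(17, 28),
                               n = 120, temp_effect = -0.2, seed = s,
                               base = synthetic_truth(bands = list(c(40, 76))))
    tab <- population_traits(pop)
    mean(tab$odk[tab$temperature == 17]) >
      mean(tab$odk[tab$temperature == 28])
  })
  expect_gte(mean(wins), 0.95)
})

test_that("populations are reproducible and carry their design labels", {
  p1 <- generate_population(n_per_group = 2, seed = 3, n = 140)
  p2 <- generate_population(n_per_group = 2, seed = 3, n = 140)
  expect_identical(p1$series[[5]]$colors, p2$series[[5]]$colors)
  expect_equal(nrow(p1$meta), 2 * 2 * 2 * 2)
  tab <- population_traits(p1)
  expect_setequal(unique(tab$strain), c("CanS", "OreR"))
  expect_setequal(unique(tab$temperature), c(17, 28))
})
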