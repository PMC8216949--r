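test_that("overall darkness matches hand-computed means", {
  p <- darkness_params()
  black <- color_series(matrix(0, 50, 3))
  expect_equal(compute_odk(series_darkness(black, p)), sqrt(3))

  half <- color_series(rbind(matrix(0, 25, 3), matrix(1, 25, 3)))
  expect_equal(compute_odk(series_darkness(half, p)), sqrt(3) / 2)

  # Dbk of gray (v, v, v) is v * sqrt(3)
  grays <- color_series(rbind(matrix(0.2, 50, 3), matrix(0.8, 50, 3)))
  expect_equal(compute_odk(series_darkness(grays, p)),
               mean(c(sqrt(3) * 0.8, sqrt(3) * 0.2)))
})

test_that("pattern fraction recovers band coverage on clean profiles", {
  ser <- square_wave_series(200, band = c(70, 130))
  env <- compute_envelope(series_darkness(ser))
  expect_equal(compute_pat(env), 0.30, tolerance = 0.02)

  flat <- compute_envelope(series_darkness(
    color_series(matrix(0.5, 100, 3))))
  expect_equal(compute_pat(flat), 0)

  # alternating one-position comb: half the positions are the dark phase
  comb <- color_series(matrix(rep(c(0.3, 0.7), 50), 100, 3))
  env_comb <- compute_envelope(series_darkness(comb))
  expect_lte(abs(compute_pat(env_comb) - 0.5), 0.02)
})

test_that("cluster trimming retains the 95% nearest the centroid", {
  ser <- square_wave_series(200, band = c(50, 150))  # 100 dark, 100 light
  env <- compute_envelope(series_darkness(ser), max_window = 50)
  split <- split_color_clusters(ser, env, keep_fraction = 0.95)
  expect_equal(nrow(split$pattern), 95)
  expect_equal(nrow(split$background), 95)

  # n = 40 with one far outlier: retain ceil(0.95 * 40) = 38, outlier out
  colors <- matrix(0.7, 80, 3)
  colors[31:70, ] <- 0.25
  colors[50, ] <- c(0.02, 0.02, 0.02)      # outlying "pattern" pixel
  ser2 <- color_series(colors)
  env2 <- compute_envelope(series_darkness(ser2), max_window = 20)
  split2 <- split_color_clusters(ser2, env2, keep_fraction = 0.95)
  expect_equal(nrow(split2$pattern), 38)
  expect_false(50 %in% split2$pattern_idx)

  # homogeneous class: retention count only, centroid unchanged
  flat <- color_series(matrix(0.5, 40, 3))
  envf <- compute_envelope(series_darkness(flat))
  splitf <- split_color_clusters(flat, envf)
  expect_equal(nrow(splitf$background), 38)
  expect_equal(colMeans(splitf$background), c(r = 0.5, g = 0.5, b = 0.5))
})

test_that("color angles come from the cluster color lines", {
  t <- seq(0.3, 0.9, length.out = 30)
  gray_ramp <- cbind(t, t, t)
  red_ramp <- cbind(seq(0.2, 0.8, length.out = 30), 0, 0)
  ang <- compute_color_angles(red_ramp, gray_ramp)
  expect_equal(ang$cbk, 0, tolerance = 1e-10)
  expect_equal(ang$cpa, acos(1 / sqrt(3)) * 180 / pi, tolerance = 1e-6)

  # empty pattern class: missing angle, not zero
  ang2 <- compute_color_angles(gray_ramp[0, , drop = FALSE], gray_ramp)
  expect_true(is.na(ang2$cpa))
  expect_false(is.na(ang2$cbk))

  expect_error(compute_color_angles(red_ramp[0, , drop = FALSE],
                                    gray_ramp[0, , drop = FALSE]),
               "both pixel clusters are empty")
})

test_that("color range is exact on noise-free two-color transects", {
  c1 <- c(0.1, 0.1, 0.1); c2 <- c(0.7, 0.7, 0.7)
  colors <- rbind(matrix(rep(c1, each = 50), 50),
                  matrix(rep(c2, each = 50), 50))
  ser <- color_series(colors)
  d <- series_darkness(ser)
  expect_equal(compute_ran(ser, d), 0.6 * sqrt(3), tolerance = 1e-12)

  const <- color_series(matrix(0.4, 60, 3))
  expect_equal(compute_ran(const, series_darkness(const)), 0)
})

test_that("color range enforces its minimum-length policy", {
  short <- color_series(matrix(seq(0.1, 0.9, length.out = 30), 30, 3))
  d <- series_darkness(short)
  expect_error(compute_ran(short, d), "at least 40")
  expect_warning(r <- compute_ran(short, d, allow_short = TRUE),
                 "k = 15")
  expect_gt(r, 0)
  one <- color_series(matrix(0.5, 1, 3))
  expect_error(compute_ran(one, series_darkness(one)), "at least 2")
})

test_that("full trait records behave on edge-case transects", {
  # single-color transect: no pattern, zero range, defined background
  flat <- color_series(matrix(0.55, 80, 3))
  rec <- compute_traits(flat)
  expect_equal(rec$pat, 0)
  expect_equal(rec$ran, 0)
  expect_true(is.na(rec$cpa))
  expect_equal(rec$cbk, 0, tolerance = 1e-9)
  expect_equal(rec$n_pattern + rec$n_background, 80)

  fully_masked <- color_series(matrix(0.5, 50, 3), mask = rep(TRUE, 50))
  expect_error(compute_traits(fully_masked), "masked")
})

test_that("odk is permutation invariant; the envelope split is not", {
  set.seed(41)
  g <- generate_transect(200, synthetic_truth(noise_sd = 0.02), seed = 41)
  rec <- compute_traits(g$series)
  perm <- sample(200)
  shuffled <- color_series(g$series$colors[perm, ])
  rec2 <- compute_traits(shuffled)
  expect_equal(rec2$odk, rec$odk)
  expect_equal(rec2$ran, rec$ran)
  # the envelope depends on position order: it is not carried along by
  # the permutation (labels can still coincide when the two darkness
  # modes are well separated)
  env <- compute_envelope(series_darkness(g$series))
  env2 <- compute_envelope(series_darkness(shuffled))
  expect_false(isTRUE(all.equal(env2$median_line, env$median_line[perm])))
})

test_that("pat plus background fraction is one over unmasked positions", {
  set.seed(42)
  for (rep in 1:10) {
    g <- generate_transect(150, synthetic_truth(
      bands = list(c(40, 80)), noise_sd = runif(1, 0, 0.03)), seed = rep)
    ser <- apply_mask(g$series, list(c(100, 110)))
    rec <- compute_traits(ser)
    expect_equal(rec$n_pattern + rec$n_background, 140)
    expect_equal(rec$pat, rec$n_pattern / 140)
  }
})

test_that("darkening the pattern color darkens the traits monotonically", {
  base <- synthetic_truth(noise_sd = 0)
  darker <- synthetic_truth(pattern_color = base$pattern_color - 0.1,
                            noise_sd = 0)
  r1 <- compute_traits(generate_transect(200, base)$series)
  r2 <- compute_traits(generate_transect(200, darker)$series)
  expect_gt(r2$odk, r1$odk)
  expect_gt(r2$ran, r1$ran)
  expect_gte(r2$pat, r1$pat)
})

test_that("trait records are bit-identical across repeated runs", {
  g <- generate_transect(200, synthetic_truth(noise_sd = 0.02), seed = 5)
  expect_identical(compute_traits(g$series), compute_traits(g$series))
})

test_that("group mean colors pool retained pixels per group", {
  c1 <- c(0.8, 0.6, 0.4); c2 <- c(0.6, 0.4, 0.2)
  make_split <- function(col) {
    ser <- color_series(matrix(rep(col, each = 40), 40))
    env <- compute_envelope(series_darkness(ser))
    split_color_clusters(ser, env, keep_fraction = 1)
  }
  gm <- group_mean_color(list(make_split(c1), make_split(c2)),
                         groups = c("g1", "g1"))
  bk <- gm[gm$cluster == "background", ]
  expect_equal(unlist(bk[, c("r", "g", "b")], use.names = FALSE),
               (c1 + c2) / 2)
  # no pattern anywhere in the group: missing pattern color
  pa <- gm[gm$cluster == "pattern", ]
  expect_true(all(is.na(pa[, c("r", "g", "b")])))
  expect_error(group_mean_color(list(), character(0)), "no transects")
})
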