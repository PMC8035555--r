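# Node-aligned fixture: measured pixel centers coincide with fine-grid
# nodes, so the in-place test point is available at distance exactly 0.
aligned_pair <- function(fill = 200, n_meas = 11, pitch = 6, calc_spacing = 2) {
  calc <- uniform_plane(fill, (n_meas - 1) * pitch, calc_spacing,
                        label = "calculated")
  meas <- dose_plane(matrix(fill, n_meas, n_meas), spacing = pitch,
                     origin = rep(-(n_meas - 1) * pitch / 2, 2),
                     label = "measured")
  list(measured = meas, calculated = calc)
}

test_that("identical planes give gamma exactly zero everywhere evaluated", {
  p <- aligned_pair()
  g <- compute_gamma(p$measured, p$calculated, criteria(),
                     search_spacing_mm = 0.5)
  expect_true(all(g$pixels$evaluated))
  expect_true(all(g$pixels$gamma == 0))
  expect_equal(gamma_pass_rate(g), 100)
})

test_that("a uniform +3% of max offset sits exactly on the gamma boundary", {
  p <- aligned_pair()
  p$measured$values <- p$measured$values + 0.03 * global_max(p$calculated)
  for (dta in c(1, 2, 5)) {
    g <- compute_gamma(p$measured, p$calculated,
                       criteria(dose_pct = 3, distance_mm = dta),
                       search_spacing_mm = 0.5)
    gv <- g$pixels$gamma[g$pixels$evaluated]
    expect_equal(unique(gv), 1)                      # minimizer at distance 0
    expect_true(all(g$pixels$argmin_distance_mm[g$pixels$evaluated] == 0))
  }
  expect_equal(gamma_pass_rate(compute_gamma(
    p$measured, p$calculated, criteria(), search_spacing_mm = 0.5)), 100)
})

test_that("gamma matches the scalar brute-force oracle on toy planes", {
  set.seed(31)
  crit <- criteria(3, 2, 1)
  for (k in 1:3) {
    pr <- random_pair()
    meas5 <- dose_plane(pr$measured$values[1:5, 1:5], pr$measured$spacing,
                        pr$measured$origin, "measured")
    fine <- resample_to_search_grid(pr$calculated, 0.75)
    g <- compute_gamma(meas5, fine, crit, search_spacing_mm = 0.75)
    oracle <- oracle_gamma_scalar(meas5, fine, crit, 3 * crit$distance_mm)
    expect_equal(gamma_matrix(g), oracle, tolerance = 1e-12)
  }
})

test_that("per-pixel argmin provenance reconstructs the gamma value", {
  set.seed(5)
  pr <- random_pair()
  crit <- criteria(3, 2, 1)
  g <- compute_gamma(pr$measured, pr$calculated, crit, search_spacing_mm = 0.5)
  px <- g$pixels[g$pixels$evaluated, ]
  recon <- sqrt((px$argmin_distance_mm / crit$distance_mm)^2 +
                  (px$argmin_dose_diff_pct / crit$dose_pct)^2)
  expect_equal(recon, px$gamma, tolerance = 1e-9)
})

test_that("loosening either criterion never increases any pixel's gamma", {
  set.seed(17)
  pr <- random_pair()
  base <- gamma_matrix(compute_gamma(pr$measured, pr$calculated,
                                     criteria(3, 2), search_spacing_mm = 0.5,
                                     max_search_mm = 9))
  wider_dose <- gamma_matrix(compute_gamma(pr$measured, pr$calculated,
                                           criteria(6, 2),
                                           search_spacing_mm = 0.5,
                                           max_search_mm = 9))
  wider_dta <- gamma_matrix(compute_gamma(pr$measured, pr$calculated,
                                          criteria(3, 3),
                                          search_spacing_mm = 0.5,
                                          max_search_mm = 9))
  expect_true(all(wider_dose <= base + 1e-12, na.rm = TRUE))
  expect_true(all(wider_dta <= base + 1e-12, na.rm = TRUE))
})

test_that("as the DTA criterion shrinks, gamma approaches |dose diff| / dose tolerance", {
  p <- aligned_pair()
  p$measured$values <- p$measured$values * 1.02   # +2% of max everywhere
  g <- compute_gamma(p$measured, p$calculated,
                     criteria(dose_pct = 3, distance_mm = 0.01),
                     max_search_mm = 0.01, search_spacing_mm = 0.5)
  gv <- g$pixels$gamma[g$pixels$evaluated]
  expect_equal(unique(gv), 2 / 3, tolerance = 1e-12)
})

test_that("pass rate and summary count exactly", {
  p <- aligned_pair(n_meas = 2, pitch = 6)
  # hand-build doses giving gamma 0, 0, 2/3, 4/3 at 3%/tiny-DTA
  M <- 200
  p$measured$values <- matrix(c(M, M, M * 1.02, M * 1.04), 2, 2)
  g <- compute_gamma(p$measured, p$calculated,
                     criteria(3, 0.01), max_search_mm = 0.01,
                     search_spacing_mm = 0.5)
  expect_equal(gamma_pass_rate(g), 75)            # 3 of 4 pass
  s <- gamma_summary(g)
  expect_equal(s$max_gamma, 4 / 3, tolerance = 1e-12)
  expect_equal(s$pct_above_1p5, 0)
  expect_equal(s$n_evaluated, 4)
  # one gamma of 2 in ten pixels -> max 2, 10% above 1.5
  p10 <- aligned_pair(n_meas = 5, pitch = 3)
  vals <- rep(M, 25)
  vals[1] <- M * 1.06                              # gamma = 2 at 3%/tiny DTA
  p10$measured$values <- matrix(vals, 5, 5)
  g10 <- compute_gamma(p10$measured, p10$calculated, criteria(3, 0.01),
                       max_search_mm = 0.01, search_spacing_mm = 0.5)
  s10 <- gamma_summary(g10)
  expect_equal(s10$max_gamma, 2, tolerance = 1e-12)
  expect_equal(s10$pct_above_1p5, 100 * 1 / 25)
})

test_that("the low-dose cutoff excludes pixels at or below 10% of max", {
  calc <- uniform_plane(200, 40, 2)
  meas <- dose_plane(matrix(c(200, 20, 19, 200), 2, 2), spacing = 4,
                     origin = c(-2, -2))
  g <- compute_gamma(meas, calc, criteria(), search_spacing_mm = 0.5)
  expect_equal(sum(g$pixels$evaluated), 2)   # 20 = 10% exactly -> excluded
})

test_that("disjoint grids are a comparison error", {
  a <- dose_plane(matrix(100, 3, 3), spacing = 2, origin = c(0, 0))
  b <- dose_plane(matrix(100, 3, 3), spacing = 2, origin = c(500, 500))
  expect_error(compute_gamma(a, b, criteria(), search_spacing_mm = 2),
               class = "ddmqa_comparison_error")
})
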