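aligned_uniform <- function(fill = 200, n_meas = 11, pitch = 6,
                            calc_spacing = 2) {
  calc <- uniform_plane(fill, (n_meas - 1) * pitch, calc_spacing,
                        label = "calculated")
  meas <- dose_plane(matrix(fill, n_meas, n_meas), spacing = pitch,
                     origin = rep(-(n_meas - 1) * pitch / 2, 2),
                     label = "measured")
  list(measured = meas, calculated = calc)
}

test_that("identical planes give DDM exactly zero; uniform offsets cannot escape", {
  p <- aligned_uniform()
  d0 <- compute_ddm(p$measured, p$calculated, criteria(),
                    search_spacing_mm = 0.5)
  expect_true(all(d0$pixels$ddm_pct[d0$pixels$evaluated] == 0))
  expect_equal(ddm_pass_rate(d0), 100)

  p$measured$values <- p$measured$values * 1.02
  d2 <- compute_ddm(p$measured, p$calculated, criteria(),
                    search_spacing_mm = 0.5)
  expect_true(all(d2$pixels$ddm_pct[d2$pixels$evaluated] == 2))
  expect_equal(ddm_pass_rate(d2), 100)   # 2 < 3 tolerance
  expect_equal(ddm_pass_rate(d2, tolerance_pct = 2), 0)          # strict
  expect_equal(ddm_pass_rate(d2, tolerance_pct = 2, boundary = "inclusive"),
               100)
})

test_that("a shift along a linear dose gradient is absorbed within r", {
  # calculated ramp g %/mm; measured = same ramp sampled s mm upstream
  g_per_mm <- 2    # % of max per mm
  xs <- seq(0, 40, by = 1)
  M <- 200
  ramp <- function(x) M * (0.2 + g_per_mm / 100 * x)
  calc <- dose_plane(outer(rep(1, 41), ramp(xs)), spacing = 1,
                     origin = c(0, 0), label = "calculated")
  s <- 0.6  # mm, < r = 1
  xm <- seq(10, 30, by = 5)
  meas <- dose_plane(outer(rep(1, 3), ramp(xm - s)),
                     spacing = c(5, 5), origin = c(15, 10), "measured")
  d <- compute_ddm(meas, calc, criteria(search_radius_mm = 1),
                   search_spacing_mm = 0.1)
  expect_lt(max(abs(d$pixels$ddm_pct[d$pixels$evaluated])), 0.05)
})

test_that("DDM matches the exhaustive disk oracle, including the signed tie rule", {
  set.seed(19)
  crit <- criteria(3, 2, 1.5)
  for (k in 1:3) {
    pr <- random_pair()
    fine <- resample_to_search_grid(pr$calculated, 0.75)
    d <- compute_ddm(pr$measured, fine, crit, search_spacing_mm = 0.75)
    expect_equal(ddm_matrix(d), oracle_ddm(pr$measured, fine, crit),
                 tolerance = 1e-12)
  }
})

test_that("ties in |deviation| resolve to the smaller distance, then positive sign", {
  # calculated row: 100 at the pixel, 104 and 96 at +/-1 mm -> |delta| = 2
  # both sides; the positive deviation (against the 96 neighbour... sign =
  # measured - calculated) must win at equal distance.
  calc <- dose_plane(matrix(c(104, 100, 96), 1, 3), spacing = 1,
                     origin = c(0, -1), label = "calculated")
  meas <- dose_plane(matrix(102, 1, 1), spacing = 1, origin = c(0, 0))
  crit <- criteria(dose_pct = 3, search_radius_mm = 1)
  d <- compute_ddm(meas, calc, crit, search_spacing_mm = 1)
  px <- d$pixels[d$pixels$evaluated, ]
  # in-place point gives |delta| = 2/1.04... all three nodes give ~2
  expect_equal(px$argmin_distance_mm, 0)    # smaller distance wins first
  meas2 <- dose_plane(matrix(100, 1, 1), spacing = 1, origin = c(0, 0))
  d2 <- compute_ddm(meas2, calc, crit, search_spacing_mm = 1)
  # nodes at distance 1 give deviations -4/1.04 and +4/1.04; node at 0 wins
  expect_equal(d2$pixels$ddm_pct[1], 0)
})

test_that("|DDM| never exceeds the in-place dose difference and shrinks with r", {
  set.seed(23)
  pr <- random_pair()
  fine <- resample_to_search_grid(pr$calculated, 0.5)
  M <- max(fine$values)
  d1 <- compute_ddm(pr$measured, fine, criteria(search_radius_mm = 1),
                    search_spacing_mm = 0.5)
  d2 <- compute_ddm(pr$measured, fine, criteria(search_radius_mm = 2),
                    search_spacing_mm = 0.5)
  # in-place (nearest-node) reference difference
  px <- d1$pixels[d1$pixels$evaluated, ]
  near <- interp_plane(fine,
                       round(px$y_mm / 0.5) * 0.5,
                       round(px$x_mm / 0.5) * 0.5)
  point_diff <- 100 * (px$measured_cgy - near) / M
  expect_true(all(abs(px$ddm_pct) <= abs(point_diff) + 1e-9))
  ev <- d1$pixels$evaluated
  expect_true(all(abs(d2$pixels$ddm_pct[ev]) <= abs(d1$pixels$ddm_pct[ev]) + 1e-12))
  expect_gte(ddm_pass_rate(d2), ddm_pass_rate(d1))
  expect_gte(ddm_pass_rate(d1, tolerance_pct = 5),
             ddm_pass_rate(d1, tolerance_pct = 3))
})

test_that("r below the search-grid spacing is a configuration error", {
  p <- aligned_uniform()
  expect_error(compute_ddm(p$measured, p$calculated,
                           criteria(search_radius_mm = 0.2),
                           search_spacing_mm = 0.5),
               class = "ddmqa_config_error")
})

test_that("edge pixels with clipped search disks are flagged truncated", {
  calc <- uniform_plane(100, 20, 1)
  meas <- dose_plane(matrix(100, 3, 3), spacing = 10, origin = c(-10, -10))
  d <- compute_ddm(meas, calc, criteria(search_radius_mm = 1),
                   search_spacing_mm = 0.5)
  tr <- matrix(d$pixels$truncated, 3, 3)
  expect_true(all(tr[c(1, 3), ]))
  expect_true(all(tr[, c(1, 3)]))
  expect_false(tr[2, 2])
})

test_that("histogram counts, mu and sigma match direct formulas", {
  p <- aligned_uniform()
  d <- compute_ddm(p$measured, p$calculated, criteria(),
                   search_spacing_mm = 0.5)
  h0 <- ddm_histogram(d)
  expect_equal(nrow(h0$bins[h0$bins$count > 0, ]), 1)
  expect_equal(h0$bins$bin_center[h0$bins$count > 0], 0)
  expect_equal(h0$mu, 0)
  expect_equal(h0$sigma, 0)
  expect_equal(sum(h0$bins$count), sum(d$pixels$evaluated))

  # values {-1, +1}: mu 0, sigma 1
  fake <- d
  n <- sum(fake$pixels$evaluated)
  vals <- rep(c(-1, 1), length.out = n)
  fake$pixels$ddm_pct[fake$pixels$evaluated] <- vals
  h <- ddm_histogram(fake, bin_width_pct = 0.5)
  expect_equal(h$mu, mean(vals))
  expect_equal(h$sigma, stats::sd(vals))
  expect_equal(sum(h$bins$count), n)
  expect_error(ddm_histogram(d, bin_width_pct = 0),
               class = "ddmqa_config_error")
})

test_that("pass rates recount a hand-mixed map", {
  p <- aligned_uniform(n_meas = 4, pitch = 6)
  d <- compute_ddm(p$measured, p$calculated, criteria(),
                   search_spacing_mm = 0.5)
  vals <- c(rep(0, 6), rep(2.9, 4), rep(3.0, 3), rep(5, 3))
  d$pixels$ddm_pct[d$pixels$evaluated] <- vals
  expect_equal(ddm_pass_rate(d, 3), 100 * 10 / 16)
  expect_equal(ddm_pass_rate(d, 3, boundary = "inclusive"), 100 * 13 / 16)
})
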