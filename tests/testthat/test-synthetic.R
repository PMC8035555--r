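test_that("rendered spot fields have the right peaks, symmetry and integral", {
  one <- spot_field(spots = data.frame(x_mm = 0, y_mm = 0, weight = 100,
                                       sigma_mm = 5))
  pl <- render_plane(one, spacing_mm = 1)
  tb <- tibble::as_tibble(pl)
  peak <- tb[which.max(tb$dose_cgy), ]
  expect_equal(c(peak$y_mm, peak$x_mm), c(0, 0))
  expect_equal(peak$dose_cgy, 100)

  two <- spot_field(spots = data.frame(x_mm = c(-20, 20), y_mm = 0,
                                       weight = 80, sigma_mm = 4))
  p2 <- render_plane(two, spacing_mm = 1)
  m <- p2$values
  expect_equal(m, m[, rev(seq_len(ncol(m)))], tolerance = 1e-12)

  # quadrature total = sum of w * 2 pi sigma^2 within discretization error
  grid <- spot_field(extent_mm = 15, pitch_mm = 5, sigma_mm = 5, weight = 10)
  pg <- render_plane(grid, spacing_mm = 1, margin_mm = 20)
  total <- sum(pg$values) * prod(pg$spacing)
  analytic <- sum(grid$spots$weight * 2 * pi * grid$spots$sigma_mm^2)
  expect_equal(total, analytic, tolerance = 1e-4)
})

test_that("apply_error implements each error family exactly", {
  pl <- uniform_plane(100, 40, 2)
  ident <- apply_error(pl, error_spec("global_scale", magnitude_pct = 0))
  expect_identical(ident$values, pl$values)

  rg <- c(-10, 10, -10, 10)
  off <- apply_error(pl, error_spec("region_offset", magnitude_pct = 5,
                                    region = rg))
  inside <- abs(plane_rows_mm(pl)) <= 10
  expect_true(all(off$values[inside, inside] == 105))
  expect_true(all(off$values[!inside, ] == 100))
  expect_error(apply_error(pl, error_spec("region_offset", magnitude_pct = 5,
                                          region = c(-100, 100, 0, 1))),
               class = "ddmqa_config_error")

  noisy1 <- apply_error(pl, error_spec("noise", magnitude_pct = 1, seed = 4))
  noisy2 <- apply_error(pl, error_spec("noise", magnitude_pct = 1, seed = 4))
  expect_identical(noisy1$values, noisy2$values)   # bit-identical at a seed
  expect_false(identical(noisy1$values, pl$values))
})

test_that("spot jitter draws have the requested spread", {
  f <- spot_field(extent_mm = 40, pitch_mm = 4)   # 21 x 21 = 441 spots
  pl <- render_plane(f, spacing_mm = 2)
  j <- apply_error(pl, error_spec("spot_jitter", jitter_mm = 0.19, seed = 8),
                   field = f)
  draws <- attr(j, "jitter_draws_mm")
  expect_equal(nrow(draws), nrow(f$spots))
  expect_equal(stats::sd(c(draws$dx_mm, draws$dy_mm)), 0.19, tolerance = 0.1)
  j2 <- apply_error(pl, error_spec("spot_jitter", jitter_mm = 0.19, seed = 8),
                    field = f)
  expect_identical(j$values, j2$values)
})

test_that("detector sampling uses the chamber pitch and the true interpolant", {
  f <- spot_field(extent_mm = 30)
  calc <- render_plane(f, spacing_mm = 1)
  det <- downsample_to_detector(calc, 7.62)
  expect_equal(det$spacing, c(7.62, 7.62))
  expect_equal(diff(plane_cols_mm(det))[1], 7.62)
  ys <- plane_rows_mm(det)
  xs <- plane_cols_mm(det)
  tru <- interp_plane(calc, rep(ys, times = length(xs)),
                      rep(xs, each = length(ys)))
  expect_equal(as.vector(det$values), tru)
  cst <- downsample_to_detector(uniform_plane(7, 30, 1), 7.62)
  expect_true(all(cst$values == 7))
  expect_error(downsample_to_detector(calc, 0.5),
               class = "ddmqa_config_error")
})

test_that("folded-normal sampling matches its moment targets", {
  tight <- sample_radial_deviations(500, 0.5, 1e-9, seed = 2)
  expect_equal(mean(tight$radial_deviation_mm), 0.5, tolerance = 1e-6)
  expect_lt(stats::sd(tight$radial_deviation_mm), 1e-6)

  d <- sample_radial_deviations(10000, 0.38, 0.19, seed = 14)
  s <- summarize_deviations(d)
  expect_equal(s$mean_mm, 0.38, tolerance = 0.01)
  expect_equal(s$sd_mm, 0.19, tolerance = 0.01)
  expect_equal(s$frac_below_limit, 0.999, tolerance = 2e-3)

  d2 <- sample_radial_deviations(10000, 0.38, 0.19, seed = 14)
  expect_identical(d$radial_deviation_mm, d2$radial_deviation_mm)
  expect_error(sample_radial_deviations(100, 0.1, 0.5, seed = 1),
               class = "ddmqa_config_error")   # infeasible moment pair
})

test_that("synth_pair presets are deterministic and carry their manifest", {
  a <- synth_pair("region-error", magnitude_pct = 5, seed = 3)
  b <- synth_pair("region-error", magnitude_pct = 5, seed = 3)
  expect_identical(a$measured$values, b$measured$values)
  expect_identical(a$calculated$values, b$calculated$values)
  expect_equal(a$manifest$magnitude_pct, 5)
  expect_equal(a$measured$label, "measured")
  expect_equal(a$calculated$label, "calculated")
  expect_equal(a$measured$spacing, c(7.62, 7.62))
  j <- synth_pair("jitter", jitter_mm = 0.2, seed = 6, field_size_mm = 60)
  expect_equal(j$manifest$jitter_mm, 0.2)
  expect_false(identical(j$measured$values,
                         downsample_to_detector(j$calculated, 7.62)$values))
})
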