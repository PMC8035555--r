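test_that("the full pipeline report agrees with direct module calls", {
  pair <- synth_pair("region-error", magnitude_pct = 5, field_size_mm = 80)
  crit <- criteria()
  cmp <- compare_planes(pair$measured, pair$calculated, crit,
                        register = FALSE, search_spacing_mm = 0.5)
  g <- compute_gamma(pair$measured, pair$calculated, crit,
                     search_spacing_mm = 0.5)
  d <- compute_ddm(pair$measured, pair$calculated, crit,
                   search_spacing_mm = 0.5)
  expect_equal(cmp$gamma_pass_rate, gamma_pass_rate(g))
  expect_equal(cmp$ddm_pass_rate, ddm_pass_rate(d))
  gl <- glance(cmp)
  expect_equal(gl$gamma_pass_rate_pct, gamma_pass_rate(g))
  expect_equal(gl$mu_pct, mean(d$pixels$ddm_pct[d$pixels$evaluated]))
})

test_that("an identical pair passes everything at 100%", {
  pair <- synth_pair("identical", field_size_mm = 60)
  cmp <- compare_planes(pair$measured, pair$calculated, criteria(),
                        register = FALSE, search_spacing_mm = 0.5)
  expect_equal(cmp$gamma_pass_rate, 100)
  expect_equal(cmp$ddm_pass_rate, 100)
})

test_that("run_compare reads files, writes a stable JSON report and a pixel CSV", {
  pair <- synth_pair("region-error", magnitude_pct = 5, field_size_mm = 80)
  mp <- withr::local_tempfile(fileext = ".csv")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_dose_plane(pair$measured, mp)
  write_dose_plane(pair$calculated, cp)
  out1 <- withr::local_tempfile(fileext = ".json")
  out2 <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  r1 <- run_compare(mp, cp, criteria(), out_json = out1, out_csv = csv,
                    register = FALSE, search_spacing_mm = 0.5)
  run_compare(mp, cp, criteria(), out_json = out2,
              register = FALSE, search_spacing_mm = 0.5)
  expect_identical(readLines(out1), readLines(out2))  # byte-identical rerun
  js <- jsonlite::fromJSON(out1)
  expect_equal(js$gamma$pass_rate_pct, r1$gamma_pass_rate)
  expect_equal(js$ddm$pass_rate_pct, r1$ddm_pass_rate)
  expect_equal(js$criteria$dose_pct, 3)
  expect_named(js$histogram, c("bin_width_pct", "bin_center", "count"))
  tab <- utils::read.csv(csv)
  expect_equal(nrow(tab), length(pair$measured$values))
  expect_true(all(c("gamma", "ddm_pct", "gamma_argmin_distance_mm") %in%
                    names(tab)))
})

test_that("report JSON round-trips the headline numbers", {
  pair <- synth_pair("global-scale", magnitude_pct = -3, field_size_mm = 60)
  cmp <- compare_planes(pair$measured, pair$calculated, criteria(),
                        register = FALSE, search_spacing_mm = 0.5)
  js <- jsonlite::fromJSON(report_json(cmp))
  expect_equal(js$ddm$mu_pct, cmp$histogram$mu)
  expect_equal(js$ddm$r_mm, 1)
  expect_false(js$ddm$mu_within_1pct)
  expect_equal(sum(js$histogram$count), cmp$histogram$n)
})

test_that("the heat map marks exactly the gamma-failing pixels", {
  pair <- synth_pair("region-error", magnitude_pct = 8, field_size_mm = 80)
  crit <- criteria()
  g <- compute_gamma(pair$measured, pair$calculated, crit,
                     search_spacing_mm = 0.5)
  d <- compute_ddm(pair$measured, pair$calculated, crit,
                   search_spacing_mm = 0.5)
  p <- ddm_heatmap(d, g)
  n_fail <- sum(g$pixels$gamma[g$pixels$evaluated] > 1)
  expect_gt(n_fail, 0)
  star_layer <- p$layers[[length(p$layers)]]
  expect_equal(nrow(star_layer$data), n_fail)
  expect_equal(star_layer$aes_params$shape, 8)
  # all-pass map draws no asterisks
  ok <- synth_pair("identical", field_size_mm = 60)
  g0 <- compute_gamma(ok$measured, ok$calculated, crit, search_spacing_mm = 0.5)
  d0 <- compute_ddm(ok$measured, ok$calculated, crit, search_spacing_mm = 0.5)
  p0 <- ddm_heatmap(d0, g0)
  expect_equal(length(p0$layers), 1)
  # shape mismatch is an error
  small <- compute_ddm(
    dose_plane(pair$measured$values[1:5, 1:5], pair$measured$spacing,
               pair$measured$origin), pair$calculated, crit,
    search_spacing_mm = 0.5)
  expect_error(ddm_heatmap(small, g), class = "ddmqa_comparison_error")
})

test_that("the histogram figure uses a log count axis with tolerance lines", {
  pair <- synth_pair("region-error", magnitude_pct = 5, field_size_mm = 80)
  d <- compute_ddm(pair$measured, pair$calculated, criteria(),
                   search_spacing_mm = 0.5)
  h <- ddm_histogram(d)
  p <- ggplot2::autoplot(h)
  b <- ggplot2::ggplot_build(p)
  expect_equal(b$layout$panel_scales_y[[1]]$trans$name, "log-10")
  vlines <- p$layers[[2]]$data
  expect_s3_class(p, "ggplot")
  f <- withr::local_tempfile(fileext = ".pdf")
  ggplot2::ggsave(f, p, width = 6, height = 4)
  expect_true(file.exists(f))
})

test_that("tidiers expose per-pixel tables and one-row summaries", {
  pair <- synth_pair("identical", field_size_mm = 60)
  g <- compute_gamma(pair$measured, pair$calculated, criteria(),
                     search_spacing_mm = 0.5)
  td <- generics::tidy(g)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("gamma", "argmin_distance_mm", "evaluated") %in% names(td)))
  gl <- generics::glance(g)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$pass_rate_pct, 100)
})
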