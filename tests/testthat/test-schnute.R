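test_that("schnute_eval matches its closed-form definition and boundaries", {
  p <- schnute_params(2.14e-3, 0.47, 20.6, 1310)
  expect_equal(schnute_eval(p, p$t_max), p$y_max)
  expect_equal(schnute_eval(p, 0), 0)
  # frozen value from an independent 30-digit evaluation of the same form
  expect_equal(schnute_eval(p, 655), 12.8974920866869, tolerance = 1e-12)
  expect_error(schnute_params(NA, 0.5, 10, 100), "finite")
  expect_error(schnute_params(-1e-3, 0.5, 10, 100), "> 0")
  expect_error(schnute_eval(p, -5), ">= 0")
})

test_that("schnute_eval is monotone non-decreasing for all cultivar parameter sets", {
  tt <- seq(0, 2000, by = 10)
  for (p in table4_params()) {
    y <- schnute_eval(p, pmin(tt, p$t_max))
    expect_true(all(diff(y) >= -1e-12))
    expect_true(all(is.finite(y)))
  }
})

test_that("schnute_rate agrees with a brute-force derivative scan", {
  for (p in table4_params()) {
    r <- schnute_rate(p)
    expect_false(r$boundary)
    tt <- seq(0.5, p$t_max, by = 0.5)
    dy <- schnute_deriv(p, tt)
    i <- which.max(dy)
    expect_lt(abs(tt[i] - r$t_star), 1)
    expect_lt(abs(dy[i] - r$v_max) / r$v_max, 0.01)
    # far beyond saturation the rate decays towards zero
    expect_lt(schnute_deriv(p, 3 * p$t_max), 0.05 * r$v_max)
  }
})

test_that("maximal appearance rates match the reference cultivar values", {
  r_china <- schnute_rate(schnute_params(2.14e-3, 0.47, 20.6, 1310))
  expect_equal(r_china$t_star, 352.814291718707, tolerance = 1e-10)
  expect_lt(abs(r_china$t_star - 350) / 350, 0.05)
  expect_lt(abs(r_china$v_max - 0.026) / 0.026, 0.10)
  r_james <- schnute_rate(schnute_params(1.94e-3, 0.49, 25.6, 1445))
  expect_lt(abs(r_james$t_star - 360) / 360, 0.05)
})

test_that("a shape exponent >= 1 puts the maximal rate at the domain boundary", {
  r <- schnute_rate(schnute_params(1e-3, 1.3, 20, 1500))
  expect_true(r$boundary)
})

test_that("fitting noiseless data recovers the generating parameters", {
  p <- schnute_params(1.18e-3, 0.57, 32.9, 1630)
  s <- simulate_series(p, seq(200, 1630, length.out = 21))
  fit <- schnute_fit(s)
  expect_true(fit$converged)
  expect_lt(fit$rmse, 1e-8)
  expect_equal(fit$params$A, p$A, tolerance = 1e-6)
  expect_equal(fit$params$B, p$B, tolerance = 1e-6)
  expect_equal(fit$params$y_max, p$y_max, tolerance = 1e-6)
  expect_equal(fit$params$t_max, 1630)  # fixed to the last observation
})

test_that("degenerate or insufficient series are refused", {
  expect_error(schnute_fit(phytomer_series("p", c(100, 200, 300), c(1, 2, 3))),
               "insufficient")
  s <- phytomer_series("p", seq(100, 700, by = 100), rep(5, 7))
  expect_error(schnute_fit(s), "degenerate")
  expect_warning(phytomer_series("p", c(1, 2, 3), c(3, 2, 2)), "monotone")
  expect_error(phytomer_series("p", c(1, 2, 2), c(1, 2, 3)), "increasing")
})

test_that("noisy multi-plant fits recover y_max within the reference spread", {
  p <- schnute_params(0.80e-3, 0.65, 37.6, 1890)
  times <- seq(200, 1890, length.out = 21)
  fits <- lapply(1:8, function(i)
    schnute_fit(simulate_series(p, times, sigma = 0.5, seed = 400 + i)))
  ymax_hat <- mean(vapply(fits, function(f) f$params$y_max, 0))
  expect_lt(abs(ymax_hat - 37.6), 1.6)
})

test_that("series CSV reader and cultivar summary table round-trip", {
  p <- table4_params()$China
  times <- seq(200, 1310, length.out = 15)
  df <- do.call(rbind, lapply(1:3, function(i)
    data.frame(plant_id = paste0("china_", i), thermal_time_dd = times,
               phytomer_count = schnute_eval(p, times))))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  series <- read_phytomer_series(path)
  expect_length(series, 3)
  fits <- lapply(series, schnute_fit)
  tab <- schnute_table(fits, rep("China", 3))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$A_e3, 2.14, tolerance = 1e-4)
  expect_equal(tab$y_max, 20.6, tolerance = 1e-4)
  expect_lt(abs(tab$t_star_dd - 352.8), 0.5)
})
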