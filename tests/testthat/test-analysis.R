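fake_records <- function(x, y, h = NULL, dev = NULL) {
  df <- data.frame(share_theoretical = x, share_computed = y)
  if (!is.null(h)) df$height_ratio <- h
  if (!is.null(dev)) df$deviation <- dev
  df
}

test_that("share regressions recover exact linear relations", {
  x <- seq(0.1, 0.9, by = 0.1)
  r <- suppressWarnings(regress_shares(fake_records(x, x)))  # exact fit
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  r2 <- regress_shares(fake_records(x, 1.28 * x), through_origin = TRUE)
  expect_equal(r2$slope, 1.28, tolerance = 1e-12)
  expect_error(regress_shares(fake_records(0.5, 0.5)), "at least 2")
  expect_error(regress_shares(fake_records(rep(0.5, 5), runif(5))),
               "degenerate")
})

test_that("noisy regression slopes fall within the analytic standard error", {
  withr::with_seed(7, {
    x <- runif(60, 0.1, 0.9)
    y <- 0.4 + 0.9 * x + rnorm(60, 0, 0.03)
    r <- regress_shares(fake_records(x, y))
    # closed-form OLS slope standard error as the oracle
    fit_res <- y - (r$intercept + r$slope * x)
    se <- sqrt(sum(fit_res^2) / 58 / sum((x - mean(x))^2))
    expect_lt(abs(r$slope - 0.9), 3 * se)
  })
})

test_that("height-ratio curve recovers a saturating exponential", {
  withr::with_seed(21, {
    h <- runif(80, 1, 3)
    dev <- 0.2 * (1 - exp(-3 * (h - 1))) + rnorm(80, 0, 0.005)
    fit <- height_ratio_curve(fake_records(h, h, h = h, dev = dev))
    expect_lt(abs(fit$asymptote - 0.2) / 0.2, 0.10)
    expect_lt(abs(fit$rate - 3) / 3, 0.10)
    expect_true(fit$saturating)
  })
})

test_that("flat or degenerate deviation data are flagged or refused", {
  withr::with_seed(22, {
    h <- runif(40, 1, 3)
    dev <- rnorm(40, 0, 0.004)  # independent of height ratio
    fit <- suppressWarnings(height_ratio_curve(fake_records(h, h, h = h,
                                                            dev = dev)))
    expect_false(fit$saturating)
  })
  expect_error(height_ratio_curve(fake_records(rep(1, 6), rep(1, 6),
                                               h = rep(1, 6),
                                               dev = rep(0, 6))),
               "degenerate|spread")
})

test_that("stage experiments produce complete, reproducible records", {
  spec <- scene_spec(plot_x = 0.34, plot_y = 0.34, seed = 1)
  rec <- run_stage_experiment(300, "Lucy", spec = spec, seeds = 5,
                              n_rays_per_sector = 2e3, n_variants = 2)
  expect_equal(nrow(rec), 1)
  num <- vapply(rec, is.numeric, TRUE)
  expect_true(all(is.finite(unlist(rec[, num]))))
  expect_true(rec$share_computed >= 0 && rec$share_computed <= 1)
  expect_true(abs(rec$deviation) <= 1)
  rec2 <- run_stage_experiment(300, "Lucy", spec = spec, seeds = 5,
                               n_rays_per_sector = 2e3, n_variants = 2)
  expect_identical(rec, rec2)
})

test_that("experiments yield one record per genotype-replicate pair", {
  spec <- scene_spec(plot_x = 0.34, plot_y = 0.34, seed = 1)
  rec <- run_stage_experiment(300, c("Lucy", "James"), spec = spec,
                              seeds = c(3, 4), n_rays_per_sector = 1e3,
                              n_variants = 2)
  expect_equal(nrow(rec), 4)
  expect_setequal(unique(rec$genotype), c("Lucy", "James"))
  summ <- stage_regression_summary(rec)
  expect_equal(nrow(summ), 1)
  expect_equal(summ$n, 4)
})

test_that("raising pea internode length raises the pea light share", {
  spec0 <- pea_genotype("Lucy")
  sspec <- scene_spec(plot_x = 0.34, plot_y = 0.34, seed = 1)
  shares <- vapply(c(1, 1.7, 2.6), function(f) {
    spec <- spec0
    spec$internode_profile$scale_mm <- spec0$internode_profile$scale_mm * f
    rec <- run_stage_experiment(600, list(spec), spec = sspec, seeds = 1:2,
                                n_rays_per_sector = 4e3, n_variants = 3)
    mean(rec$share_computed)
  }, 0)
  expect_true(all(diff(shares) > 0))
})
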