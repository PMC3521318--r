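#' Run a stage-wise light-sharing experiment
#'
#' For each (genotype, replicate) pair: builds a set of pea mock-up variants
#' and wheat mock-ups at the stage, assembles the row mixture, measures the
#' canopy descriptors, computes the pea share of intercepted diffuse light by
#' ray casting, and the theoretical well-mixed share from the scene's own
#' descriptors (extinction coefficients from the per-species mean foliage
#' inclinations, relative LAI of pea). The deviation (computed minus
#' theoretical) and the wheat/pea height ratio are recorded per simulation.
#'
#' @param stage_dd thermal time of the stage (DD).
#' @param genotypes character vector of shipped cultivar names, or a list of
#'   `genotype_spec` objects.
#' @param spec a [scene_spec()] (its `seed` is overridden per replicate).
#' @param sky a [build_sky()] vault.
#' @param seeds integer vector of replicate seeds (default 1:8, mirroring the
#'   eight plants per cultivar of the reference design).
#' @param n_rays_per_sector ray budget per sky sector.
#' @param n_variants number of distinct plant mock-ups recycled per species.
#' @param on_error `"stop"` or `"record"` (failed records carry NAs plus an
#'   `error` message).
#' @return A data.frame of class `simulation_records`, one row per
#'   (genotype, replicate).
#' @export
run_stage_experiment <- function(stage_dd, genotypes, spec = scene_spec(),
                                 sky = build_sky(), seeds = 1:8,
                                 n_rays_per_sector = 1e5, n_variants = 8,
                                 on_error = c("stop", "record")) {
  on_error <- match.arg(on_error)
  if (length(genotypes) < 1 || length(seeds) < 1)
    stop("need at least one genotype and one replicate seed")
  if (is.character(genotypes))
    genotypes <- lapply(genotypes, pea_genotype)
  wstage <- wheat_stage(stage_dd)
  rows <- list()
  for (g in seq_along(genotypes)) {
    gspec <- genotypes[[g]]
    for (r in seq_along(seeds)) {
      seed <- as.integer(seeds[r])
      row <- tryCatch(
        simulate_one_mixture(stage_dd, gspec, wstage, spec, sky, seed,
                             n_rays_per_sector, n_variants),
        error = function(e) {
          if (on_error == "stop") stop(e)
          message("record failed (", gspec$name, ", seed ", seed, "): ",
                  conditionMessage(e))
          data.frame(stage = stage_dd, genotype = gspec$name, seed = seed,
                     error = conditionMessage(e))
        })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("simulation_records", "data.frame")
  out
}

simulate_one_mixture <- function(stage_dd, gspec, wstage, spec, sky, seed,
                                 n_rays_per_sector, n_variants) {
  pea <- mockup_variants(function(s) build_pea(gspec, stage_dd, s),
                         n = n_variants, seed = derive_seed(seed, 1))
  wheat <- mockup_variants(function(s) build_wheat(wstage, s),
                           n = n_variants, seed = derive_seed(seed, 2))
  sspec <- spec
  sspec$seed <- derive_seed(seed, 3)
  scene <- assemble_mixture(pea, wheat, sspec)
  d <- canopy_descriptors(scene)
  res <- diffuse_interception(scene, sky, n_rays_per_sector,
                              seed = derive_seed(seed, 4))
  sh <- species_share(res)
  # diffuse-effective K evaluated at the scene's own optical depth: for erect
  # foliage the directional K(theta) varies strongly, so the effective
  # coefficient of a sparse stand differs markedly from the LAI = 1 value
  ref_lai <- max(sum(d$lai_by_species), 0.05)
  k_pea <- extinction_from_inclination(d$mean_inclination_by_species[["pea"]],
                                       sky, ref_lai = ref_lai)
  k_wheat <- extinction_from_inclination(d$mean_inclination_by_species[["wheat"]],
                                         sky, ref_lai = ref_lai)
  p <- d$lai_by_species[["pea"]] /
    (d$lai_by_species[["pea"]] + d$lai_by_species[["wheat"]])
  th <- share_theoretical(k_pea / k_wheat, p)
  data.frame(
    stage = stage_dd, genotype = gspec$name, seed = seed,
    lai_pea = d$lai_by_species[["pea"]],
    lai_wheat = d$lai_by_species[["wheat"]],
    p_pea = p,
    incl_pea = d$mean_inclination_by_species[["pea"]],
    incl_wheat = d$mean_inclination_by_species[["wheat"]],
    height_pea = d$height_by_species[["pea"]],
    height_wheat = d$height_by_species[["wheat"]],
    height_ratio = d$height_ratio,
    k_pea = k_pea, k_wheat = k_wheat,
    share_computed = sh$pea_share,
    share_stderr = sh$stderr,
    share_theoretical = th,
    deviation = sh$pea_share - th,
    total_interception = sum(res$fraction_by_species),
    stringsAsFactors = FALSE)
}

#' Regress computed light shares on theoretical shares
#'
#' Ordinary least squares of `share_computed` on `share_theoretical`, either
#' with a free intercept (default) or constrained through the origin. R2 is
#' the squared correlation for the free fit and the uncentered R2 for the
#' origin-constrained fit.
#'
#' @param records a `simulation_records` data.frame (or any data.frame with
#'   `share_computed` and `share_theoretical`).
#' @param through_origin logical.
#' @return An object of class `regression_result`: `slope`, `intercept`,
#'   `r2`, `n`.
#' @export
regress_shares <- function(records, through_origin = FALSE) {
  df <- records[stats::complete.cases(records[, c("share_computed",
                                                  "share_theoretical")]), ]
  if (nrow(df) < 2) stop("need at least 2 complete records")
  if (diff(range(df$share_theoretical)) == 0)
    stop("degenerate regressor: all theoretical shares equal")
  if (through_origin) {
    fit <- stats::lm(share_computed ~ 0 + share_theoretical, data = df)
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum(df$share_computed^2)
    slope <- stats::coef(fit)[[1]]
    intercept <- 0
  } else {
    fit <- stats::lm(share_computed ~ share_theoretical, data = df)
    r2 <- summary(fit)$r.squared
    slope <- stats::coef(fit)[[2]]
    intercept <- stats::coef(fit)[[1]]
  }
  structure(list(slope = slope, intercept = intercept, r2 = r2, n = nrow(df),
                 through_origin = through_origin, fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("share_computed = %.3f x share_theoretical%s (R2 = %.3f, n = %d%s)\n",
              x$slope,
              if (x$through_origin) "" else sprintf(" %+.3f", x$intercept),
              x$r2, x$n,
              if (x$through_origin) ", through origin" else ""))
  invisible(x)
}

#' Saturating-exponential fit of share deviations vs species height ratio
#'
#' Fits `deviation = a * (1 - exp(-b * (h - 1)))` over records with
#' height ratio `h >= 1` (wheat taller than pea) by nonlinear least squares:
#' the deviation from the well-mixed prediction grows with vertical dominance
#' and saturates for height ratios beyond about 2. The fit is flagged
#' non-saturating when the rate is near zero or the exponential model does
#' not beat a constant model.
#'
#' @param records a `simulation_records` data.frame with `deviation` and
#'   `height_ratio` columns.
#' @param h_min minimum height ratio retained (default 1).
#' @return An object of class `height_curve_fit`: `asymptote`, `rate`, `r2`,
#'   `n`, `saturating`.
#' @export
height_ratio_curve <- function(records, h_min = 1) {
  df <- records[stats::complete.cases(records[, c("deviation", "height_ratio")]) &
                  records$height_ratio >= h_min, ]
  if (nrow(df) < 4) stop("need at least 4 records with height_ratio >= ", h_min)
  if (diff(range(df$height_ratio)) < 1e-8)
    stop("degenerate fit: no spread in height ratio")
  h <- df$height_ratio; y <- df$deviation
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("degenerate fit: deviations have no variance")
  start <- list(a = stats::quantile(y, 0.9, names = FALSE), b = 2)
  if (abs(start$a) < 1e-6) start$a <- 0.1
  fit <- minpack.lm::nlsLM(y ~ a * (1 - exp(-b * (h - 1))),
                           start = start,
                           lower = c(a = -1, b = 0), upper = c(a = 1, b = 100))
  cf <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  r2 <- 1 - ss_res / ss_tot
  # a constant model has one parameter; the exponential must explain more
  saturating <- cf[["b"]] > 0.1 && r2 > 0.05
  structure(list(asymptote = cf[["a"]], rate = cf[["b"]], r2 = r2,
                 n = nrow(df), saturating = saturating, fit = fit),
            class = "height_curve_fit")
}

#' @export
print.height_curve_fit <- function(x, ...) {
  cat(sprintf("deviation = %.3f x (1 - exp(-%.2f (h - 1))); R2 = %.3f, n = %d%s\n",
              x$asymptote, x$rate, x$r2, x$n,
              if (!x$saturating) " [non-saturating]" else ""))
  invisible(x)
}

#' Write simulation records to CSV
#' @param records a `simulation_records` data.frame.
#' @param path CSV output path.
#' @export
write_records_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(records)
}

#' Read simulation records from CSV
#' @param path CSV path written by [write_records_csv()].
#' @export
read_records_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("simulation_records", "data.frame")
  out
}

#' Per-stage regression summary of simulation records
#'
#' @param records a `simulation_records` data.frame (possibly several stages).
#' @return data.frame with one row per stage: free-intercept and
#'   origin-constrained slopes and R2.
#' @export
stage_regression_summary <- function(records) {
  rows <- lapply(split(records, records$stage), function(df) {
    free <- regress_shares(df, through_origin = FALSE)
    orig <- regress_shares(df, through_origin = TRUE)
    data.frame(stage = df$stage[1], n = free$n,
               slope = free$slope, intercept = free$intercept, r2 = free$r2,
               slope_origin = orig$slope, r2_origin = orig$r2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
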