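#' Schnute growth-curve parameters
#'
#' Container for the parameters of the Schnute phytomer-appearance model
#' \deqn{Y(t) = y_{max} \left(\frac{1 - e^{-A t}}{1 - e^{-A t_{max}}}\right)^{1/B}}
#' where `Y` is the number of visible phytomers on the main stem at thermal
#' time `t` (degree-days, DD, base 0 degrees C). `A` (per DD) and `B`
#' (dimensionless) set the shape of the sigmoid, `t_max` is the end of the
#' fitted thermal-time domain and `y_max` is the value of `Y` at `t_max`.
#' Emergence is at `t = 0`, where `Y = 0`.
#'
#' @param A rate constant (per DD), > 0.
#' @param B shape exponent (dimensionless), > 0.
#' @param y_max phytomer count reached at `t_max`, > 0.
#' @param t_max end of the thermal-time domain (DD), > 0.
#' @return An object of class `schnute_params`.
#' @examples
#' p <- schnute_params(A = 2.14e-3, B = 0.47, y_max = 20.6, t_max = 1310)
#' schnute_eval(p, c(0, 655, 1310))
#' @export
schnute_params <- function(A, B, y_max, t_max) {
  vals <- c(A = A, B = B, y_max = y_max, t_max = t_max)
  if (any(!is.finite(vals)))
    stop("invalid Schnute parameters: all of A, B, y_max, t_max must be finite")
  if (any(vals <= 0))
    stop("invalid Schnute parameters: all of A, B, y_max, t_max must be > 0")
  structure(list(A = A, B = B, y_max = y_max, t_max = t_max),
            class = "schnute_params")
}

#' @export
print.schnute_params <- function(x, ...) {
  cat(sprintf(
    "Schnute parameters: A = %.4g DD^-1, B = %.3g, y_max = %.3f phytomers, t_max = %.0f DD\n",
    x$A, x$B, x$y_max, x$t_max))
  invisible(x)
}

stopifnot_schnute <- function(params) {
  if (!inherits(params, "schnute_params"))
    params <- do.call(schnute_params, as.list(params)[c("A", "B", "y_max", "t_max")])
  params
}

#' Evaluate the Schnute phytomer-appearance curve
#'
#' @param params a [schnute_params()] object.
#' @param t thermal time(s) in DD, >= 0.
#' @return Numeric vector of phytomer counts (real-valued; round to get the
#'   integer number of visible phytomers).
#' @seealso [schnute_rate()], [schnute_fit()]
#' @export
schnute_eval <- function(params, t) {
  params <- stopifnot_schnute(params)
  if (any(t < 0)) stop("t must be >= 0")
  denom <- 1 - exp(-params$A * params$t_max)
  f <- (1 - exp(-params$A * t)) / denom
  params$y_max * f^(1 / params$B)
}

#' First derivative of the Schnute curve (phytomer appearance rate)
#'
#' @inheritParams schnute_eval
#' @return Rate dY/dt in phytomers per DD.
#' @export
schnute_deriv <- function(params, t) {
  params <- stopifnot_schnute(params)
  if (any(t < 0)) stop("t must be >= 0")
  A <- params$A; B <- params$B
  denom <- 1 - exp(-A * params$t_max)
  f <- (1 - exp(-A * t)) / denom
  # limit t -> 0 handled explicitly: f^(1/B - 1) diverges for B > 1
  out <- params$y_max / B * f^(1 / B - 1) * A * exp(-A * t) / denom
  out[t == 0 & B < 1] <- 0
  out
}

# Inverse of the curve: thermal time at which Y(t) = y (0 < y < y_max).
schnute_inverse <- function(params, y) {
  A <- params$A; B <- params$B
  denom <- 1 - exp(-A * params$t_max)
  g <- (y / params$y_max)^B * denom
  if (any(g >= 1)) stop("y out of reachable range for these parameters")
  -log(1 - g) / A
}

#' Maximum phytomer-appearance rate from a Schnute curve
#'
#' Locates the thermal time of maximal dY/dt on (0, t_max] and the rate there.
#' For the adopted form the interior maximum is closed form,
#' `t_star = -log(B)/A` (for B < 1); when the maximiser falls outside
#' (0, t_max] the rate is maximal at a domain boundary, which is flagged.
#'
#' @param params a [schnute_params()] object.
#' @return An object of class `rate_summary` with fields `t_star` (DD),
#'   `v_max` (phytomers per DD) and `boundary` (logical).
#' @examples
#' schnute_rate(schnute_params(2.14e-3, 0.47, 20.6, 1310))
#' @export
schnute_rate <- function(params) {
  params <- stopifnot_schnute(params)
  A <- params$A; B <- params$B; t_max <- params$t_max
  boundary <- FALSE
  if (B < 1) {
    t_star <- -log(B) / A
    if (t_star > t_max) {          # rate still rising at the end of the domain
      t_star <- t_max
      boundary <- TRUE
    }
  } else {
    # B >= 1: dY/dt is non-increasing on (0, t_max]; supremum at the origin.
    # Smallest-t tie-break: report the lower domain edge and flag it.
    t_star <- 0
    boundary <- TRUE
  }
  v_max <- if (t_star > 0) schnute_deriv(params, t_star) else Inf
  structure(list(t_star = t_star, v_max = v_max, boundary = boundary),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("Maximal phytomer-appearance rate: %.4g phytomer DD^-1 at %.1f DD%s\n",
              x$v_max, x$t_star,
              if (x$boundary) " (domain boundary)" else ""))
  invisible(x)
}

#' Phytomer-count time series for one plant
#'
#' @param plant_id identifier (character or numeric).
#' @param times thermal times (DD), strictly increasing.
#' @param counts visible phytomer counts, non-negative. A decrease between
#'   successive observations (possible for noisy synthetic series) raises a
#'   warning, not an error, since phytomer number cannot truly decrease.
#' @return An object of class `phytomer_series`.
#' @export
phytomer_series <- function(plant_id, times, counts) {
  if (length(times) != length(counts))
    stop("times and counts must have equal length")
  if (any(!is.finite(times)) || any(!is.finite(counts)))
    stop("times and counts must be finite")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(diff(counts) < 0))
    warning("counts are not monotone non-decreasing; treating as noisy observations")
  structure(list(plant_id = plant_id, times = as.numeric(times),
                 counts = as.numeric(counts)),
            class = "phytomer_series")
}

#' Fit the Schnute model to a phytomer-count series
#'
#' Least-squares fit by the Levenberg-Marquardt algorithm
#' ([minpack.lm::nlsLM()]). `t_max` is not a free parameter: it is fixed to the
#' last observation time. Requires at least 5 observations. Non-convergence is
#' never silent: the fit either errors or returns with `converged = FALSE`
#' depending on `on_failure`.
#'
#' @param series a [phytomer_series()] object.
#' @param init optional [schnute_params()] starting values; defaults to
#'   `A = 2/t_max`, `B = 0.5`, `y_max = max(counts)`.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @param on_failure `"error"` (default) or `"flag"`.
#' @return An object of class `schnute_fit`: `params` ([schnute_params()]),
#'   `rmse` (phytomers), `residuals`, `n_iter`, `converged`.
#' @export
schnute_fit <- function(series, init = NULL, max_iter = 200,
                        on_failure = c("error", "flag")) {
  on_failure <- match.arg(on_failure)
  if (!inherits(series, "phytomer_series"))
    stop("series must be a phytomer_series")
  n <- length(series$times)
  if (n < 5) stop("insufficient data: at least 5 observations are required")
  if (diff(range(series$counts)) == 0)
    stop("degenerate series: all counts equal; the sigmoid is unidentifiable")
  t_max <- series$times[n]
  if (is.null(init)) {
    init <- list(A = 2 / t_max, B = 0.5, y_max = max(series$counts))
  } else {
    init <- stopifnot_schnute(init)
  }
  df <- data.frame(t = series$times, y = series$counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y_max * ((1 - exp(-A * t)) / (1 - exp(-A * t_max)))^(1 / B),
      data = df,
      start = list(A = init$A, B = init$B, y_max = init$y_max),
      lower = c(A = 1e-8, B = 1e-6, y_max = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = max_iter)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    msg <- paste("Schnute fit failed:", conditionMessage(fit))
    if (on_failure == "error") stop(msg)
    return(structure(list(params = init, rmse = NA_real_,
                          residuals = rep(NA_real_, n), n_iter = NA_integer_,
                          converged = FALSE, message = msg),
                     class = "schnute_fit"))
  }
  info <- fit$convInfo
  converged <- isTRUE(info$isConv)
  if (!converged && on_failure == "error")
    stop("Schnute fit did not converge after ", info$finIter,
         " iterations: ", info$stopMessage)
  cf <- stats::coef(fit)
  res <- as.numeric(stats::residuals(fit))
  structure(list(
    params = schnute_params(cf[["A"]], cf[["B"]], cf[["y_max"]], t_max),
    rmse = sqrt(mean(res^2)),
    residuals = res,
    n_iter = info$finIter,
    converged = converged),
    class = "schnute_fit")
}

#' @export
print.schnute_fit <- function(x, ...) {
  cat("Schnute fit", if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  print(x$params)
  cat(sprintf("  RMSE = %.3f phytomers over %d observations (%s iterations)\n",
              x$rmse, length(x$residuals), format(x$n_iter)))
  invisible(x)
}

#' Read phytomer-count series from CSV
#'
#' Expects columns `plant_id`, `thermal_time_dd`, `phytomer_count`.
#'
#' @param path CSV file path.
#' @return A named list of [phytomer_series()] objects, one per plant.
#' @export
read_phytomer_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "thermal_time_dd", "phytomer_count")
  if (!all(need %in% names(df)))
    stop("phytomer series CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$plant_id), function(d) {
    d <- d[order(d$thermal_time_dd), ]
    phytomer_series(d$plant_id[1], d$thermal_time_dd, d$phytomer_count)
  })
  out[order(names(out))]
}

#' Summarize Schnute fits in a per-cultivar table
#'
#' Produces one row per label with the mean fitted parameters (`A` reported on
#' the conventional x 10^-3 scale), RMSE and the derived maximal
#' phytomer-appearance rate, optionally written to CSV.
#'
#' @param fits list of [schnute_fit()] objects.
#' @param labels character vector, one label (e.g. cultivar) per fit.
#' @param path optional CSV output path.
#' @return A data.frame with columns `cultivar`, `n_plants`, `A_e3`, `B`,
#'   `y_max`, `rmse`, `t_star_dd`, `v_max`.
#' @export
schnute_table <- function(fits, labels, path = NULL) {
  stopifnot(length(fits) == length(labels))
  rows <- lapply(split(seq_along(fits), labels), function(idx) {
    ps <- lapply(fits[idx], `[[`, "params")
    mean_par <- schnute_params(
      mean(vapply(ps, `[[`, 0, "A")),
      mean(vapply(ps, `[[`, 0, "B")),
      mean(vapply(ps, `[[`, 0, "y_max")),
      mean(vapply(ps, `[[`, 0, "t_max")))
    rate <- schnute_rate(mean_par)
    data.frame(
      cultivar = labels[idx[1]],
      n_plants = length(idx),
      A_e3 = mean_par$A * 1e3,
      B = mean_par$B,
      y_max = mean_par$y_max,
      rmse = mean(vapply(fits[idx], `[[`, 0, "rmse")),
      t_star_dd = rate$t_star,
      v_max = rate$v_max,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
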