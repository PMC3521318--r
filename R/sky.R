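#' Discretize a Uniform Overcast Sky into solid-angle sectors
#'
#' Splits the sky vault into `n_zenith` zenith bands with boundaries equally
#' spaced over \[0, 90\] degrees, each divided into `n_azimuth` equal azimuth
#' sectors (20 sectors under the defaults). Under a Uniform Overcast Sky
#' (direction-independent radiance) the fraction of diffuse flux on the
#' horizontal contributed by a band \[z1, z2\] is proportional to
#' \eqn{\int \cos\theta \sin\theta\, d\theta = (\sin^2 z_2 - \sin^2 z_1)/2},
#' split equally over azimuths and normalized to sum to 1.
#'
#' Sector directions are placed, by default, at the band's upper zenith
#' boundary (18, 36, 54, 72, 90 degrees under the defaults), except that a
#' boundary at exactly 90 degrees is replaced by the band's flux-weighted mean
#' zenith to avoid grazing rays of unbounded path length.
#' `zenith_mode = "band_mean"` instead uses the flux-weighted mean zenith for
#' every band.
#'
#' @param n_zenith number of zenith bands (default 5).
#' @param n_azimuth number of azimuth sectors per band (default 4).
#' @param zenith_mode `"boundary"` (default) or `"band_mean"`.
#' @return An object of class `sky_vault`: a data.frame with columns
#'   `zenith`, `azimuth` (degrees) and `weight` (fractions summing to 1).
#' @examples
#' sky <- build_sky()
#' nrow(sky)        # 20 sectors
#' sum(sky$weight)  # 1
#' @export
build_sky <- function(n_zenith = 5, n_azimuth = 4,
                      zenith_mode = c("boundary", "band_mean")) {
  zenith_mode <- match.arg(zenith_mode)
  if (n_zenith < 1 || n_azimuth < 1) stop("n_zenith and n_azimuth must be >= 1")
  edges <- seq(0, 90, length.out = n_zenith + 1)
  lo <- edges[-(n_zenith + 1)]
  hi <- edges[-1]
  band_w <- sin(hi * pi / 180)^2 - sin(lo * pi / 180)^2  # already sums to 1
  band_zen <- if (zenith_mode == "band_mean") {
    mapply(flux_mean_zenith, lo, hi)
  } else {
    ifelse(hi >= 90, mapply(flux_mean_zenith, lo, hi), hi)
  }
  az <- (seq_len(n_azimuth) - 0.5) * 360 / n_azimuth
  out <- data.frame(
    zenith = rep(band_zen, each = n_azimuth),
    azimuth = rep(az, times = n_zenith),
    weight = rep(band_w / n_azimuth, each = n_azimuth))
  out$weight <- out$weight / sum(out$weight)
  class(out) <- c("sky_vault", "data.frame")
  out
}

# Flux-weighted mean zenith of a band [z1, z2] (degrees) under uniform
# radiance: E[theta] with density proportional to cos(theta) sin(theta).
flux_mean_zenith <- function(z1, z2) {
  a <- z1 * pi / 180; b <- z2 * pi / 180
  # antiderivatives of theta*sin(2theta)/2 and sin(2theta)/2
  num <- function(x) (sin(2 * x) / 4 - x * cos(2 * x) / 2) / 2
  den <- function(x) -cos(2 * x) / 4
  ((num(b) - num(a)) / (den(b) - den(a))) * 180 / pi
}

#' @export
print.sky_vault <- function(x, ...) {
  cat(sprintf("Uniform Overcast Sky vault: %d sectors (%d zenith bands x %d azimuths)\n",
              nrow(x), length(unique(x$zenith)), length(unique(x$azimuth))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write per-sector interception results to CSV
#'
#' @param result an `interception_result` from [diffuse_interception()].
#' @param path CSV output path.
#' @return The per-direction data.frame, invisibly.
#' @export
write_directional_csv <- function(result, path) {
  stopifnot(inherits(result, "interception_result"))
  utils::write.csv(result$per_direction, path, row.names = FALSE)
  invisible(result$per_direction)
}
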