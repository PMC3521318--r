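#' Turbid-medium light interception of a well-mixed multi-species canopy
#'
#' Implements the classical extension of the Beer-Lambert law to well-mixed
#' mixtures: species i intercepts
#' \deqn{LIE_i = \frac{K_i \, LAI_i}{\sum_j K_j LAI_j}
#'       \left(1 - e^{-\sum_j K_j LAI_j}\right)}
#' so that the species' shares of intercepted light are proportional to
#' K x LAI and the total follows a single exponential extinction.
#'
#' @param K extinction coefficients, one per species (>= 0), optionally named.
#' @param LAI leaf area indices (m2 m-2), one per species (>= 0).
#' @return An object of class `theory_prediction`: `lie_by_species`,
#'   `total_interception`, and (for two species) `share_species1`.
#' @examples
#' lie_mixture(K = c(wheat = 0.5, pea = 0.5), LAI = c(1, 1))
#' @export
lie_mixture <- function(K, LAI) {
  if (length(K) != length(LAI) || length(K) < 1)
    stop("K and LAI must be equal-length vectors with >= 1 species")
  if (any(!is.finite(K)) || any(!is.finite(LAI)) || any(K < 0) || any(LAI < 0))
    stop("K and LAI must be finite and non-negative")
  kl <- K * LAI
  total_kl <- sum(kl)
  total <- 1 - exp(-total_kl)
  lie <- if (total_kl == 0) rep(0, length(K)) else kl / total_kl * total
  names(lie) <- names(K)
  out <- list(lie_by_species = lie, total_interception = total)
  if (length(K) == 2L)
    out$share_species1 <- if (total_kl == 0) NA_real_ else kl[[1]] / total_kl
  structure(out, class = "theory_prediction")
}

#' @export
print.theory_prediction <- function(x, ...) {
  cat("Turbid-medium prediction\n")
  cat("  LIE by species:", paste(sprintf("%s=%.4f",
      if (is.null(names(x$lie_by_species))) seq_along(x$lie_by_species)
      else names(x$lie_by_species), x$lie_by_species), collapse = ", "), "\n")
  cat(sprintf("  total interception: %.4f\n", x$total_interception))
  if (!is.null(x$share_species1))
    cat(sprintf("  share of species 1: %.4f\n", x$share_species1))
  invisible(x)
}

#' Theoretical light share of species 1 in a well-mixed bi-specific canopy
#'
#' With `alpha = K1/K2` and `p` the relative LAI of species 1, the exponential
#' factors of the two species' interception cancel in the ratio and the share
#' reduces to
#' \deqn{s(p) = \frac{\alpha p}{\alpha p + (1 - p)}.}
#' This is the isoline family plotted against `p` for fixed ratios of the
#' extinction coefficients.
#'
#' @param alpha ratio of extinction coefficients K1/K2, > 0.
#' @param p relative LAI of species 1 in \[0, 1\] (vectorized).
#' @return Share of species 1 in \[0, 1\].
#' @examples
#' share_theoretical(alpha = 10, p = 0.5)  # 10/11
#' @export
share_theoretical <- function(alpha, p) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be finite and > 0")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]")
  alpha * p / (alpha * p + (1 - p))
}

#' Beam extinction coefficient of an ellipsoidal leaf-angle distribution
#'
#' Campbell's ellipsoidal leaf-angle distribution with shape parameter `x`
#' (ratio of horizontal to vertical semi-axes; x -> Inf horizontal leaves,
#' x = 1 spherical, x -> 0 vertical):
#' \deqn{K_{be}(\theta) = \frac{\sqrt{x^2 + \tan^2\theta}}
#'       {x + 1.774\,(x + 1.182)^{-0.733}}}
#' which equals G(theta)/cos(theta).
#'
#' @param x ellipsoidal shape parameter, > 0.
#' @param zenith_deg beam zenith angle(s) in degrees, in \[0, 90).
#' @return K(theta), dimensionless.
#' @export
ellipsoidal_kbe <- function(x, zenith_deg) {
  if (!is.finite(x) || x <= 0) stop("x must be finite and > 0")
  th <- zenith_deg * pi / 180
  sqrt(x^2 + tan(th)^2) / (x + 1.774 * (x + 1.182)^(-0.733))
}

# Mean leaf inclination (degrees from horizontal) of an ellipsoidal
# distribution with parameter x (Campbell's approximation, radians
# 9.65 * (3 + x)^-1.65), and its numeric inverse.
ellipsoidal_mean_inclination <- function(x) {
  9.65 * (3 + x)^(-1.65) * 180 / pi
}

ellipsoidal_x_from_inclination <- function(mean_inclination_deg) {
  if (mean_inclination_deg <= ellipsoidal_mean_inclination(5e4)) return(5e4)
  if (mean_inclination_deg >= ellipsoidal_mean_inclination(1e-4)) return(1e-4)
  stats::uniroot(function(x) ellipsoidal_mean_inclination(x) - mean_inclination_deg,
                 interval = c(1e-4, 5e4), tol = 1e-10)$root
}

#' Diffuse-effective extinction coefficient from mean foliage inclination
#'
#' Maps a mean foliage inclination (degrees from horizontal) to the ellipsoidal
#' leaf-angle distribution with the same mean, evaluates the directional
#' extinction coefficient K(theta) = G(theta)/cos(theta) for each sky sector,
#' and defines the diffuse-effective K as the single coefficient giving the
#' same interception of the whole vault at a reference LAI:
#' \deqn{1 - e^{-K \cdot L} = \sum_s w_s (1 - e^{-K(\theta_s) L}).}
#' The reference LAI defaults to 1 (the dependence on it is weak); the
#' convention is fixed and documented rather than tunable per call site.
#'
#' @param mean_inclination_deg mean foliage inclination in \[0, 90\] degrees.
#' @param sky a [build_sky()] vault.
#' @param ref_lai reference LAI for the diffuse average (default 1).
#' @return Diffuse-effective extinction coefficient (dimensionless).
#' @examples
#' extinction_from_inclination(0, build_sky())   # horizontal leaves: K = 1
#' @export
extinction_from_inclination <- function(mean_inclination_deg, sky = build_sky(),
                                        ref_lai = 1) {
  if (!is.finite(mean_inclination_deg) ||
      mean_inclination_deg < 0 || mean_inclination_deg > 90)
    stop("mean_inclination_deg must lie in [0, 90]")
  stopifnot(inherits(sky, "sky_vault"))
  x <- ellipsoidal_x_from_inclination(mean_inclination_deg)
  kdir <- ellipsoidal_kbe(x, pmin(sky$zenith, 89.9))
  absorbed <- sum(sky$weight * (1 - exp(-kdir * ref_lai)))
  -log(1 - absorbed) / ref_lai
}

#' Theoretical light-sharing isolines
#'
#' Evaluates [share_theoretical()] on a grid of relative LAI values for a set
#' of extinction-coefficient ratios, reproducing the classical isoline fan
#' (share of species 1 vs its share of the LAI).
#'
#' @param alpha_values ratios K1/K2; default 9 values log-spaced over
#'   \[0.1, 10\].
#' @param p_grid relative LAI grid in \[0, 1\].
#' @return An object of class `isoline_grid`: list with `alpha_values`,
#'   `p_grid` and a `shares` matrix (rows = alphas).
#' @export
isolines <- function(alpha_values = 10^seq(-1, 1, length.out = 9),
                     p_grid = seq(0, 1, by = 0.01)) {
  if (any(alpha_values <= 0)) stop("alpha values must be > 0")
  shares <- t(vapply(alpha_values, share_theoretical, numeric(length(p_grid)),
                     p = p_grid))
  dimnames(shares) <- list(sprintf("alpha=%.4g", alpha_values), NULL)
  structure(list(alpha_values = alpha_values, p_grid = p_grid, shares = shares),
            class = "isoline_grid")
}

#' Write an isoline grid to CSV (long format: alpha, p, share)
#'
#' @param grid an [isolines()] object.
#' @param path CSV output path.
#' @return The long-format data.frame, invisibly.
#' @export
write_isolines_csv <- function(grid, path) {
  stopifnot(inherits(grid, "isoline_grid"))
  df <- data.frame(
    alpha = rep(grid$alpha_values, each = length(grid$p_grid)),
    relative_lai_sp1 = rep(grid$p_grid, times = length(grid$alpha_values)),
    share_sp1 = as.vector(t(grid$shares)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Plot light-sharing isolines
#'
#' @param x an [isolines()] object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.isoline_grid <- function(x, ...) {
  graphics::matplot(x$p_grid, t(x$shares), type = "l", lty = 1,
                    xlab = "Relative LAI of species 1",
                    ylab = "Relative light interception of species 1", ...)
  graphics::abline(0, 1, col = "grey", lty = 3)
  invisible(x)
}
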