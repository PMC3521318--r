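# Deterministic seed fan-out: a single run-level seed plus an integer key
# yields independent sub-streams, so adding replicates or sectors never
# perturbs earlier ones.
derive_seed <- function(seed, key) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + as.double(key) * 7919) %%
               2147483647)
}

scene_tri_class <- function(scene) {
  if (nrow(scene$organs) == 0) return(integer(0))
  cls <- rep.int(match(scene$organs$species, scene$species_levels),
                 scene$organs$n_tri)
  as.integer(cls)
}

#' Directional interception of a parallel beam by a scene
#'
#' Casts a stratified-jittered grid of parallel rays over the (doubly
#' periodic) footprint from direction (`zenith`, `azimuth`) and assigns each
#' ray to the species of its first intersected organ, or to the soil. Organs
#' are opaque: no transmission or scattering, so the per-direction species
#' fractions and soil fraction sum to exactly 1 in counting measure.
#'
#' @param scene a `scene`.
#' @param zenith beam zenith angle (degrees, in \[0, 90)).
#' @param azimuth beam azimuth (degrees).
#' @param n_rays requested ray budget (the stratified grid uses the nearest
#'   factorable count; see `n_rays` in the result).
#' @param seed integer seed for the jitter.
#' @return List with `fractions` (named per species), `soil`, `counts`,
#'   `n_rays`.
#' @export
directional_interception <- function(scene, zenith, azimuth, n_rays = 1e5,
                                     seed = 1L) {
  stopifnot(inherits(scene, "scene"))
  if (any(scene$footprint <= 0)) stop("degenerate footprint")
  counts <- withr::with_seed(seed,
    raycast_direction_cpp(scene$tris, scene_tri_class(scene),
                          length(scene$species_levels),
                          scene$footprint[1], scene$footprint[2],
                          zenith, azimuth, as.integer(n_rays)))
  n <- sum(counts)
  k <- length(scene$species_levels)
  list(fractions = stats::setNames(counts[seq_len(k)] / n, scene$species_levels),
       soil = counts[k + 1] / n,
       counts = counts,
       n_rays = n)
}

#' Diffuse interception over a discretized sky vault
#'
#' Computes [directional_interception()] for every sky sector and integrates
#' with the sector weights. The Monte-Carlo standard error per species is
#' propagated as a weighted binomial error,
#' sqrt(sum_s w_s^2 p_s (1 - p_s) / n_s).
#'
#' @param scene a `scene`.
#' @param sky a [build_sky()] vault.
#' @param n_rays_per_sector ray budget per sector (default 1e5).
#' @param seed run seed; per-sector jitter streams are derived from it.
#' @return An object of class `interception_result`: `fraction_by_species`,
#'   `fraction_soil`, `mc_stderr`, `per_direction` (data.frame), `n_rays`.
#' @export
diffuse_interception <- function(scene, sky = build_sky(),
                                 n_rays_per_sector = 1e5, seed = 1L) {
  stopifnot(inherits(scene, "scene"), inherits(sky, "sky_vault"))
  k <- length(scene$species_levels)
  per <- vector("list", nrow(sky))
  for (s in seq_len(nrow(sky))) {
    r <- directional_interception(scene, sky$zenith[s], sky$azimuth[s],
                                  n_rays_per_sector, derive_seed(seed, s))
    per[[s]] <- c(r$fractions, soil = r$soil, n_rays = r$n_rays)
  }
  pm <- do.call(rbind, per)
  w <- sky$weight
  frac <- colSums(pm[, seq_len(k), drop = FALSE] * w)
  soil <- sum(pm[, "soil"] * w)
  stderr <- sqrt(colSums(w^2 * pm[, seq_len(k), drop = FALSE] *
                           (1 - pm[, seq_len(k), drop = FALSE]) /
                           pm[, "n_rays"]))
  per_direction <- data.frame(zenith = sky$zenith, azimuth = sky$azimuth,
                              weight = w)
  for (j in seq_len(k)) {
    sp <- scene$species_levels[j]
    per_direction[[paste0("frac_", sp)]] <- pm[, j]
    per_direction[[paste0("stderr_", sp)]] <-
      sqrt(pm[, j] * (1 - pm[, j]) / pm[, "n_rays"])
  }
  per_direction$frac_soil <- pm[, "soil"]
  per_direction$n_rays <- pm[, "n_rays"]
  structure(list(fraction_by_species = frac,
                 fraction_soil = soil,
                 mc_stderr = stderr,
                 per_direction = per_direction,
                 n_rays = sum(pm[, "n_rays"])),
            class = "interception_result")
}

#' @export
print.interception_result <- function(x, ...) {
  cat("Diffuse interception (Uniform Overcast Sky)\n")
  for (sp in names(x$fraction_by_species))
    cat(sprintf("  %-6s intercepts %.4f of incident diffuse PAR (MC stderr %.2g)\n",
                sp, x$fraction_by_species[[sp]], x$mc_stderr[[sp]]))
  cat(sprintf("  soil: %.4f; rays: %d\n", x$fraction_soil, x$n_rays))
  invisible(x)
}

#' Species light-sharing estimate from an interception result
#'
#' The pea share is LIE_pea / (LIE_pea + LIE_wheat), i.e. the fraction of the
#' light intercepted by the whole mixture that goes to pea.
#'
#' @param result an `interception_result` with wheat and pea fractions.
#' @return An object of class `share_estimate`: `pea_share`,
#'   `lie_by_species`, `stderr`.
#' @export
species_share <- function(result) {
  stopifnot(inherits(result, "interception_result"))
  f <- result$fraction_by_species
  if (!all(c("wheat", "pea") %in% names(f)))
    stop("result must contain wheat and pea fractions")
  tot <- f[["pea"]] + f[["wheat"]]
  if (tot <= 0) stop("undefined share: total interception is zero")
  share <- f[["pea"]] / tot
  # delta-method error on the ratio from the per-species binomial errors
  se <- sqrt((f[["wheat"]] / tot^2)^2 * result$mc_stderr[["pea"]]^2 +
               (f[["pea"]] / tot^2)^2 * result$mc_stderr[["wheat"]]^2)
  structure(list(pea_share = share, lie_by_species = f, stderr = se),
            class = "share_estimate")
}

#' @export
print.share_estimate <- function(x, ...) {
  cat(sprintf("Pea share of intercepted light: %.4f (MC stderr %.2g)\n",
              x$pea_share, x$stderr))
  invisible(x)
}
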