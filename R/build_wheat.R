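#' Build a 3D wheat plant mock-up for a stand stage
#'
#' The wheat generator is parametric and stage-wise: it takes the per-plant
#' green area, plant height and area-weighted blade inclination of the stand
#' at the requested stage (see [wheat_stage()] for the shipped values) and
#' builds an erect plant matching them: a thin vertical pseudo-stem ribbon
#' spanning the full height plus lanceolate blade strips whose total area
#' makes up the target exactly, inclined at the stage's blade angle with a
#' mean-preserving jitter, attached at seeded heights and azimuths. Declining
#' green area late in the cycle is handled by scaling blade area to the
#' target, not by a senescence model.
#'
#' @param stage list with `area_m2` (green area per plant), `height_m`,
#'   `inclination_deg` (degrees from horizontal).
#' @param seed integer seed; identical (stage, seed) give bit-identical
#'   mock-ups.
#' @param n_blades optional blade count; by default scaled with area.
#' @return A `plant_mockup`.
#' @examples
#' build_wheat(wheat_stage(1240), seed = 1)
#' @export
build_wheat <- function(stage, seed = 1L, n_blades = NULL) {
  need <- c("area_m2", "height_m", "inclination_deg")
  if (!all(need %in% names(stage)))
    stop("stage must have fields: ", paste(need, collapse = ", "))
  a <- stage$area_m2; h <- stage$height_m; incl <- stage$inclination_deg
  if (any(!is.finite(c(a, h, incl))) || a < 0 || h < 0 ||
      incl < 0 || incl > 90)
    stop("invalid wheat stage: area and height must be >= 0, inclination in [0, 90]")
  if (a == 0 || h == 0)
    return(new_plant_mockup(list(), "wheat", 0L, 0L))

  withr::with_seed(seed, {
    stem_w_mm <- 2
    stem_area <- stem_w_mm / 1000 * h
    if (stem_area > 0.25 * a) {
      stem_w_mm <- 0.25 * a / h * 1000
      stem_area <- 0.25 * a
    }
    blade_area <- a - stem_area
    if (is.null(n_blades))
      n_blades <- max(3, min(12, round(blade_area / 8e-4)))
    ab <- blade_area / n_blades
    aspect <- 12                       # blade length : width
    len_m <- sqrt(aspect * ab)
    organs <- list()
    organs[[1]] <- organ_tessellate(
      "stem", h * 1000, width_ratio = stem_w_mm / (h * 1000),
      inclination = 90, azimuth = stats::runif(1, 0, 360),
      base = c(0, 0, 0), species = "wheat", axis_id = 0L, rank = 0L)
    incs <- jitter_inclinations(incl, n_blades, sd = 3)
    azs <- stats::runif(n_blades, 0, 360)
    for (i in seq_len(n_blades)) {
      extent <- len_m * sin(incs[i] * pi / 180)
      zmax_base <- max(0.03 * h, h - extent)
      z0 <- stats::runif(1, 0.02 * h, zmax_base)
      # sheath offset: blades splay outward from the pseudo-stem
      a <- azs[i] * pi / 180
      base <- c(cos(a), sin(a), 0) * 0.08 * len_m + c(0, 0, z0)
      organs[[length(organs) + 1L]] <- organ_tessellate(
        "blade", len_m * 1000, width_ratio = 1 / aspect,
        inclination = incs[i], azimuth = azs[i],
        base = base, species = "wheat", axis_id = 0L, rank = i)
    }
    new_plant_mockup(organs, "wheat", as.integer(n_blades), 0L)
  })
}

#' Build a list of seeded mock-up variants
#'
#' Convenience wrapper mirroring the study design of eight digitized plants
#' per cultivar: builds `n` mock-ups with seeds derived from `seed`.
#'
#' @param builder function of a single `seed` argument returning a
#'   `plant_mockup` (e.g. a closure over [build_pea()] or [build_wheat()]).
#' @param n number of variants (default 8).
#' @param seed base seed.
#' @return List of `plant_mockup`s.
#' @export
mockup_variants <- function(builder, n = 8, seed = 1L) {
  lapply(seq_len(n), function(i) builder(derive_seed(seed, 1000 + i)))
}
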