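# Synthetic canopy fixtures built in code.

# One free-floating planar leaf as a one-organ plant mock-up.
leaf_mockup <- function(species, length_mm, inclination, azimuth, z,
                        width_ratio = 1, organ_type = "blade") {
  o <- organ_tessellate(organ_type, length_mm, width_ratio = width_ratio,
                        inclination = inclination, azimuth = azimuth,
                        base = c(0, 0, z), species = species)
  canopymix:::new_plant_mockup(list(o), species, 1L, 0L)
}

# Homogeneous canopy of randomly placed small leaves with prescribed
# inclination: LAI = n * leaf_area / footprint area.
random_leaf_scene <- function(seed, n = 2500, leaf_m = 0.02, inclination = 0,
                              footprint = c(1, 1), hmax = 1,
                              species = c("pea", "wheat")) {
  withr::with_seed(seed, {
    mks <- lapply(seq_len(n), function(i) {
      leaf_mockup(species[(i %% length(species)) + 1], leaf_m * 1000,
                  inclination, stats::runif(1, 0, 360),
                  stats::runif(1, 0, hmax))
    })
    pos <- cbind(stats::runif(n, 0, footprint[1]),
                 stats::runif(n, 0, footprint[2]))
    scene_from_mockups(mks, pos, footprint = footprint)
  })
}

# Noiseless or noisy phytomer series simulated from known parameters.
simulate_series <- function(params, times, sigma = 0, plant_id = "p1",
                            seed = NULL) {
  y <- schnute_eval(params, times)
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(times), 0, sigma)
    y <- pmax(y, 0)
  }
  suppressWarnings(phytomer_series(plant_id, times, y))
}

table4_params <- function() {
  list(
    China = schnute_params(2.14e-3, 0.47, 20.6, 1310),
    US13 = schnute_params(1.89e-3, 0.44, 24.6, 1445),
    Lucy = schnute_params(1.89e-3, 0.39, 24.8, 1565),
    James = schnute_params(1.94e-3, 0.49, 25.6, 1445),
    AOPH10 = schnute_params(1.18e-3, 0.57, 32.9, 1630),
    `886/01` = schnute_params(0.80e-3, 0.65, 37.6, 1890))
}

# Independent triangle-area summation (oracle for mesh areas).
oracle_mesh_area <- function(mesh) {
  if (nrow(mesh) == 0) return(0)
  sum(vapply(seq_len(nrow(mesh)), function(i) {
    p1 <- mesh[i, 1:3]; p2 <- mesh[i, 4:6]; p3 <- mesh[i, 7:9]
    a <- p2 - p1; b <- p3 - p1
    cr <- c(a[2] * b[3] - a[3] * b[2],
            a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    0.5 * sqrt(sum(cr^2))
  }, 0))
}
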