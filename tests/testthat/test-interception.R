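test_that("empty and fully covered scenes give the exact limits", {
  empty <- canopymix:::new_scene(data.frame(), matrix(numeric(0), 0, 9),
                                 c(1, 1))
  r <- directional_interception(empty, 30, 45, n_rays = 1000, seed = 1)
  expect_equal(sum(r$fractions), 0)
  expect_equal(r$soil, 1)
  d <- diffuse_interception(empty, build_sky(), 500, seed = 1)
  expect_equal(sum(d$fraction_by_species), 0)
  expect_equal(d$fraction_soil, 1)
  # an opaque horizontal sheet tiling the footprint intercepts everything
  sheet <- leaf_mockup("pea", 4000, 0, 0, 0.5, width_ratio = 1)
  sc <- scene_from_mockups(list(sheet), cbind(0, 0), footprint = c(1, 1))
  r2 <- directional_interception(sc, 0, 0, n_rays = 5000, seed = 2)
  expect_equal(unname(r2$fractions[["pea"]]), 1)
})

test_that("species and soil fractions sum to one in counting measure", {
  sc <- random_leaf_scene(11, n = 800, leaf_m = 0.03, inclination = 25)
  for (zen in c(0, 36, 72)) {
    r <- directional_interception(sc, zen, 135, n_rays = 2e4, seed = 3)
    expect_identical(sum(r$counts), r$n_rays)
    expect_equal(sum(r$fractions) + r$soil, 1, tolerance = 1e-15)
  }
  d <- diffuse_interception(sc, build_sky(), 5e3, seed = 4)
  expect_equal(sum(d$fraction_by_species) + d$fraction_soil, 1,
               tolerance = 1e-12)
})

test_that("a Poisson canopy of horizontal leaves follows Beer-Lambert", {
  vals <- vapply(1:4, function(s) {
    sc <- random_leaf_scene(s, n = 2500, leaf_m = 0.02, inclination = 0)
    r <- directional_interception(sc, 0, 0, n_rays = 1e5, seed = 50 + s)
    sum(r$fractions)
  }, 0)
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - (1 - exp(-1))), 3 * max(se, 1.6e-3))
})

test_that("diffuse interception of inclined-leaf canopies matches the turbid model", {
  # 45-degree leaves, LAI 1: per-direction prediction from the exact
  # projected-area ratio of the scene's own triangles (independent oracle)
  sky <- build_sky()
  sc <- random_leaf_scene(21, n = 2500, leaf_m = 0.02, inclination = 45)
  areas <- triangle_areas(sc$tris)
  # per-triangle unit normals
  a1 <- sc$tris[, 4:6] - sc$tris[, 1:3]; a2 <- sc$tris[, 7:9] - sc$tris[, 1:3]
  nx <- a1[, 2] * a2[, 3] - a1[, 3] * a2[, 2]
  ny <- a1[, 3] * a2[, 1] - a1[, 1] * a2[, 3]
  nz <- a1[, 1] * a2[, 2] - a1[, 2] * a2[, 1]
  nn <- sqrt(nx^2 + ny^2 + nz^2)
  pred <- 0
  for (s in seq_len(nrow(sky))) {
    th <- sky$zenith[s] * pi / 180; ph <- sky$azimuth[s] * pi / 180
    d <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    proj <- sum(abs(nx * d[1] + ny * d[2] + nz * d[3]) / nn * areas) / cos(th)
    lai_eff <- proj / prod(sc$footprint)
    pred <- pred + sky$weight[s] * (1 - exp(-lai_eff))
  }
  d <- diffuse_interception(sc, sky, 2e4, seed = 8)
  obs <- sum(d$fraction_by_species)
  expect_lt(abs(obs - pred), 0.012)
})

test_that("a single-sector vault reduces to the directional computation", {
  sc <- random_leaf_scene(31, n = 300, leaf_m = 0.04, inclination = 20)
  sky1 <- build_sky(1, 1, zenith_mode = "band_mean")
  d <- diffuse_interception(sc, sky1, 1e4, seed = 12)
  r <- directional_interception(sc, sky1$zenith[1], sky1$azimuth[1], 1e4,
                                seed = canopymix:::derive_seed(12, 1))
  expect_equal(d$fraction_by_species, r$fractions, tolerance = 1e-15)
})

test_that("a species-symmetric canopy shares light equally", {
  sc <- random_leaf_scene(41, n = 3000, leaf_m = 0.02, inclination = 10,
                          species = c("pea", "wheat"))
  d <- diffuse_interception(sc, build_sky(), 2e4, seed = 6)
  sh <- species_share(d)
  expect_lt(abs(sh$pea_share - 0.5), 3 * sh$stderr + 0.01)
  expect_error(species_share(diffuse_interception(
    canopymix:::new_scene(data.frame(), matrix(numeric(0), 0, 9), c(1, 1)),
    build_sky(1, 1), 100, 1)), "undefined share")
})

test_that("adding an organ never decreases total interception", {
  sc <- random_leaf_scene(51, n = 400, leaf_m = 0.03, inclination = 30)
  base_mks <- list(leaf_mockup("pea", 60, 20, 10, 0.3))
  sc_more <- random_leaf_scene(51, n = 400, leaf_m = 0.03, inclination = 30)
  extra <- leaf_mockup("pea", 120, 15, 90, 1.2)
  sc_more$organs <- rbind(sc_more$organs,
                          canopymix:::flatten_mockups(list(extra))$table)
  sc_more$tris <- rbind(sc_more$tris, extra$organs[[1]]$mesh)
  for (zen in c(0, 54)) {
    r0 <- directional_interception(sc, zen, 0, 2e4, seed = 9)
    r1 <- directional_interception(sc_more, zen, 0, 2e4, seed = 9)
    expect_gte(sum(r1$fractions), sum(r0$fractions))
  }
})

test_that("the Monte-Carlo standard error follows binomial scaling", {
  sc <- random_leaf_scene(61, n = 1000, leaf_m = 0.03, inclination = 15)
  sky <- build_sky()
  d1 <- diffuse_interception(sc, sky, 5e3, seed = 13)
  d4 <- diffuse_interception(sc, sky, 2e4, seed = 13)
  ratio <- d4$mc_stderr[["pea"]] / d1$mc_stderr[["pea"]]
  expect_lt(abs(ratio - 0.5), 0.1)
  # and the binomial formula tracks the empirical spread across seeds
  reps <- vapply(1:6, function(s)
    sum(directional_interception(sc, 36, 45, 5e3, seed = 100 + s)$fractions), 0)
  p <- mean(reps)
  expect_lt(stats::sd(reps), 4 * sqrt(p * (1 - p) / 5e3))
})

test_that("per-direction CSV writer reports sector geometry and errors", {
  sc <- random_leaf_scene(71, n = 200, leaf_m = 0.04)
  d <- diffuse_interception(sc, build_sky(), 2e3, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_directional_csv(d, path)
  out <- read.csv(path)
  expect_equal(nrow(out), 20)
  expect_true(all(c("zenith", "azimuth", "weight", "frac_pea", "stderr_pea",
                    "frac_soil", "n_rays") %in% names(out)))
})
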