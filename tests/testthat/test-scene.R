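tiny_mockup <- function(species) leaf_mockup(species, 20, 10, 0, 0.05)

test_that("row mixtures place round(density x area) plants per species", {
  spec <- scene_spec(plot_x = 1, plot_y = 1, inter_row = 0.17, seed = 3)
  sc <- assemble_mixture(list(tiny_mockup("pea")), list(tiny_mockup("wheat")),
                         spec)
  n_by_sp <- tapply(sc$organs$plant_id, sc$organs$species,
                    function(x) length(unique(x)))
  expect_equal(unname(n_by_sp[["wheat"]]), 125)
  expect_equal(unname(n_by_sp[["pea"]]), 45)
})

test_that("row count follows the inter-row spacing", {
  expect_equal(scene_spec(plot_x = 0.34, plot_y = 1)$n_rows, 2)
  expect_error(scene_spec(plot_x = 0.05, plot_y = 1),
               "plot too small|within one row")
  expect_error(assemble_mixture(list(), list(),
                                scene_spec(plot_x = 0.34, plot_y = 0.34)),
               "configuration error")
})

test_that("descriptors follow their definitions on hand-built scenes", {
  # one horizontal 1 m2 leaf over a 1 m2 plot
  sc <- scene_from_mockups(list(leaf_mockup("pea", 1000, 0, 0, 0.4)),
                           cbind(0.5, 0.5), footprint = c(1, 1))
  d <- canopy_descriptors(sc)
  expect_equal(unname(d$lai_by_species[["pea"]]), 1, tolerance = 1e-9)
  expect_equal(unname(d$mean_inclination_by_species[["pea"]]), 0)
  # equal-area organs at 0 and 90 degrees average to 45
  sc2 <- scene_from_mockups(
    list(leaf_mockup("pea", 1000, 0, 0, 0.4),
         leaf_mockup("pea", 1000, 90, 0, 0.1)),
    cbind(c(0.2, 0.8), c(0.5, 0.5)), footprint = c(2, 1))
  d2 <- canopy_descriptors(sc2)
  expect_equal(unname(d2$mean_inclination_by_species[["pea"]]), 45)
  # doubling every organ at fixed footprint doubles LAI exactly
  expect_equal(unname(d2$lai_by_species[["pea"]]), 2 * 1 / 2, tolerance = 1e-9)
})

test_that("descriptors are invariant to organ order and rigid translation", {
  mks <- lapply(1:6, function(i)
    leaf_mockup(c("pea", "wheat")[i %% 2 + 1], 80, 30, i * 50, 0.1 * i))
  pos <- cbind(seq(0.1, 0.6, by = 0.1), seq(0.6, 0.1, by = -0.1))
  sc <- scene_from_mockups(mks, pos, footprint = c(1, 1))
  perm <- c(4, 1, 6, 2, 5, 3)
  sc_perm <- scene_from_mockups(mks[perm], pos[perm, ], footprint = c(1, 1))
  sc_shift <- scene_from_mockups(mks, (pos + 0.37) %% 1, footprint = c(1, 1))
  for (other in list(sc_perm, sc_shift)) {
    d1 <- canopy_descriptors(sc); d2 <- canopy_descriptors(other)
    expect_equal(d1$lai_by_species, d2$lai_by_species, tolerance = 1e-12)
    expect_equal(d1$mean_inclination_by_species,
                 d2$mean_inclination_by_species, tolerance = 1e-12)
    expect_equal(d1$height_by_species, d2$height_by_species,
                 tolerance = 1e-12)
  }
})

test_that("scene LAI equals independent per-triangle summation", {
  sc <- random_leaf_scene(5, n = 200, leaf_m = 0.05, inclination = 40)
  d <- canopy_descriptors(sc)
  total <- sum(d$lai_by_species) * prod(sc$footprint)
  expect_equal(total, oracle_mesh_area(sc$tris), tolerance = 1e-9)
})

test_that("scene summary CSV has the descriptor columns", {
  spec <- scene_spec(plot_x = 0.34, plot_y = 0.34, seed = 2)
  sc <- assemble_mixture(list(tiny_mockup("pea")), list(tiny_mockup("wheat")),
                         spec)
  path <- withr::local_tempfile(fileext = ".csv")
  out <- write_scene_summary_csv(list(demo = sc), path)
  expect_true(file.exists(path))
  expect_named(out, c("scene", "lai_wheat", "lai_pea", "inclination_wheat",
                      "inclination_pea", "height_wheat", "height_pea",
                      "height_ratio"))
})
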