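test_that("mock-ups are bit-identical for identical (spec, t, seed)", {
  for (g in c("China", "886/01")) {
    spec <- pea_genotype(g)
    expect_identical(build_pea(spec, 600, seed = 42),
                     build_pea(spec, 600, seed = 42))
  }
  expect_identical(build_wheat(wheat_stage(600), seed = 7),
                   build_wheat(wheat_stage(600), seed = 7))
})

test_that("pre-emergence plants are empty, not errors", {
  spec <- pea_genotype("Lucy")
  m <- build_pea(spec, 0, seed = 1)
  expect_length(m$organs, 0)
  expect_equal(m$height, 0)
  expect_equal(sum(m$green_area_by_type), 0)
  w <- build_wheat(list(area_m2 = 0, height_m = 0.1, inclination_deg = 60))
  expect_length(w$organs, 0)
})

test_that("main-stem phytomer counts follow the development curve", {
  spec <- pea_genotype("China")
  # at the end of the fitted domain the count reaches round(y_max) = 21
  expect_equal(build_pea(spec, 1310, seed = 1)$n_phytomers_main, 21)
  expect_equal(build_pea(spec, 5000, seed = 1)$n_phytomers_main, 21)
  expect_equal(build_pea(spec, 1080, seed = 1)$n_phytomers_main,
               round(schnute_eval(spec$schnute, 1080)))
})

test_that("branch counts are drawn from the stage's observed range", {
  spec <- pea_genotype("886/01")
  nb <- vapply(1:12, function(s) build_pea(spec, 1240, seed = s)$n_branches, 0L)
  expect_true(all(nb >= 1 & nb <= 3))
  expect_gt(length(unique(nb)), 1)
  # no branches before the first branching stage
  expect_equal(build_pea(spec, 400, seed = 3)$n_branches, 0L)
})

test_that("leaf habit matches the genotype: leaflets only on leafy cultivars", {
  for (g in genotype_names()) {
    spec <- pea_genotype(g)
    m <- build_pea(spec, 1240, seed = 2)
    types <- unique(vapply(m$organs, `[[`, "", "organ_type"))
    if (spec$leaf_type == "semi-leafless") {
      expect_false("leaflet" %in% types)
    } else {
      expect_true("leaflet" %in% types)
      # leaflet and stipule shares of green area are comparable
      g_area <- m$green_area_by_type
      ratio <- g_area[["leaflet"]] / g_area[["stipule"]]
      expect_gt(ratio, 0.7)
      expect_lt(ratio, 1.4)
    }
  }
})

test_that("stipule final length peaks between normalized ranks 0.6 and 0.8", {
  for (g in genotype_names()) {
    spec <- pea_genotype(g)
    r <- seq(0, 1, by = 0.01)
    len <- canopymix:::stipule_length_mm(spec, r)
    peak <- r[which(len == max(len))]
    expect_true(all(peak >= 0.6 & peak <= 0.8))
  }
})

test_that("mature leaf area shares match the genotype's stated contributions", {
  for (g in genotype_names()) {
    spec <- pea_genotype(g)
    m <- build_pea(spec, spec$maturity_dd, seed = 5)
    target <- spec$area_contributions$stipules +
      ifelse(is.null(spec$area_contributions$leaflets), 0,
             spec$area_contributions$leaflets)
    expect_lt(abs(leaf_area_fraction(m) - target), 0.03)
  }
})

test_that("wheat mock-ups hit the stage descriptors", {
  for (dd in c(300, 600, 1240, 1560)) {
    st <- wheat_stage(dd)
    w <- build_wheat(st, seed = dd)
    expect_equal(w$height, st$height_m, tolerance = 0.05)
    expect_equal(sum(w$green_area_by_type), st$area_m2, tolerance = 0.02)
    tab <- canopymix:::flatten_mockups(list(w))$table
    blades <- tab[tab$organ_type == "blade", ]
    wmean <- sum(blades$area * blades$inclination) / sum(blades$area)
    expect_lt(abs(wmean - st$inclination_deg), 3)
    # declared areas match an independent triangle-area routine
    for (o in w$organs)
      expect_equal(o$area, oracle_mesh_area(o$mesh), tolerance = 1e-9)
  }
  expect_error(build_wheat(list(area_m2 = -1, height_m = 0.1,
                                inclination_deg = 60)), "invalid")
})

test_that("green area by organ type sums to the total plant area", {
  m <- build_pea(pea_genotype("US13"), 900, seed = 9)
  total <- sum(vapply(m$organs, `[[`, 0, "area"))
  expect_equal(sum(m$green_area_by_type), total, tolerance = 1e-12)
})

test_that("assembled stands reproduce the reference LAI and inclination bands", {
  ref <- reference_stand_descriptors()
  for (g in genotype_names()) {
    spec <- pea_genotype(g)
    sub <- ref[ref$species == "pea" & ref$genotype == g, ]
    for (i in seq_len(nrow(sub))) {
      mks <- mockup_variants(function(s) build_pea(spec, sub$dd[i], s),
                             n = 8, seed = 11)
      lai <- mean(vapply(mks, plant_area, 0)) * 45
      expect_lt(abs(lai / sub$lai[i] - 1), 0.20,
                label = sprintf("%s LAI at %d DD (rel err)", g, sub$dd[i]))
      tab <- canopymix:::flatten_mockups(mks)$table
      fol <- tab[tab$organ_type %in% c("stipule", "leaflet"), ]
      incl <- sum(fol$area * fol$inclination) / sum(fol$area)
      expect_lt(abs(incl - sub$inclination_deg[i]), 6,
                label = sprintf("%s inclination at %d DD", g, sub$dd[i]))
    }
  }
})
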