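#' Load and validate a pea genotype specification
#'
#' Genotype specifications are plain-text YAML files holding the per-cultivar
#' architectural parameter set: Schnute development parameters, branching
#' ranges per stage, internode/stipule/leaflet final-length profiles over the
#' normalized phytomer rank, inclination dynamics over thermal time, and the
#' expected contributions of stipules, leaflets and stems to the green area.
#' Six cultivar files (China, US13, Lucy, James, AOPH10, 886/01) ship with the
#' package.
#'
#' @param path path to a genotype YAML file.
#' @return A validated object of class `genotype_spec`.
#' @seealso [pea_genotype()], [genotype_names()], [build_pea()]
#' @export
load_genotype_spec <- function(path) {
  if (!file.exists(path)) stop("genotype spec file not found: ", path)
  spec <- yaml::read_yaml(path)
  validate_genotype_spec(spec, context = path)
}

validate_genotype_spec <- function(spec, context = "genotype spec") {
  fail <- function(...) stop(context, ": ", ..., call. = FALSE)
  need <- c("name", "leaf_type", "maturity_dd", "schnute", "expansion_dd",
            "basal_offset_mm", "stem_width_mm", "internode_profile",
            "stipule_profile", "inclination_dynamics", "branching",
            "area_contributions")
  missing <- setdiff(need, names(spec))
  if (length(missing)) fail("missing fields: ", paste(missing, collapse = ", "))
  if (!spec$leaf_type %in% c("leafy", "semi-leafless"))
    fail("leaf_type must be 'leafy' or 'semi-leafless'")
  spec$schnute <- do.call(schnute_params, spec$schnute)
  ac <- spec$area_contributions
  total <- ac$stipules + ifelse(is.null(ac$leaflets), 0, ac$leaflets) + ac$stems
  if (abs(total - 1) > 0.01)
    fail("area_contributions must sum to 1 +/- 0.01 (got ", round(total, 3), ")")
  ip <- spec$internode_profile
  if (length(ip$r) != length(ip$m) || any(ip$m < 0) || ip$scale_mm < 0)
    fail("invalid internode_profile")
  sp <- spec$stipule_profile
  if (any(unlist(sp[c("base_mm", "peak_mm", "tip_mm")]) < 0) ||
      sp$peak_from > sp$peak_to)
    fail("invalid stipule_profile")
  # cultivar-specific leaf-size multiplier applied to the (shared) stipule and
  # leaflet length profiles; calibrated against the reference stand LAIs
  if (is.null(spec$leaf_scale)) spec$leaf_scale <- 1
  if (spec$leaf_scale <= 0) fail("leaf_scale must be > 0")
  if (spec$leaf_type == "leafy") {
    if (is.null(spec$leaflet_profile)) fail("leafy genotype needs leaflet_profile")
    if (is.null(spec$leaflet_pairs)) spec$leaflet_pairs <- 1L
    if (is.null(spec$inclination_dynamics$leaflet))
      fail("leafy genotype needs leaflet inclination dynamics")
  }
  for (st in spec$branching$stages) {
    if (st$min > st$max) fail("branching range must have min <= max")
    if (length(st$phytomers) < st$max)
      fail("branching stage needs one phytomer mean per possible branch")
  }
  ins <- spec$branching$insertion
  if (!(identical(ins, "basal") || (is.numeric(unlist(ins)) && length(unlist(ins)) == 2)))
    fail("branching insertion must be 'basal' or a two-element rank range")
  structure(spec, class = "genotype_spec")
}

#' @export
print.genotype_spec <- function(x, ...) {
  cat(sprintf("Pea genotype %s (%s), maturity %d DD\n", x$name, x$leaf_type,
              as.integer(x$maturity_dd)))
  print(x$schnute)
  invisible(x)
}

#' Names of the shipped pea genotype specifications
#' @return Character vector of cultivar names.
#' @export
genotype_names <- function() {
  files <- shipped_genotype_files()
  vapply(files, function(f) yaml::read_yaml(f)$name, "")
}

shipped_genotype_files <- function() {
  dir <- system.file("extdata", "genotypes", package = "canopymix")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  stats::setNames(files, vapply(files, function(f) yaml::read_yaml(f)$name, ""))
}

#' Load a shipped pea genotype by cultivar name
#'
#' @param name one of the shipped cultivar names (see [genotype_names()]).
#' @return A `genotype_spec`.
#' @export
pea_genotype <- function(name) {
  files <- shipped_genotype_files()
  if (!name %in% names(files))
    stop("unknown genotype '", name, "'; shipped: ",
         paste(names(files), collapse = ", "))
  load_genotype_spec(files[[name]])
}

#' Shipped wheat stand stages
#'
#' @return A data.frame of stage descriptors (dd, lai, height_m,
#'   inclination_deg) with the reference density as attribute `density`.
#' @export
wheat_stage_table <- function() {
  path <- system.file("extdata", "wheat_stages.yaml", package = "canopymix")
  y <- yaml::read_yaml(path)
  df <- do.call(rbind, lapply(y$stages, as.data.frame))
  attr(df, "density") <- y$density
  df
}

#' Wheat stage parameters for [build_wheat()] at a thermal time
#'
#' Interpolates the shipped stage table linearly in thermal time and converts
#' stand LAI to per-plant green area at the reference density.
#'
#' @param dd thermal time (DD).
#' @return List with `area_m2` (per plant), `height_m`, `inclination_deg`.
#' @export
wheat_stage <- function(dd) {
  tab <- wheat_stage_table()
  dens <- attr(tab, "density")
  list(area_m2 = stats::approx(tab$dd, tab$lai, dd, rule = 2)$y / dens,
       height_m = stats::approx(tab$dd, tab$height_m, dd, rule = 2)$y,
       inclination_deg = stats::approx(tab$dd, tab$inclination_deg, dd, rule = 2)$y)
}

#' Reference stand descriptors shipped with the package
#'
#' Per-species LAI, foliage inclination and plant height of the wheat and pea
#' stands at the four simulated stages, used to calibrate the generators and
#' checked by the calibration tests.
#'
#' @return A data.frame with columns species, genotype, dd, lai,
#'   inclination_deg, height_m.
#' @export
reference_stand_descriptors <- function() {
  utils::read.csv(system.file("extdata", "reference_stand_descriptors.csv",
                              package = "canopymix"),
                  stringsAsFactors = FALSE)
}

# Piecewise-linear profile helpers (lengths in mm, rank r in [0, 1]).
internode_length_mm <- function(spec, r) {
  p <- spec$internode_profile
  p$scale_mm * stats::approx(p$r, p$m, r, rule = 2)$y
}

stipule_length_mm <- function(spec, r) {
  p <- spec$stipule_profile
  spec$leaf_scale *
    stats::approx(c(0, p$peak_from, p$peak_to, 1),
                  c(p$base_mm, p$peak_mm, p$peak_mm, p$tip_mm),
                  pmin(r, 1), rule = 2)$y
}

leaflet_length_mm <- function(spec, r) {
  p <- spec$leaflet_profile
  spec$leaf_scale *
    stats::approx(c(0, p$peak_pos, 1), c(p$base_mm, p$peak_mm, p$tip_mm),
                  pmin(r, 1), rule = 2)$y
}

organ_inclination_deg <- function(spec, organ, t) {
  d <- spec$inclination_dynamics[[organ]]
  if (is.null(d)) stop("no inclination dynamics for organ ", organ)
  stats::approx(d$t, d$deg, t, rule = 2)$y
}

branching_stage <- function(spec, t) {
  stages <- spec$branching$stages
  if (is.null(stages) || !length(stages)) return(NULL)
  from <- vapply(stages, `[[`, 0, "from_dd")
  ok <- which(from <= t)
  if (!length(ok)) return(NULL)
  stages[[ok[which.max(from[ok])]]]
}
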