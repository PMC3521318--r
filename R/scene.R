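#' Mixture scene specification
#'
#' Row-intercrop design of the virtual stand: a rectangular plot with rows
#' spaced `inter_row` apart (0.17 m default), wheat and pea mixed within each
#' row at final densities of 125 and 45 plants m-2. The scene is treated as
#' doubly periodic in x and y, emulating an infinite stand.
#'
#' @param plot_x,plot_y plot dimensions (m); rows run along y.
#' @param inter_row row spacing (m), default 0.17.
#' @param density_wheat,density_pea final densities (plants m-2).
#' @param jitter_m maximum per-plant placement jitter (m), default 0.02.
#' @param seed integer seed for placement randomness.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(plot_x = 0.68, plot_y = 0.68, inter_row = 0.17,
                       density_wheat = 125, density_pea = 45,
                       jitter_m = 0.02, seed = 1L) {
  vals <- c(plot_x, plot_y, inter_row, density_wheat, density_pea)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("scene_spec values must be finite and positive")
  n_rows <- round(plot_x / inter_row)
  if (n_rows < 1) stop("plot too small for one row at this inter-row spacing")
  if (abs(plot_x - n_rows * inter_row) > inter_row)
    stop("inter_row must divide plot width to within one row")
  structure(list(plot_x = plot_x, plot_y = plot_y, inter_row = inter_row,
                 density_wheat = density_wheat, density_pea = density_pea,
                 jitter_m = jitter_m, seed = as.integer(seed),
                 n_rows = n_rows),
            class = "scene_spec")
}

# Low-level scene constructor from a flat organ table + triangle matrix.
new_scene <- function(table, tris, footprint) {
  if (nrow(table) && any(tris[, c(3, 6, 9)] < -1e-9))
    stop("scene organs must lie above the ground plane")
  structure(list(organs = table, tris = tris,
                 footprint = footprint,
                 species_levels = c("wheat", "pea")),
            class = "scene")
}

#' Build a scene directly from mock-ups at given positions
#'
#' Low-level assembly used by [assemble_mixture()] and by synthetic test
#' canopies: places each mock-up at the given (x, y) with an optional rotation
#' about its own vertical axis.
#'
#' @param mockups list of `plant_mockup` objects.
#' @param positions n x 2 matrix of (x, y) positions (m).
#' @param rotations optional vector of z-rotations (degrees).
#' @param footprint c(plot_x, plot_y) in metres.
#' @return A `scene` object.
#' @export
scene_from_mockups <- function(mockups, positions, rotations = NULL,
                               footprint) {
  stopifnot(length(mockups) == nrow(positions))
  if (is.null(rotations)) rotations <- rep(0, length(mockups))
  placed <- vector("list", length(mockups))
  for (i in seq_along(mockups)) {
    placed[[i]] <- transform_mockup(mockups[[i]], positions[i, 1],
                                    positions[i, 2], rotations[i],
                                    instance = i)
  }
  flat <- flatten_mockups(placed)
  new_scene(flat$table, flat$tris, footprint)
}

# Rotate a mock-up about its own vertical axis and translate it; tags each
# organ with a unique placed-plant instance id.
transform_mockup <- function(mockup, x, y, rot_deg, instance) {
  th <- rot_deg * pi / 180
  cs <- cos(th); sn <- sin(th)
  mockup$organs <- lapply(mockup$organs, function(o) {
    m <- o$mesh
    if (nrow(m)) {
      for (k in c(1, 4, 7)) {
        xs <- m[, k]; ys <- m[, k + 1]
        m[, k] <- cs * xs - sn * ys + x
        m[, k + 1] <- sn * xs + cs * ys + y
      }
    }
    o$mesh <- m
    o$plant_id <- sprintf("%s_%03d", o$species, instance)
    o
  })
  mockup
}

#' Assemble a wheat-pea row mixture scene
#'
#' Plant counts are `round(density x plot area)` per species. Plants are laid
#' out on `n_rows` rows spaced `inter_row` apart, the two species alternating
#' within each row in proportion to their densities, with seeded placement
#' jitter and a seeded rotation of every mock-up about its vertical axis.
#' Mock-ups are recycled from the supplied lists.
#'
#' @param pea list of pea `plant_mockup`s (may be empty if density rounds to 0).
#' @param wheat list of wheat `plant_mockup`s.
#' @param spec a [scene_spec()].
#' @return A `scene` object.
#' @export
assemble_mixture <- function(pea, wheat, spec) {
  stopifnot(inherits(spec, "scene_spec"))
  area <- spec$plot_x * spec$plot_y
  n_pea <- round(spec$density_pea * area)
  n_wheat <- round(spec$density_wheat * area)
  if (n_pea + n_wheat < 1) stop("configuration error: no plants to place")
  if (n_pea > 0 && length(pea) == 0)
    stop("configuration error: pea plants required but none supplied")
  if (n_wheat > 0 && length(wheat) == 0)
    stop("configuration error: wheat plants required but none supplied")

  withr::with_seed(spec$seed, {
    # Proportional within-row alternation: merge the two species by their
    # fractional positions in the planting order.
    ord <- order(c((seq_len(n_wheat) - 0.5) / max(n_wheat, 1),
                   (seq_len(n_pea) - 0.5) / max(n_pea, 1)))
    species_seq <- c(rep("wheat", n_wheat), rep("pea", n_pea))[ord]
    n <- length(species_seq)
    row_of <- rep(seq_len(spec$n_rows), length.out = n)
    x_rows <- (seq_len(spec$n_rows) - 0.5) * spec$plot_x / spec$n_rows
    positions <- matrix(0, n, 2)
    for (r in seq_len(spec$n_rows)) {
      idx <- which(row_of == r)
      positions[idx, 1] <- x_rows[r]
      positions[idx, 2] <- (seq_along(idx) - 0.5) * spec$plot_y / length(idx)
    }
    positions <- positions + matrix(
      stats::runif(2 * n, -spec$jitter_m, spec$jitter_m), n, 2)
    positions[, 1] <- positions[, 1] %% spec$plot_x
    positions[, 2] <- positions[, 2] %% spec$plot_y
    rotations <- stats::runif(n, 0, 360)
    ip <- 0; iw <- 0
    mockups <- vector("list", n)
    for (i in seq_len(n)) {
      if (species_seq[i] == "pea") {
        ip <- ip + 1
        mockups[[i]] <- pea[[(ip - 1) %% length(pea) + 1]]
      } else {
        iw <- iw + 1
        mockups[[i]] <- wheat[[(iw - 1) %% length(wheat) + 1]]
      }
    }
    scene_from_mockups(mockups, positions, rotations,
                       footprint = c(spec$plot_x, spec$plot_y))
  })
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("Canopy scene: %d organs, %d triangles, footprint %.2f x %.2f m\n",
              nrow(x$organs), nrow(x$tris), x$footprint[1], x$footprint[2]))
  if (nrow(x$organs)) {
    for (sp in unique(x$organs$species)) {
      sub <- x$organs[x$organs$species == sp, ]
      cat(sprintf("  %s: %d plants, green area %.4g m2\n", sp,
                  length(unique(sub$plant_id)), sum(sub$area)))
    }
  }
  invisible(x)
}

# Organ types counting as foliage for the mean-inclination descriptor; stems
# and internodes are green (count in LAI) but are not foliage.
FOLIAGE_TYPES <- c("stipule", "leaflet", "blade")

#' Macroscopic canopy descriptors of a scene
#'
#' Per species: LAI (total green organ area over footprint area, stems
#' included), mean foliage inclination (area-weighted over stipules, leaflets
#' and blades), plant height (mean over plants of the highest organ vertex),
#' and the wheat/pea height ratio.
#'
#' @param scene a `scene`.
#' @return An object of class `canopy_descriptors`.
#' @export
canopy_descriptors <- function(scene) {
  stopifnot(inherits(scene, "scene"))
  if (nrow(scene$organs) == 0) stop("scene is empty")
  af <- prod(scene$footprint)
  if (af <= 0) stop("zero footprint")
  org <- scene$organs
  species <- sort(unique(org$species))
  lai <- sapply(species, function(sp) sum(org$area[org$species == sp]) / af)
  incl <- sapply(species, function(sp) {
    sub <- org[org$species == sp & org$organ_type %in% FOLIAGE_TYPES, ]
    if (nrow(sub) == 0 || sum(sub$area) == 0) return(NA_real_)
    sum(sub$area * sub$inclination) / sum(sub$area)
  })
  height <- sapply(species, function(sp) {
    sub <- org[org$species == sp, ]
    mean(tapply(sub$zmax, sub$plant_id, max))
  })
  hr <- if (all(c("wheat", "pea") %in% species) && height[["pea"]] > 0)
    height[["wheat"]] / height[["pea"]] else NA_real_
  structure(list(lai_by_species = lai,
                 mean_inclination_by_species = incl,
                 height_by_species = height,
                 height_ratio = hr),
            class = "canopy_descriptors")
}

#' @export
print.canopy_descriptors <- function(x, ...) {
  cat("Canopy descriptors\n")
  for (sp in names(x$lai_by_species))
    cat(sprintf("  %-6s LAI %.3f m2 m-2, foliage inclination %.1f deg, height %.3f m\n",
                sp, x$lai_by_species[[sp]],
                x$mean_inclination_by_species[[sp]],
                x$height_by_species[[sp]]))
  if (!is.na(x$height_ratio))
    cat(sprintf("  height ratio (wheat/pea): %.3f\n", x$height_ratio))
  invisible(x)
}

#' Write a one-row scene summary CSV (descriptor columns per species)
#'
#' @param scenes named list of `scene` objects (names become row labels).
#' @param path CSV output path.
#' @return The summary data.frame, invisibly.
#' @export
write_scene_summary_csv <- function(scenes, path) {
  rows <- lapply(names(scenes), function(nm) {
    d <- canopy_descriptors(scenes[[nm]])
    data.frame(scene = nm,
               lai_wheat = d$lai_by_species[["wheat"]],
               lai_pea = d$lai_by_species[["pea"]],
               inclination_wheat = d$mean_inclination_by_species[["wheat"]],
               inclination_pea = d$mean_inclination_by_species[["pea"]],
               height_wheat = d$height_by_species[["wheat"]],
               height_pea = d$height_by_species[["pea"]],
               height_ratio = d$height_ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
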