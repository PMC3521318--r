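# Triangle meshes are numeric matrices with 9 columns
# (v1x v1y v1z v2x v2y v2z v3x v3y v3z), coordinates in metres.

#' Areas of mesh triangles
#'
#' @param mesh n x 9 triangle matrix (metres).
#' @return Numeric vector of per-triangle areas (m2).
#' @export
triangle_areas <- function(mesh) {
  if (is.null(mesh) || nrow(mesh) == 0) return(numeric(0))
  ax <- mesh[, 4] - mesh[, 1]; ay <- mesh[, 5] - mesh[, 2]; az <- mesh[, 6] - mesh[, 3]
  bx <- mesh[, 7] - mesh[, 1]; by <- mesh[, 8] - mesh[, 2]; bz <- mesh[, 9] - mesh[, 3]
  cx <- ay * bz - az * by
  cy <- az * bx - ax * bz
  cz <- ax * by - ay * bx
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Planar outlines in a local (midrib u, lateral w) frame, lengths in mm.
# Leaves use an elliptical outline with width = length * width_ratio;
# strips and ribbons are rectangles.
organ_outline <- function(organ_type, length_mm, width_ratio, n_arc = 8) {
  L <- length_mm
  switch(organ_type,
    stipule = ,
    leaflet = {
      tt <- seq(0, 2 * pi, length.out = n_arc + 1)[-(n_arc + 1)]
      cbind(u = L / 2 + L / 2 * cos(tt), w = L * width_ratio / 2 * sin(tt))
    },
    blade = {
      W <- L * width_ratio
      cbind(u = c(0, L, L, 0), w = c(-W / 2, -W / 2, W / 2, W / 2))
    },
    internode = ,
    stem = {
      W <- L * width_ratio
      cbind(u = c(0, L, L, 0), w = c(-W / 2, -W / 2, W / 2, W / 2))
    },
    stop("unknown organ_type: ", organ_type))
}

# Fan triangulation of a convex planar polygon given in (u, w) coordinates.
fan_triangulate <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(matrix(numeric(0), 0, 4))
  idx <- cbind(1, 2:(n - 1), 3:n)
  idx
}

#' Tessellate a planar organ into a triangle mesh
#'
#' Builds a planar polygon (elliptical outline for stipules and leaflets,
#' rectangular strip for blades, internodes and stems), places it with its
#' midrib rising at `inclination` degrees from the horizontal towards
#' `azimuth`, with the lateral axis horizontal, and fan-triangulates it. The
#' angle between the polygon's plane and the horizontal therefore equals the
#' midrib inclination.
#'
#' @param organ_type one of `"stipule"`, `"leaflet"`, `"blade"`,
#'   `"internode"`, `"stem"`.
#' @param length_mm midrib length in mm (>= 0; zero gives a zero-area organ).
#' @param width_ratio width as a fraction of length (default 0.5, the 2:1
#'   length:width model used for pea leaves).
#' @param inclination degrees from horizontal in \[0, 90\].
#' @param azimuth degrees, direction of the midrib's horizontal projection.
#' @param base 3D attachment point (metres).
#' @param species,plant_id,axis_id,rank organ tags.
#' @param n_arc vertices on the elliptical outline.
#' @return An object of class `organ`: tags, `mesh` (metres), `area` (m2,
#'   equal to the summed triangle areas) and `inclination` (degrees).
#' @examples
#' sq <- organ_tessellate("blade", 1000, width_ratio = 1, inclination = 0,
#'                        azimuth = 0)
#' sq$area  # 1 m2
#' @export
organ_tessellate <- function(organ_type, length_mm, width_ratio = 0.5,
                             inclination = 0, azimuth = 0,
                             base = c(0, 0, 0), species = "pea",
                             plant_id = 1L, axis_id = 0L, rank = 0L,
                             n_arc = 8) {
  if (length_mm < 0) stop("length_mm must be >= 0")
  if (inclination < 0 || inclination > 90)
    stop("inclination must lie in [0, 90] degrees")
  poly <- organ_outline(organ_type, length_mm / 1000, width_ratio, n_arc)
  a <- inclination * pi / 180
  phi <- azimuth * pi / 180
  u_dir <- c(cos(a) * cos(phi), cos(a) * sin(phi), sin(a))
  w_dir <- c(-sin(phi), cos(phi), 0)
  verts <- cbind(base[1] + poly[, 1] * u_dir[1] + poly[, 2] * w_dir[1],
                 base[2] + poly[, 1] * u_dir[2] + poly[, 2] * w_dir[2],
                 base[3] + poly[, 1] * u_dir[3] + poly[, 2] * w_dir[3])
  idx <- fan_triangulate(poly)
  mesh <- cbind(verts[idx[, 1], , drop = FALSE],
                verts[idx[, 2], , drop = FALSE],
                verts[idx[, 3], , drop = FALSE])
  structure(list(species = species, plant_id = plant_id, axis_id = axis_id,
                 rank = rank, organ_type = organ_type, mesh = mesh,
                 area = sum(triangle_areas(mesh)), inclination = inclination),
            class = "organ")
}

#' @export
print.organ <- function(x, ...) {
  cat(sprintf("%s organ (%s, plant %s, axis %s, rank %d): area %.3g m2, inclination %.1f deg, %d triangles\n",
              x$organ_type, x$species, format(x$plant_id), format(x$axis_id),
              x$rank, x$area, x$inclination, nrow(x$mesh)))
  invisible(x)
}

# Assemble a plant_mockup object from a list of organs.
new_plant_mockup <- function(organs, species, n_phytomers_main, n_branches) {
  areas <- vapply(organs, `[[`, 0, "area")
  types <- vapply(organs, `[[`, "", "organ_type")
  height <- if (length(organs)) {
    max(vapply(organs, function(o) if (nrow(o$mesh)) max(o$mesh[, c(3, 6, 9)]) else 0, 0))
  } else 0
  structure(list(
    organs = organs,
    species = species,
    height = height,
    green_area_by_type = if (length(organs)) tapply(areas, types, sum) else
      stats::setNames(numeric(0), character(0)),
    n_phytomers_main = n_phytomers_main,
    n_branches = n_branches),
    class = "plant_mockup")
}

#' @export
print.plant_mockup <- function(x, ...) {
  cat(sprintf("%s mock-up: %d organs, height %.3f m, green area %.4g m2, %d main-stem phytomers, %d branches\n",
              x$species, length(x$organs), x$height,
              sum(x$green_area_by_type), x$n_phytomers_main, x$n_branches))
  if (length(x$green_area_by_type)) {
    cat("  area by organ type (m2):\n")
    for (nm in names(x$green_area_by_type))
      cat(sprintf("    %-10s %.5g\n", nm, x$green_area_by_type[[nm]]))
  }
  invisible(x)
}

#' Total green area of a mock-up (m2)
#' @param mockup a `plant_mockup`.
#' @export
plant_area <- function(mockup) sum(mockup$green_area_by_type)

#' Leaf (stipule + leaflet) fraction of a mock-up's green area
#' @param mockup a `plant_mockup`.
#' @return Fraction in \[0, 1\].
#' @export
leaf_area_fraction <- function(mockup) {
  g <- mockup$green_area_by_type
  tot <- sum(g)
  if (tot == 0) return(NA_real_)
  sum(g[names(g) %in% c("stipule", "leaflet")]) / tot
}

# Flat per-organ table plus triangle matrix for a list of mock-ups.
flatten_mockups <- function(mockups) {
  organs <- unlist(lapply(mockups, `[[`, "organs"), recursive = FALSE)
  if (!length(organs))
    return(list(table = data.frame(), tris = matrix(numeric(0), 0, 9)))
  tri_counts <- vapply(organs, function(o) nrow(o$mesh), 0L)
  tris <- do.call(rbind, lapply(organs, `[[`, "mesh"))
  table <- data.frame(
    species = vapply(organs, `[[`, "", "species"),
    plant_id = vapply(organs, function(o) as.character(o$plant_id), ""),
    axis_id = vapply(organs, function(o) as.integer(o$axis_id), 0L),
    rank = vapply(organs, function(o) as.integer(o$rank), 0L),
    organ_type = vapply(organs, `[[`, "", "organ_type"),
    area = vapply(organs, `[[`, 0, "area"),
    inclination = vapply(organs, `[[`, 0, "inclination"),
    zmax = vapply(organs, function(o)
      if (nrow(o$mesh)) max(o$mesh[, c(3, 6, 9)]) else 0, 0),
    n_tri = tri_counts,
    stringsAsFactors = FALSE)
  list(table = table, tris = tris)
}
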