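#' Export a mock-up or scene mesh to Wavefront OBJ
#'
#' Writes triangle soup with one `g` group per organ, tagged
#' `species/plant/axis/rank/organ_type`.
#'
#' @param x a `plant_mockup` or `scene`.
#' @param path output `.obj` path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(x, path) {
  organs <- mesh_organ_list(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# canopymix mesh export", con)
  voff <- 0L
  for (o in organs) {
    m <- o$mesh
    if (!nrow(m)) next
    writeLines(sprintf("g %s/%s/%s/%d/%s", o$species, format(o$plant_id),
                       format(o$axis_id), o$rank, o$organ_type), con)
    verts <- rbind(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE],
                   m[, 7:9, drop = FALSE])
    n <- nrow(m)
    ord <- as.vector(t(matrix(seq_len(3 * n), ncol = 3)))
    verts <- verts[ord, , drop = FALSE]
    writeLines(sprintf("v %.6f %.6f %.6f", verts[, 1], verts[, 2], verts[, 3]), con)
    f0 <- voff + seq(1, 3 * n, by = 3)
    writeLines(sprintf("f %d %d %d", f0, f0 + 1, f0 + 2), con)
    voff <- voff + 3L * n
  }
  invisible(path)
}

#' Export a mock-up or scene mesh to ASCII PLY
#'
#' @param x a `plant_mockup` or `scene`.
#' @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(x, path) {
  organs <- mesh_organ_list(x)
  meshes <- lapply(organs, `[[`, "mesh")
  ntri <- sum(vapply(meshes, nrow, 0L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment canopymix mesh export",
               sprintf("element vertex %d", 3 * ntri),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", ntri),
               "property list uchar int vertex_indices",
               "end_header"), con)
  for (o in organs) {
    m <- o$mesh
    if (!nrow(m)) next
    for (i in seq_len(nrow(m)))
      writeLines(sprintf("%.6f %.6f %.6f",
                         m[i, c(1, 4, 7)], m[i, c(2, 5, 8)], m[i, c(3, 6, 9)]), con)
  }
  idx <- seq_len(3 * ntri) - 1L
  if (ntri > 0) {
    fm <- matrix(idx, ncol = 3, byrow = TRUE)
    writeLines(sprintf("3 %d %d %d", fm[, 1], fm[, 2], fm[, 3]), con)
  }
  invisible(path)
}

mesh_organ_list <- function(x) {
  if (inherits(x, "plant_mockup")) return(x$organs)
  if (inherits(x, "scene")) {
    # rebuild per-organ meshes from the flat triangle matrix
    org <- x$organs
    start <- cumsum(c(0, org$n_tri))
    return(lapply(seq_len(nrow(org)), function(i) {
      list(species = org$species[i], plant_id = org$plant_id[i],
           axis_id = org$axis_id[i], rank = org$rank[i],
           organ_type = org$organ_type[i],
           mesh = x$tris[seq.int(start[i] + 1, length.out = org$n_tri[i]), ,
                         drop = FALSE])
    }))
  }
  stop("x must be a plant_mockup or scene")
}
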