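clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Attachment point displaced horizontally from the stem axis (petiole/rachis
# offset, mm) towards the organ azimuth.
leaf_base <- function(node, azimuth_deg, offset_mm) {
  if (length(node) == 1) node <- c(0, 0, node)
  a <- azimuth_deg * pi / 180
  node + c(cos(a), sin(a), 0) * offset_mm / 1000
}

# Mean-zero inclination jitter, clipped to plausible organ angles and then
# recentred so the target mean inclination is preserved exactly.
jitter_inclinations <- function(target, n, sd = 10) {
  if (n == 0) return(numeric(0))
  j <- stats::rnorm(n, 0, sd)
  out <- pmin(pmax(target + j - mean(j), 2), 88)
  out
}

#' Build a 3D pea plant mock-up from a genotype specification
#'
#' Deterministically (given `seed`) constructs the plant at thermal time `t`:
#' the main stem carries `round(Y(t))` phytomers from the Schnute development
#' curve, each phytomer an internode plus an opposite pair of stipules (and,
#' for leafy genotypes, leaflet pairs). Organ final lengths follow the
#' genotype's rank profiles; every organ expands linearly over
#' `spec$expansion_dd` degree-days after its phytomer appears. Stipule and
#' leaflet inclinations follow the genotype's thermal-time dynamics with a
#' small mean-preserving jitter; azimuths are drawn uniformly. Branches are
#' drawn from the stage's observed range and carry the main-stem profiles
#' truncated to their phytomer count; insertion is basal except where the
#' genotype specifies mid-stem ranks. Stems are staked upright.
#'
#' @param spec a [load_genotype_spec()] object.
#' @param t thermal time since emergence (DD), >= 0.
#' @param seed integer seed; identical (spec, t, seed) give bit-identical
#'   mock-ups.
#' @return A `plant_mockup`.
#' @examples
#' spec <- pea_genotype("Lucy")
#' build_pea(spec, t = 600, seed = 1)
#' @export
build_pea <- function(spec, t, seed = 1L) {
  stopifnot(inherits(spec, "genotype_spec"))
  if (!is.finite(t) || t < 0) stop("t must be >= 0")
  td <- min(t, spec$schnute$t_max)
  n_main <- round(schnute_eval(spec$schnute, td))
  if (n_main < 1)
    return(new_plant_mockup(list(), "pea", 0L, 0L))

  withr::with_seed(seed, {
    organs <- list()
    leafy <- spec$leaf_type == "leafy"

    t_app <- schnute_inverse(spec$schnute, seq_len(n_main) - 0.5)
    frac <- clamp01((t - t_app) / spec$expansion_dd)
    ranks <- seq_len(n_main) / spec$schnute$y_max
    int_len <- internode_length_mm(spec, ranks) * frac
    offset <- spec$basal_offset_mm * clamp01(t / 150)
    nodes_z <- (offset + cumsum(int_len)) / 1000

    stip_target <- organ_inclination_deg(spec, "stipule", t)
    stip_inc <- jitter_inclinations(stip_target, 2 * n_main)
    leaf_inc <- if (leafy)
      jitter_inclinations(organ_inclination_deg(spec, "leaflet", t),
                          2 * spec$leaflet_pairs * n_main) else numeric(0)
    node_az <- stats::runif(n_main, 0, 360)

    # basal stem segment below the first phytomer (vestigial ranks)
    if (offset > 0)
      organs[[length(organs) + 1L]] <- organ_tessellate(
        "stem", offset, width_ratio = spec$stem_width_mm / max(offset, 1e-9),
        inclination = 90, azimuth = stats::runif(1, 0, 360),
        base = c(0, 0, 0), species = "pea", axis_id = 0L, rank = 0L)

    li <- 0L
    for (i in seq_len(n_main)) {
      z0 <- if (i == 1) offset / 1000 else nodes_z[i - 1]
      if (int_len[i] > 0)
        organs[[length(organs) + 1L]] <- organ_tessellate(
          "internode", int_len[i],
          width_ratio = spec$stem_width_mm / int_len[i],
          inclination = 90, azimuth = node_az[i],
          base = c(0, 0, z0), species = "pea", axis_id = 0L, rank = i)
      s_len <- stipule_length_mm(spec, ranks[i]) * frac[i]
      for (k in 0:1) {
        if (s_len > 0)
          organs[[length(organs) + 1L]] <- organ_tessellate(
            "stipule", s_len, inclination = stip_inc[2 * i - 1 + k],
            azimuth = node_az[i] + 180 * k,
            base = leaf_base(nodes_z[i], node_az[i] + 180 * k, 3),
            species = "pea", axis_id = 0L, rank = i)
      }
      if (leafy) {
        l_len <- leaflet_length_mm(spec, ranks[i]) * frac[i]
        for (k in seq_len(2 * spec$leaflet_pairs)) {
          li <- li + 1L
          az_k <- node_az[i] + 90 + 180 * (k - 1) +
            360 / (2 * spec$leaflet_pairs) * ((k - 1) %/% 2)
          # leaflets sit on a rachis away from the stem; successive pairs of
          # the compound leaf attach lower down the internode
          z_k <- nodes_z[i] - ((k - 1) %/% 2) * 0.4 * int_len[i] / 1000
          if (l_len > 0)
            organs[[length(organs) + 1L]] <- organ_tessellate(
              "leaflet", l_len, inclination = leaf_inc[li],
              azimuth = az_k,
              base = leaf_base(z_k, az_k, 0.8 * l_len),
              species = "pea", axis_id = 0L, rank = i)
        }
      }
    }

    # Branches
    n_branches <- 0L
    stage <- branching_stage(spec, t)
    if (!is.null(stage)) {
      n_branches <- sample(stage$min:stage$max, 1)
      for (b in seq_len(n_branches)) {
        nb <- max(1, round(stats::rnorm(1, stage$phytomers[b], stage$sd[b])))
        nb <- min(nb, n_main)
        ins <- spec$branching$insertion
        rank_ins <- if (identical(ins, "basal")) {
          sample(seq_len(min(3, n_main)), 1)
        } else {
          lo <- ins[[1]]; hi <- min(ins[[2]], n_main)
          if (lo > n_main) sample(seq_len(min(3, n_main)), 1)
          else sample(lo:hi, 1)
        }
        base_z <- nodes_z[rank_ins]
        # branch phytomer k co-develops with main-stem phytomer rank_ins + k
        bfrac <- frac[pmin(n_main, rank_ins + seq_len(nb))]
        organs <- c(organs, build_pea_branch(spec, b, nb, base_z, t, leafy,
                                             bfrac))
      }
    }

    new_plant_mockup(organs, "pea", as.integer(n_main), as.integer(n_branches))
  })
}

# One branch: main-stem profiles truncated to nb phytomers, rising at a
# slight lean from the insertion node.
build_pea_branch <- function(spec, axis_id, nb, base_z, t, leafy,
                             bfrac = rep(1, nb)) {
  lean <- 35                       # degrees from vertical
  az <- stats::runif(1, 0, 360)
  ranks <- seq_len(nb) / spec$schnute$y_max
  int_len <- internode_length_mm(spec, ranks) * 0.9 * bfrac
  stip_inc <- jitter_inclinations(organ_inclination_deg(spec, "stipule", t), 2 * nb)
  leaf_inc <- if (leafy)
    jitter_inclinations(organ_inclination_deg(spec, "leaflet", t),
                        2 * spec$leaflet_pairs * nb) else numeric(0)
  node_az <- stats::runif(nb, 0, 360)
  dxy <- sin(lean * pi / 180)
  dir <- c(dxy * cos(az * pi / 180), dxy * sin(az * pi / 180),
           cos(lean * pi / 180))
  organs <- list()
  pos <- c(0, 0, base_z)
  li <- 0L
  for (k in seq_len(nb)) {
    if (int_len[k] > 0)
      organs[[length(organs) + 1L]] <- organ_tessellate(
        "internode", int_len[k],
        width_ratio = spec$stem_width_mm / int_len[k],
        inclination = 90 - lean, azimuth = az,
        base = pos, species = "pea", axis_id = axis_id, rank = k)
    pos <- pos + dir * int_len[k] / 1000
    s_len <- stipule_length_mm(spec, ranks[k]) * bfrac[k]
    for (j in 0:1)
      organs[[length(organs) + 1L]] <- organ_tessellate(
        "stipule", s_len, inclination = stip_inc[2 * k - 1 + j],
        azimuth = node_az[k] + 180 * j,
        base = leaf_base(pos, node_az[k] + 180 * j, 3), species = "pea",
        axis_id = axis_id, rank = k)
    if (leafy) {
      l_len <- leaflet_length_mm(spec, ranks[k]) * bfrac[k]
      for (j in seq_len(2 * spec$leaflet_pairs)) {
        li <- li + 1L
        az_j <- node_az[k] + 90 + 180 * (j - 1)
        organs[[length(organs) + 1L]] <- organ_tessellate(
          "leaflet", l_len, inclination = leaf_inc[li],
          azimuth = az_j, base = leaf_base(pos, az_j, 0.8 * l_len),
          species = "pea", axis_id = axis_id, rank = k)
      }
    }
  }
  organs
}
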