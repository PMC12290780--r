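#' Generate a labelled two-hemisphere cortical mesh stand-in
#'
#' Places vertices quasi-uniformly (Fibonacci lattice with jitter) on two
#' unit hemispheric shells offset left/right, assigns contiguous functional
#' network and atlas region labels by angular sectors, and masks a small
#' medial patch per hemisphere (a corpus-callosum stand-in). Regions nest
#' within hemispheres; each network patch contains several vertices.
#'
#' @param n_vertices_per_hemisphere vertex count per hemisphere.
#' @param n_networks number of functional networks (Yeo-style; labels
#'   1..n_networks repeated in both hemispheres).
#' @param n_regions number of atlas regions per hemisphere (Glasser-style).
#' @param seed integer seed.
#' @param mask_fraction fraction of vertices masked per hemisphere.
#' @return a `surface_mesh` data.frame: `vertex_id`, `x`, `y`, `z`,
#'   `hemisphere` ("L"/"R"), `network` (integer), `region` (integer, unique
#'   across hemispheres), `mask` (logical; TRUE = excluded).
#' @export
generate_mesh <- function(n_vertices_per_hemisphere, n_networks, n_regions,
                          seed = 1L, mask_fraction = 0.03) {
  if (n_networks < 1 || n_regions < n_networks)
    stop("need n_regions >= n_networks >= 1")
  set.seed(seed)
  n <- n_vertices_per_hemisphere
  hemi_one <- function(side) {
    i <- seq_len(n) - 0.5
    phi <- acos(1 - 2 * i / n)                  # polar angle
    theta <- pi * (1 + sqrt(5)) * i             # golden-angle azimuth
    theta <- theta %% (2 * pi)
    xyz <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
    xyz <- xyz + matrix(stats::rnorm(3 * n, 0, 0.005), n, 3)
    offset <- if (side == "L") -1.1 else 1.1
    xyz[, 1] <- xyz[, 1] + offset
    # contiguous labels: sectors of azimuth (networks), finer (regions)
    net <- pmin(n_networks, 1L + floor(theta / (2 * pi) * n_networks))
    reg <- pmin(n_regions, 1L + floor(theta / (2 * pi) * n_regions))
    # mask the medial pole patch: vertices closest to the midline
    medial <- if (side == "L") xyz[, 1] else -xyz[, 1]
    k <- max(1L, round(mask_fraction * n))
    mask <- rank(-medial, ties.method = "first") <= k
    data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               hemisphere = side, network = as.integer(net),
               region = as.integer(reg), mask = mask,
               stringsAsFactors = FALSE)
  }
  mesh <- rbind(hemi_one("L"), hemi_one("R"))
  mesh$region <- mesh$region + ifelse(mesh$hemisphere == "R", n_regions, 0L)
  mesh <- cbind(vertex_id = sprintf("v%04d", seq_len(nrow(mesh))), mesh,
                stringsAsFactors = FALSE)
  class(mesh) <- c("surface_mesh", "data.frame")
  mesh
}

#' Map unmasked vertices to grouping labels
#'
#' @param mesh a `surface_mesh`.
#' @param grouping one of "region", "functional_network",
#'   "anatomical_network" (networks collapsed into coarse groups) or
#'   "cortex" (single label).
#' @return data.frame `vertex_id`, `label` for unmasked vertices.
#' @export
map_vertices <- function(mesh, grouping = c("region", "functional_network",
                                            "anatomical_network", "cortex")) {
  grouping <- match.arg(grouping)
  m <- mesh[!mesh$mask, , drop = FALSE]
  label <- switch(grouping,
    region = sprintf("region%03d", m$region),
    functional_network = sprintf("%s_net%d", m$hemisphere, m$network),
    anatomical_network = sprintf("anat%d", 1L + (m$network - 1L) %/% 2L),
    cortex = rep("cortex", nrow(m)))
  data.frame(vertex_id = m$vertex_id, label = label,
             stringsAsFactors = FALSE)
}

#' Per-label counts of significant associations
#'
#' Aggregation helper: counts significant (SNP, vertex) associations within
#' each grouping label.
#'
#' @param vertex_labels output of [map_vertices()].
#' @param assoc_vertices character vector, one vertex id per significant
#'   association (repeats allowed: one entry per SNP-vertex pair).
#' @return data.frame `label`, `n_signif`.
#' @export
count_hits_by_label <- function(vertex_labels, assoc_vertices) {
  lab <- vertex_labels$label[match(assoc_vertices, vertex_labels$vertex_id)]
  if (anyNA(lab)) stop("association refers to unknown or masked vertex")
  all_lab <- sort(unique(vertex_labels$label))
  cnt <- table(factor(lab, levels = all_lab))
  data.frame(label = all_lab, n_signif = as.integer(cnt),
             stringsAsFactors = FALSE)
}

#' Pairwise Euclidean vertex distances
#'
#' @param mesh a `surface_mesh`.
#' @param vertices vertex ids.
#' @return list with `dist` (matrix) and `intra_hemisphere` (logical
#'   matrix flagging same-hemisphere pairs).
#' @export
vertex_distances <- function(mesh, vertices) {
  idx <- match(vertices, mesh$vertex_id)
  if (anyNA(idx)) stop("unknown vertex id: ",
                       paste(vertices[is.na(idx)], collapse = ", "))
  xyz <- as.matrix(mesh[idx, c("x", "y", "z")])
  D <- as.matrix(stats::dist(xyz))
  dimnames(D) <- list(vertices, vertices)
  hemi <- mesh$hemisphere[idx]
  intra <- outer(hemi, hemi, "==")
  dimnames(intra) <- dimnames(D)
  list(dist = D, intra_hemisphere = intra)
}
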