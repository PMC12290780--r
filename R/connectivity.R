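#' Kernel smoothing of a sparse SC matrix
#'
#' Convolves each row of the structural-connectivity matrix with a Gaussian
#' kernel over inter-vertex Euclidean distance; kernel weights for each
#' target vertex are normalized to sum to one, and symmetry is restored by
#' averaging with the transpose.
#'
#' @param sc vertices x vertices non-negative SC matrix.
#' @param mesh a `surface_mesh` whose rows match the SC columns.
#' @param bandwidth Gaussian kernel standard deviation, in mesh coordinate
#'   units (> 0). Bandwidths below the minimum vertex spacing reduce to the
#'   identity.
#' @return smoothed symmetric SC matrix.
#' @export
smooth_sc <- function(sc, mesh, bandwidth) {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  xyz <- as.matrix(mesh[, c("x", "y", "z")])
  if (nrow(xyz) != ncol(sc)) stop("mesh and SC dimensions disagree")
  D <- as.matrix(stats::dist(xyz))
  W <- exp(-0.5 * (D / bandwidth)^2)
  W <- sweep(W, 2, colSums(W), "/")       # weights per target vertex sum to 1
  out <- sc %*% W
  (out + t(out)) / 2
}

#' Pearson-correlation FC from BOLD time series
#'
#' @param bold time x vertices matrix; needs >= 3 time points and
#'   non-constant columns.
#' @return vertices x vertices correlation matrix, unit diagonal.
#' @export
fc_from_timeseries <- function(bold) {
  if (nrow(bold) < 3) stop("need at least 3 time points")
  v <- apply(bold, 2, stats::var)
  if (any(v <= 0)) {
    bad <- which(v <= 0)
    nm <- if (!is.null(colnames(bold))) colnames(bold)[bad] else bad
    stop("constant time series at vertex ", paste(nm, collapse = ", "))
  }
  FC <- stats::cor(bold)
  diag(FC) <- 1
  FC
}

coupling_region <- function(mesh, v_idx) {
  # integration patch E: unmasked vertices of the same functional network
  # and hemisphere, excluding the focal vertex itself
  which(!mesh$mask &
          mesh$network == mesh$network[v_idx] &
          mesh$hemisphere == mesh$hemisphere[v_idx] &
          seq_len(nrow(mesh)) != v_idx)
}

#' Vertex-wise SC-FC coupling
#'
#' For each unmasked vertex, restricts the subject's SC and FC local
#' profiles to the vertex's functional-network patch on its own hemisphere
#' (excluding the vertex itself) and measures their similarity:
#' \code{inner} is the normalized inner product
#' \eqn{\langle f_1/\|f_1\|, f_2/\|f_2\|\rangle}
#' (1 = proportional, 0 = orthogonal, -1 = opposite), with uniform vertex
#' weights; \code{pearson}/\code{spearman} are the corresponding profile
#' correlations. SC profiles are log(1 + SC)-transformed by default to tame
#' the heavy-tailed streamline counts.
#'
#' @param profiles list with elements `sc` and `fc`, each a list of
#'   per-subject vertices x vertices matrices (as from
#'   [simulate_connectivity()] or [read_profiles()]).
#' @param mesh a `surface_mesh` matching the profile dimensions.
#' @param method "inner", "pearson" or "spearman".
#' @param log_transform_sc apply log1p to SC profiles first.
#' @param log_offset offset c in log(c + SC); default 1.
#' @return a `coupling_matrix`: subjects x unmasked-vertices numeric matrix
#'   with vertex ids as colnames and attributes `method`, `vertex_ids`.
#'   Vertices whose SC or FC profile has zero norm over the patch get `NA`
#'   (with one warning).
#' @export
compute_coupling <- function(profiles, mesh,
                             method = c("inner", "pearson", "spearman"),
                             log_transform_sc = TRUE, log_offset = 1) {
  method <- match.arg(method)
  n_sub <- length(profiles$sc)
  stopifnot(length(profiles$fc) == n_sub)
  keep <- which(!mesh$mask)
  regions <- lapply(seq_len(nrow(mesh)), function(v)
    if (mesh$mask[v]) integer(0) else coupling_region(mesh, v))
  out <- matrix(NA_real_, n_sub, length(keep),
                dimnames = list(names(profiles$sc), mesh$vertex_id[keep]))
  zero_norm <- FALSE
  for (s in seq_len(n_sub)) {
    SC <- profiles$sc[[s]]; FC <- profiles$fc[[s]]
    if (nrow(SC) != nrow(mesh)) stop("profiles and mesh vertex sets disagree")
    for (j in seq_along(keep)) {
      v <- keep[j]
      E <- regions[[v]]
      a <- SC[v, E]
      if (log_transform_sc) a <- log(log_offset + a)
      b <- FC[v, E]
      out[s, j] <- switch(method,
        inner = {
          na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
          if (na == 0 || nb == 0) { zero_norm <- TRUE; NA_real_ }
          else sum(a * b) / (na * nb)
        },
        pearson = if (stats::sd(a) == 0 || stats::sd(b) == 0) {
          zero_norm <- TRUE; NA_real_
        } else stats::cor(a, b),
        spearman = if (stats::sd(a) == 0 || stats::sd(b) == 0) {
          zero_norm <- TRUE; NA_real_
        } else stats::cor(a, b, method = "spearman"))
    }
  }
  if (zero_norm)
    warning("degenerate profile over a network patch; coupling set to NA")
  structure(out, method = method, class = c("coupling_matrix", "matrix",
                                            "array"))
}

#' Simulate connectivity profiles with a genetic coupling signal
#'
#' For every subject and unmasked vertex a latent target coupling value is
#' drawn with between-subject covariance \eqn{h^2 K + (1 - h^2) I} (scaled
#' and shifted into (-1, 1); values outside are clipped with a warning).
#' Each subject's SC matrix is a shared lognormal backbone perturbed per
#' subject; the FC local profile at a vertex is then constructed as
#' \eqn{\cos\theta \, u + \sin\theta \, w} where u is the unit
#' log1p-transformed SC profile over the vertex's network patch, w a unit
#' profile orthogonal to u, and \eqn{\theta = \arccos(c)} — so the
#' normalized inner-product coupling of the emitted profiles equals the
#' target c exactly. FC matrices are therefore row-profile-oriented
#' (coupling reads row profiles), not globally symmetric.
#'
#' @param mesh a `surface_mesh`; every network patch per hemisphere must
#'   hold at least 3 unmasked vertices.
#' @param K a `grm` object or matrix giving the subject genetic covariance.
#' @param h2_coupling per-vertex heritability of the coupling target
#'   (scalar recycled).
#' @param coupling_mean,coupling_sd location/scale of the latent target.
#' @param seed integer seed.
#' @return list with `sc`, `fc` (per-subject matrices, named by subject
#'   id) and `targets` (subjects x unmasked-vertices matrix of latent
#'   coupling values).
#' @export
simulate_connectivity <- function(mesh, K, h2_coupling = 0.4,
                                  coupling_mean = 0.3, coupling_sd = 0.15,
                                  seed = 1L) {
  set.seed(seed)
  Km <- if (inherits(K, "grm")) K$K else K
  n_sub <- nrow(Km)
  ids <- rownames(Km)
  if (is.null(ids)) ids <- sprintf("ind%d", seq_len(n_sub))
  nv <- nrow(mesh)
  keep <- which(!mesh$mask)
  h2 <- rep_len(h2_coupling, length(keep))

  patch_sizes <- vapply(keep, function(v) length(coupling_region(mesh, v)), 0L)
  if (any(patch_sizes < 2))
    stop("each network patch needs at least 3 unmasked vertices")

  # latent targets: MVN across subjects per vertex
  e <- eigen((Km + t(Km)) / 2, symmetric = TRUE)
  sq <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  targets <- matrix(0, n_sub, length(keep),
                    dimnames = list(ids, mesh$vertex_id[keep]))
  for (j in seq_along(keep)) {
    g <- drop(sq %*% stats::rnorm(n_sub)) * sqrt(h2[j])
    eps <- stats::rnorm(n_sub) * sqrt(1 - h2[j])
    targets[, j] <- coupling_mean + coupling_sd * (g + eps)
  }
  if (any(targets <= -1 | targets >= 1)) {
    warning("latent coupling targets outside (-1, 1) were clipped")
    targets <- pmin(pmax(targets, -0.999), 0.999)
  }

  # shared SC backbone, lognormal weights
  base <- matrix(0, nv, nv)
  ut <- upper.tri(base)
  base[ut] <- exp(stats::rnorm(sum(ut), 0, 1))
  base <- base + t(base)

  sc_list <- fc_list <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    noise <- matrix(0, nv, nv)
    noise[ut] <- exp(stats::rnorm(sum(ut), 0, 0.3))
    noise <- noise + t(noise)
    SC <- base * noise
    FC <- matrix(0, nv, nv)
    diag(FC) <- 1
    for (j in seq_along(keep)) {
      v <- keep[j]
      E <- coupling_region(mesh, v)
      a <- log1p(SC[v, E])
      u <- a / sqrt(sum(a^2))
      w <- stats::rnorm(length(E))
      w <- w - sum(w * u) * u
      w <- w / sqrt(sum(w^2))
      cv <- targets[s, j]
      prof <- cv * u + sqrt(1 - cv^2) * w
      scl <- max(abs(prof))
      if (scl > 1) prof <- prof / scl     # positive rescale: coupling unchanged
      FC[v, E] <- prof
    }
    sc_list[[s]] <- SC; fc_list[[s]] <- FC
  }
  names(sc_list) <- names(fc_list) <- ids
  list(sc = sc_list, fc = fc_list, targets = targets)
}
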