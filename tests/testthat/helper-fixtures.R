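# shared fixture builders; everything is generated in code at test time

drop_monomorphic <- function(g) {
  af <- colMeans(g$dosage, na.rm = TRUE) / 2
  keep <- !is.na(af) & af > 0 & af < 1
  sfcoupling:::new_genotype_matrix(g$dosage[, keep, drop = FALSE],
                                   g$snp_meta[keep, , drop = FALSE])
}

# small related cohort with polymorphic genotypes and its GRM
make_cohort <- function(n_mz = 15, n_dz = 10, n_fs = 15, n_single = 20,
                        n_snps = 600, seed = 101) {
  ped <- generate_pedigree(n_mz, n_dz, n_fs, n_single, seed = seed)
  geno <- drop_monomorphic(simulate_genotypes(
    ped, n_snps, ld_block_size = min(50, n_snps), seed = seed + 1))
  K <- compute_grm(geno)
  list(ped = ped, geno = geno, K = K, n = length(analysis_ids(ped)))
}

# draw y with covariance h2*K + (1-h2)*I
mvn_trait <- function(K, h2, seed) {
  Km <- if (inherits(K, "grm")) K$K else K
  n <- nrow(Km)
  e <- eigen((Km + t(Km)) / 2, symmetric = TRUE)
  sq <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  set.seed(seed)
  drop(sq %*% stats::rnorm(n)) * sqrt(h2) + stats::rnorm(n) * sqrt(1 - h2)
}

# hand-built single-network mesh for coupling unit tests
toy_mesh <- function(n = 8, masked = integer(0)) {
  set.seed(42)
  m <- data.frame(
    vertex_id = sprintf("v%02d", seq_len(n)),
    x = stats::rnorm(n), y = stats::rnorm(n), z = stats::rnorm(n),
    hemisphere = "L", network = 1L, region = 1L,
    mask = seq_len(n) %in% masked, stringsAsFactors = FALSE)
  class(m) <- c("surface_mesh", "data.frame")
  m
}

# symmetric profile pair on a toy mesh with a prescribed FC row at vertex v
toy_profiles <- function(mesh, fc_row_at = NULL, v = 1) {
  n <- nrow(mesh)
  set.seed(7)
  SC <- matrix(stats::runif(n * n, 0.5, 3), n, n)
  SC <- (SC + t(SC)) / 2; diag(SC) <- 0
  FC <- matrix(stats::runif(n * n, -0.5, 0.5), n, n)
  FC <- (FC + t(FC)) / 2; diag(FC) <- 1
  if (!is.null(fc_row_at)) {
    FC[v, ] <- fc_row_at
    FC[, v] <- fc_row_at
  }
  list(sc = list(s1 = SC), fc = list(s1 = FC))
}
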