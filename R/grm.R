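new_grm <- function(K, ids, source = c("snp", "pedigree"), n_snps = NULL) {
  source <- match.arg(source)
  structure(list(K = K, ids = ids, source = source, n_snps = n_snps),
            class = "grm")
}

#' @export
#' @method print grm
print.grm <- function(x, ...) {
  cat(sprintf("grm (%s-based): %d individuals", x$source, length(x$ids)))
  if (!is.null(x$n_snps))
    cat(sprintf(", median SNPs/pair %d",
                as.integer(stats::median(x$n_snps))))
  cat("\n")
  invisible(x)
}

#' SNP-based genetic relationship matrix
#'
#' The standard GREML similarity estimator: for individuals j, k,
#' \deqn{K_{jk} = \frac{1}{M_{jk}} \sum_i
#'   \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2 p_i (1 - p_i)}}
#' with \eqn{p_i} the sample alternate-allele frequency of SNP i and
#' \eqn{M_{jk}} the number of SNPs non-missing in both individuals
#' (pairwise-complete handling of missing genotypes).
#'
#' @param genotypes a `genotype_matrix` (post-QC; no monomorphic SNPs).
#' @return a `grm` object: `K` (n x n symmetric), `ids`, per-pair SNP counts
#'   `n_snps`, `source = "snp"`.
#' @export
compute_grm <- function(genotypes) {
  G <- genotypes$dosage
  p <- colMeans(G, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1)) stop("monomorphic SNP in GRM input")
  W <- sweep(G, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  obs <- !is.na(W)
  W[!obs] <- 0
  M <- tcrossprod(obs * 1)               # pairwise-complete SNP counts
  if (any(M == 0)) stop("a pair of individuals shares no genotyped SNP")
  K <- tcrossprod(W) / M
  K <- (K + t(K)) / 2
  ids <- rownames(G)
  if (is.null(ids)) ids <- sprintf("ind%d", seq_len(nrow(G)))
  dimnames(K) <- list(ids, ids)
  new_grm(K, ids = ids, source = "snp", n_snps = M)
}

#' Genetic principal components
#'
#' Top eigenvectors of a genetic relationship matrix, the usual ancestry
#' covariates. Each component is unit-norm with sign fixed so its
#' largest-magnitude loading is positive.
#'
#' @param K a `grm` object or symmetric matrix.
#' @param n_components number of components (default 10).
#' @return list with `vectors` (n x n_components, rownames = ids) and
#'   `values` (eigenvalues).
#' @export
genetic_pcs <- function(K, n_components = 10) {
  Km <- if (inherits(K, "grm")) K$K else K
  if (!isTRUE(all.equal(Km, t(Km), tolerance = 1e-8)))
    stop("K must be symmetric")
  n <- nrow(Km)
  if (n_components > n - 1) stop("n_components must be <= n - 1")
  e <- eigen((Km + t(Km)) / 2, symmetric = TRUE)
  V <- e$vectors[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- rownames(Km)
  colnames(V) <- sprintf("PC%d", seq_len(n_components))
  list(vectors = V, values = e$values[seq_len(n_components)])
}

#' Write / read a GRM in GCTA text dialect
#'
#' The triplet file (gzip) holds one row per pair `i j m_ij k_ij` with
#' `i >= j`, 1-based indices, the per-pair SNP count and the similarity
#' value; the companion `.grm.id` file holds family and individual ids.
#'
#' @param grm a `grm` object.
#' @param prefix output path prefix; writes `<prefix>.grm.gz` and
#'   `<prefix>.grm.id`.
#' @param family_ids optional family ids (defaults to the individual ids).
#' @return `prefix`, invisibly.
#' @export
write_grm <- function(grm, prefix, family_ids = NULL) {
  n <- length(grm$ids)
  if (is.null(family_ids)) family_ids <- grm$ids
  idx <- which(lower.tri(grm$K, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  m <- if (is.null(grm$n_snps)) matrix(0L, n, n) else grm$n_snps
  con <- gzfile(paste0(prefix, ".grm.gz"), "w")
  writeLines(sprintf("%d\t%d\t%d\t%.10g",
                     idx[, 1], idx[, 2], m[idx], grm$K[idx]), con)
  close(con)
  utils::write.table(data.frame(family_ids, grm$ids),
                     paste0(prefix, ".grm.id"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_grm
#' @param source source tag to attach on read.
#' @export
read_grm <- function(prefix, source = "snp") {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           stringsAsFactors = FALSE)[[2]]
  tri <- utils::read.table(gzfile(paste0(prefix, ".grm.gz")))
  n <- length(ids)
  K <- matrix(0, n, n); M <- matrix(0L, n, n)
  K[cbind(tri[[1]], tri[[2]])] <- tri[[4]]
  M[cbind(tri[[1]], tri[[2]])] <- tri[[3]]
  K[upper.tri(K)] <- t(K)[upper.tri(K)]
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  dimnames(K) <- list(ids, ids)
  new_grm(K, ids = ids, source = source, n_snps = M)
}
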