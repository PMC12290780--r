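#' Two-step mixed-linear-model GWAS
#'
#' fastGWA-style association scan: (1) a null-model AI-REML fit (via
#' [greml()]) fixes \eqn{\hat V = \hat\sigma_g^2 K + \hat\sigma_e^2 I};
#' (2) the model is rotated onto the eigenbasis of K once, so each SNP
#' costs a single weighted (generalized-least-squares) regression with the
#' covariates included and a Wald p-value under the fixed \eqn{\hat V}.
#' Missing genotypes are mean-imputed per SNP; monomorphic SNPs are skipped
#' with a reason.
#'
#' @param trait numeric trait vector.
#' @param genotypes a `genotype_matrix`.
#' @param covariates covariate data.frame or NULL.
#' @param K a `grm` object/matrix, or NULL with `K_eigen` supplied.
#' @param K_eigen optional precomputed [grm_eigen()].
#' @param X optional explicit design matrix.
#' @return list with `assoc` (data.frame: chrom, id, pos, ref, alt, af,
#'   beta, se, p_value), `skipped` (id, reason) and `null_model` (the
#'   `greml` fit).
#' @export
lmm_gwas <- function(trait, genotypes, covariates = NULL, K = NULL,
                     K_eigen = NULL, X = NULL) {
  G <- genotypes$dosage
  n <- nrow(G)
  stopifnot(length(trait) == n)
  if (is.null(K_eigen)) K_eigen <- grm_eigen(K)
  if (is.null(X)) {
    X <- if (is.null(covariates)) matrix(1, n, 1)
         else covariate_design(covariates)
  }
  lam <- pmax(K_eigen$values, 0)
  if (max(lam) - min(lam) < 1e-10) {
    # K proportional to the identity: the mixed model degenerates to OLS
    null_fit <- NULL
    qrX <- qr(X)
    d <- rep(sum(qr.resid(qrX, trait)^2) / (n - ncol(X)), n)
  } else {
    null_fit <- greml(trait, K_eigen = K_eigen, X = X)
    if (!null_fit$converged)
      stop("null-model REML did not converge; association scan aborted")
    d <- null_fit$sigma_g2 * lam + null_fit$sigma_e2
  }
  U <- K_eigen$vectors
  w <- 1 / d
  ty <- drop(crossprod(U, trait))
  tX <- crossprod(U, X)
  # residualize trait against covariates under weights w
  XtWX <- crossprod(tX, w * tX)
  Rx <- chol(XtWX)
  solve_XtWX <- function(b) backsolve(Rx, backsolve(Rx, b, transpose = TRUE))
  y_res <- ty - tX %*% solve_XtWX(crossprod(tX, w * ty))

  af <- colMeans(G, na.rm = TRUE) / 2
  mono <- is.na(af) | af <= 0 | af >= 1
  Gi <- G
  if (anyNA(Gi)) {
    for (j in which(colSums(is.na(Gi)) > 0))
      Gi[is.na(Gi[, j]), j] <- 2 * af[j]
  }
  tG <- crossprod(U, Gi[, !mono, drop = FALSE])
  # residualize each SNP against covariates under weights w
  tG_res <- tG - tX %*% solve_XtWX(crossprod(tX, w * tG))
  gWg <- colSums(tG_res * (w * tG_res))
  gWy <- colSums(tG_res * (w * drop(y_res)))
  beta <- gWy / gWg
  se <- sqrt(1 / gWg)
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  meta <- genotypes$snp_meta[!mono, , drop = FALSE]
  assoc <- data.frame(chrom = meta$chrom, id = meta$id, pos = meta$pos,
                      ref = meta$ref, alt = meta$alt, af = af[!mono],
                      beta = beta, se = se, p_value = p,
                      stringsAsFactors = FALSE)
  skipped <- data.frame(id = genotypes$snp_meta$id[mono],
                        reason = rep("monomorphic", sum(mono)),
                        stringsAsFactors = FALSE)
  list(assoc = assoc, skipped = skipped, null_model = null_fit)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error level in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return alpha / n_tests.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Benjamini-Hochberg FDR selection
#'
#' Step-up selection at level `q` plus monotone BH-adjusted p-values
#' (via [stats::p.adjust()]).
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param q FDR level.
#' @return data.frame `p`, `p_adjusted`, `selected` in input order; empty
#'   input gives an empty frame.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0)
    return(data.frame(p = numeric(0), p_adjusted = numeric(0),
                      selected = logical(0)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  adj <- stats::p.adjust(p_values, method = "BH")
  o <- order(p_values)
  ok <- which(p_values[o] <= q * seq_len(m) / m)
  sel <- logical(m)
  if (length(ok)) sel[o[seq_len(max(ok))]] <- TRUE
  data.frame(p = p_values, p_adjusted = adj, selected = sel)
}
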