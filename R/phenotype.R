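#' Simulate phenotypes under the variance-component model
#'
#' Two generators for a quantitative trait with additive genetic signal of
#' known heritability:
#' \describe{
#'   \item{covariance}{draws \eqn{y \sim N(\mu, \Sigma)} with
#'     \eqn{\Sigma = K h^2 + I (1 - h^2)} and \eqn{\mu = X\beta} over
#'     \code{n_causal} randomly chosen (centered) causal SNP dosages, with
#'     \eqn{\beta \sim N(\code{beta_mean}, \code{beta_var})}. This is the
#'     classical sensitivity-simulation design; note its realized
#'     heritability is only approximately \code{h2_true} because the causal
#'     mean term adds genetic variance on top of \eqn{\Sigma}.}
#'   \item{causal}{builds \eqn{y = g + e} where \eqn{g = X_c \beta} over the
#'     causal SNPs and both parts are rescaled so the sample genetic variance
#'     fraction equals \code{h2_true} exactly; preferred for
#'     parameter-recovery experiments.}
#' }
#' When covariates are supplied, fixed effects with standard-normal-scaled
#' coefficients are added on top (they are adjusted out again in REML).
#'
#' @param K a `grm` object or symmetric matrix (required for covariance
#'   mode).
#' @param covariates optional covariate data.frame; its design columns get
#'   nuisance fixed effects.
#' @param h2_true target heritability in \[0, 1\].
#' @param mode "covariance" or "causal".
#' @param n_causal number of causal SNPs (0 = no causal mean term).
#' @param beta_mean,beta_var causal effect-size distribution (mean,
#'   variance).
#' @param genotypes a `genotype_matrix` (required when n_causal > 0 or
#'   mode = "causal").
#' @param seed integer seed.
#' @return data.frame with columns `individual_id` and `trait`.
#' @export
simulate_phenotype <- function(K = NULL, covariates = NULL, h2_true,
                               mode = c("causal", "covariance"),
                               n_causal = 500, beta_mean = -0.5,
                               beta_var = 0.5, genotypes = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (h2_true < 0 || h2_true > 1) stop("h2_true must be in [0, 1]")
  set.seed(seed)
  Km <- if (inherits(K, "grm")) K$K else K
  if (mode == "covariance") {
    if (is.null(Km)) stop("covariance mode requires K")
    if (!isTRUE(all.equal(Km, t(Km), tolerance = 1e-8)))
      stop("K must be symmetric")
  }
  if ((mode == "causal" || n_causal > 0) && is.null(genotypes))
    stop("causal SNPs requested but no genotypes supplied")

  n <- if (!is.null(Km)) nrow(Km) else nrow(genotypes$dosage)
  ids <- if (!is.null(Km) && !is.null(rownames(Km))) rownames(Km)
         else rownames(genotypes$dosage)
  if (is.null(ids)) ids <- sprintf("ind%d", seq_len(n))

  g_mean <- numeric(n)
  if (n_causal > 0) {
    G <- genotypes$dosage
    if (n_causal > ncol(G)) stop("n_causal exceeds number of SNPs")
    causal <- sample(ncol(G), n_causal)
    Xc <- scale(G[, causal, drop = FALSE], center = TRUE, scale = FALSE)
    Xc[is.na(Xc)] <- 0
    beta <- stats::rnorm(n_causal, beta_mean, sqrt(beta_var))
    g_mean <- drop(Xc %*% beta)
  }

  if (mode == "covariance") {
    Sigma <- h2_true * Km + (1 - h2_true) * diag(n)
    e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
    L <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
    y <- g_mean + drop(L %*% stats::rnorm(n))
  } else {
    g <- g_mean
    sg <- stats::sd(g)
    g <- if (sg > 0) (g - mean(g)) / sg * sqrt(h2_true) else numeric(n)
    eps <- stats::rnorm(n)
    eps <- (eps - mean(eps)) / stats::sd(eps) * sqrt(1 - h2_true)
    y <- g + eps
  }

  if (!is.null(covariates)) {
    Xf <- covariate_design(covariates)
    Xs <- scale(Xf[, -1, drop = FALSE])   # drop intercept, standardize
    bf <- stats::rnorm(ncol(Xs), 0, 0.3)
    y <- y + drop(Xs %*% bf)
  }
  data.frame(individual_id = ids, trait = y, stringsAsFactors = FALSE)
}
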