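blockmat <- function(A11, A12, A21, A22) {
  rbind(cbind(A11, A12), cbind(A21, A22))
}

#' Bivariate GREML: genetic correlation between two traits
#'
#' Stacked two-trait AI-REML with genetic (co)variances
#' \eqn{\sigma_{g1}^2, \sigma_{g2}^2, \sigma_{g12}} structured by a shared
#' GRM and residual (co)variances on the identity; the genetic correlation
#' is \eqn{r_g = \sigma_{g12} / \sqrt{\sigma_{g1}^2 \sigma_{g2}^2}},
#' constrained to \[-1, 1\]. The p-value is a 1-df likelihood-ratio test of
#' \eqn{\sigma_{g12} = 0}.
#'
#' @param y1,y2 trait vectors on the same individuals.
#' @param covariates covariate data.frame or NULL (intercept only).
#' @param K a `grm` object or symmetric matrix.
#' @param X optional explicit per-trait design matrix.
#' @param max_iter,tol iteration controls.
#' @return object of class `greml_bivariate` with the six variance
#'   components, `rg`, `se_rg`, `p_value`, `converged`. `rg` is `NA` when
#'   either trait's genetic variance sits at its lower bound.
#' @export
reml_bivariate <- function(y1, y2, covariates = NULL, K = NULL, X = NULL,
                           max_iter = 100, tol = 1e-8) {
  n <- length(y1)
  if (length(y2) != n) stop("traits must cover the same individuals")
  Km <- if (inherits(K, "grm")) K$K else K
  stopifnot(nrow(Km) == n)
  if (is.null(X)) {
    X <- if (is.null(covariates)) matrix(1, n, 1)
         else covariate_design(covariates)
  }
  X2 <- blockmat(X, matrix(0, n, ncol(X)), matrix(0, n, ncol(X)), X)
  I <- diag(n); Z <- matrix(0, n, n)
  Vlist <- list(
    g1  = blockmat(Km, Z, Z, Z),
    g2  = blockmat(Z, Z, Z, Km),
    g12 = blockmat(Z, Km, Km, Z),
    e1  = blockmat(I, Z, Z, Z),
    e2  = blockmat(Z, Z, Z, I),
    e12 = blockmat(Z, I, I, Z))
  var_idx <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  cov_pairs <- list(c(3L, 1L, 2L), c(6L, 4L, 5L))
  y <- c(y1, y2)
  v1 <- stats::var(y1); v2 <- stats::var(y2)
  c12 <- stats::cov(y1, y2)
  # split the phenotypic covariance evenly across the genetic and residual
  # covariance terms so the initial V is non-degenerate for collinear traits
  init <- c(v1 / 2, v2 / 2, c12 / 4, v1 / 2, v2 / 2, c12 / 4)
  fit <- aireml_fit(y, X2, Vlist, init = init, var_idx = var_idx,
                    cov_pairs = cov_pairs, max_iter = max_iter, tol = tol)
  th <- fit$theta
  floor_val <- 1e-6 * stats::var(y)
  boundary <- th[1] <= floor_val * (1 + 1e-9) || th[2] <= floor_val * (1 + 1e-9)
  rg <- if (boundary) NA_real_ else
    max(-1, min(1, th[3] / sqrt(th[1] * th[2])))
  se_rg <- NA_real_
  if (!boundary && all(is.finite(fit$cov_theta[1:3, 1:3]))) {
    r <- th[3] / sqrt(th[1] * th[2])
    grad <- c(-r / (2 * th[1]), -r / (2 * th[2]), 1 / sqrt(th[1] * th[2]))
    se_rg <- sqrt(max(0, drop(t(grad) %*% fit$cov_theta[1:3, 1:3] %*% grad)))
  }
  null <- aireml_fit(y, X2, Vlist, init = replace(init, 3, 0),
                     var_idx = var_idx, cov_pairs = cov_pairs,
                     fixed = 3L, max_iter = max_iter, tol = tol)
  lrt <- max(0, 2 * (fit$loglik - null$loglik))
  p_value <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(sigma_g1 = th[1], sigma_g2 = th[2], sigma_g12 = th[3],
                 sigma_e1 = th[4], sigma_e2 = th[5], sigma_e12 = th[6],
                 rg = rg, se_rg = se_rg, p_value = p_value,
                 loglik = fit$loglik, converged = fit$converged,
                 n_iterations = fit$n_iterations, n = n),
            class = "greml_bivariate")
}

#' @export
#' @method print greml_bivariate
print.greml_bivariate <- function(x, ...) {
  cat("Bivariate GREML (AI-REML)\n")
  cat(sprintf("  n = %d, converged = %s\n", x$n, x$converged))
  cat(sprintf("  genetic: var1 = %.4f, var2 = %.4f, cov = %.4f\n",
              x$sigma_g1, x$sigma_g2, x$sigma_g12))
  cat(sprintf("  rg = %s (SE %s), LRT p = %.3g\n",
              format(x$rg, digits = 4), format(x$se_rg, digits = 3),
              x$p_value))
  invisible(x)
}

#' Repeated-measures pedigree heritability model
#'
#' Two scans per subject, stacked. The subject-level random effect is split
#' into a genetic part with pedigree covariance \eqn{K_{ped}\sigma_g^2} and
#' a common-subject (environmental) part \eqn{I\sigma_c^2}, both shared
#' across scans; a scan-level residual \eqn{\sigma_e^2} captures
#' intra-subject variation. Heritability is
#' \eqn{h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_c^2 + \sigma_e^2)}.
#'
#' @param y_scan1,y_scan2 trait vectors, both scans observed for every
#'   subject.
#' @param covariates covariate data.frame or NULL.
#' @param K_ped pedigree-based `grm` (see [pedigree_grm()]).
#' @param max_iter,tol iteration controls.
#' @return object of class `greml` (with an extra `sigma_c2` field).
#' @export
reml_repeated <- function(y_scan1, y_scan2 = NULL, covariates = NULL,
                          K_ped = NULL, max_iter = 100, tol = 1e-8) {
  if (is.null(y_scan2))
    stop("single-scan input: use reml_univariate")
  n <- length(y_scan1)
  if (length(y_scan2) != n) stop("both scans must cover every subject")
  Km <- if (inherits(K_ped, "grm")) K_ped$K else K_ped
  stopifnot(nrow(Km) == n)
  X <- if (is.null(covariates)) matrix(1, n, 1)
       else covariate_design(covariates)
  X2 <- rbind(X, X)
  I <- diag(n)
  Vlist <- list(
    g = blockmat(Km, Km, Km, Km),
    c = blockmat(I, I, I, I),
    e = diag(2 * n))
  y <- c(y_scan1, y_scan2)
  v0 <- stats::var(y)
  fit <- aireml_fit(y, X2, Vlist, init = c(v0 / 3, v0 / 3, v0 / 3),
                    max_iter = max_iter, tol = tol)
  th <- fit$theta
  tot <- sum(th)
  h2 <- th[1] / tot
  grad <- c(tot - th[1], -th[1], -th[1]) / tot^2
  se_h2 <- if (all(is.finite(fit$cov_theta)))
    sqrt(max(0, drop(t(grad) %*% fit$cov_theta %*% grad))) else NA_real_
  null <- aireml_fit(y, X2, Vlist, init = c(0, v0 / 2, v0 / 2),
                     fixed = 1L, max_iter = max_iter, tol = tol)
  lrt <- max(0, 2 * (fit$loglik - null$loglik))
  p_value <- if (lrt == 0) 0.5 else
    0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(sigma_g2 = th[1], sigma_c2 = th[2], sigma_e2 = th[3],
                 h2 = h2, se_h2 = se_h2, loglik = fit$loglik, lrt = lrt,
                 p_value = p_value, n_iterations = fit$n_iterations,
                 converged = fit$converged, beta = fit$beta,
                 coef_names = colnames(X), n = n),
            class = c("greml_repeated", "greml"))
}

#' @export
#' @method print greml_repeated
print.greml_repeated <- function(x, ...) {
  cat("Repeated-measures pedigree REML\n")
  cat(sprintf("  n = %d subjects x 2 scans, converged = %s\n",
              x$n, x$converged))
  cat(sprintf("  sigma_g2 = %.4f, sigma_c2 = %.4f, sigma_e2 = %.4f\n",
              x$sigma_g2, x$sigma_c2, x$sigma_e2))
  cat(sprintf("  h2 = %.4f (SE %.4f), LRT p = %.3g\n",
              x$h2, x$se_h2, x$p_value))
  invisible(x)
}
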