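# ---------------------------------------------------------------------------
# AI-REML core.  V(theta) = sum_i theta_i V_i with X fixed effects.
# Two backends share the same update loop: "dense" takes a list of n x n
# matrices; "diag" takes a list of length-n vectors (used after rotating the
# univariate model onto the GRM eigenbasis, where every V_i is diagonal).
# ---------------------------------------------------------------------------

# restricted log-likelihood and derivative ingredients at theta
aireml_eval <- function(theta, y, X, Vlist, diag_backend) {
  n <- length(y); p <- ncol(X)
  if (diag_backend) {
    d <- numeric(n)
    for (i in seq_along(theta)) d <- d + theta[i] * Vlist[[i]]
    if (any(d <= 0)) return(NULL)
    Vinv_y <- y / d
    Vinv_X <- X / d
    XtVX <- crossprod(X, Vinv_X)
    R <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    XtVy <- crossprod(X, Vinv_y)
    beta <- backsolve(R, backsolve(R, XtVy, transpose = TRUE))
    Py <- Vinv_y - Vinv_X %*% beta
    ll <- -0.5 * (sum(log(d)) + 2 * sum(log(diag(R))) + sum(y * Py))
    list(ll = as.numeric(ll), Py = drop(Py), d = d, Vinv_X = Vinv_X,
         R = R, beta = drop(beta))
  } else {
    V <- matrix(0, n, n)
    for (i in seq_along(theta)) V <- V + theta[i] * Vlist[[i]]
    C <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(C)) return(NULL)
    Vinv <- chol2inv(C)
    Vinv_X <- Vinv %*% X
    XtVX <- crossprod(X, Vinv_X)
    R <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    XtVXinv <- chol2inv(R)
    P <- Vinv - Vinv_X %*% XtVXinv %*% t(Vinv_X)
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(C))) + 2 * sum(log(diag(R))) +
                    sum(y * Py))
    beta <- drop(XtVXinv %*% crossprod(X, Vinv %*% y))
    list(ll = as.numeric(ll), Py = Py, P = P, beta = beta)
  }
}

# gradient and average-information matrix at an evaluated point
aireml_grad_ai <- function(ev, y, X, Vlist, diag_backend) {
  k <- length(Vlist)
  dL <- numeric(k)
  Ts <- vector("list", k)               # T_i = V_i P y
  if (diag_backend) {
    XtVXinv_Xt <- function(v) {          # returns P v for diagonal backend
      u <- v / ev$d
      u - (X / ev$d) %*% backsolve(ev$R, backsolve(ev$R, crossprod(X, u),
                                                   transpose = TRUE))
    }
    # tr(P V_i) = tr(Vinv V_i) - tr((X'VinvX)^-1 X' Vinv V_i Vinv X)
    for (i in seq_len(k)) {
      vi <- Vlist[[i]]
      Ts[[i]] <- vi * ev$Py
      A <- crossprod(X, (vi / ev$d) * ev$Vinv_X)   # X' Vinv V_i Vinv X
      trPVi <- sum(vi / ev$d) -
        sum(diag(backsolve(ev$R, backsolve(ev$R, A, transpose = TRUE))))
      dL[i] <- -0.5 * (trPVi - sum(ev$Py * Ts[[i]]))
    }
    AI <- matrix(0, k, k)
    PT <- lapply(Ts, XtVXinv_Xt)
    for (i in seq_len(k)) for (j in i:k) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(Ts[[i]] * PT[[j]])
    }
  } else {
    for (i in seq_len(k)) {
      Ts[[i]] <- drop(Vlist[[i]] %*% ev$Py)
      trPVi <- sum(ev$P * Vlist[[i]])
      dL[i] <- -0.5 * (trPVi - sum(ev$Py * Ts[[i]]))
    }
    AI <- matrix(0, k, k)
    PT <- lapply(Ts, function(t) drop(ev$P %*% t))
    for (i in seq_len(k)) for (j in i:k) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(Ts[[i]] * PT[[j]])
    }
  }
  list(dL = dL, AI = AI)
}

# constraint projection: variances floored, covariances clamped so each
# implied correlation stays inside (-1, 1)
aireml_project <- function(theta, var_idx, cov_pairs, floor_val) {
  theta[var_idx] <- pmax(theta[var_idx], floor_val)
  for (cp in cov_pairs) {
    i <- cp[1]; a <- cp[2]; b <- cp[3]
    lim <- 0.9999 * sqrt(theta[a] * theta[b])
    theta[i] <- max(-lim, min(lim, theta[i]))
  }
  theta
}

#' @keywords internal
aireml_fit <- function(y, X, Vlist, init, var_idx = NULL, cov_pairs = list(),
                       fixed = integer(0), diag_backend = FALSE,
                       max_iter = 100, tol = 1e-8, floor_frac = 1e-6) {
  k <- length(Vlist)
  if (is.null(var_idx)) var_idx <- rep(TRUE, k)
  floor_val <- floor_frac * stats::var(y)
  free <- setdiff(seq_len(k), fixed)
  theta <- aireml_project(init, var_idx & !(seq_len(k) %in% fixed),
                          cov_pairs, floor_val)
  ev <- aireml_eval(theta, y, X, Vlist, diag_backend)
  if (is.null(ev)) stop("initial variance structure is not positive definite")
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    ga <- aireml_grad_ai(ev, y, X, Vlist, diag_backend)
    dL <- ga$dL[free]
    AI <- ga$AI[free, free, drop = FALSE]
    delta <- tryCatch(solve(AI + diag(1e-10, length(free)), dL),
                      error = function(e) NULL)
    if (is.null(delta)) delta <- dL / max(1, sqrt(sum(dL^2)))
    try_direction <- function(dir) {
      step <- 1
      for (h in 1:25) {
        cand <- theta
        cand[free] <- theta[free] + step * dir
        cand <- aireml_project(cand, var_idx & !(seq_len(k) %in% fixed),
                               cov_pairs, floor_val)
        ev_new <- aireml_eval(cand, y, X, Vlist, diag_backend)
        if (!is.null(ev_new) && ev_new$ll >= ev$ll - 1e-12)
          return(list(cand = cand, ev = ev_new))
        step <- step / 2
      }
      NULL
    }
    got <- try_direction(delta)
    if (is.null(got))                      # AI direction failed: gradient step
      got <- try_direction(dL * max(abs(theta[free])) /
                             max(abs(dL), 1e-12))
    if (is.null(got)) { converged <- TRUE; break }  # no uphill move left
    cand <- got$cand; ev_new <- got$ev
    d_ll <- ev_new$ll - ev$ll
    d_th <- max(abs(cand - theta))
    theta <- cand; ev <- ev_new
    if (d_ll < tol && d_th < tol * max(1, max(abs(theta)))) {
      converged <- TRUE; break
    }
  }
  ga <- aireml_grad_ai(ev, y, X, Vlist, diag_backend)
  AIinv <- tryCatch(solve(ga$AI[free, free, drop = FALSE]),
                    error = function(e)
                      matrix(NA_real_, length(free), length(free)))
  cov_theta <- matrix(NA_real_, k, k)
  cov_theta[free, free] <- AIinv
  list(theta = theta, loglik = ev$ll, cov_theta = cov_theta, beta = ev$beta,
       converged = converged, n_iterations = it, at_floor =
         var_idx & abs(theta - floor_val) < 1e-12)
}

# ---------------------------------------------------------------------------

#' Eigendecompose a GRM for repeated REML fits
#'
#' @param K a `grm` object or symmetric matrix.
#' @return list with `values`, `vectors`, `ids` — pass as `K_eigen` to
#'   [greml()] / [lmm_gwas()] to amortize the decomposition.
#' @export
grm_eigen <- function(K) {
  Km <- if (inherits(K, "grm")) K$K else K
  e <- eigen((Km + t(Km)) / 2, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, ids = rownames(Km))
}

#' Univariate GREML: SNP heritability by AI-REML
#'
#' Fits \eqn{y = X\beta + u + e}, \eqn{u \sim N(0, K\sigma_g^2)},
#' \eqn{e \sim N(0, I\sigma_e^2)} by average-information REML, rotated onto
#' the eigenbasis of K so every iteration is linear in n. Reports
#' \eqn{h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)}, its delta-method
#' standard error from the inverse average-information matrix, and a
#' likelihood-ratio p-value for \eqn{\sigma_g^2 = 0} using the boundary
#' \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1} mixture.
#'
#' @param y numeric trait vector (n >= 30).
#' @param K a `grm` object or symmetric matrix (ignored when `K_eigen`
#'   given).
#' @param covariates covariate data.frame (see [covariate_design()]), or a
#'   ready design matrix via `X`, or NULL for intercept only.
#' @param X optional explicit fixed-effect design matrix (overrides
#'   `covariates`).
#' @param pcs optional genetic PC matrix appended to the design.
#' @param K_eigen optional precomputed [grm_eigen()] result.
#' @param max_iter,tol AI-REML iteration controls.
#' @param min_n smallest cohort the fit will accept (variance components
#'   are poorly identified below a few dozen individuals).
#' @return an object of class `greml`.
#' @export
greml <- function(y, K = NULL, covariates = NULL, X = NULL, pcs = NULL,
                  K_eigen = NULL, max_iter = 100, tol = 1e-8, min_n = 30) {
  if (is.null(K_eigen)) {
    if (is.null(K)) stop("supply K or K_eigen")
    K_eigen <- grm_eigen(K)
  }
  n <- length(y)
  if (n < min_n) stop("need at least ", min_n, " individuals for REML")
  if (is.null(X)) {
    X <- if (is.null(covariates)) matrix(1, n, 1,
                                         dimnames = list(NULL, "intercept"))
         else covariate_design(covariates, pcs = pcs)
  }
  stopifnot(nrow(X) == n, length(K_eigen$values) == n)
  lam <- pmax(K_eigen$values, 0)
  if (max(lam) - min(lam) < 1e-10)
    stop("components not identifiable: K is proportional to the identity")
  U <- K_eigen$vectors
  ty <- drop(crossprod(U, y))
  tX <- crossprod(U, X)

  v0 <- stats::var(y)
  init <- c(g = v0 / 2, e = v0 / 2)
  fit <- aireml_fit(ty, tX, list(lam, rep(1, n)), init = init,
                    diag_backend = TRUE, max_iter = max_iter, tol = tol)
  sg <- fit$theta[1]; se2 <- fit$theta[2]
  h2 <- sg / (sg + se2)
  grad <- c(se2, -sg) / (sg + se2)^2
  se_h2 <- sqrt(max(0, drop(t(grad) %*% fit$cov_theta %*% grad)))

  # null model sigma_g2 = 0: closed-form REML on the original scale
  qrX <- qr(X)
  res <- qr.resid(qrX, y)
  p <- ncol(X)
  s2 <- sum(res^2) / (n - p)
  R <- qr.R(qrX)
  ll0 <- -0.5 * (n * log(s2) + sum(res^2) / s2 +
                   2 * sum(log(abs(diag(R)))) - p * log(s2))
  lrt <- max(0, 2 * (fit$loglik - ll0))
  p_value <- if (lrt == 0) 0.5 else
    0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  structure(list(sigma_g2 = sg, sigma_e2 = se2, h2 = h2, se_h2 = se_h2,
                 loglik = fit$loglik, loglik_null = ll0, lrt = lrt,
                 p_value = p_value, n_iterations = fit$n_iterations,
                 converged = fit$converged, beta = fit$beta,
                 coef_names = colnames(X), n = n),
            class = "greml")
}

#' @rdname greml
#' @param ... passed to [greml()].
#' @export
reml_univariate <- function(y, covariates = NULL, K = NULL, ...) {
  greml(y, K = K, covariates = covariates, ...)
}

#' @export
#' @method print greml
print.greml <- function(x, ...) {
  cat("Univariate GREML (AI-REML)\n")
  cat(sprintf("  n = %d, iterations = %d, converged = %s\n",
              x$n, x$n_iterations, x$converged))
  cat(sprintf("  sigma_g2 = %.4f, sigma_e2 = %.4f\n",
              x$sigma_g2, x$sigma_e2))
  cat(sprintf("  h2 = %.4f (SE %.4f), LRT p = %.3g\n",
              x$h2, x$se_h2, x$p_value))
  invisible(x)
}

#' @export
summary.greml <- function(object, ...) {
  vc <- data.frame(
    component = c("genetic", "residual"),
    variance = c(object$sigma_g2, object$sigma_e2))
  out <- list(varcomp = vc, h2 = object$h2, se_h2 = object$se_h2,
              p_value = object$p_value, loglik = object$loglik,
              converged = object$converged,
              fixed = stats::setNames(object$beta, object$coef_names))
  class(out) <- "summary.greml"
  out
}

#' @export
#' @method print summary.greml
print.summary.greml <- function(x, ...) {
  cat("Variance components:\n")
  print(x$varcomp, row.names = FALSE)
  cat(sprintf("h2 = %.4f (SE %.4f), boundary-LRT p = %.3g, logLik = %.3f\n",
              x$h2, x$se_h2, x$p_value, x$loglik))
  cat("Fixed effects:\n")
  print(round(x$fixed, 4))
  invisible(x)
}

#' @export
coef.greml <- function(object, ...) {
  stats::setNames(object$beta, object$coef_names)
}

#' @export
logLik.greml <- function(object, ...) {
  structure(object$loglik, df = 2, class = "logLik")
}

#' @export
confint.greml <- function(object, parm = "h2", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- max(0, object$h2 - z * object$se_h2)
  hi <- min(1, object$h2 + z * object$se_h2)
  matrix(c(lo, hi), 1, 2,
         dimnames = list("h2", sprintf("%g %%", c((1 - level) / 2,
                                                  1 - (1 - level) / 2) * 100)))
}
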