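# dense restricted log-likelihood, written independently of the package path
reml_ll <- function(sg, se, y, X, Km) {
  n <- length(y)
  V <- sg * Km + se * diag(n)
  C <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(C)) return(-Inf)
  Vi <- chol2inv(C)
  XtVX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtVX) %*% t(X) %*% Vi
  -0.5 * (2 * sum(log(diag(C))) + determinant(XtVX)$modulus[1] +
            drop(t(y) %*% P %*% y))
}

test_that("AI-REML agrees with a restricted-likelihood grid/optim oracle", {
  co <- make_cohort(n_mz = 3, n_dz = 2, n_fs = 3, n_single = 4,
                    n_snps = 250, seed = 81)   # 20 analysis individuals
  y <- mvn_trait(co$K, 0.5, seed = 82)
  X <- matrix(1, co$n, 1)
  fit <- greml(y, K = co$K, X = X, min_n = 20)
  # coarse grid then local refinement
  gr <- expand.grid(sg = seq(0.02, 2, length.out = 40),
                    se = seq(0.02, 2, length.out = 40))
  vals <- mapply(reml_ll, gr$sg, gr$se,
                 MoreArgs = list(y = y, X = X, Km = co$K$K))
  st <- as.numeric(gr[which.max(vals), ])
  opt <- optim(st, function(p) -reml_ll(p[1], p[2], y, X, co$K$K),
               method = "L-BFGS-B", lower = 1e-6)
  expect_lt(abs(-opt$value - fit$loglik), 1e-6)
  expect_true(fit$converged)
  # h2 identity
  expect_equal(fit$h2, fit$sigma_g2 / (fit$sigma_g2 + fit$sigma_e2))
})

test_that("REML estimates are invariant to trait shift and covariate reparameterization", {
  co <- make_cohort(n_snps = 300, seed = 83)
  cov <- simulate_covariates(co$ped, seed = 84)
  y <- mvn_trait(co$K, 0.4, seed = 85)
  Ke <- grm_eigen(co$K)
  X <- covariate_design(cov)
  f1 <- greml(y, K_eigen = Ke, X = X)
  f2 <- greml(y + 100, K_eigen = Ke, X = X)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-6)
  expect_equal(f1$sigma_g2, f2$sigma_g2, tolerance = 1e-6)
  # invertible reparameterization of the design
  A <- diag(ncol(X)); A[1, 2] <- 0.5; A[3, 4] <- -2
  f3 <- greml(y, K_eigen = Ke, X = X %*% A)
  expect_equal(f1$loglik, f3$loglik, tolerance = 1e-6)
  expect_equal(f1$h2, f3$h2, tolerance = 1e-4)
})

test_that("boundary LRT is calibrated under the null and greml methods work", {
  co <- make_cohort(n_mz = 20, n_dz = 10, n_fs = 15, n_single = 20,
                    n_snps = 400, seed = 86)
  Ke <- grm_eigen(co$K)
  n_rep <- 200
  rej <- vapply(seq_len(n_rep), function(r) {
    set.seed(8600 + r)
    y <- rnorm(co$n)                      # sigma_g2 = 0 truth
    fit <- greml(y, K_eigen = Ke, X = matrix(1, co$n, 1))
    fit$lrt > qchisq(0.90, df = 1)       # 5% point of the 50:50 mixture
  }, TRUE)
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)

  # S3 surface of the fitted object
  y <- mvn_trait(co$K, 0.4, seed = 87)
  fit <- greml(y, K_eigen = Ke, X = matrix(1, co$n, 1,
                                           dimnames = list(NULL, "mu")))
  expect_s3_class(fit, "greml")
  expect_output(print(fit), "h2")
  expect_named(coef(fit), "mu")
  expect_s3_class(summary(fit), "summary.greml")
  ci <- confint(fit)
  expect_true(ci[1] >= 0 && ci[2] <= 1 && ci[1] <= fit$h2 &&
                fit$h2 <= ci[2])
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_error(greml(y, K = diag(co$n), X = matrix(1, co$n, 1)),
               "identifiable")
})

test_that("bivariate GREML recovers genetic correlations", {
  co <- make_cohort(n_mz = 10, n_dz = 8, n_fs = 10, n_single = 14,
                    n_snps = 300, seed = 88)
  Km <- co$K$K; n <- co$n
  e <- eigen(Km, symmetric = TRUE)
  sq <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  # identical traits: rg at the +1 constraint boundary
  y <- mvn_trait(co$K, 0.5, seed = 89)
  expect_equal(reml_bivariate(y, y, K = co$K)$rg, 1, tolerance = 0.01)

  # shared-architecture traits: target rg = 0.5
  target <- 0.5
  rgs <- vapply(1:8, function(r) {
    set.seed(900 + r)
    gs <- drop(sq %*% rnorm(n)); g1 <- drop(sq %*% rnorm(n))
    g2 <- drop(sq %*% rnorm(n))
    a <- sqrt(target)
    u1 <- a * gs + sqrt(1 - a^2) * g1
    u2 <- a * gs + sqrt(1 - a^2) * g2
    y1 <- sqrt(0.6) * u1 + sqrt(0.4) * rnorm(n)
    y2 <- sqrt(0.6) * u2 + sqrt(0.4) * rnorm(n)
    reml_bivariate(y1, y2, K = co$K)$rg
  }, 0)
  expect_lt(abs(mean(rgs) - target), 0.15)

  # disjoint genetic architectures: rg near 0
  rg0 <- vapply(1:8, function(r) {
    set.seed(950 + r)
    y1 <- drop(sq %*% rnorm(n)) * sqrt(0.6) + rnorm(n) * sqrt(0.4)
    y2 <- drop(sq %*% rnorm(n)) * sqrt(0.6) + rnorm(n) * sqrt(0.4)
    reml_bivariate(y1, y2, K = co$K)$rg
  }, 0)
  expect_lt(abs(mean(rg0, na.rm = TRUE)), 0.15)
  expect_error(reml_bivariate(rnorm(10), rnorm(9), K = diag(10)),
               "same individuals")
})

test_that("repeated-measures model separates intra- from inter-subject variation", {
  ped <- generate_pedigree(25, 15, 20, 25, seed = 91)
  Kp <- pedigree_grm(ped)
  n <- length(Kp$ids)
  e <- eigen(Kp$K, symmetric = TRUE)
  sq <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))

  # scan2 == scan1: scan-level residual variance collapses
  set.seed(92)
  y <- drop(sq %*% rnorm(n)) * sqrt(0.5) + rnorm(n) * sqrt(0.5)
  same <- reml_repeated(y, y, K_ped = Kp)
  expect_lt(same$sigma_e2 / (same$sigma_g2 + same$sigma_c2 + same$sigma_e2),
            0.01)

  # known components sigma_g2 = 0.4, sigma_c2 = 0.3, sigma_e2 = 0.3
  h2s <- vapply(1:6, function(r) {
    set.seed(920 + r)
    gi <- drop(sq %*% rnorm(n))
    ci <- rnorm(n)
    s1 <- sqrt(0.4) * gi + sqrt(0.3) * ci + sqrt(0.3) * rnorm(n)
    s2 <- sqrt(0.4) * gi + sqrt(0.3) * ci + sqrt(0.3) * rnorm(n)
    reml_repeated(s1, s2, K_ped = Kp)$h2
  }, 0)
  expect_lt(abs(mean(h2s) - 0.4), 0.12)

  # repeated-model h2 tracks univariate h2 on scan means across traits
  Ks <- grm_eigen(Kp)
  hr <- hu <- numeric(8)
  for (r in 1:8) {
    set.seed(940 + r)
    h2_true <- runif(1, 0.1, 0.7)
    gi <- drop(sq %*% rnorm(n))
    s1 <- sqrt(h2_true) * gi + sqrt(1 - h2_true) * rnorm(n)
    s2 <- sqrt(h2_true) * gi + sqrt(1 - h2_true) * rnorm(n)
    hr[r] <- reml_repeated(s1, s2, K_ped = Kp)$h2
    hu[r] <- greml((s1 + s2) / 2, K_eigen = Ks,
                   X = matrix(1, n, 1))$h2
  }
  expect_gt(cor(hr, hu), 0.5)
  expect_error(reml_repeated(y, NULL, K_ped = Kp), "reml_univariate")
})
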