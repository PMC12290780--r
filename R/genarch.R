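#' Pairwise genetic-correlation matrix across coupling vertices
#'
#' Runs [reml_bivariate()] for every unordered pair of the selected
#' coupling traits and applies Benjamini-Hochberg FDR flags to the pair
#' p-values. Pairs whose genetic variances hit the lower bound get an
#' undefined (`NA`) entry.
#'
#' @param traits numeric matrix, individuals x selected vertices (e.g.
#'   columns of a `coupling_matrix`), with column names.
#' @param covariates covariate data.frame or NULL.
#' @param K a `grm` object or matrix.
#' @param fdr_q FDR level for the flags (default 0.05).
#' @return an `rg_matrix` list: `rg`, `se`, `p` (symmetric matrices, unit
#'   diagonal for `rg`), `fdr_flag` (logical matrix), `pairs` (long-format
#'   data.frame).
#' @export
pairwise_rg <- function(traits, covariates = NULL, K, fdr_q = 0.05) {
  m <- ncol(traits)
  if (m < 2) stop("need at least 2 selected vertices")
  nms <- colnames(traits)
  if (is.null(nms)) nms <- sprintf("trait%d", seq_len(m))
  rg <- diag(1, m); se <- matrix(NA_real_, m, m); p <- matrix(NA_real_, m, m)
  dimnames(rg) <- dimnames(se) <- dimnames(p) <- list(nms, nms)
  long <- list()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    fit <- reml_bivariate(traits[, i], traits[, j], covariates = covariates,
                          K = K)
    rg[i, j] <- rg[j, i] <- fit$rg
    se[i, j] <- se[j, i] <- fit$se_rg
    p[i, j] <- p[j, i] <- fit$p_value
    long[[length(long) + 1]] <-
      data.frame(vertex_a = nms[i], vertex_b = nms[j], rg = fit$rg,
                 se = fit$se_rg, p = fit$p_value, stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, long)
  sel <- bh_fdr(long$p, q = fdr_q)
  long$fdr_flag <- sel$selected
  flag <- matrix(FALSE, m, m, dimnames = list(nms, nms))
  for (r in seq_len(nrow(long))) {
    i <- match(long$vertex_a[r], nms); j <- match(long$vertex_b[r], nms)
    flag[i, j] <- flag[j, i] <- long$fdr_flag[r]
  }
  structure(list(rg = rg, se = se, p = p, fdr_flag = flag, pairs = long,
                 fdr_q = fdr_q),
            class = "rg_matrix")
}

#' @export
#' @method print rg_matrix
print.rg_matrix <- function(x, ...) {
  cat(sprintf("rg_matrix: %d traits, %d pairs, %d FDR-significant at q = %g\n",
              nrow(x$rg), nrow(x$pairs), sum(x$pairs$fdr_flag), x$fdr_q))
  invisible(x)
}

#' Distance decay of genetic correlation
#'
#' Least-squares linear (rg ~ d) and quadratic (rg ~ d + d^2) fits to
#' genetic correlation as a function of inter-vertex Euclidean distance,
#' compared by the nested F-test. Pairs with undefined rg are dropped
#' listwise.
#'
#' @param rg_values numeric vector of genetic correlations.
#' @param distances numeric vector of matching distances.
#' @param hemisphere optional label stored on the fit.
#' @return a `distance_decay_fit` list: `linear`, `quadratic` (lm fits),
#'   `rss_linear`, `rss_quadratic`, `rss_difference`, `f_statistic`,
#'   `df`, `p_value`, `n`.
#' @export
fit_distance_decay <- function(rg_values, distances, hemisphere = NA) {
  ok <- is.finite(rg_values) & is.finite(distances)
  rg <- rg_values[ok]; d <- distances[ok]
  if (length(rg) < 4) stop("need at least 4 complete pairs")
  if (stats::sd(d) == 0) stop("collinear distances")
  dat <- data.frame(rg = rg, d = d, d2 = d^2)
  lin <- stats::lm(rg ~ d, data = dat)
  quad <- stats::lm(rg ~ d + d2, data = dat)
  rss_l <- sum(stats::residuals(lin)^2)
  rss_q <- sum(stats::residuals(quad)^2)
  cmp <- stats::anova(lin, quad)
  structure(list(hemisphere = hemisphere, linear = lin, quadratic = quad,
                 rss_linear = rss_l, rss_quadratic = rss_q,
                 rss_difference = rss_l - rss_q,
                 f_statistic = cmp$F[2], df = unname(cmp$Df[2]),
                 p_value = cmp$`Pr(>F)`[2], n = length(rg)),
            class = "distance_decay_fit")
}

#' @export
#' @method print distance_decay_fit
print.distance_decay_fit <- function(x, ...) {
  cat("Distance decay of genetic correlation\n")
  cat(sprintf("  n pairs = %d, RSS linear = %.4f, RSS quadratic = %.4f\n",
              x$n, x$rss_linear, x$rss_quadratic))
  cat(sprintf("  RSS difference = %.4f, F = %.3f, p = %.4g\n",
              x$rss_difference, x$f_statistic, x$p_value))
  invisible(x)
}
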