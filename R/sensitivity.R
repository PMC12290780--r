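#' Subsample sensitivity experiment for heritability estimation
#'
#' Per replicate: draw the given proportion of individuals, rebuild the
#' GRM on the subsample, simulate a phenotype at `h2_true` (causal mode by
#' default), re-estimate heritability by AI-REML, and aggregate the mean
#' squared difference \eqn{MSD = \overline{(\hat h^2 - h^2_{true})^2}} and
#' the mean standard error across replicates per proportion.
#'
#' @param genotypes a `genotype_matrix` (post-QC).
#' @param covariates optional covariate data.frame for the cohort.
#' @param proportions subsample fractions, e.g. `seq(0.5, 0.9, 0.1)`.
#' @param h2_true true heritability.
#' @param n_causal causal SNPs per phenotype.
#' @param n_replicates replicates per grid value (default 200; the full
#'   protocol uses 4,000).
#' @param mode phenotype generator mode (see [simulate_phenotype()]).
#' @param seed integer seed.
#' @return `sensitivity_result` data.frame: `grid`, `msd`, `mean_se`,
#'   `mean_h2`, `n_replicates`, `seed`.
#' @export
subsample_experiment <- function(genotypes, covariates = NULL,
                                 proportions = seq(0.5, 0.9, by = 0.1),
                                 h2_true = 0.4, n_causal = 500,
                                 n_replicates = 200,
                                 mode = "causal", seed = 1L) {
  stopifnot(all(proportions > 0 & proportions <= 1))
  n <- nrow(genotypes$dosage)
  rows <- lapply(seq_along(proportions), function(pi) {
    prop <- proportions[pi]
    h2s <- ses <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      rep_seed <- (seed * 10007L + pi * 1009L + r) %% .Machine$integer.max
      set.seed(rep_seed)
      idx <- sort(sample(n, round(prop * n)))
      if (length(idx) < 30) stop("subsample below minimum REML size")
      sub <- new_genotype_matrix(genotypes$dosage[idx, , drop = FALSE],
                                 genotypes$snp_meta)
      poly <- {
        af <- colMeans(sub$dosage, na.rm = TRUE) / 2
        !is.na(af) & af > 0 & af < 1
      }
      sub <- new_genotype_matrix(sub$dosage[, poly, drop = FALSE],
                                 sub$snp_meta[poly, , drop = FALSE])
      K <- compute_grm(sub)
      cv <- if (is.null(covariates)) NULL else
        covariates[idx, , drop = FALSE]
      ph <- simulate_phenotype(K = K, covariates = cv, h2_true = h2_true,
                               mode = mode, n_causal = min(n_causal,
                                                           ncol(sub$dosage)),
                               genotypes = sub, seed = rep_seed + 1L)
      fit <- greml(ph$trait, K = K, covariates = cv)
      h2s[r] <- fit$h2; ses[r] <- fit$se_h2
    }
    data.frame(grid = prop, msd = mean((h2s - h2_true)^2),
               mean_se = mean(ses), mean_h2 = mean(h2s),
               n_replicates = n_replicates, seed = seed)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_result", "data.frame")
  out
}

#' Relatedness sensitivity experiment
#'
#' Starts from one individual per family (the unrelated base set) and, at
#' each grid fraction, adds that share of the remaining relatives
#' (uniformly at random, fresh per replicate) before simulating and
#' re-estimating heritability as in [subsample_experiment()].
#'
#' @param genotypes a `genotype_matrix` for the full cohort.
#' @param pedigree the matching pedigree.
#' @param covariates optional covariate data.frame.
#' @param fractions_related fractions of the relative pool to add, in
#'   \[0, 1\].
#' @param h2_true,n_causal,n_replicates,mode,seed as in
#'   [subsample_experiment()].
#' @return `sensitivity_result` data.frame as above.
#' @export
relatedness_experiment <- function(genotypes, pedigree, covariates = NULL,
                                   fractions_related = seq(0, 0.9, by = 0.3),
                                   h2_true = 0.4, n_causal = 500,
                                   n_replicates = 200, mode = "causal",
                                   seed = 1L) {
  ids <- rownames(genotypes$dosage)
  fam <- pedigree$family_id[match(ids, pedigree$individual_id)]
  if (anyNA(fam)) stop("pedigree does not cover all genotyped individuals")
  fractions_related <- pmin(fractions_related, 1)
  rows <- lapply(seq_along(fractions_related), function(fi) {
    frac <- fractions_related[fi]
    h2s <- ses <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      rep_seed <- (seed * 20011L + fi * 1013L + r) %% .Machine$integer.max
      set.seed(rep_seed)
      base <- vapply(split(seq_along(ids), fam),
                     function(ii) ii[sample.int(length(ii), 1)], 0L)
      pool <- setdiff(seq_along(ids), base)
      extra <- if (frac > 0 && length(pool))
        sample(pool, round(frac * length(pool))) else integer(0)
      idx <- sort(c(base, extra))
      if (length(idx) < 30) stop("cohort below minimum REML size")
      sub <- new_genotype_matrix(genotypes$dosage[idx, , drop = FALSE],
                                 genotypes$snp_meta)
      af <- colMeans(sub$dosage, na.rm = TRUE) / 2
      poly <- !is.na(af) & af > 0 & af < 1
      sub <- new_genotype_matrix(sub$dosage[, poly, drop = FALSE],
                                 sub$snp_meta[poly, , drop = FALSE])
      K <- compute_grm(sub)
      cv <- if (is.null(covariates)) NULL else
        covariates[idx, , drop = FALSE]
      ph <- simulate_phenotype(K = K, covariates = cv, h2_true = h2_true,
                               mode = mode,
                               n_causal = min(n_causal, ncol(sub$dosage)),
                               genotypes = sub, seed = rep_seed + 1L)
      fit <- greml(ph$trait, K = K, covariates = cv)
      h2s[r] <- fit$h2; ses[r] <- fit$se_h2
    }
    data.frame(grid = frac, msd = mean((h2s - h2_true)^2),
               mean_se = mean(ses), mean_h2 = mean(h2s),
               n_replicates = n_replicates, seed = seed)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_result", "data.frame")
  out
}

#' Concordance of per-vertex heritability across coupling methods
#'
#' @param h2_vectors named list of equal-length per-vertex heritability
#'   vectors (>= 3 vertices), one per coupling construction method.
#' @return data.frame `method_a`, `method_b`, `r` (Pearson correlation).
#' @export
method_concordance <- function(h2_vectors) {
  nm <- names(h2_vectors)
  stopifnot(length(h2_vectors) >= 2, !is.null(nm))
  len <- unique(vapply(h2_vectors, length, 0L))
  if (length(len) != 1 || len < 3)
    stop("need equal-length vectors over at least 3 vertices")
  if (any(vapply(h2_vectors, stats::sd, 0) == 0))
    stop("constant heritability vector")
  rows <- list()
  for (i in seq_along(nm)[-length(nm)]) for (j in (i + 1):length(nm)) {
    rows[[length(rows) + 1]] <-
      data.frame(method_a = nm[i], method_b = nm[j],
                 r = stats::cor(h2_vectors[[i]], h2_vectors[[j]]),
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
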