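#' Simulate subject covariates
#'
#' Draws age (years; twins share family age), sex (0/1), handedness score
#' and total brain volume for the analysis individuals of a pedigree, and
#' attaches the derived columns age-squared, age x sex and age-squared x sex
#' used as heritability/GWAS fixed effects.
#'
#' @param pedigree a pedigree from [generate_pedigree()].
#' @param seed integer seed.
#' @param age_mean,age_sd cohort age distribution (young-adult default).
#' @return data.frame with rownames = individual ids and columns `age`,
#'   `sex`, `handedness`, `tbv`, `age2`, `age_sex`, `age2_sex`.
#' @export
simulate_covariates <- function(pedigree, seed = 1L,
                                age_mean = 28.7, age_sd = 3.7) {
  set.seed(seed)
  ids <- analysis_ids(pedigree)
  fam <- pedigree$family_id[match(ids, pedigree$individual_id)]
  fam_age <- stats::rnorm(length(unique(fam)), age_mean, age_sd)
  names(fam_age) <- unique(fam)
  age <- round(pmax(22, pmin(37, fam_age[fam])), 1)
  sex <- stats::rbinom(length(ids), 1, 0.5)
  handedness <- round(pmax(-100, pmin(100, stats::rnorm(length(ids), 65, 45))))
  tbv <- stats::rnorm(length(ids), 1200, 110)
  cov <- data.frame(age = as.numeric(age), sex = sex,
                    handedness = handedness, tbv = tbv)
  rownames(cov) <- ids
  add_derived_covariates(cov)
}

add_derived_covariates <- function(cov) {
  cov$age2 <- cov$age^2
  cov$age_sex <- cov$age * cov$sex
  cov$age2_sex <- cov$age2 * cov$sex
  cov
}

#' Fixed-effect design matrix for the heritability/GWAS models
#'
#' Intercept, age, age-squared, sex, age x sex, age-squared x sex,
#' handedness, total brain volume, plus optional genetic PCs — the covariate
#' set used throughout the variance-component and association analyses.
#'
#' @param covariates covariate data.frame (see [simulate_covariates()]).
#' @param pcs optional matrix of genetic principal components (same row
#'   order).
#' @return numeric design matrix with intercept column.
#' @export
covariate_design <- function(covariates, pcs = NULL) {
  base <- c("age", "age2", "sex", "age_sex", "age2_sex", "handedness", "tbv")
  miss <- setdiff(base, colnames(covariates))
  if (length(miss)) stop("missing covariate columns: ",
                         paste(miss, collapse = ", "))
  X <- cbind(intercept = 1, as.matrix(covariates[, base]))
  if (!is.null(pcs)) X <- cbind(X, as.matrix(pcs))
  q <- qr(X)
  if (q$rank < ncol(X)) stop("covariate design matrix is rank deficient")
  X
}
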