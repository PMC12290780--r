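#' Simulate biallelic genotypes on a pedigree by gene dropping
#'
#' Founder haplotypes are drawn per SNP from a minor-allele-frequency
#' spectrum uniform over \code{maf_range}; optional linkage disequilibrium is
#' induced within blocks of consecutive SNPs through a Gaussian copula with
#' first-order autoregressive correlation. Children inherit one allele per
#' parent per SNP (independent transmission); MZ twins copy their co-twin's
#' genotype, so MZ rows are identical.
#'
#' @param pedigree a pedigree from [generate_pedigree()].
#' @param n_snps number of SNPs.
#' @param maf_range length-2 numeric in (0, 0.5]; per-SNP MAF drawn uniform.
#' @param ld_block_size SNPs per LD block (1 = independent SNPs).
#' @param ld_rho within-block haplotype AR(1) correlation on the latent scale.
#' @param seed integer seed.
#' @param include_founders also emit the synthetic founder parents' rows
#'   (useful for transmission checks); default analysis individuals only.
#' @return a `genotype_matrix`: list with `dosage` (analysis individuals x
#'   SNPs, alternate-allele counts 0/1/2) and `snp_meta` (chromosome,
#'   position, ref, alt, id, maf used at simulation).
#' @export
simulate_genotypes <- function(pedigree, n_snps, maf_range = c(0.05, 0.5),
                               ld_block_size = 50, ld_rho = 0.8, seed = 1L,
                               include_founders = FALSE) {
  stopifnot(n_snps >= 1)
  if (ld_block_size > n_snps) stop("ld_block_size exceeds n_snps")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  set.seed(seed)

  maf <- runif(n_snps, maf_range[1], maf_range[2])
  # founders: two haplotypes each, latent AR(1) within LD blocks
  founders <- pedigree$individual_id[is.na(pedigree$father_id)]
  nf <- length(founders)
  blocks <- split(seq_len(n_snps),
                  ceiling(seq_len(n_snps) / ld_block_size))
  hap <- function() {
    h <- integer(n_snps)
    for (b in blocks) {
      m <- length(b)
      z <- numeric(m)
      z[1] <- rnorm(1)
      if (m > 1)
        for (j in 2:m) z[j] <- ld_rho * z[j - 1] + sqrt(1 - ld_rho^2) * rnorm(1)
      h[b] <- as.integer(z < qnorm(maf[b]))
    }
    h
  }
  H1 <- matrix(0L, nf, n_snps); H2 <- matrix(0L, nf, n_snps)
  for (i in seq_len(nf)) { H1[i, ] <- hap(); H2[i, ] <- hap() }
  rownames(H1) <- rownames(H2) <- founders

  # gene dropping in pedigree order (parents precede children)
  all_ids <- pedigree$individual_id
  hapA <- matrix(0L, length(all_ids), n_snps, dimnames = list(all_ids, NULL))
  hapB <- hapA
  hapA[founders, ] <- H1; hapB[founders, ] <- H2
  done_mz <- character(0)
  for (r in seq_len(nrow(pedigree))) {
    id <- pedigree$individual_id[r]
    fa <- pedigree$father_id[r]
    if (is.na(fa)) next
    mo <- pedigree$mother_id[r]
    if (pedigree$relationship_tag[r] == "MZ") {
      fam <- pedigree$family_id[r]
      tw <- intersect(done_mz,
                      pedigree$individual_id[pedigree$family_id == fam])
      if (length(tw)) {                      # copy co-twin
        hapA[id, ] <- hapA[tw[1], ]; hapB[id, ] <- hapB[tw[1], ]
        next
      }
      done_mz <- c(done_mz, id)
    }
    pickA <- runif(n_snps) < 0.5
    pickB <- runif(n_snps) < 0.5
    hapA[id, ] <- ifelse(pickA, hapA[fa, ], hapB[fa, ])
    hapB[id, ] <- ifelse(pickB, hapA[mo, ], hapB[mo, ])
  }

  ids <- if (include_founders) all_ids else analysis_ids(pedigree)
  dosage <- hapA[ids, , drop = FALSE] + hapB[ids, , drop = FALSE]
  storage.mode(dosage) <- "integer"

  # SNP metadata: one synthetic chromosome per ~ n/22, increasing positions
  n_chr <- max(1L, min(22L, n_snps %/% 100L + 1L))
  chr <- sort(rep_len(seq_len(n_chr), n_snps))
  pos <- integer(n_snps)
  for (c in unique(chr)) {
    m <- sum(chr == c)
    pos[chr == c] <- cumsum(sample(1000:20000, m, replace = TRUE))
  }
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")
  snp_meta <- data.frame(
    chrom = as.character(chr), pos = pos,
    id = sprintf("snp%d_%d", chr, pos),
    ref = ref, alt = alt, maf_sim = maf, stringsAsFactors = FALSE)
  colnames(dosage) <- snp_meta$id
  new_genotype_matrix(dosage, snp_meta)
}

new_genotype_matrix <- function(dosage, snp_meta) {
  stopifnot(ncol(dosage) == nrow(snp_meta))
  structure(list(dosage = dosage, snp_meta = snp_meta),
            class = "genotype_matrix")
}

#' @export
#' @method print genotype_matrix
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%s missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              format(mean(is.na(x$dosage)), digits = 3)))
  invisible(x)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test for a biallelic SNP: conditional on the observed
#' allele counts, the probability of each possible heterozygote count is
#' enumerated and the p-value is the summed probability of all
#' configurations no more probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("negative genotype counts")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no observations")
  n_a <- 2 * n_aa + n_Aa          # rare-or-not does not matter: symmetric
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_a, n_A)
  het_possible <- seq(rare %% 2, rare, by = 2)
  # log probability of het count conditional on allele counts
  logp <- vapply(het_possible, function(h) {
    hom_rare <- (rare - h) / 2
    hom_com <- (2 * n - rare - h) / 2
    h * log(2) + lfactorial(n) - lfactorial(h) - lfactorial(hom_rare) -
      lfactorial(hom_com) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, 0)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[het_possible == n_Aa]
  min(1, sum(p[p <= obs + 1e-12]))
}

#' Genotype quality control
#'
#' Applies, in order: (1) removal of individuals with more than
#' \code{ind_missing_max} missing genotypes; (2) removal of SNPs with minor
#' allele frequency below \code{maf_min}; (3) removal of SNPs with missing
#' rate above \code{snp_missing_max}; (4) removal of SNPs failing the exact
#' Hardy-Weinberg test at \code{hwe_p_min}. Allele frequencies and missing
#' rates are recomputed on retained individuals. When a pedigree is given,
#' HWE uses parentless individuals plus singletons only, since related
#' genotypes distort the test.
#'
#' @param genotypes a `genotype_matrix`.
#' @param ind_missing_max,maf_min,snp_missing_max,hwe_p_min thresholds.
#' @param pedigree optional pedigree for founder-only HWE.
#' @return list with `genotypes` (filtered) and `report` (a `qc_report`
#'   data.frame of removal counts in application order).
#' @export
qc_filter <- function(genotypes, ind_missing_max = 0.10, maf_min = 0.01,
                      snp_missing_max = 0.10, hwe_p_min = 1e-7,
                      pedigree = NULL) {
  G <- genotypes$dosage
  if (nrow(G) == 0 || ncol(G) == 0) stop("empty genotype matrix")
  meta <- genotypes$snp_meta

  ind_miss <- rowMeans(is.na(G))
  keep_ind <- ind_miss <= ind_missing_max
  n_ind_removed <- sum(!keep_ind)
  G <- G[keep_ind, , drop = FALSE]

  af <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep_maf <- !is.na(maf) & maf >= maf_min
  n_maf_removed <- sum(!keep_maf)
  G <- G[, keep_maf, drop = FALSE]; meta <- meta[keep_maf, , drop = FALSE]

  snp_miss <- colMeans(is.na(G))
  keep_miss <- snp_miss <= snp_missing_max
  n_miss_removed <- sum(!keep_miss)
  G <- G[, keep_miss, drop = FALSE]; meta <- meta[keep_miss, , drop = FALSE]

  hwe_rows <- rownames(G)
  if (!is.null(pedigree)) {
    unrel <- pedigree$individual_id[is.na(pedigree$father_id)]
    hwe_rows <- intersect(hwe_rows, unrel)
    if (length(hwe_rows) < 2) hwe_rows <- rownames(G)
  }
  Gh <- G[hwe_rows, , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(Gh)), function(j) {
    g <- Gh[, j]; g <- g[!is.na(g)]
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, 0)
  keep_hwe <- hwe_p >= hwe_p_min
  n_hwe_removed <- sum(!keep_hwe)
  G <- G[, keep_hwe, drop = FALSE]; meta <- meta[keep_hwe, , drop = FALSE]

  if (ncol(G) == 0) stop("no variants survive QC")
  report <- data.frame(
    filter = c("individual_missingness", "maf", "snp_missingness", "hwe"),
    unit = c("individual", "snp", "snp", "snp"),
    removed = c(n_ind_removed, n_maf_removed, n_miss_removed, n_hwe_removed))
  class(report) <- c("qc_report", "data.frame")
  list(genotypes = new_genotype_matrix(G, meta), report = report)
}
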