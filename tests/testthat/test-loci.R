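make_ld_genotypes <- function() {
  # hand-crafted LD structure on one chromosome:
  #  s1-s2-s3 tightly correlated cluster; s4 independent far away;
  #  s5 moderately linked to s4
  set.seed(111)
  n <- 120
  base1 <- rbinom(n, 2, 0.4)
  jig <- function(x, k) { y <- x; i <- sample(n, k); y[i] <- rbinom(k, 2, 0.4); y }
  G <- cbind(s1 = base1, s2 = jig(base1, 6), s3 = jig(base1, 8),
             s4 = rbinom(n, 2, 0.3), s5 = NA)
  G[, "s5"] <- jig(G[, "s4"], 25)
  rownames(G) <- sprintf("i%d", seq_len(n))
  meta <- data.frame(chrom = "1",
                     pos = c(100000L, 105000L, 110000L, 700000L, 705000L),
                     id = colnames(G), ref = "A", alt = "C",
                     stringsAsFactors = FALSE)
  sfcoupling:::new_genotype_matrix(G, meta)
}

test_that("LD r2 is the squared dosage correlation over complete pairs", {
  g <- make_ld_genotypes()
  expect_equal(ld_r2(g, "s1", "s1"), 1)
  # hand-constructed 6-individual pair
  a <- c(0L, 1L, 2L, 0L, 1L, 2L); b <- c(0L, 2L, 1L, 1L, 0L, 2L)
  G <- cbind(x = a, y = b); rownames(G) <- sprintf("i%d", 1:6)
  gm <- sfcoupling:::new_genotype_matrix(
    G, data.frame(chrom = "1", pos = 1:2, id = c("x", "y"),
                  ref = "A", alt = "C"))
  r_hand <- (sum((a - mean(a)) * (b - mean(b))) /
               sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)))^2
  expect_equal(ld_r2(gm, "x", "y"), r_hand, tolerance = 1e-12)
  # deviation-orthogonal dosage vectors
  a2 <- c(0L, 2L, 0L, 2L); b2 <- c(0L, 1L, 2L, 1L)
  G2 <- cbind(x = a2, y = b2); rownames(G2) <- sprintf("i%d", 1:4)
  gm2 <- sfcoupling:::new_genotype_matrix(
    G2, data.frame(chrom = "1", pos = 1:2, id = c("x", "y"),
                   ref = "A", alt = "C"))
  expect_equal(ld_r2(gm2, "x", "y"), 0, tolerance = 1e-12)
  G3 <- G2; G3[2:4, 2] <- NA
  gm3 <- sfcoupling:::new_genotype_matrix(
    G3, data.frame(chrom = "1", pos = 1:2, id = c("x", "y"),
                   ref = "A", alt = "C"))
  expect_error(ld_r2(gm3, "x", "y"), "3 pairwise-complete")
})

test_that("clumping collapses correlated significant SNPs and merges nearby blocks", {
  g <- make_ld_genotypes()
  r2_12 <- ld_r2(g, "s1", "s2")
  expect_gt(r2_12, 0.6)                   # construction sanity
  expect_lt(ld_r2(g, "s1", "s4"), 0.1)

  assoc <- data.frame(chrom = "1", id = g$snp_meta$id, pos = g$snp_meta$pos,
                      ref = "A", alt = "C", af = 0.4,
                      beta = 0, se = 1,
                      p_value = c(1e-10, 5e-9, 8e-9, 2e-12, 0.5),
                      stringsAsFactors = FALSE)

  # cluster s1-s3 -> one locus; s4 (600 kb away) -> separate locus
  loci <- define_loci(assoc, g, p_threshold = 1e-6)
  expect_equal(nrow(loci), 2)
  near <- loci[loci$start < 500000, ]
  expect_equal(near$n_indep, 1)           # s2, s3 clumped into s1
  expect_identical(near$lead_id, "s1")
  far <- loci[loci$start >= 500000, ]
  expect_identical(far$lead_id, "s4")

  # boundary gap below the merge distance: single locus
  g2 <- make_ld_genotypes()
  g2$snp_meta$pos <- c(100000L, 105000L, 110000L, 300000L, 305000L)
  loci2 <- define_loci(assoc, g2, p_threshold = 1e-6)
  expect_equal(nrow(loci2), 1)            # 190 kb gap < 250 kb -> merged
  expect_equal(loci2$n_indep, 2)
  expect_identical(loci2$lead_id, "s4")   # smallest p among members

  # no significant SNPs: empty, not an error
  expect_equal(nrow(define_loci(assoc, g, p_threshold = 1e-20)), 0)
})

test_that("clumping is order-invariant and satisfies the greedy-selection definition", {
  co <- make_cohort(n_mz = 0, n_dz = 0, n_fs = 0, n_single = 100,
                    n_snps = 15, seed = 113)
  g <- co$geno
  set.seed(114)
  assoc <- data.frame(chrom = g$snp_meta$chrom, id = g$snp_meta$id,
                      pos = g$snp_meta$pos, ref = "A", alt = "C", af = 0.3,
                      beta = 0, se = 1,
                      p_value = 10^-runif(nrow(g$snp_meta), 2, 12),
                      stringsAsFactors = FALSE)
  loci <- define_loci(assoc, g, p_threshold = 1e-3)
  perm <- sample(nrow(assoc))
  loci_perm <- define_loci(assoc[perm, ], g, p_threshold = 1e-3)
  expect_equal(as.data.frame(loci), as.data.frame(loci_perm))

  # exhaustive verification of the greedy definition on this instance
  sig <- assoc[assoc$p_value < 1e-3, ]
  chosen <- unlist(strsplit(loci$indep_ids, ","))
  # (a) chosen significant SNPs are pairwise independent at r2 < 0.6
  if (length(chosen) > 1) {
    for (i in seq_along(chosen)[-1]) for (j in seq_len(i - 1)) {
      expect_lt(ld_r2(g, chosen[i], chosen[j]), 0.6)
    }
  }
  # (b) every non-chosen significant SNP is tagged by a smaller-p chosen SNP
  for (s in setdiff(sig$id, chosen)) {
    partners <- chosen[vapply(chosen, function(t) ld_r2(g, s, t) >= 0.6,
                              TRUE)]
    expect_true(length(partners) > 0)
    expect_true(any(assoc$p_value[match(partners, assoc$id)] <=
                      assoc$p_value[match(s, assoc$id)]))
  }
  # (c) every significant SNP falls inside exactly one locus span
  for (s in sig$id) {
    pos <- assoc$pos[match(s, assoc$id)]
    chr <- assoc$chrom[match(s, assoc$id)]
    hits <- sum(loci$chrom == chr & loci$start <= pos & pos <= loci$end)
    expect_equal(hits, 1)
  }
})

test_that("cytoband parsing and interval lookup follow UCSC conventions", {
  tb <- c("chr1\t0\t2300000\tp36.33\tgneg",
          "chr1\t2300000\t5300000\tp36.32\tgpos25",
          "chr8\t0\t2200000\tp23.3\tgneg",
          "chr8\t2200000\t6200000\tp23.2\tgpos75")
  f <- tempfile(fileext = ".txt")
  writeLines(tb, f)
  bands <- read_cytoband(f)
  expect_equal(bands$start, c(1, 2300001, 1, 2200001))
  expect_identical(assign_cytoband("8", 3000000, bands), "8p23.2")
  expect_identical(assign_cytoband("chr1", 1, bands), "1p36.33")
  # UCSC end boundary belongs to the lower band after conversion
  expect_identical(assign_cytoband("1", 2300000, bands), "1p36.33")
  expect_identical(assign_cytoband("1", 2300001, bands), "1p36.32")
  expect_error(assign_cytoband("1", 99999999, bands), "outside")
  unlink(f)
})
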