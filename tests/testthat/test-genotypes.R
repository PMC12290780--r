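test_that("gene dropping respects MZ identity and Mendelian transmission", {
  ped <- generate_pedigree(6, 6, 6, 6, seed = 11)
  geno <- simulate_genotypes(ped, 400, seed = 12)
  ids <- analysis_ids(ped)
  tag <- ped$relationship_tag[match(ids, ped$individual_id)]
  fam <- ped$family_id[match(ids, ped$individual_id)]

  # MZ pairs: identical dosage vectors
  for (f in unique(fam[tag == "MZ"])) {
    pr <- ids[fam == f]
    expect_identical(geno$dosage[pr[1], ], geno$dosage[pr[2], ])
  }

  # every (father, mother, child) dosage triple must be reachable under the
  # exhaustive 3x3 Mendelian transmission table
  allele_opts <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  reachable <- function(f, m, d)
    d %in% outer(allele_opts[[as.character(f)]],
                 allele_opts[[as.character(m)]], "+")
  gf <- simulate_genotypes(ped, 200, seed = 13, include_founders = TRUE)
  children <- ped[!is.na(ped$father_id), ]
  ok <- TRUE
  combos_seen <- matrix(FALSE, 3, 3)
  for (r in seq_len(nrow(children))) {
    f <- gf$dosage[children$father_id[r], ]
    m <- gf$dosage[children$mother_id[r], ]
    d <- gf$dosage[children$individual_id[r], ]
    for (j in seq_along(d)) {
      combos_seen[f[j] + 1, m[j] + 1] <- TRUE
      if (!reachable(f[j], m[j], d[j])) ok <- FALSE
    }
  }
  expect_true(ok)
  expect_true(all(combos_seen))          # all 9 parental combinations hit

  # sample allele frequency of founders near target for fixed MAF
  ped_f <- generate_pedigree(0, 0, 0, 400, seed = 15)
  g3 <- simulate_genotypes(ped_f, 60, maf_range = c(0.3, 0.3),
                           ld_block_size = 1, seed = 16)
  af <- colMeans(g3$dosage) / 2
  se <- sqrt(0.3 * 0.7 / (2 * 400))
  expect_true(all(abs(af - 0.3) < 3.5 * se + 1e-12))

  expect_error(simulate_genotypes(ped, 10, ld_block_size = 50, seed = 1),
               "ld_block_size")
})

test_that("gene-drop realized kinship converges to the pedigree coding", {
  ped <- generate_pedigree(4, 4, 4, 8, seed = 21)
  g <- simulate_genotypes(ped, 2000, maf_range = c(0.2, 0.5), seed = 22)
  ids <- analysis_ids(ped)
  fam <- ped$family_id[match(ids, ped$individual_id)]
  tag <- ped$relationship_tag[match(ids, ped$individual_id)]
  K <- compute_grm(drop_monomorphic(g))
  for (f in unique(fam[tag != "SINGLETON"])) {
    pr <- which(fam == f)
    expected <- if (tag[pr[1]] == "MZ") 1 else 0.5
    expect_lt(abs(K$K[pr[1], pr[2]] - expected), 0.2)
  }
  off <- K$K[fam[row(K$K)] != fam[col(K$K)]]
  expect_lt(abs(mean(off)), 0.05)
})

test_that("exact HWE test matches enumeration arithmetic", {
  # modal configurations give p = 1
  expect_equal(hwe_exact_test(25, 50, 25), 1)
  expect_equal(hwe_exact_test(0, 2, 0), 1)
  # extreme heterozygote deficit
  expect_lt(hwe_exact_test(100, 0, 100), 1e-7)
  # probabilities over all het configurations sum to 1 (enumeration check)
  n_AA <- 6; n_Aa <- 4; n_aa <- 2
  n <- n_AA + n_Aa + n_aa
  rare <- min(2 * n_aa + n_Aa, 2 * n_AA + n_Aa)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- vapply(hets, function(h) {
    hr <- (rare - h) / 2; hc <- (2 * n - rare - h) / 2
    exp(h * log(2) + lfactorial(n) - lfactorial(h) - lfactorial(hr) -
          lfactorial(hc) + lfactorial(rare) + lfactorial(2 * n - rare) -
          lfactorial(2 * n))
  }, 0)
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  # p-value equals the enumerated tail mass for the observed config
  p_obs <- probs[hets == n_Aa]
  expect_equal(hwe_exact_test(n_AA, n_Aa, n_aa),
               sum(probs[probs <= p_obs + 1e-12]), tolerance = 1e-12)
  expect_error(hwe_exact_test(-1, 0, 1), "negative")
})

test_that("QC filters apply in order with recomputed frequencies", {
  # clean matrix: nothing removed
  ped <- generate_pedigree(0, 0, 0, 60, seed = 31)
  g <- simulate_genotypes(ped, 40, maf_range = c(0.25, 0.35),
                          ld_block_size = 1, seed = 32)
  out <- qc_filter(g)
  expect_equal(sum(out$report$removed), 0)
  expect_equal(dim(out$genotypes$dosage), dim(g$dosage))

  # hand-built 6 x 10 toy: one 40%-missing individual, one SNP at 20%
  # missingness among the retained individuals (the lone NA leaves its
  # carrier at exactly the 10% individual threshold, so only the SNP goes)
  dos <- matrix(rep(c(0L, 1L, 2L, 1L, 0L, 1L), 10), 6, 10)
  rownames(dos) <- sprintf("i%d", 1:6)
  dos[1, 1:4] <- NA                      # individual 1: 4/10 = 40% missing
  dos[3, 3] <- NA                        # SNP 3: 1/5 = 20% missing after i1 out
  meta <- data.frame(chrom = "1", pos = 1:10, id = sprintf("s%d", 1:10),
                     ref = "A", alt = "C", stringsAsFactors = FALSE)
  toy <- sfcoupling:::new_genotype_matrix(dos, meta)
  res <- qc_filter(toy, hwe_p_min = 0)   # HWE off for the hand count
  expect_equal(res$report$removed[res$report$filter ==
                                    "individual_missingness"], 1)
  expect_equal(res$report$removed[res$report$filter == "snp_missingness"], 1)
  expect_equal(res$report$removed[res$report$filter == "maf"], 0)
  expect_false("i1" %in% rownames(res$genotypes$dosage))
  expect_false("s3" %in% colnames(res$genotypes$dosage))

  # a MAF 0.005-style rare SNP is removed by the MAF filter
  dos2 <- matrix(1L, 100, 2)
  dos2[, 1] <- rep(c(0L, 1L, 2L), length.out = 100)
  dos2[, 2] <- 0L; dos2[1, 2] <- 1L      # MAF = 1/200 = 0.005
  rownames(dos2) <- sprintf("j%d", 1:100)
  meta2 <- data.frame(chrom = "1", pos = 1:2, id = c("common", "rare"),
                      ref = "A", alt = "C", stringsAsFactors = FALSE)
  res2 <- qc_filter(sfcoupling:::new_genotype_matrix(dos2, meta2),
                    hwe_p_min = 0)
  expect_false("rare" %in% colnames(res2$genotypes$dosage))
  expect_equal(res2$report$removed[res2$report$filter == "maf"], 1)

  # idempotence
  once <- qc_filter(g)
  twice <- qc_filter(once$genotypes)
  expect_identical(once$genotypes$dosage, twice$genotypes$dosage)
})
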