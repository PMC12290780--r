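#' Linkage-disequilibrium r-squared between two SNPs
#'
#' Squared Pearson correlation of dosage vectors over pairwise-complete
#' individuals.
#'
#' @param genotypes a `genotype_matrix`.
#' @param snp_a,snp_b SNP ids.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(genotypes, snp_a, snp_b) {
  G <- genotypes$dosage
  ja <- match(snp_a, colnames(G)); jb <- match(snp_b, colnames(G))
  if (is.na(ja) || is.na(jb)) stop("unknown SNP id")
  a <- G[, ja]; b <- G[, jb]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("fewer than 3 pairwise-complete individuals")
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
    stop("monomorphic SNP in LD computation")
  stats::cor(a[ok], b[ok])^2
}

# r2 of one SNP column against many, pairwise complete
ld_r2_vec <- function(G, j, js) {
  if (!length(js)) return(numeric(0))
  r <- suppressWarnings(
    stats::cor(G[, j], G[, js, drop = FALSE],
               use = "pairwise.complete.obs"))
  drop(r)^2
}

#' Define genomic risk loci by LD clumping and block merging
#'
#' Implements the standard FUMA-style locus definition on in-sample LD:
#' (1) significant SNPs are those with p below `p_threshold`;
#' (2) independent significant SNPs are chosen greedily in ascending p
#' (ties broken by position), each required to have r-squared below
#' `r2_independent` with all previously chosen ones;
#' (3) lead SNPs are selected among these by the same greedy rule at
#' `r2_lead`;
#' (4) each independent significant SNP tags all analyzed SNPs with
#' r-squared at or above `r2_independent` and MAF at least `maf_tag_min`;
#' (5) the LD block of an independent significant SNP is the positional
#' span of its tagged set; (6) blocks on the same chromosome whose closest
#' boundaries are less than `merge_kb` kilobases apart are merged
#' iteratively to a fixed point.
#'
#' @param assoc association data.frame from [lmm_gwas()] (columns id,
#'   chrom, pos, p_value).
#' @param genotypes a `genotype_matrix` sharing the SNP ids.
#' @param p_threshold genome-wide significance threshold.
#' @param r2_independent,r2_lead clumping thresholds (defaults 0.6, 0.1).
#' @param maf_tag_min minimum MAF for tagged SNPs (default 5e-4).
#' @param merge_kb merge distance between block boundaries, kb (default
#'   250).
#' @param bands optional `cytoband_table` for band assignment.
#' @return data.frame of class `locus_table`, one row per locus: `chrom`,
#'   `start`, `end`, `lead_id`, `lead_p`, `n_indep`, `n_tagged`,
#'   `indep_ids`, `tagged_ids` (comma-separated), `cytoband` (NA without
#'   `bands`). Empty input or no significant SNP returns zero rows.
#' @export
define_loci <- function(assoc, genotypes, p_threshold,
                        r2_independent = 0.6, r2_lead = 0.1,
                        maf_tag_min = 5e-4, merge_kb = 250,
                        bands = NULL) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), lead_id = character(0),
                      lead_p = numeric(0), n_indep = integer(0),
                      n_tagged = integer(0), indep_ids = character(0),
                      tagged_ids = character(0), cytoband = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("locus_table", "data.frame")
  sig <- assoc[assoc$p_value < p_threshold, , drop = FALSE]
  if (nrow(sig) == 0) return(empty)
  G <- genotypes$dosage
  if (!all(sig$id %in% colnames(G)))
    stop("association table and genotypes disagree on SNP ids")

  greedy_select <- function(cand, r2_max) {
    cand <- cand[order(cand$p_value, cand$pos), , drop = FALSE]
    chosen <- integer(0)
    for (r in seq_len(nrow(cand))) {
      j <- match(cand$id[r], colnames(G))
      same_chr <- chosen[assoc_chr[chosen] == cand$chrom[r]]
      if (length(same_chr)) {
        r2 <- ld_r2_vec(G, j, same_chr)
        if (any(r2 >= r2_max, na.rm = TRUE)) next
      }
      chosen <- c(chosen, j)
    }
    chosen
  }
  assoc_chr <- stats::setNames(rep(NA_character_, ncol(G)), colnames(G))
  assoc_chr[match(genotypes$snp_meta$id, colnames(G))] <-
    genotypes$snp_meta$chrom

  sig2 <- sig
  sig2$pos <- sig2$pos
  indep_j <- greedy_select(sig2, r2_independent)
  indep_ids <- colnames(G)[indep_j]
  lead_j <- greedy_select(sig2[sig2$id %in% indep_ids, , drop = FALSE],
                          r2_lead)
  lead_ids <- colnames(G)[lead_j]

  # tagged set and block span per independent significant SNP
  meta <- genotypes$snp_meta
  af <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  blocks <- lapply(indep_j, function(j) {
    chr <- assoc_chr[j]
    same <- which(assoc_chr == chr & maf >= maf_tag_min)
    r2 <- ld_r2_vec(G, j, same)
    tagged <- same[!is.na(r2) & r2 >= r2_independent]
    tagged <- union(tagged, j)
    pos <- meta$pos[match(colnames(G)[tagged], meta$id)]
    list(chrom = chr, start = min(pos), end = max(pos),
         indep = colnames(G)[j], tagged = colnames(G)[tagged])
  })

  # iterative same-chromosome merge on closest boundary distance
  repeat {
    merged <- FALSE
    i <- 1
    while (i < length(blocks) + 1 && !merged) {
      j <- i + 1
      while (j <= length(blocks)) {
        bi <- blocks[[i]]; bj <- blocks[[j]]
        if (bi$chrom == bj$chrom) {
          gap <- max(bi$start, bj$start) - min(bi$end, bj$end)
          if (gap < merge_kb * 1000) {
            blocks[[i]] <- list(chrom = bi$chrom,
                                start = min(bi$start, bj$start),
                                end = max(bi$end, bj$end),
                                indep = c(bi$indep, bj$indep),
                                tagged = union(bi$tagged, bj$tagged))
            blocks[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }

  rows <- lapply(blocks, function(b) {
    # the locus lead is its smallest-p independent member (ties by
    # position); the r2 < r2_lead lead list is reported alongside
    lead_in <- intersect(lead_ids, b$indep)
    lp <- sig$p_value[match(b$indep, sig$id)]
    lead <- b$indep[order(lp, sig$pos[match(b$indep, sig$id)])][1]
    band <- NA_character_
    if (!is.null(bands)) {
      lead_pos <- meta$pos[match(lead, meta$id)]
      band <- tryCatch(assign_cytoband(b$chrom, lead_pos, bands),
                       error = function(e) NA_character_)
    }
    data.frame(chrom = b$chrom, start = b$start, end = b$end,
               lead_id = lead, lead_p = min(lp),
               n_indep = length(b$indep), n_tagged = length(b$tagged),
               indep_ids = paste(sort(b$indep), collapse = ","),
               lead_ids = paste(sort(lead_in), collapse = ","),
               tagged_ids = paste(sort(b$tagged), collapse = ","),
               cytoband = band, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("locus_table", "data.frame")
  out
}

#' Read a UCSC cytoBand table
#'
#' Consumes the cytoBand.txt dialect (chrom, chromStart, chromEnd, name,
#' gieStain; 0-based half-open intervals) and converts to 1-based inclusive
#' coordinates.
#'
#' @param path file path (plain or gzip).
#' @return `cytoband_table` data.frame: chrom (without "chr" prefix),
#'   start, end (1-based inclusive), name (e.g. "8p23.2"), stain.
#' @export
read_cytoband <- function(path) {
  tb <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start0", "end", "band",
                                        "stain"))
  chrom <- sub("^chr", "", tb$chrom)
  out <- data.frame(chrom = chrom, start = tb$start0 + 1L, end = tb$end,
                    name = paste0(chrom, tb$band), stain = tb$stain,
                    stringsAsFactors = FALSE)
  class(out) <- c("cytoband_table", "data.frame")
  out
}

#' Cytogenetic band containing a position
#'
#' @param chromosome chromosome (with or without "chr" prefix).
#' @param position 1-based base-pair position.
#' @param bands a `cytoband_table` from [read_cytoband()].
#' @return band name, chromosome-prefixed (e.g. "8p23.2").
#' @export
assign_cytoband <- function(chromosome, position, bands) {
  chrom <- sub("^chr", "", chromosome)
  b <- bands[bands$chrom == chrom, , drop = FALSE]
  hit <- which(b$start <= position & position <= b$end)
  if (length(hit) != 1)
    stop(sprintf("position %s:%d outside the cytoband table",
                 chrom, as.integer(position)))
  b$name[hit]
}
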