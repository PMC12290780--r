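#' Pearson chi-squared enrichment test on a 2x2 table
#'
#' Counts: significant in the group, significant outside, non-significant
#' in the group, non-significant outside. Plain Pearson statistic, no
#' continuity correction, 1 df.
#'
#' @param a,b,c,d the four cell counts (or `a` a 2x2 matrix).
#' @return list with `chi2` and `p`.
#' @export
enrichment_chisq <- function(a, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2, 2)
  if (any(tab < 0)) stop("negative cell count")
  if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

#' Network enrichment of significant associations
#'
#' For each label (network/region), builds the 2x2 table of significant
#' versus non-significant tested units inside versus outside the label and
#' applies [enrichment_chisq()]. The tested unit is the (SNP, vertex) pair
#' by default; pass per-vertex flags for vertex-level enrichment.
#'
#' @param labels character vector, one label per tested unit.
#' @param significant logical vector, same length.
#' @return data.frame `label`, `a`, `b`, `c`, `d`, `chi2`, `p`; labels with
#'   a degenerate table get NA statistics (with a warning).
#' @export
network_enrichment <- function(labels, significant) {
  stopifnot(length(labels) == length(significant))
  out <- lapply(sort(unique(labels)), function(L) {
    a <- sum(labels == L & significant)
    b <- sum(labels != L & significant)
    cc <- sum(labels == L & !significant)
    dd <- sum(labels != L & !significant)
    res <- tryCatch(enrichment_chisq(a, b, cc, dd),
                    error = function(e) list(chi2 = NA_real_, p = NA_real_))
    data.frame(label = L, a = a, b = b, c = cc, d = dd,
               chi2 = res$chi2, p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (anyNA(out$chi2)) warning("degenerate table(s) skipped")
  out
}

#' Locus-by-network enrichment
#'
#' One 2x2 chi-squared test per (cytoband, network) pair that occurs among
#' the significant associations. Significant associations are
#' cross-classified by cytoband membership and network membership: inside
#' both, inside the band only, inside the network only, inside neither.
#'
#' @param assignments data.frame with columns `cytoband`, `network`,
#'   `significant` (logical), one row per association.
#' @return data.frame `cytoband`, `network`, `a`..`d`, `chi2`, `p`;
#'   degenerate pairs are skipped with a warning.
#' @export
locus_network_enrichment <- function(assignments) {
  stopifnot(all(c("cytoband", "network", "significant") %in%
                  colnames(assignments)))
  if (nrow(assignments) == 0) stop("no associations supplied")
  sig <- assignments[assignments$significant, , drop = FALSE]
  pairs <- unique(sig[, c("cytoband", "network")])
  rows <- list(); skipped <- 0
  for (r in seq_len(nrow(pairs))) {
    cb <- pairs$cytoband[r]; nw <- pairs$network[r]
    in_cb <- sig$cytoband == cb
    in_nw <- sig$network == nw
    a <- sum(in_cb & in_nw); b <- sum(in_cb & !in_nw)
    cc <- sum(!in_cb & in_nw); dd <- sum(!in_cb & !in_nw)
    res <- tryCatch(enrichment_chisq(a, b, cc, dd),
                    error = function(e) NULL)
    if (is.null(res)) { skipped <- skipped + 1; next }
    rows[[length(rows) + 1]] <-
      data.frame(cytoband = cb, network = nw, a = a, b = b, c = cc, d = dd,
                 chi2 = res$chi2, p = res$p, stringsAsFactors = FALSE)
  }
  if (skipped > 0) warning(skipped, " degenerate pair(s) skipped")
  if (!length(rows))
    return(data.frame(cytoband = character(0), network = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), chi2 = numeric(0), p = numeric(0)))
  do.call(rbind, rows)
}

#' Dice overlap of two association sets
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; 0 when both sets are empty.
#'
#' @param set_a,set_b vectors of association ids.
#' @return proportion in \[0, 1\].
#' @export
dice_overlap <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) + length(set_b) == 0) return(0)
  2 * length(intersect(set_a, set_b)) / (length(set_a) + length(set_b))
}
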