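#' Generate a twin/sibling/singleton pedigree
#'
#' Builds a synthetic cohort of monozygotic (MZ) twin pairs, dizygotic (DZ)
#' twin pairs, full-sibling pairs and singletons, each family with its own
#' pair of founder parents (singletons are parentless founding individuals).
#' Analysis individuals are those tagged \code{MZ}, \code{DZ},
#' \code{FULL_SIB} or \code{SINGLETON}; \code{FOUNDER} rows are the synthetic
#' parents and are not part of the analysis cohort.
#'
#' @param n_mz_pairs number of MZ twin pairs.
#' @param n_dz_pairs number of DZ twin pairs.
#' @param n_fullsib_pairs number of full-sibling pairs (two sibs each).
#' @param n_singletons number of unrelated singletons.
#' @param seed integer seed; the pedigree is deterministic given the counts,
#'   the seed is kept for interface symmetry with the other generators.
#' @return a data.frame of class \code{pedigree_df} with columns
#'   \code{individual_id}, \code{family_id}, \code{father_id},
#'   \code{mother_id} (\code{NA} for founders/singletons) and
#'   \code{relationship_tag}. Parents precede children.
#' @export
generate_pedigree <- function(n_mz_pairs, n_dz_pairs, n_fullsib_pairs,
                              n_singletons, seed = 1L) {
  counts <- c(n_mz_pairs, n_dz_pairs, n_fullsib_pairs, n_singletons)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("empty cohort")

  rows <- list()
  fam <- 0L
  add_pair_family <- function(tag, k) {
    out <- vector("list", k)
    for (i in seq_len(k)) {
      fam <<- fam + 1L
      fid <- sprintf("F%04d", fam)
      fa <- sprintf("%s_P1", fid); mo <- sprintf("%s_P2", fid)
      out[[i]] <- data.frame(
        individual_id = c(fa, mo, sprintf("%s_C1", fid), sprintf("%s_C2", fid)),
        family_id = fid,
        father_id = c(NA, NA, fa, fa),
        mother_id = c(NA, NA, mo, mo),
        relationship_tag = c("FOUNDER", "FOUNDER", tag, tag),
        stringsAsFactors = FALSE)
    }
    out
  }
  rows <- c(rows,
            add_pair_family("MZ", n_mz_pairs),
            add_pair_family("DZ", n_dz_pairs),
            add_pair_family("FULL_SIB", n_fullsib_pairs))
  if (n_singletons > 0) {
    sing <- vector("list", n_singletons)
    for (i in seq_len(n_singletons)) {
      fam <- fam + 1L
      fid <- sprintf("F%04d", fam)
      sing[[i]] <- data.frame(
        individual_id = sprintf("%s_S1", fid), family_id = fid,
        father_id = NA_character_, mother_id = NA_character_,
        relationship_tag = "SINGLETON", stringsAsFactors = FALSE)
    }
    rows <- c(rows, sing)
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  class(ped) <- c("pedigree_df", "data.frame")
  ped
}

#' Analysis individuals of a pedigree
#'
#' @param pedigree a pedigree data.frame from [generate_pedigree()].
#' @return character vector of ids with tag other than FOUNDER.
#' @export
analysis_ids <- function(pedigree) {
  pedigree$individual_id[pedigree$relationship_tag != "FOUNDER"]
}

#' Pedigree-based genetic relationship matrix
#'
#' Expected genetic similarity coded from pedigree structure: 1 for MZ twin
#' pairs, 1/2 for DZ twin pairs and full siblings, 0 for unrelated pairs,
#' 1 on the diagonal. Only analysis individuals (non-founders) are included.
#'
#' @param pedigree a pedigree data.frame.
#' @return a `grm` object (see [compute_grm()]) with `source = "pedigree"`.
#' @export
pedigree_grm <- function(pedigree) {
  ids <- analysis_ids(pedigree)
  n <- length(ids)
  K <- diag(1, n)
  tag <- pedigree$relationship_tag[match(ids, pedigree$individual_id)]
  famv <- pedigree$family_id[match(ids, pedigree$individual_id)]
  for (f in unique(famv)) {
    idx <- which(famv == f)
    if (length(idx) < 2) next
    for (a in idx) for (b in idx) {
      if (a >= b) next
      v <- if (tag[a] == "MZ" && tag[b] == "MZ") 1 else 0.5
      K[a, b] <- K[b, a] <- v
    }
  }
  dimnames(K) <- list(ids, ids)
  new_grm(K, ids = ids, source = "pedigree")
}
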