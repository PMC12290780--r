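#' Write genotypes
#'
#' `vcf` writes a minimal VCF v4.2 with GT fields (missing = "./.");
#' `dosage_tsv` writes rows = SNPs, columns = individuals, values in
#' {0, 1, 2, NA}.
#'
#' @param genotypes a `genotype_matrix`.
#' @param path output file.
#' @param format "vcf" or "dosage_tsv".
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path,
                            format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  G <- genotypes$dosage; meta <- genotypes$snp_meta
  if (format == "vcf") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=sfcoupling",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", rownames(G)),
                       collapse = "\t")), con)
    gt_code <- c("0/0", "0/1", "1/1")
    for (j in seq_len(ncol(G))) {
      g <- G[, j]
      gt <- ifelse(is.na(g), "./.", gt_code[g + 1])
      writeLines(paste(c(meta$chrom[j], meta$pos[j], meta$id[j],
                         meta$ref[j], meta$alt[j], ".", "PASS", ".",
                         "GT", gt), collapse = "\t"), con)
    }
  } else {
    out <- cbind(data.frame(snp = meta$id), as.data.frame(t(G)))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read genotypes
#'
#' VCF input goes through \pkg{vcfR}; multiallelic records and malformed
#' GT fields are rejected. Dosage TSV input validates that every token is
#' 0, 1, 2 or NA.
#'
#' @param path input file.
#' @param format "vcf" or "dosage_tsv".
#' @param snp_meta optional metadata to attach to a dosage TSV (must match
#'   the SNP ids).
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv"),
                           snp_meta = NULL) {
  format <- match.arg(format)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix)))                 # single-record VCF drops dims
      fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
      stop("multiallelic site in VCF: ",
           fix[grepl(",", fix[, "ALT"]), "ID"][1])
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt)))
      gt <- matrix(gt, nrow = 1, dimnames = list(fix[, "ID"], names(gt)))
    parse_gt <- function(x) {
      x <- gsub("|", "/", x, fixed = TRUE)
      d <- rep(NA_integer_, length(x))
      d[x %in% "0/0"] <- 0L; d[x %in% c("0/1", "1/0")] <- 1L
      d[x %in% "1/1"] <- 2L
      bad <- !is.na(x) & is.na(d) & x != "./."
      if (any(bad)) stop("malformed GT field: ", x[bad][1])
      d
    }
    dosage <- t(apply(gt, 1, parse_gt))
    dimnames(dosage) <- list(rownames(gt), colnames(gt))
    dosage <- t(dosage)                       # individuals x SNPs
    meta <- data.frame(chrom = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]),
                       id = fix[, "ID"], ref = fix[, "REF"],
                       alt = fix[, "ALT"], stringsAsFactors = FALSE)
    colnames(dosage) <- meta$id
    new_genotype_matrix(dosage, meta)
  } else {
    tb <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- tb[[1]]
    M <- as.matrix(tb[, -1, drop = FALSE])
    bad <- !(is.na(M) | M %in% c(0, 1, 2))
    if (any(bad)) stop("dosage TSV contains a non-{0,1,2,NA} token: ",
                       M[bad][1])
    storage.mode(M) <- "integer"
    dosage <- t(M)
    colnames(dosage) <- ids
    if (is.null(snp_meta))
      snp_meta <- data.frame(chrom = "1", pos = seq_along(ids), id = ids,
                             ref = "A", alt = "C",
                             stringsAsFactors = FALSE)
    stopifnot(identical(snp_meta$id, ids))
    new_genotype_matrix(dosage, snp_meta)
  }
}

#' Write / read GCTA-dialect phenotype or covariate tables
#'
#' Whitespace-separated, leading family-ID and individual-ID columns, no
#' header (phenotype) or header (covariates kept with header = FALSE too,
#' matching the tool dialect).
#'
#' @param values data.frame or vector of trait/covariate values.
#' @param ids individual ids; `family_ids` defaults to them.
#' @param path output file.
#' @param family_ids optional family ids.
#' @return `path` (writers) / data.frame (readers).
#' @export
write_gcta_table <- function(values, ids, path, family_ids = NULL) {
  if (is.null(family_ids)) family_ids <- ids
  out <- cbind(data.frame(fid = family_ids, iid = ids),
               as.data.frame(values))
  utils::write.table(out, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gcta_table
#' @param col_names names for the value columns on read.
#' @export
read_gcta_table <- function(path, col_names = NULL) {
  tb <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  colnames(tb)[1:2] <- c("fid", "iid")
  if (!is.null(col_names)) colnames(tb)[-(1:2)] <- col_names
  tb
}

#' Write / read the mesh vertex table
#'
#' TSV with columns vertex_id, x, y, z, hemisphere, network, region, mask.
#'
#' @param mesh a `surface_mesh`.
#' @param path file path.
#' @return `path` / a `surface_mesh`.
#' @export
write_mesh <- function(mesh, path) {
  utils::write.table(as.data.frame(mesh), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  m$mask <- as.logical(m$mask)
  class(m) <- c("surface_mesh", "data.frame")
  m
}

#' Write / read a coupling matrix
#'
#' Subjects x vertices TSV with a header row of vertex ids and a leading
#' subject-id column.
#'
#' @param coupling a `coupling_matrix`.
#' @param path file path.
#' @return `path` / a `coupling_matrix` (method tag restored from the
#'   `method` argument on read).
#' @export
write_coupling <- function(coupling, path) {
  out <- cbind(data.frame(subject = rownames(coupling)),
               as.data.frame(unclass(coupling)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_coupling
#' @param method method tag to restore.
#' @export
read_coupling <- function(path, method = "inner") {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(tb[, -1, drop = FALSE])
  rownames(M) <- tb[[1]]
  structure(M, method = method,
            class = c("coupling_matrix", "matrix", "array"))
}

#' Write / read per-subject connectivity profiles
#'
#' One whitespace matrix file per subject per modality under `dir`:
#' `<subject>.<sc|fc>.txt`. Symmetry (to 1e-8) and, for FC, a unit
#' diagonal are enforced on read when `validate = TRUE`.
#'
#' @param profiles list with `sc` and `fc` per-subject matrix lists.
#' @param dir directory (created if needed).
#' @return `dir` / profiles list.
#' @export
write_profiles <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(profiles$sc)) {
    utils::write.table(profiles$sc[[s]],
                       file.path(dir, paste0(s, ".sc.txt")),
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(profiles$fc[[s]],
                       file.path(dir, paste0(s, ".fc.txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_profiles
#' @param subjects subject ids to read.
#' @param validate check symmetry/diagonal invariants.
#' @export
read_profiles <- function(dir, subjects, validate = TRUE) {
  rd <- function(f) as.matrix(utils::read.table(f))
  sc <- lapply(subjects, function(s) {
    M <- unname(rd(file.path(dir, paste0(s, ".sc.txt"))))
    if (validate) {
      if (max(abs(M - t(M))) > 1e-8) stop("SC not symmetric for ", s)
      if (any(M < 0)) stop("negative SC entries for ", s)
    }
    M
  })
  fc <- lapply(subjects, function(s) {
    M <- unname(rd(file.path(dir, paste0(s, ".fc.txt"))))
    if (validate && max(abs(M - t(M))) > 1e-8)
      stop("FC not symmetric for ", s)
    M
  })
  names(sc) <- names(fc) <- subjects
  list(sc = sc, fc = fc)
}

#' Write a fastGWA-like summary-statistics table
#'
#' Columns CHR SNP POS A1 A2 AF1 BETA SE P, tab-separated.
#'
#' @param assoc association data.frame from [lmm_gwas()].
#' @param path file path.
#' @return `path` / data.frame in [lmm_gwas()] column naming.
#' @export
write_sumstats <- function(assoc, path) {
  out <- data.frame(CHR = assoc$chrom, SNP = assoc$id, POS = assoc$pos,
                    A1 = assoc$alt, A2 = assoc$ref, AF1 = assoc$af,
                    BETA = assoc$beta, SE = assoc$se, P = assoc$p_value)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  data.frame(chrom = as.character(tb$CHR), id = tb$SNP, pos = tb$POS,
             ref = tb$A2, alt = tb$A1, af = tb$AF1, beta = tb$BETA,
             se = tb$SE, p_value = tb$P, stringsAsFactors = FALSE)
}
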