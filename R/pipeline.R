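#' Default pipeline configuration
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed; each stage derives its own substream.
#' @param ... overrides for any config entry.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("sfc_run_"), seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    n_mz_pairs = 35, n_dz_pairs = 21, n_fullsib_pairs = 35,
    n_singletons = 51,
    n_snps = 2000, maf_range = c(0.05, 0.5), ld_block_size = 50,
    n_vertices_per_hemisphere = 30, n_networks = 3, n_regions = 6,
    h2_coupling = 0.4,
    qc_ind_missing_max = 0.10, qc_maf_min = 0.01,
    qc_snp_missing_max = 0.10, qc_hwe_p_min = 1e-7,
    n_pcs = 10,
    n_gwas_vertices = 3, gwas_alpha = 0.05,
    fdr_q = 0.05, r2_independent = 0.6, r2_lead = 0.1, merge_kb = 250,
    n_rg_vertices = 4,
    run_gwas = TRUE, run_loci = TRUE, run_enrichment = TRUE,
    run_rg = TRUE, quiet = FALSE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

stage_seed <- function(cfg, stage) {
  offs <- c(pedigree = 11L, genotypes = 23L, covariates = 37L,
            connectivity = 41L, phenotype = 53L, mesh = 67L)
  (cfg$seed * 7919L + offs[[stage]]) %% .Machine$integer.max
}

pipe_log <- function(cfg, stage, msg) {
  if (!isTRUE(cfg$quiet))
    message(sprintf("[%s] %s", stage, msg))
}

provenance_header <- function(cfg, stage) {
  flat <- paste(vapply(cfg[order(names(cfg))],
                       function(v) paste(format(v), collapse = ","), ""),
                collapse = ";")
  hash <- sum(utf8ToInt(flat) * seq_along(utf8ToInt(flat))) %% 1000000L
  sprintf("# sfcoupling %s | stage=%s | seed=%d | config_hash=%06d",
          as.character(utils::packageVersion("sfcoupling")), stage,
          cfg$seed, hash)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Chains the stages end to end on a synthetic cohort: cohort simulation
#' (pedigree, genotypes, covariates, mesh, connectivity) -> coupling ->
#' genotype QC / GRM / PCs -> per-vertex heritability -> GWAS on the most
#' heritable vertices -> locus definition -> network enrichment ->
#' pairwise genetic correlation and distance decay. Every artifact is
#' written as TSV under `cfg$out_dir` with a provenance comment line.
#'
#' @param cfg a [pipeline_config()].
#' @return invisible list of the main in-memory results.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name, stage) {
    f <- file.path(cfg$out_dir, name)
    con <- file(f, "w")
    writeLines(provenance_header(cfg, stage), con)
    suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    close(con)
    f
  }

  pipe_log(cfg, "simulate", "generating cohort")
  ped <- generate_pedigree(cfg$n_mz_pairs, cfg$n_dz_pairs,
                           cfg$n_fullsib_pairs, cfg$n_singletons,
                           seed = stage_seed(cfg, "pedigree"))
  geno <- simulate_genotypes(ped, cfg$n_snps, cfg$maf_range,
                             cfg$ld_block_size,
                             seed = stage_seed(cfg, "genotypes"))
  cov <- simulate_covariates(ped, seed = stage_seed(cfg, "covariates"))
  mesh <- generate_mesh(cfg$n_vertices_per_hemisphere, cfg$n_networks,
                        cfg$n_regions, seed = stage_seed(cfg, "mesh"))
  wt(as.data.frame(ped), "pedigree.tsv", "simulate")
  wt(as.data.frame(mesh), "mesh.tsv", "simulate")

  pipe_log(cfg, "qc", "genotype QC and GRM")
  qc <- qc_filter(geno, cfg$qc_ind_missing_max, cfg$qc_maf_min,
                  cfg$qc_snp_missing_max, cfg$qc_hwe_p_min,
                  pedigree = ped)
  wt(qc$report, "qc_report.tsv", "qc")
  K <- compute_grm(qc$genotypes)
  write_grm(K, file.path(cfg$out_dir, "cohort"))
  pcs <- genetic_pcs(K, n_components = cfg$n_pcs)$vectors

  pipe_log(cfg, "connectivity", "simulating profiles and coupling")
  prof <- simulate_connectivity(mesh, K, h2_coupling = cfg$h2_coupling,
                                seed = stage_seed(cfg, "connectivity"))
  cpl <- compute_coupling(prof, mesh, method = "inner")
  write_coupling(cpl, file.path(cfg$out_dir, "coupling.tsv"))

  pipe_log(cfg, "reml", "per-vertex heritability")
  Keig <- grm_eigen(K)
  X <- covariate_design(cov, pcs = pcs)
  h2tab <- do.call(rbind, lapply(colnames(cpl), function(v) {
    fit <- greml(cpl[, v], K_eigen = Keig, X = X)
    data.frame(trait = v, sigma_g2 = fit$sigma_g2,
               sigma_e2 = fit$sigma_e2, h2 = fit$h2, se = fit$se_h2,
               p = fit$p_value, converged = fit$converged)
  }))
  wt(h2tab, "heritability.tsv", "reml")

  res <- list(pedigree = ped, mesh = mesh, qc = qc, grm = K,
              coupling = cpl, heritability = h2tab)

  if (!cfg$run_gwas) {
    pipe_log(cfg, "gwas", "disabled")
    if (cfg$run_loci)
      stop("loci stage requires the gwas stage; enable run_gwas")
    return(invisible(res))
  }

  pipe_log(cfg, "gwas", "association scan on top heritable vertices")
  top <- h2tab$trait[order(-h2tab$h2)][seq_len(cfg$n_gwas_vertices)]
  n_tests <- nrow(qc$genotypes$snp_meta) * length(top)
  thr <- bonferroni_threshold(cfg$gwas_alpha, n_tests)
  assoc_all <- list()
  for (v in top) {
    g <- lmm_gwas(cpl[, v], qc$genotypes, K_eigen = Keig, X = X)
    a <- g$assoc; a$vertex <- v
    assoc_all[[v]] <- a
    write_sumstats(g$assoc,
                   file.path(cfg$out_dir, sprintf("gwas_%s.tsv", v)))
  }
  assoc_all <- do.call(rbind, assoc_all)
  res$assoc <- assoc_all
  res$p_threshold <- thr

  if (cfg$run_loci) {
    pipe_log(cfg, "loci", "clumping and merging")
    loci <- define_loci(assoc_all, qc$genotypes, p_threshold = thr,
                        r2_independent = cfg$r2_independent,
                        r2_lead = cfg$r2_lead, merge_kb = cfg$merge_kb)
    wt(as.data.frame(loci), "loci.tsv", "loci")
    res$loci <- loci
  }

  if (cfg$run_enrichment) {
    pipe_log(cfg, "enrich", "network enrichment")
    vl <- map_vertices(mesh, "functional_network")
    lab <- vl$label[match(assoc_all$vertex, vl$vertex_id)]
    enr <- network_enrichment(lab, assoc_all$p_value < thr)
    wt(enr, "enrichment.tsv", "enrich")
    res$enrichment <- enr
  }

  if (cfg$run_rg) {
    pipe_log(cfg, "rg", "pairwise genetic correlation and distance decay")
    sel <- h2tab$trait[order(-h2tab$h2)][seq_len(cfg$n_rg_vertices)]
    rgm <- pairwise_rg(cpl[, sel, drop = FALSE], covariates = cov, K = K,
                       fdr_q = cfg$fdr_q)
    vd <- vertex_distances(mesh, sel)
    long <- rgm$pairs
    long$distance <- vd$dist[cbind(long$vertex_a, long$vertex_b)]
    long$intra_hemisphere <-
      vd$intra_hemisphere[cbind(long$vertex_a, long$vertex_b)]
    wt(long, "genetic_correlation.tsv", "rg")
    res$rg <- rgm
    dec <- tryCatch(fit_distance_decay(long$rg, long$distance),
                    error = function(e) NULL)
    if (!is.null(dec)) {
      wt(data.frame(rss_linear = dec$rss_linear,
                    rss_quadratic = dec$rss_quadratic,
                    rss_difference = dec$rss_difference,
                    f = dec$f_statistic, p = dec$p_value, n = dec$n),
         "distance_decay.tsv", "rg")
      res$distance_decay <- dec
    }
  }
  pipe_log(cfg, "done", sprintf("artifacts in %s", cfg$out_dir))
  invisible(res)
}
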