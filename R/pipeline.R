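#' Default pipeline configuration
#'
#' Returns the full run configuration with every procedural constant at its
#' standard value: 50 kb cis window, 3 PCs removed, 10 cis / 1 trans
#' permutation replicates, FDR target 10%, methylation-state bounds 0.3/0.7,
#' 300 bp TSS profile window, 100 bp decay bins, 2 kb promoter rule,
#' 8 matched control sets, 10,000 expression permutations.
#'
#' @param out_dir Output directory for the run.
#' @param seed Master seed.
#' @return A named list (`run_config`).
#' @export
default_run_config <- function(out_dir = "meqtl_run", seed = 1L) {
  list(out_dir = out_dir, seed = as.integer(seed),
       stages = c("simulate", "qc", "preprocess", "describe",
                  "scan-cis", "fdr", "integrate-corr", "integrate-overlap"),
       simulation = list(),          # overrides for sim_config()
       k_pcs = 3L,
       cis_window_bp = 50000,
       secondary_rings_bp = c(2000, 10000, 50000),
       tss_promoter_bp = 2000,
       tss_profile_window_bp = 300,
       decay_bin_bp = 100,
       fdr_target = 0.10,
       n_reps_cis = 10L,
       n_reps_trans = 1L,
       n_perms_expression = 10000L,
       n_control_sets = 8L)
}

#' Read a run configuration from YAML
#'
#' Missing fields fall back to [default_run_config()] values.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  cfg[names(user)] <- user
  cfg
}

# small stable FNV-1a hash of a config for the manifest
config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, ascii = TRUE))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the pipeline end-to-end
#'
#' Executes the configured stages in dependency order on a simulated study,
#' writing stage outputs, structured log lines and a manifest (config hash,
#' seeds, row counts per output) to the run directory. Reruns with the same
#' config produce byte-identical result tables.
#'
#' @param config A `run_config` list (see [default_run_config()]) or a path
#'   to a YAML file.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  req <- c("out_dir", "seed", "stages")
  missing_fields <- req[!req %in% names(config)]
  if (length(missing_fields)) {
    stop("config is missing field(s): ", paste(missing_fields, collapse = ", "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stages = list())
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }
  note <- function(stage, outputs = character(0), rows = integer(0)) {
    manifest$stages[[stage]] <<- list(outputs = outputs,
                                      rows = as.list(rows))
  }

  scfg <- do.call(sim_config, c(config$simulation, list(seed = config$seed)))
  study <- NULL; mset <- NULL; fdr <- NULL; scan <- NULL

  for (stage in config$stages) {
    if (stage == "simulate") {
      study <- simulate_study(scfg)
      paths <- write_simulation(study, file.path(config$out_dir, "simulated"))
      log_stage(stage, "simulated ", scfg$n_probes, " probes, ",
                ncol(study$genotypes$dosage), " SNPs, ",
                scfg$n_individuals, " individuals")
      note(stage, paths, c(probes = scfg$n_probes))
    } else if (stage == "qc") {
      if (is.null(study)) stop("stage 'qc' needs 'simulate' first")
      qc <- filter_probes(study$methylation$probes)
      p <- file.path(config$out_dir, "qc_report.tsv")
      write_qc_report(qc$report, p)
      log_stage(stage, qc$report$n_retained, " of ", qc$report$n_input,
                " probes retained")
      study$methylation$probes <- qc$retained
      note(stage, p, c(retained = qc$report$n_retained))
    } else if (stage == "preprocess") {
      if (is.null(study)) stop("stage 'preprocess' needs 'simulate' first")
      mset <- preprocess_methylation(study$methylation$replicates,
                                     k = config$k_pcs)
      p <- file.path(config$out_dir, "residuals.tsv")
      write_matrix_tsv(mset$residual, p)
      log_stage(stage, "removed ", config$k_pcs, " PCs")
      note(stage, p, c(probes = ncol(mset$beta)))
    } else if (stage == "describe") {
      if (is.null(mset)) stop("stage 'describe' needs 'preprocess' first")
      st <- classify_states(mset$beta)
      dc <- comethylation_decay(mset$beta, study$methylation$probes,
                                bin_bp = config$decay_bin_bp)
      p1 <- file.path(config$out_dir, "state_fractions.tsv")
      utils::write.table(as.data.frame(unclass(st)), p1, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      p2 <- file.path(config$out_dir, "decay_curve.tsv")
      utils::write.table(dc, p2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      log_stage(stage, sprintf("%.1f%% unmethylated",
                               100 * st$fraction_unmethylated))
      note(stage, c(p1, p2), c(decay_bins = nrow(dc)))
    } else if (stage == "scan-cis") {
      if (is.null(mset)) stop("stage 'scan-cis' needs 'preprocess' first")
      scan <- scan_cis(mset$residual, study$genotypes,
                       study$methylation$probes,
                       window_bp = config$cis_window_bp)
      p <- file.path(config$out_dir, "cis_scan.tsv")
      write_association_results(scan$results, p)
      log_stage(stage, nrow(scan$results), " tests over ",
                nrow(scan$best), " probes")
      note(stage, p, c(tests = nrow(scan$results)))
    } else if (stage == "fdr") {
      if (is.null(mset)) stop("stage 'fdr' needs 'preprocess' first")
      fdr <- permutation_fdr(mset$residual, study$genotypes,
                             study$methylation$probes, scan = "cis",
                             n_reps = config$n_reps_cis,
                             target_fdr = config$fdr_target,
                             seed = config$seed,
                             window_bp = config$cis_window_bp)
      p <- file.path(config$out_dir, "fdr_table.tsv")
      write_fdr_table(fdr, p)
      p2 <- file.path(config$out_dir, "discoveries.tsv")
      if (nrow(fdr$discoveries)) write_association_results(fdr$discoveries, p2)
      log_stage(stage, nrow(fdr$discoveries), " discoveries at FDR ",
                config$fdr_target)
      note(stage, c(p, p2), c(discoveries = nrow(fdr$discoveries)))
    } else if (stage == "integrate-corr") {
      if (is.null(mset)) stop("stage 'integrate-corr' needs 'preprocess' first")
      gpm <- build_gene_probe_map(study$methylation$probes,
                                  config$tss_promoter_bp)
      wic <- within_individual_correlation(mset$beta, study$expression, gpm)
      cic <- cross_individual_correlation(
        mset$beta, study$expression, gpm,
        n_perms = min(config$n_perms_expression, 10000L),
        seed = config$seed)
      p <- file.path(config$out_dir, "gene_correlations.tsv")
      utils::write.table(
        data.frame(gene_id = names(cic$r), spearman_r = cic$r),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
      log_stage(stage, "mean within-individual r = ",
                signif(wic$mean, 3))
      note(stage, p, c(genes = length(cic$r)))
    } else if (stage == "integrate-overlap") {
      if (is.null(mset)) stop("stage 'integrate-overlap' needs 'preprocess' first")
      gpm <- build_gene_probe_map(study$methylation$probes,
                                  config$tss_promoter_bp)
      gene_pos <- study$gene_truth[, c("gene_id", "chrom", "tss")]
      ov <- residual_eqtl_analysis(study$expression, mset$beta,
                                   study$genotypes, gpm, gene_pos,
                                   fdr_target = config$fdr_target,
                                   n_reps = config$n_reps_cis,
                                   seed = config$seed,
                                   window_bp = config$cis_window_bp)
      p <- file.path(config$out_dir, "eqtl_overlap.tsv")
      utils::write.table(ov$per_gene, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      log_stage(stage, ov$n_overlap, " shared eQTLs, ",
                ov$n_original_only, " original-only, ",
                ov$n_residual_only, " residual-only")
      note(stage, p, c(overlap = ov$n_overlap))
    } else {
      stop("unknown stage: ", stage)
    }
  }
  manifest_path <- file.path(config$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest)
}
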