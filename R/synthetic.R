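#' Simulation configuration
#'
#' Builds the parameter set for the synthetic-data generator. The generator
#' emulates the statistical structure of a population methylation-array
#' study: trimodal beta values (unmethylated / hemi-methylated / methylated
#' probe classes), two technical replicates per individual, cis SNP effects
#' on a subset of probes, distance-correlated co-methylation within probe
#' clusters, batch and latent confounders loading on leading principal
#' components, and expression negatively coupled to promoter methylation for
#' mediated genes.
#'
#' Genotype effects are expressed on the latent logit-methylation scale in
#' units of the residual (co-methylation) standard deviation, which is 1, so
#' `effect_fixed = 0.5` means a standardized per-allele effect of 0.5.
#'
#' @param n_individuals Number of individuals (default 77).
#' @param n_probes Total number of CpG probes.
#' @param probes_per_gene Probes per gene cluster (one gene per cluster).
#' @param snps_per_cis_window SNPs simulated in each cluster's cis window.
#' @param cis_window_bp Half-width of the cis window in bp.
#' @param maf_range Range for the minor-allele frequency draw, within (0, 0.5].
#' @param ld_rho First-order LD: probability an allele copies its neighbor.
#' @param fraction_probes_with_meqtl Fraction of probes with a causal cis SNP.
#' @param effect_size_sd SD of per-allele effects on the latent logit scale
#'   (effects drawn from N(0, effect_size_sd^2)).
#' @param effect_fixed If non-NULL, causal effects have this magnitude with
#'   random sign instead of being drawn from a normal.
#' @param comethylation_length_scale Exponential co-methylation kernel length
#'   scale in bp (correlation exp(-d / l)).
#' @param probe_spacing_bp Spacing between probes within a cluster.
#' @param cluster_spacing_bp Spacing between cluster centers on a chromosome.
#' @param replicate_noise_sd SD of technical replicate noise on the beta
#'   scale (applied then clipped to \[0, 1\]).
#' @param n_pcs_confounding Number of latent Gaussian confounders.
#' @param confounder_loading_sd SD of per-probe confounder loadings.
#' @param batch_fraction Fraction of individuals in batch level 1 (0 or 1
#'   disables the batch); emulates a two-level processing batch.
#' @param batch_probe_fraction Fraction of probes receiving the batch shift.
#' @param batch_loading_sd SD of the per-probe batch mean shift.
#' @param state_weights Mixture weights of the unmethylated / hemi /
#'   methylated probe baseline classes.
#' @param state_means Logit-scale means of the three baseline classes.
#' @param state_sds Logit-scale SDs of the three baseline classes.
#' @param cgi_fraction Fraction of clusters labelled as CpG-island.
#' @param annotation_fraction Fraction of SNPs carrying the generic
#'   annotation flag (for enrichment-model tests).
#' @param annotation_enrichment Relative odds that a causal SNP carries the
#'   annotation (1 = no enrichment).
#' @param causal_distance_scale Exponential scale (bp) concentrating causal
#'   SNPs near the probe (`Inf` = uniform over the cis window).
#' @param fraction_genes_methylation_mediated Fraction of genes whose
#'   expression is driven (negatively) by promoter methylation.
#' @param fraction_genes_direct_eqtl Fraction of genes with a direct eQTL.
#' @param mediation_strength Ratio of the methylation-driven expression
#'   component's SD to the expression noise SD for mediated genes.
#' @param eqtl_strength Same ratio for direct genotype effects on expression.
#' @param expression_noise_sd SD of expression noise.
#' @param seed Integer seed; all draws are deterministic given the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_individuals = 77,
                       n_probes = 300,
                       probes_per_gene = 3,
                       snps_per_cis_window = 20,
                       cis_window_bp = 50000,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0,
                       fraction_probes_with_meqtl = 0.1,
                       effect_size_sd = 0.5,
                       effect_fixed = NULL,
                       comethylation_length_scale = 1000,
                       probe_spacing_bp = 400,
                       cluster_spacing_bp = 200000,
                       replicate_noise_sd = 0.02,
                       n_pcs_confounding = 0,
                       confounder_loading_sd = 0.3,
                       batch_fraction = 0,
                       batch_probe_fraction = 0.3,
                       batch_loading_sd = 0.5,
                       state_weights = c(0.714, 0.156, 0.130),
                       state_means = stats::qlogis(c(0.10, 0.50, 0.90)),
                       state_sds = c(0.5, 0.3, 0.5),
                       cgi_fraction = 0.5,
                       annotation_fraction = 0.2,
                       annotation_enrichment = 1,
                       causal_distance_scale = Inf,
                       fraction_genes_methylation_mediated = 0.2,
                       fraction_genes_direct_eqtl = 0.2,
                       mediation_strength = 1,
                       eqtl_strength = 1,
                       expression_noise_sd = 1,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_individuals >= 3,
            n_probes >= 1, probes_per_gene >= 1,
            all(maf_range > 0), all(maf_range <= 0.5),
            comethylation_length_scale > 0,
            fraction_probes_with_meqtl >= 0, fraction_probes_with_meqtl <= 1,
            fraction_genes_methylation_mediated >= 0,
            fraction_genes_methylation_mediated <= 1,
            fraction_genes_direct_eqtl >= 0, fraction_genes_direct_eqtl <= 1,
            batch_fraction >= 0, batch_fraction <= 1,
            abs(sum(state_weights) - 1) < 1e-8)
  cfg$n_genes <- as.integer(ceiling(n_probes / probes_per_gene))
  structure(cfg, class = "sim_config")
}

# genomic layout shared by the genotype and methylation simulators:
# one gene cluster per gene, round-robin over 22 autosomes, clusters on the
# same chromosome spaced so cis windows never overlap across genes
sim_layout <- function(config) {
  g <- seq_len(config$n_genes)
  chrom <- as.character(((g - 1L) %% 22L) + 1L)
  idx_on_chr <- (g - 1L) %/% 22L
  center <- 100000 + idx_on_chr *
    max(config$cluster_spacing_bp, 2 * config$cis_window_bp + 10000)
  data.frame(gene_id = sprintf("gene%04d", g), cluster = g,
             chrom = chrom, tss = as.numeric(center),
             stringsAsFactors = FALSE)
}

#' Simulate genotypes
#'
#' Draws per-SNP minor-allele frequencies uniformly from `maf_range` and
#' dosages as Binomial(2, f), with optional first-order LD (each allele is
#' copied from the neighboring SNP with probability `ld_rho`). SNPs that come
#' out monomorphic in the sample are redrawn. Deterministic under the config
#' seed.
#'
#' @param config A [sim_config()].
#' @return A `genotype_matrix` whose map carries the simulation extras
#'   `cluster` and `annotated`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lay <- sim_layout(config)
  n <- config$n_individuals
  s_per <- config$snps_per_cis_window
  ids <- sprintf("ind%03d", seq_len(n))
  dosage_list <- vector("list", nrow(lay))
  map_list <- vector("list", nrow(lay))
  for (k in seq_len(nrow(lay))) {
    pos <- sort(sample.int(2L * config$cis_window_bp + 1L, s_per)) - 1L -
      config$cis_window_bp + lay$tss[k]
    f <- stats::runif(s_per, config$maf_range[1], config$maf_range[2])
    G <- matrix(0, n, s_per)
    for (j in seq_len(s_per)) {
      for (try in 1:50) {
        a1 <- stats::rbinom(n, 1, f[j])
        a2 <- stats::rbinom(n, 1, f[j])
        if (config$ld_rho > 0 && j > 1) {
          # copy alleles from the previous SNP with probability rho
          prev <- G[, j - 1L]
          cp <- stats::runif(n) < config$ld_rho
          g <- ifelse(cp, prev, a1 + a2)
        } else {
          g <- a1 + a2
        }
        if (stats::var(g) > 0) break
      }
      G[, j] <- g
    }
    dosage_list[[k]] <- G
    map_list[[k]] <- data.frame(
      snp_id = sprintf("snp%04d_%02d", k, seq_len(s_per)),
      chrom = lay$chrom[k], pos = pos, cluster = k,
      annotated = stats::runif(s_per) < config$annotation_fraction,
      stringsAsFactors = FALSE)
  }
  dosage <- do.call(cbind, dosage_list)
  map <- do.call(rbind, map_list)
  dimnames(dosage) <- list(ids, map$snp_id)
  geno <- new_genotype_matrix(dosage, map)
  attr(geno, "layout") <- lay
  geno
}

#' Simulate replicate methylation arrays with known truth
#'
#' Latent logit-methylation for probe j in individual i is
#' `m_ij = mu_j + b_j g_i + sum_k w_jk u_ik + batch_i s_j + eps_ij`, where
#' `mu_j` comes from a three-component mixture (unmethylated / hemi /
#' methylated), `b_j` is the causal cis-SNP effect for the subset of causal
#' probes, `u` are latent confounders, and `eps` within each gene cluster is
#' multivariate normal with unit variance and correlation `exp(-d / l)` in
#' inter-probe distance `d`. Beta is the logistic of `m`; two technical
#' replicates add independent beta-scale noise, clipped to \[0, 1\].
#'
#' @param genotypes Output of [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @return A `meth_sim` list: `replicates` (list of two individual x probe
#'   beta matrices), `beta_true` (noiseless beta), `truth` (per-probe truth
#'   table incl. causal SNP id, latent slope, and the standardized slope
#'   `slope_std` = latent slope over latent SD), `probes` (probe annotation),
#'   `confounders`, `batch`.
#' @export
simulate_methylation <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  lay <- attr(genotypes, "layout")
  if (is.null(lay)) stop("genotypes must come from simulate_genotypes()")
  if (config$probes_per_gene < 2 && config$comethylation_length_scale > 0) {
    warning("probes_per_gene < 2: co-methylation decay is untestable")
  }
  n <- config$n_individuals
  ppg <- config$probes_per_gene
  n_probes <- config$n_probes
  map <- genotypes$map

  # probe annotation: probes downstream of the TSS (plus strand), so
  # tss_distance equals the within-cluster offset
  cluster_of <- rep(seq_len(config$n_genes), each = ppg)[seq_len(n_probes)]
  offset <- ((seq_len(n_probes) - 1L) %% ppg) * config$probe_spacing_bp
  cgi_cluster <- stats::runif(config$n_genes) < config$cgi_fraction
  probes <- data.frame(
    probe_id = sprintf("cg%05d", seq_len(n_probes)),
    chrom = lay$chrom[cluster_of],
    position = lay$tss[cluster_of] + offset,
    gene_id = lay$gene_id[cluster_of],
    tss_distance = offset,
    in_cgi = cgi_cluster[cluster_of],
    maps_uniquely = TRUE, contains_snp = FALSE, overlaps_cnv = FALSE,
    cluster = cluster_of,
    stringsAsFactors = FALSE)

  # baseline class mixture
  cls <- sample.int(3L, n_probes, replace = TRUE, prob = config$state_weights)
  mu <- stats::rnorm(n_probes, config$state_means[cls], config$state_sds[cls])

  # causal SNP assignment
  causal <- stats::runif(n_probes) < config$fraction_probes_with_meqtl
  b <- numeric(n_probes)
  if (is.null(config$effect_fixed)) {
    b[causal] <- stats::rnorm(sum(causal), 0, config$effect_size_sd)
  } else {
    b[causal] <- config$effect_fixed *
      sample(c(-1, 1), sum(causal), replace = TRUE)
  }
  causal_snp <- rep(NA_character_, n_probes)
  for (j in which(causal)) {
    cand <- which(map$cluster == probes$cluster[j] &
                    abs(map$pos - probes$position[j]) <= config$cis_window_bp)
    if (!length(cand)) { causal[j] <- FALSE; b[j] <- 0; next }
    w <- exp(log(config$annotation_enrichment) * map$annotated[cand] -
               abs(map$pos[cand] - probes$position[j]) /
                 config$causal_distance_scale)
    causal_snp[j] <- map$snp_id[cand[sample.int(length(cand), 1L, prob = w)]]
  }

  # confounders and batch
  kq <- config$n_pcs_confounding
  U <- if (kq > 0) matrix(stats::rnorm(n * kq), n, kq) else NULL
  W <- if (kq > 0) {
    matrix(stats::rnorm(n_probes * kq, 0, config$confounder_loading_sd),
           n_probes, kq)
  } else NULL
  batch <- rep(0L, n)
  bshift <- numeric(n_probes)
  if (config$batch_fraction > 0 && config$batch_fraction < 1) {
    batch <- as.integer(seq_len(n) <= round(n * config$batch_fraction))
    hit <- stats::runif(n_probes) < config$batch_probe_fraction
    bshift[hit] <- stats::rnorm(sum(hit), 0, config$batch_loading_sd)
  }

  # co-methylation residuals per cluster: correlation exp(-d / l), unit sd
  eps <- matrix(0, n, n_probes)
  for (k in seq_len(config$n_genes)) {
    jj <- which(probes$cluster == k)
    if (!length(jj)) next
    d <- abs(outer(probes$position[jj], probes$position[jj], "-"))
    S <- exp(-d / config$comethylation_length_scale)
    Uc <- chol(S + diag(1e-10, length(jj)))
    eps[, jj] <- matrix(stats::rnorm(n * length(jj)), n) %*% Uc
  }

  m <- matrix(rep(mu, each = n), n, n_probes) + eps
  gmat <- genotypes$dosage
  for (j in which(causal)) {
    m[, j] <- m[, j] + b[j] * gmat[, causal_snp[j]]
  }
  if (kq > 0) m <- m + U %*% t(W)
  if (any(bshift != 0)) m <- m + outer(batch, bshift)

  beta_true <- stats::plogis(m)
  dimnames(beta_true) <- list(rownames(gmat), probes$probe_id)
  clip01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }
  reps <- list(
    rep1 = clip01(beta_true + stats::rnorm(length(beta_true), 0,
                                           config$replicate_noise_sd)),
    rep2 = clip01(beta_true + stats::rnorm(length(beta_true), 0,
                                           config$replicate_noise_sd)))
  reps <- lapply(reps, function(x) { dimnames(x) <- dimnames(beta_true); x })

  f <- map$maf[match(causal_snp, map$snp_id)]
  conf_var <- if (kq > 0) rowSums(W^2) else 0
  batch_q <- mean(batch)
  sd_latent <- sqrt(ifelse(causal, b^2 * 2 * f * (1 - f), 0) +
                      conf_var + bshift^2 * batch_q * (1 - batch_q) + 1)
  truth <- data.frame(
    probe_id = probes$probe_id, gene_id = probes$gene_id,
    cluster = probes$cluster, chrom = probes$chrom,
    position = probes$position,
    causal_snp = causal_snp, maf = f,
    slope_latent = b, sd_latent = sd_latent,
    slope_std = b / sd_latent,
    stringsAsFactors = FALSE)

  structure(list(replicates = reps, beta_true = beta_true, truth = truth,
                 probes = probes, confounders = U, batch = batch),
            class = "meth_sim")
}

#' Simulate expression coupled to promoter methylation and direct eQTLs
#'
#' Expression of gene j is `e_ij = c_j beta_ij(promoter) [mediated] +
#' d_j g_it [direct eQTL] + eta_ij`, shifted per gene so all values are
#' non-negative. `c_j < 0` for mediated genes; its magnitude is set so the
#' methylation-driven component has SD `mediation_strength` times the noise
#' SD, and analogously for `d_j` via `eqtl_strength`.
#'
#' @param methylation A `meth_sim` from [simulate_methylation()].
#' @param genotypes The matching `genotype_matrix`.
#' @param config The same [sim_config()].
#' @return List with `expression` (individual x gene matrix, values >= 0)
#'   and `gene_truth` (per-gene mediation flag, coefficients, promoter probe,
#'   direct-eQTL SNP, TSS position).
#' @export
simulate_expression <- function(methylation, genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  lay <- attr(genotypes, "layout")
  probes <- methylation$probes
  n <- config$n_individuals
  ng <- config$n_genes
  map <- genotypes$map
  sig <- config$expression_noise_sd

  mediated <- stats::runif(ng) < config$fraction_genes_methylation_mediated
  direct <- stats::runif(ng) < config$fraction_genes_direct_eqtl
  expr <- matrix(stats::rnorm(n * ng, 0, sig), n, ng,
                 dimnames = list(rownames(genotypes$dosage), lay$gene_id))
  c_coef <- numeric(ng); d_coef <- numeric(ng)
  promoter <- rep(NA_character_, ng); esnp <- rep(NA_character_, ng)
  for (k in seq_len(ng)) {
    jj <- which(probes$cluster == k)
    if (!length(jj)) { mediated[k] <- FALSE; direct[k] <- FALSE; next }
    promoter[k] <- probes$probe_id[jj[1L]]
    if (mediated[k]) {
      bcol <- methylation$beta_true[, promoter[k]]
      sdb <- stats::sd(bcol)
      if (sdb < 1e-8) { mediated[k] <- FALSE } else {
        c_coef[k] <- -config$mediation_strength * sig / sdb
        expr[, k] <- expr[, k] + c_coef[k] * bcol
      }
    }
    if (direct[k]) {
      cand <- which(map$cluster == k)
      esnp[k] <- map$snp_id[cand[sample.int(length(cand), 1L)]]
      g <- genotypes$dosage[, esnp[k]]
      d_coef[k] <- sample(c(-1, 1), 1L) * config$eqtl_strength * sig /
        stats::sd(g)
      expr[, k] <- expr[, k] + d_coef[k] * g
    }
  }
  expr <- sweep(expr, 2, apply(expr, 2, min))  # shift to >= 0
  gene_truth <- data.frame(
    gene_id = lay$gene_id, chrom = lay$chrom, tss = lay$tss,
    mediated = mediated, c_coef = c_coef, promoter_probe = promoter,
    direct_snp = esnp, d_coef = d_coef, stringsAsFactors = FALSE)
  list(expression = expr, gene_truth = gene_truth)
}

#' Simulate a full study
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_methylation()] and [simulate_expression()] under one config.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes`, `methylation`, `expression`, `gene_truth`
#'   and the `config`.
#' @export
simulate_study <- function(config) {
  geno <- simulate_genotypes(config)
  meth <- simulate_methylation(geno, config)
  expr <- simulate_expression(meth, geno, config)
  list(genotypes = geno, methylation = meth,
       expression = expr$expression, gene_truth = expr$gene_truth,
       config = config)
}

#' Build a probe universe with prescribed QC defect counts
#'
#' Emits exactly the requested numbers of multi-mapping, SNP-containing,
#' CNV-overlapping and clean probes. Defect categories are disjoint:
#' SNP and CNV defects are assigned only among uniquely-mapping probes,
#' mirroring sequential QC accounting.
#'
#' @param clean Number of defect-free probes.
#' @param multimap Number of multi-mapping probes.
#' @param snp Number of uniquely-mapping probes containing a SNP.
#' @param cnv Number of uniquely-mapping probes overlapping a CNV.
#' @param fraction_autosomal Fraction of clean probes placed on autosomes
#'   (the rest go to the X chromosome).
#' @return Probe annotation data.frame with QC flags set accordingly.
#' @export
simulate_probe_universe <- function(clean, multimap = 0, snp = 0, cnv = 0,
                                    fraction_autosomal = 1) {
  counts <- c(clean = clean, multimap = multimap, snp = snp, cnv = cnv)
  if (any(counts < 0)) stop("probe counts must be non-negative")
  total <- sum(counts)
  cat_lab <- rep(names(counts), counts)
  n_clean <- counts[["clean"]]
  chrom <- rep("1", total)
  if (n_clean > 0 && fraction_autosomal < 1) {
    idx <- which(cat_lab == "clean")
    n_x <- round(n_clean * (1 - fraction_autosomal))
    if (n_x > 0) chrom[idx[seq_len(n_x)]] <- "X"
  }
  data.frame(
    probe_id = sprintf("cg%06d", seq_len(total)),
    chrom = chrom,
    position = 1000 * seq_len(total),
    gene_id = sprintf("gene%06d", seq_len(total)),
    tss_distance = 0L,
    in_cgi = FALSE,
    maps_uniquely = cat_lab != "multimap",
    contains_snp = cat_lab == "snp",
    overlaps_cnv = cat_lab == "cnv",
    stringsAsFactors = FALSE)
}

#' Write a simulated study to disk in the package's file formats
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             snp_map = file.path(dir, "snp_map.tsv"),
             rep1 = file.path(dir, "beta_rep1.tsv"),
             rep2 = file.path(dir, "beta_rep2.tsv"),
             probes = file.path(dir, "probes.tsv"),
             expression = file.path(dir, "expression.tsv"),
             probe_truth = file.path(dir, "probe_truth.tsv"),
             gene_truth = file.path(dir, "gene_truth.tsv"))
  write_matrix_tsv(study$genotypes$dosage, paths["genotypes"])
  utils::write.table(study$genotypes$map, paths["snp_map"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(study$methylation$replicates[[1]], paths["rep1"])
  write_matrix_tsv(study$methylation$replicates[[2]], paths["rep2"])
  utils::write.table(study$methylation$probes, paths["probes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(study$expression, paths["expression"])
  utils::write.table(study$methylation$truth, paths["probe_truth"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$gene_truth, paths["gene_truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
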