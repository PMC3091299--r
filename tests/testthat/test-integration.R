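make_integration_study <- function(...) {
  cfg <- small_config(n_individuals = 80, n_probes = 60, probes_per_gene = 2,
                      probe_spacing_bp = 300, snps_per_cis_window = 8,
                      fraction_probes_with_meqtl = 0.6, effect_fixed = 1.5,
                      ...)
  simulate_study(cfg)
}

test_that("gene-probe pairing keeps the nearest promoter probe within 2 kb", {
  ann <- data.frame(probe_id = c("a", "b", "c", "d"),
                    gene_id = c("g1", "g1", "g1", "g2"),
                    tss_distance = c(500, -200, 2500, 1999))
  map <- build_gene_probe_map(ann)
  expect_equal(map$probe_id[map$gene_id == "g1"], "b")  # nearest, within 2 kb
  expect_equal(map$probe_id[map$gene_id == "g2"], "d")
  ann2 <- data.frame(probe_id = c("x", "y"), gene_id = "g3",
                     tss_distance = c(300, -300))
  expect_equal(build_gene_probe_map(ann2)$probe_id, "x")  # tie -> probe_id
})

test_that("within-individual correlation hits -1 for anti-monotone expression", {
  study <- make_integration_study(seed = 71)
  gpm <- build_gene_probe_map(study$methylation$probes)
  b <- study$methylation$beta_true
  e <- -b[, gpm$probe_id, drop = FALSE]
  colnames(e) <- gpm$gene_id
  out <- within_individual_correlation(b, e, gpm)
  expect_true(all(out$per_individual == -1))
  expect_equal(out$mean, -1)
})

test_that("within-individual correlation is near zero under independence and
           negative under mediation", {
  study0 <- make_integration_study(fraction_genes_methylation_mediated = 0,
                                   fraction_genes_direct_eqtl = 0, seed = 73)
  gpm <- build_gene_probe_map(study0$methylation$probes)
  out0 <- within_individual_correlation(study0$methylation$beta_true,
                                        study0$expression, gpm)
  expect_lt(abs(out0$mean), 0.15)
  study1 <- make_integration_study(fraction_genes_methylation_mediated = 0.6,
                                   mediation_strength = 3, seed = 74)
  out1 <- within_individual_correlation(study1$methylation$beta_true,
                                        study1$expression, gpm)
  expect_lt(out1$mean, -0.3)
})

test_that("cross-individual permutation enrichment flags mediated structure
           and is deterministic under seed", {
  study <- make_integration_study(fraction_genes_methylation_mediated = 1,
                                  mediation_strength = 2, seed = 79)
  gpm <- build_gene_probe_map(study$methylation$probes)
  cic <- cross_individual_correlation(study$methylation$beta_true,
                                      study$expression, gpm,
                                      n_perms = 500, seed = 3)
  expect_lt(mean(cic$r), -0.3)
  expect_equal(unname(cic$p["lower5"]), 1 / 501)
  cic2 <- cross_individual_correlation(study$methylation$beta_true,
                                       study$expression, gpm,
                                       n_perms = 500, seed = 3)
  expect_identical(cic$p, cic2$p)
})

test_that("cross-individual tail counts stay inside the null band without
           mediation", {
  study <- make_integration_study(fraction_genes_methylation_mediated = 0,
                                  fraction_genes_direct_eqtl = 0, seed = 83)
  gpm <- build_gene_probe_map(study$methylation$probes)
  cic <- cross_individual_correlation(study$methylation$beta_true,
                                      study$expression, gpm,
                                      n_perms = 500, seed = 5)
  # under the null the observed counts are exchangeable with permuted ones
  expect_true(all(cic$p > 0.01))
})

test_that("matched control sets reproduce the case (MAF, distance) histogram", {
  set.seed(87)
  cases <- data.frame(snp_id = paste0("c", 1:40),
                      maf = runif(40, 0.05, 0.5),
                      distance = runif(40, -50000, 50000))
  pool <- data.frame(snp_id = paste0("q", 1:4000),
                     maf = runif(4000, 0.05, 0.5),
                     distance = runif(4000, -50000, 50000))
  mc <- matched_control_sets(cases, pool, n_sets = 8, seed = 7)
  expect_length(mc$sets, 8)
  bin_of <- function(df) {
    mb <- findInterval(df$maf, mc$maf_edges, rightmost.closed = TRUE)
    db <- findInterval(abs(df$distance), mc$dist_edges,
                       rightmost.closed = TRUE)
    table(paste(mb, db, sep = ":"))
  }
  want <- bin_of(cases)
  for (s in mc$sets) {
    expect_equal(nrow(s), 40)
    got <- bin_of(s)
    expect_equal(got[names(want)], want)
    expect_false(any(s$snp_id %in% cases$snp_id))
    expect_false(anyDuplicated(s$snp_id) > 0 && length(mc$flagged_cells) == 0)
  }
  # pool = duplicated cases: the binned (MAF, distance) histogram matches
  # the cases' exactly, so the chi-square distance between them is zero
  pool2 <- cases
  pool2$snp_id <- paste0("dup", 1:40)
  mc2 <- matched_control_sets(cases, rbind(pool2, pool2, pool2, pool2,
                                           pool2, pool2, pool2, pool2),
                              n_sets = 2, seed = 9)
  edges <- mc2$maf_edges
  for (s in mc2$sets) {
    h_case <- table(findInterval(cases$maf, edges, rightmost.closed = TRUE))
    h_ctrl <- table(findInterval(s$maf, edges, rightmost.closed = TRUE))
    expect_equal(sum((h_ctrl - h_case)^2), 0)
  }
})

test_that("a matched cell with no eligible pool members raises an error", {
  cases <- data.frame(snp_id = c("c1", "c2"), maf = c(0.1, 0.4),
                      distance = c(100, 2000))
  # pool holds only the case SNPs themselves, which are excluded
  expect_error(matched_control_sets(cases, cases, n_sets = 2,
                                    n_maf_bins = 2, n_distance_bins = 1),
               "cell")
})

test_that("meQTL SNPs dominate matched controls as eQTLs under mediation", {
  study <- make_integration_study(fraction_genes_methylation_mediated = 1,
                                  fraction_genes_direct_eqtl = 0,
                                  mediation_strength = 2, seed = 91)
  mset <- preprocess_methylation(study$methylation$replicates, k = 0)
  tr <- study$methylation$truth
  gt <- study$gene_truth
  causal <- tr[!is.na(tr$causal_snp) &
                 tr$probe_id %in% gt$promoter_probe, ]
  meqtl <- data.frame(snp_id = causal$causal_snp,
                      gene_id = gt$gene_id[match(causal$probe_id,
                                                 gt$promoter_probe)])
  map <- study$genotypes$map
  pos <- map$pos[match(meqtl$snp_id, map$snp_id)]
  pr_pos <- tr$position[match(causal$probe_id, tr$probe_id)]
  cases <- data.frame(snp_id = meqtl$snp_id,
                      maf = map$maf[match(meqtl$snp_id, map$snp_id)],
                      distance = pos - pr_pos)
  pool <- data.frame(snp_id = map$snp_id, maf = map$maf, distance =
                       runif(nrow(map), -50000, 50000))
  mc <- matched_control_sets(cases, pool, n_sets = 4, n_maf_bins = 2,
                             n_distance_bins = 2, seed = 13)
  qq <- meqtl_as_eqtl(meqtl, mc$sets, study$expression, study$genotypes,
                      gt[, c("gene_id", "chrom", "tss")])
  med_case <- median(qq$case)
  for (ctrl in qq$controls) expect_gt(med_case, median(ctrl))
})

test_that("single-SNP input yields QQ data of length one", {
  study <- make_integration_study(seed = 95)
  gt <- study$gene_truth
  meqtl <- data.frame(snp_id = study$genotypes$map$snp_id[1],
                      gene_id = gt$gene_id[1])
  qq <- meqtl_as_eqtl(meqtl, list(), study$expression, study$genotypes,
                      gt[, c("gene_id", "chrom", "tss")])
  expect_length(qq$case, 1)
})

test_that("residual-eQTL analysis removes mediated eQTLs and keeps direct
           ones", {
  cfg <- small_config(n_individuals = 120, n_probes = 120,
                      probes_per_gene = 1, snps_per_cis_window = 10,
                      fraction_probes_with_meqtl = 1, effect_fixed = 2,
                      fraction_genes_methylation_mediated = 0.4,
                      fraction_genes_direct_eqtl = 0.4,
                      mediation_strength = 2, eqtl_strength = 2,
                      replicate_noise_sd = 0.01, seed = 97)
  study <- suppressWarnings(simulate_study(cfg))
  mset <- preprocess_methylation(study$methylation$replicates, k = 0)
  gpm <- build_gene_probe_map(study$methylation$probes)
  gt <- study$gene_truth
  ov <- residual_eqtl_analysis(study$expression, mset$beta, study$genotypes,
                               gpm, gt[, c("gene_id", "chrom", "tss")],
                               n_reps = 5, seed = 17)
  med_only <- gt$gene_id[gt$mediated & !(gt$direct_snp %in%
                                           stats::na.omit(gt$direct_snp))]
  mediated <- gt$gene_id[gt$mediated & is.na(gt$direct_snp)]
  direct <- gt$gene_id[!gt$mediated & !is.na(gt$direct_snp)]
  med_in_A <- intersect(mediated, ov$original)
  dir_in_A <- intersect(direct, ov$original)
  skip_if(length(med_in_A) < 5 || length(dir_in_A) < 5,
          "too few discovered genes to assess mediation")
  # mediated eQTLs vanish after regressing out promoter methylation
  expect_gte(mean(!med_in_A %in% ov$residual), 0.8)
  # direct eQTLs survive the adjustment
  expect_gte(mean(dir_in_A %in% ov$residual), 0.9)
})

test_that("without mediation both eQTL pipelines find the same genes", {
  cfg <- small_config(n_individuals = 100, n_probes = 80,
                      probes_per_gene = 1, snps_per_cis_window = 8,
                      fraction_genes_methylation_mediated = 0,
                      fraction_genes_direct_eqtl = 0.5, eqtl_strength = 2,
                      seed = 101)
  study <- suppressWarnings(simulate_study(cfg))
  mset <- preprocess_methylation(study$methylation$replicates, k = 0)
  gpm <- build_gene_probe_map(study$methylation$probes)
  gt <- study$gene_truth
  ov <- residual_eqtl_analysis(study$expression, mset$beta, study$genotypes,
                               gpm, gt[, c("gene_id", "chrom", "tss")],
                               n_reps = 5, seed = 19)
  union_size <- length(union(ov$original, ov$residual))
  skip_if(union_size == 0, "no discoveries")
  expect_gte(ov$n_overlap / union_size, 0.8)
})
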