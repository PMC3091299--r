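test_that("fit_additive handles perfect fit, orthogonality and degenerate input", {
  g <- c(0, 1, 2, 0, 1, 2)
  out <- fit_additive(g, g)
  expect_equal(out$slope, 1)
  expect_equal(out$r2, 1)
  expect_lt(out$p, 1e-12)
  # residualized phenotype is orthogonal to dosage
  y <- rnorm(6)
  yr <- resid(lm(y ~ g))
  expect_lt(abs(fit_additive(g, yr)$slope), 1e-10)
  mono <- fit_additive(rep(1, 6), y)
  expect_true(is.na(mono$p))
  expect_equal(mono$reason, "monomorphic in analyzed subset")
  expect_error(fit_additive(g, rep(2, 6)), "constant phenotype")
  expect_error(fit_additive(g[1:2], y[1:2]), "at least 3")
})

test_that("fit_additive matches the closed-form OLS oracle on random instances", {
  set.seed(101)
  for (rep in 1:1000) {
    n <- sample(4:12, 1)
    g <- rbinom(n, 2, 0.4)
    if (var(g) == 0) next
    y <- rnorm(n)
    if (var(y) == 0) next
    got <- fit_additive(g, y)
    want <- ols_oracle(g, y)
    expect_equal(got$slope, want$slope, tolerance = 1e-12)
    expect_equal(got$se, want$se, tolerance = 1e-12)
    expect_equal(got$stat, want$stat, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    expect_equal(got$r2, want$r2, tolerance = 1e-12)
  }
})

test_that("cis window boundary is inclusive", {
  Y <- matrix(rnorm(30), 10, 3,
              dimnames = list(paste0("i", 1:10), c("pa", "pb", "pc")))
  pm <- data.frame(probe_id = c("pa", "pb", "pc"), chrom = "1",
                   position = c(100000, 100000, 100000))
  d <- matrix(rbinom(30, 2, 0.4), 10, 3,
              dimnames = list(paste0("i", 1:10), c("s_in", "s_edge", "s_out")))
  map <- data.frame(snp_id = colnames(d), chrom = "1",
                    pos = c(100100, 150000, 150001))
  g <- new_genotype_matrix(d, map)
  sc <- scan_cis(Y, g, pm, window_bp = 50000)
  tested <- unique(sc$results$snp_id)
  expect_true(all(c("s_in", "s_edge") %in% tested))
  expect_false("s_out" %in% tested)
})

test_that("the causal SNP is usually the best cis hit at strong effects", {
  cfg <- small_config(n_individuals = 200, n_probes = 100,
                      probes_per_gene = 1, fraction_probes_with_meqtl = 1,
                      effect_fixed = 1, seed = 55)
  study <- suppressWarnings(simulate_study(cfg))
  mset <- preprocess_methylation(study$methylation$replicates, k = 0)
  sc <- scan_cis(mset$residual, study$genotypes, study$methylation$probes)
  tr <- study$methylation$truth
  hit <- sc$best$snp_id[match(tr$probe_id, sc$best$probe_id)] == tr$causal_snp
  expect_gt(mean(hit, na.rm = TRUE), 0.8)
})

test_that("null per-probe best p is stochastically below uniform", {
  cfg <- small_config(n_probes = 150, probes_per_gene = 1,
                      fraction_probes_with_meqtl = 0, seed = 77,
                      snps_per_cis_window = 10)
  study <- suppressWarnings(simulate_study(cfg))
  mset <- preprocess_methylation(study$methylation$replicates, k = 0)
  sc <- scan_cis(mset$residual, study$genotypes, study$methylation$probes)
  bp <- sc$best$p
  expect_lt(median(bp), 0.5)  # min over ~10 tests pulls the median down
  # roughly consistent with the Beta(1, m) envelope for independent tests
  expect_lt(abs(median(bp) - (1 - 0.5^(1 / 10))), 0.06)
})

test_that("scan results are invariant to joint individual reordering", {
  cfg <- small_config(n_probes = 30, seed = 5)
  study <- simulate_study(cfg)
  mset <- preprocess_methylation(study$methylation$replicates, k = 0)
  sc1 <- scan_cis(mset$residual, study$genotypes, study$methylation$probes)
  perm <- sample(nrow(mset$residual))
  g2 <- study$genotypes
  g2$dosage <- g2$dosage[perm, ]
  sc2 <- scan_cis(mset$residual[perm, ], g2, study$methylation$probes)
  expect_equal(sc1$results$p, sc2$results$p, tolerance = 1e-12)
})

test_that("planted trans effects are found and labelled", {
  cfg <- small_config(n_individuals = 200, n_probes = 20,
                      probes_per_gene = 1, fraction_probes_with_meqtl = 0,
                      seed = 66)
  study <- suppressWarnings(simulate_study(cfg))
  mset <- preprocess_methylation(study$methylation$replicates, k = 0)
  # plant an effect of a SNP on another chromosome onto probe 1
  pr <- study$methylation$probes
  map <- study$genotypes$map
  far <- which(map$chrom != pr$chrom[1])[1]
  Y <- mset$residual
  Y[, 1] <- Y[, 1] + 1 * study$genotypes$dosage[, far]
  st <- scan_trans(Y, study$genotypes, pr)
  b1 <- st$best[st$best$probe_id == pr$probe_id[1], ]
  expect_equal(b1$snp_id, map$snp_id[far])
  expect_lt(b1$p, 1e-8)
  expect_equal(b1$label, "trans")
})

test_that("single-SNP candidate mode returns exactly one test per probe", {
  cfg <- small_config(n_probes = 10, probes_per_gene = 1, seed = 9)
  study <- suppressWarnings(simulate_study(cfg))
  mset <- preprocess_methylation(study$methylation$replicates, k = 0)
  snp <- study$genotypes$map$snp_id[1]
  st <- scan_trans(mset$residual, study$genotypes, study$methylation$probes,
                   snp_subset = snp)
  expect_equal(nrow(st$results), ncol(mset$residual))
  expect_equal(unique(st$results$snp_id), snp)
  expect_error(scan_trans(mset$residual, study$genotypes,
                          study$methylation$probes, max_tests = 10),
               "force")
})

test_that("derived-phenotype scan finds a PC equal to a SNP's dosage", {
  cfg <- small_config(n_probes = 10, probes_per_gene = 1, seed = 14)
  study <- suppressWarnings(simulate_study(cfg))
  g <- study$genotypes
  snp <- g$map$snp_id[7]
  phen <- g$dosage[, snp] + rnorm(nrow(g$dosage), 0, 1e-6)
  names(phen) <- rownames(g$dosage)
  res <- scan_derived_phenotypes(phen, g)
  expect_equal(res$snp_id[which.min(res$p)], snp)
  # a mean-beta phenotype is invariant to probe order
  b <- combine_replicates(study$methylation$replicates)
  m1 <- rowMeans(b)
  m2 <- rowMeans(b[, rev(colnames(b))])
  expect_identical(m1, m2)
})

test_that("sex-interaction scan is calibrated under the null and powered
           under opposite slopes", {
  set.seed(19)
  n <- 200
  g <- matrix(rbinom(n, 2, 0.5), n, 1,
              dimnames = list(paste0("i", 1:n), "s1"))
  geno <- new_genotype_matrix(g, data.frame(snp_id = "s1", chrom = "1",
                                            pos = 1000))
  pm <- data.frame(probe_id = "p1", chrom = "1", position = 1200)
  sex <- rep(c("F", "M"), each = n / 2)
  sx <- as.numeric(sex == "M")
  # same slope in both sexes: interaction p uniform over replicates
  ps <- replicate(100, {
    y <- 0.5 * g[, 1] + rnorm(n)
    Y <- matrix(y, n, 1, dimnames = list(rownames(g), "p1"))
    scan_sex_interaction(Y, geno, sex, pm)$interaction_p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 100))
  # opposite slopes: detected
  y <- ifelse(sx == 1, -1, 1) * g[, 1] + rnorm(n)
  Y <- matrix(y, n, 1, dimnames = list(rownames(g), "p1"))
  expect_lt(scan_sex_interaction(Y, geno, sex, pm)$interaction_p, 1e-6)
})

test_that("FDR table arithmetic follows the permuted-over-observed definition", {
  # 3 observed probes at p = 1e-6; permutations average 0.3 probes below it
  obs <- c(1e-6, 1e-6, 1e-6)
  perm <- c(rep(list(1e-7), 3), rep(list(0.5), 7))
  ft <- meqtlmap:::fdr_table_from_best(obs, perm, target_fdr = 0.1)
  expect_equal(ft$table$threshold, 1e-6)
  expect_equal(ft$table$n_observed, 3)
  expect_equal(ft$table$mean_permuted, 0.3)
  expect_equal(ft$table$fdr, 0.1)
  expect_equal(ft$threshold, 1e-6)
})

test_that("on pure null data the estimated FDR is near one and conservative", {
  cfg <- small_config(n_probes = 100, probes_per_gene = 1,
                      fraction_probes_with_meqtl = 0, seed = 23)
  study <- suppressWarnings(simulate_study(cfg))
  mset <- preprocess_methylation(study$methylation$replicates, k = 0)
  fdr <- permutation_fdr(mset$residual, study$genotypes,
                         study$methylation$probes, n_reps = 10, seed = 23)
  # median estimated FDR over the grid should sit near 1 under the null
  expect_gt(median(fdr$table$fdr), 0.5)
  expect_equal(nrow(fdr$discoveries),
               if (is.na(fdr$threshold)) 0L else
                 sum(fdr$best$p <= fdr$threshold))
})

test_that("permutation FDR is bit-reproducible and respects the seed", {
  cfg <- small_config(n_probes = 60, probes_per_gene = 1, seed = 29)
  study <- suppressWarnings(simulate_study(cfg))
  mset <- preprocess_methylation(study$methylation$replicates, k = 0)
  f1 <- permutation_fdr(mset$residual, study$genotypes,
                        study$methylation$probes, n_reps = 3, seed = 11)
  f2 <- permutation_fdr(mset$residual, study$genotypes,
                        study$methylation$probes, n_reps = 3, seed = 11)
  expect_identical(f1$table, f2$table)
  f3 <- permutation_fdr(mset$residual, study$genotypes,
                        study$methylation$probes, n_reps = 3, seed = 12)
  expect_false(identical(f1$table$mean_permuted, f3$table$mean_permuted))
})
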