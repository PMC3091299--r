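#' Single-locus additive association fit
#'
#' Ordinary least squares of a phenotype on a SNP dosage with intercept:
#' the slope is the phenotype change per minor-allele copy, tested with a
#' two-sided t test on n - 2 degrees of freedom; r2 is the squared sample
#' correlation.
#'
#' @param dosage Numeric dosage vector.
#' @param phenotype Numeric phenotype vector of the same length.
#' @return List with `slope`, `se`, `stat`, `p`, `r2`, `n`; `NULL` with a
#'   "monomorphic" message attribute is never returned — constant dosage
#'   yields a list of `NA`s with `reason = "monomorphic in analyzed subset"`.
#' @export
fit_additive <- function(dosage, phenotype) {
  ok <- !is.na(dosage) & !is.na(phenotype)
  g <- dosage[ok]; y <- phenotype[ok]
  n <- length(g)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::var(y) == 0) stop("constant phenotype")
  if (stats::var(g) == 0) {
    return(list(slope = NA_real_, se = NA_real_, stat = NA_real_,
                p = NA_real_, r2 = NA_real_, n = n,
                reason = "monomorphic in analyzed subset"))
  }
  gc <- g - mean(g); yc <- y - mean(y)
  sxx <- sum(gc^2); sxy <- sum(gc * yc); syy <- sum(yc^2)
  slope <- sxy / sxx
  df <- n - 2
  rss <- syy - slope * sxy
  se <- sqrt(max(rss, 0) / df / sxx)
  stat <- if (se > 0) slope / se else sign(slope) * Inf
  p <- 2 * stats::pt(-abs(stat), df)
  list(slope = slope, se = se, stat = stat, p = p,
       r2 = sxy^2 / (sxx * syy), n = n)
}

# vectorized OLS of one phenotype against many centered SNP columns
# Gc: centered n x m dosage block, sxx: its column sums of squares
ols_block <- function(Gc, sxx, yc, syy, df) {
  sxy <- drop(crossprod(Gc, yc))
  slope <- sxy / sxx
  rss <- pmax(syy - slope * sxy, 0)
  se <- sqrt(rss / df / sxx)
  stat <- ifelse(se > 0, slope / se, sign(slope) * Inf)
  p <- 2 * stats::pt(-abs(stat), df)
  list(slope = slope, se = se, stat = stat, p = p,
       r2 = sxy^2 / (sxx * syy))
}

# shared-individual preparation for repeated scans over the same genotype
# panel: intersects individuals, centers dosages once, and indexes each
# probe's cis SNPs (all SNPs for trans)
prepare_scan <- function(phenotypes, genotypes, probe_map,
                         window_bp = 50000, mode = c("cis", "trans"),
                         snp_subset = NULL) {
  mode <- match.arg(mode)
  inds <- intersect(rownames(phenotypes), rownames(genotypes$dosage))
  if (length(inds) < 3) stop("fewer than 3 shared individuals")
  if (length(inds) < nrow(phenotypes) ||
      length(inds) < nrow(genotypes$dosage)) {
    message("restricting to ", length(inds), " shared individuals")
  }
  G <- genotypes$dosage[inds, , drop = FALSE]
  map <- genotypes$map
  if (!is.null(snp_subset)) {
    keep <- map$snp_id %in% snp_subset
    G <- G[, keep, drop = FALSE]
    map <- map[keep, , drop = FALSE]
  }
  Y <- phenotypes[inds, , drop = FALSE]
  pm <- probe_map[match(colnames(Y), probe_map$probe_id), ]
  Gc <- scale(G, center = TRUE, scale = FALSE)
  sxx <- colSums(Gc^2)
  usable <- sxx > 0
  idx <- vector("list", ncol(Y))
  for (j in seq_len(ncol(Y))) {
    if (mode == "cis") {
      sel <- which(usable & map$chrom == pm$chrom[j] &
                     abs(map$pos - pm$position[j]) <= window_bp)
    } else {
      sel <- which(usable & is_autosomal(map$chrom))
    }
    idx[[j]] <- sel
  }
  list(Y = Y, Gc = Gc, sxx = sxx, map = map, probe_map = pm, idx = idx,
       n = length(inds), df = length(inds) - 2, mode = mode,
       window_bp = window_bp)
}

# best (minimum) p per probe for a phenotype matrix sharing prep's layout;
# rows of Y may be permuted relative to prep$Y
best_p_per_probe <- function(prep, Y) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  syy <- colSums(Yc^2)
  df <- prep$df
  out <- rep(NA_real_, ncol(Y))
  for (j in seq_along(prep$idx)) {
    sel <- prep$idx[[j]]
    if (!length(sel)) next
    sxy <- drop(crossprod(prep$Gc[, sel, drop = FALSE], Yc[, j]))
    r2 <- sxy^2 / (prep$sxx[sel] * syy[j])
    r2max <- min(max(r2), 1)
    tmax <- sqrt(r2max * df / max(1 - r2max, 1e-300))
    out[j] <- 2 * stats::pt(-tmax, df)
  }
  out
}

scan_full_table <- function(prep) {
  res <- vector("list", length(prep$idx))
  Yc <- scale(prep$Y, center = TRUE, scale = FALSE)
  syy <- colSums(Yc^2)
  for (j in seq_along(prep$idx)) {
    sel <- prep$idx[[j]]
    if (!length(sel)) next
    o <- ols_block(prep$Gc[, sel, drop = FALSE], prep$sxx[sel],
                   Yc[, j], syy[j], prep$df)
    same_chr <- prep$map$chrom[sel] == prep$probe_map$chrom[j]
    res[[j]] <- data.frame(
      probe_id = prep$probe_map$probe_id[j],
      snp_id = prep$map$snp_id[sel],
      distance = ifelse(same_chr,
                        prep$map$pos[sel] - prep$probe_map$position[j],
                        NA_real_),
      slope = o$slope, se = o$se, stat = o$stat, p = o$p, r2 = o$r2,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

best_rows <- function(results) {
  if (is.null(results) || !nrow(results)) return(results)
  ad <- abs(results$distance)
  ad[is.na(ad)] <- Inf
  o <- order(results$probe_id, results$p, ad, results$snp_id)
  r <- results[o, ]
  r[!duplicated(r$probe_id), , drop = FALSE]
}

#' Cis meQTL scan
#'
#' Tests every SNP within `window_bp` (inclusive) of each probe on the same
#' chromosome with the additive model, returning the full result table and
#' the best SNP per probe (minimum p; ties broken by smaller |distance|,
#' then snp_id).
#'
#' @param phenotypes Individual x probe matrix (typically PC-corrected
#'   residuals).
#' @param genotypes A `genotype_matrix`.
#' @param probe_map Probe annotation with `probe_id`, `chrom`, `position`.
#' @param window_bp Cis window half-width in bp (default 50,000).
#' @return A `qtl_scan`: list with `results`, `best`, `no_test` (probes
#'   without any cis SNP), `window_bp`, `n_individuals`.
#' @export
scan_cis <- function(phenotypes, genotypes, probe_map, window_bp = 50000) {
  prep <- prepare_scan(phenotypes, genotypes, probe_map, window_bp, "cis")
  results <- scan_full_table(prep)
  no_test <- prep$probe_map$probe_id[vapply(prep$idx, length, 1L) == 0]
  structure(list(results = results, best = best_rows(results),
                 no_test = no_test, window_bp = window_bp,
                 n_individuals = prep$n, mode = "cis"),
            class = "qtl_scan")
}

#' Genome-wide (trans) scan
#'
#' Tests all autosomal SNPs against each probe and labels each probe's best
#' hit cis if the SNP lies within `cis_label_bp` of the probe on the same
#' chromosome, trans otherwise. Supports probe and SNP subsets
#' (candidate-region mode). Refuses scans above `max_tests` pairings unless
#' `force = TRUE`.
#'
#' @param phenotypes Individual x probe matrix.
#' @param genotypes A `genotype_matrix`.
#' @param probe_map Probe annotation with `probe_id`, `chrom`, `position`.
#' @param probe_subset,snp_subset Optional id vectors to restrict the scan.
#' @param cis_label_bp Distance defining the cis label (default 50,000).
#' @param max_tests Guard on the number of (probe, SNP) tests.
#' @param force Override the guard.
#' @return A `qtl_scan` with `results`, `best` (including a `label` column,
#'   "cis"/"trans"), `mode = "trans"`.
#' @export
scan_trans <- function(phenotypes, genotypes, probe_map,
                       probe_subset = NULL, snp_subset = NULL,
                       cis_label_bp = 50000, max_tests = 2e7,
                       force = FALSE) {
  if (!is.null(probe_subset)) {
    phenotypes <- phenotypes[, intersect(colnames(phenotypes), probe_subset),
                             drop = FALSE]
  }
  prep <- prepare_scan(phenotypes, genotypes, probe_map,
                       mode = "trans", snp_subset = snp_subset)
  n_tests <- sum(vapply(prep$idx, length, 1L))
  if (n_tests > max_tests && !force) {
    stop("scan would run ", n_tests, " tests (> max_tests); use force = TRUE")
  }
  results <- scan_full_table(prep)
  best <- best_rows(results)
  best$label <- ifelse(!is.na(best$distance) &
                         abs(best$distance) <= cis_label_bp, "cis", "trans")
  structure(list(results = results, best = best,
                 no_test = character(0), window_bp = cis_label_bp,
                 n_individuals = prep$n, mode = "trans"),
            class = "qtl_scan")
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat("qtl_scan (", x$mode, "): ",
      if (is.null(x$results)) 0L else nrow(x$results), " tests, ",
      if (is.null(x$best)) 0L else nrow(x$best), " probes, ",
      x$n_individuals, " individuals\n", sep = "")
  invisible(x)
}

#' Scan derived methylation phenotypes against all SNPs
#'
#' Tests a derived per-individual phenotype — e.g. a principal-component
#' loading vector or the genome-wide mean beta — against every autosomal
#' SNP with the additive model. Phenotypes are rank-normalized before
#' testing.
#'
#' @param phenotype Named numeric vector (or single-column matrix) per
#'   individual, or an individual x k matrix of derived phenotypes.
#' @param genotypes A `genotype_matrix`.
#' @return data.frame with `phenotype`, `snp_id`, `slope`, `se`, `stat`,
#'   `p`, `r2`, ordered by phenotype then p.
#' @export
scan_derived_phenotypes <- function(phenotype, genotypes) {
  if (is.null(dim(phenotype))) {
    phenotype <- matrix(phenotype, ncol = 1,
                        dimnames = list(names(phenotype), "derived"))
  }
  Y <- apply(phenotype, 2, rank_to_normal)
  dimnames(Y) <- dimnames(phenotype)
  inds <- intersect(rownames(Y), rownames(genotypes$dosage))
  if (length(inds) < 3) stop("fewer than 3 shared individuals")
  Y <- Y[inds, , drop = FALSE]
  G <- genotypes$dosage[inds, , drop = FALSE]
  keep <- is_autosomal(genotypes$map$chrom) | is.na(genotypes$map$chrom)
  G <- G[, keep, drop = FALSE]
  Gc <- scale(G, center = TRUE, scale = FALSE)
  sxx <- colSums(Gc^2)
  ok <- sxx > 0
  df <- length(inds) - 2
  out <- lapply(seq_len(ncol(Y)), function(j) {
    yc <- Y[, j] - mean(Y[, j])
    o <- ols_block(Gc[, ok, drop = FALSE], sxx[ok], yc, sum(yc^2), df)
    data.frame(phenotype = colnames(Y)[j], snp_id = colnames(G)[ok],
               slope = o$slope, se = o$se, stat = o$stat, p = o$p,
               r2 = o$r2, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$phenotype, res$p, res$snp_id), ]
}

#' Sex-by-genotype interaction scan
#'
#' Fits `phenotype ~ dosage + sex + dosage:sex` for every cis (probe, SNP)
#' pair and reports the interaction-term t-test p-value. Pairs where the
#' SNP is monomorphic within either sex are skipped with a reason.
#'
#' @param phenotypes Individual x probe matrix.
#' @param genotypes A `genotype_matrix`.
#' @param sex Two-level vector per individual (named or in `phenotypes` row
#'   order).
#' @param probe_map Probe annotation with `probe_id`, `chrom`, `position`.
#' @param window_bp Cis window (default 50,000).
#' @return data.frame with `probe_id`, `snp_id`, `interaction_beta`,
#'   `interaction_p`, `skipped_reason` (NA when tested).
#' @export
scan_sex_interaction <- function(phenotypes, genotypes, sex, probe_map,
                                 window_bp = 50000) {
  if (!is.null(names(sex))) sex <- sex[rownames(phenotypes)]
  sexf <- as.factor(sex)
  if (nlevels(droplevels(sexf)) != 2) stop("both sexes must be represented")
  if (min(table(droplevels(sexf))) < 3) {
    stop("each sex needs at least 3 individuals")
  }
  prep <- prepare_scan(phenotypes, genotypes, probe_map, window_bp, "cis")
  s01 <- as.numeric(sexf == levels(droplevels(sexf))[2])[
    match(rownames(prep$Y), rownames(phenotypes))]
  rows <- list()
  for (j in seq_along(prep$idx)) {
    sel <- prep$idx[[j]]
    y <- prep$Y[, j]
    for (sidx in sel) {
      g <- prep$Gc[, sidx] # centered; interaction inference is unaffected
      snp <- prep$map$snp_id[sidx]
      pid <- prep$probe_map$probe_id[j]
      if (stats::var(g[s01 == 0]) == 0 || stats::var(g[s01 == 1]) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          probe_id = pid, snp_id = snp, interaction_beta = NA_real_,
          interaction_p = NA_real_,
          skipped_reason = "monomorphic within a sex",
          stringsAsFactors = FALSE)
        next
      }
      X <- cbind(1, g, s01, g * s01)
      fit <- stats::lm.fit(X, y)
      df <- length(y) - 4
      rss <- sum(fit$residuals^2)
      XtXinv <- chol2inv(chol(crossprod(X)))
      se4 <- sqrt(rss / df * XtXinv[4, 4])
      tstat <- fit$coefficients[4] / se4
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = pid, snp_id = snp,
        interaction_beta = unname(fit$coefficients[4]),
        interaction_p = 2 * stats::pt(-abs(tstat), df),
        skipped_reason = NA_character_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# FDR table arithmetic: threshold grid is the sorted observed best-p values;
# FDR(t) = mean permuted count of probes with best p <= t over the observed
# count; selected threshold is the largest t with FDR <= target
fdr_table_from_best <- function(obs_best, perm_best, target_fdr) {
  obs <- sort(obs_best[!is.na(obs_best)])
  grid <- unique(obs)
  n_obs <- vapply(grid, function(t) sum(obs <= t), 0)
  perm_counts <- vapply(perm_best, function(pb) {
    pb <- pb[!is.na(pb)]
    vapply(grid, function(t) sum(pb <= t), 0)
  }, numeric(length(grid)))
  mean_perm <- if (length(grid) == 1L) mean(perm_counts) else
    rowMeans(matrix(perm_counts, nrow = length(grid)))
  fdr <- ifelse(n_obs > 0, mean_perm / n_obs, NA_real_)
  tab <- data.frame(threshold = grid, n_observed = n_obs,
                    mean_permuted = mean_perm, fdr = fdr)
  ok <- which(!is.na(fdr) & fdr <= target_fdr)
  threshold <- if (length(ok)) max(grid[ok]) else NA_real_
  list(table = tab, threshold = threshold)
}

#' Permutation-based FDR for a QTL scan
#'
#' Estimates the false discovery rate as the ratio of permuted to observed
#' discoveries, taking the best signal per probe. Each permutation replicate
#' applies one joint permutation of individual labels to the whole phenotype
#' matrix — breaking the genotype-phenotype linkage while preserving
#' inter-probe correlation — and reruns the scan, recording the best p per
#' probe. `FDR(t)` = mean permuted count of probes with best p <= t, divided
#' by the observed count; the selected threshold is the largest observed
#' best-p value with estimated FDR at or below the target. A per-probe
#' independent permutation mode is available for comparison.
#'
#' @param phenotypes Individual x probe residual matrix.
#' @param genotypes A `genotype_matrix`.
#' @param probe_map Probe annotation with `probe_id`, `chrom`, `position`.
#' @param scan `"cis"` (default 10 replicates) or `"trans"` (default 1).
#' @param n_reps Number of permutation replicates (defaults by scan type).
#' @param target_fdr Target FDR (default 0.10).
#' @param seed Integer seed for the permutations.
#' @param window_bp Cis window (default 50,000).
#' @param permute `"joint"` (default) or `"per-probe"`.
#' @return An `fdr_table`: list with `table` (threshold grid with observed
#'   and mean permuted counts and estimated FDR), `threshold`, `discoveries`
#'   (best rows of discovered probes), `best` (observed best per probe),
#'   `target_fdr`, `n_reps`, `seed`.
#' @export
permutation_fdr <- function(phenotypes, genotypes, probe_map,
                            scan = c("cis", "trans"), n_reps = NULL,
                            target_fdr = 0.10, seed = 1L,
                            window_bp = 50000,
                            permute = c("joint", "per-probe")) {
  scan <- match.arg(scan)
  permute <- match.arg(permute)
  if (is.null(n_reps)) n_reps <- if (scan == "cis") 10L else 1L
  if (n_reps < 1) stop("n_reps must be >= 1")
  prep <- prepare_scan(phenotypes, genotypes, probe_map, window_bp,
                       mode = scan)
  results <- scan_full_table(prep)
  best <- best_rows(results)
  obs_best <- best$p[match(prep$probe_map$probe_id, best$probe_id)]
  set.seed(seed)
  n <- prep$n
  perm_best <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    Yp <- if (permute == "joint") {
      prep$Y[sample.int(n), , drop = FALSE]
    } else {
      apply(prep$Y, 2, function(col) col[sample.int(n)])
    }
    perm_best[[r]] <- best_p_per_probe(prep, Yp)
  }
  ft <- fdr_table_from_best(obs_best, perm_best, target_fdr)
  discoveries <- if (is.na(ft$threshold)) best[0, ] else
    best[best$p <= ft$threshold, , drop = FALSE]
  structure(list(table = ft$table, threshold = ft$threshold,
                 discoveries = discoveries, best = best,
                 target_fdr = target_fdr, n_reps = n_reps, seed = seed,
                 scan = scan, permute = permute),
            class = "fdr_table")
}

#' @export
print.fdr_table <- function(x, ...) {
  cat("permutation FDR (", x$scan, ", ", x$n_reps, " replicates): ",
      nrow(x$discoveries), " discoveries at target FDR ",
      x$target_fdr, sep = "")
  if (!is.na(x$threshold)) cat(" (p <= ", signif(x$threshold, 3), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Write an FDR table grid to TSV
#' @param fdr An `fdr_table`.
#' @param path Output path.
#' @export
write_fdr_table <- function(fdr, path) {
  utils::write.table(fdr$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
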