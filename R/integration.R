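#' Map genes to their promoter methylation probe
#'
#' Pairs each gene with the probe nearest its TSS among probes within
#' `max_tss_bp` (default 2 kb); ties broken by smaller |distance| then
#' probe_id. Genes without such a probe are omitted.
#'
#' @param annotations Probe annotation with `probe_id`, `gene_id`,
#'   `tss_distance`.
#' @param max_tss_bp Promoter window around the TSS (default 2000).
#' @return data.frame with `gene_id`, `probe_id`, `tss_distance`.
#' @export
build_gene_probe_map <- function(annotations, max_tss_bp = 2000) {
  ann <- annotations[!is.na(annotations$tss_distance) &
                       abs(annotations$tss_distance) <= max_tss_bp, ]
  ann <- ann[order(ann$gene_id, abs(ann$tss_distance), ann$probe_id), ]
  ann <- ann[!duplicated(ann$gene_id), ]
  data.frame(gene_id = ann$gene_id, probe_id = ann$probe_id,
             tss_distance = ann$tss_distance, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Within-individual methylation-expression correlation
#'
#' For each individual, the Spearman correlation across genes between
#' promoter beta and expression, using one probe per gene (nearest to the
#' TSS within the promoter window).
#'
#' @param beta Individual x probe beta matrix.
#' @param expression Individual x gene expression matrix.
#' @param gene_probe_map From [build_gene_probe_map()].
#' @return List with `per_individual` (named vector of Spearman r) and
#'   `mean`.
#' @export
within_individual_correlation <- function(beta, expression, gene_probe_map) {
  map <- gene_probe_map[gene_probe_map$gene_id %in% colnames(expression) &
                          gene_probe_map$probe_id %in% colnames(beta), ]
  if (nrow(map) < 10) stop("fewer than 10 genes with a mapped promoter probe")
  inds <- intersect(rownames(beta), rownames(expression))
  B <- beta[inds, map$probe_id, drop = FALSE]
  E <- expression[inds, map$gene_id, drop = FALSE]
  r <- vapply(seq_along(inds), function(i) {
    suppressWarnings(stats::cor(B[i, ], E[i, ], method = "spearman",
                                use = "pairwise.complete.obs"))
  }, 0)
  names(r) <- inds
  list(per_individual = r, mean = mean(r, na.rm = TRUE))
}

#' Cross-individual methylation-expression correlation with permutation
#' enrichment
#'
#' Per-gene Spearman correlation across individuals between promoter beta
#' and expression. The null is built by jointly permuting the individual
#' labels of expression relative to methylation (preserving inter-gene
#' correlation). Tail cutoffs are fixed at the observed correlation
#' distribution's own 25% and 5% quantiles (both tails); the permuted
#' statistic is the count of genes beyond those fixed cutoffs, and each
#' tail's empirical p is the fraction of permutations with a count at least
#' as large as observed.
#'
#' @param beta Individual x probe beta matrix.
#' @param expression Individual x gene expression matrix.
#' @param gene_probe_map From [build_gene_probe_map()].
#' @param n_perms Number of permutations (default 10,000).
#' @param seed Integer seed.
#' @return A `gene_correlation` list: `r` (per-gene Spearman), `cutoffs`,
#'   `observed_counts`, `permuted_mean_counts`, `p` (per tail),
#'   `n_perms`.
#' @export
cross_individual_correlation <- function(beta, expression, gene_probe_map,
                                         n_perms = 10000, seed = 1L) {
  if (n_perms < 100) warning("n_perms < 100 gives poor p-value resolution")
  map <- gene_probe_map[gene_probe_map$gene_id %in% colnames(expression) &
                          gene_probe_map$probe_id %in% colnames(beta), ]
  inds <- intersect(rownames(beta), rownames(expression))
  if (length(inds) < 20) stop("fewer than 20 shared individuals")
  n <- length(inds)
  # standardized ranks: Spearman r reduces to a cross product
  std_rank <- function(M) {
    R <- apply(M, 2, rank)
    scale(R)
  }
  B <- std_rank(beta[inds, map$probe_id, drop = FALSE])
  E <- std_rank(expression[inds, map$gene_id, drop = FALSE])
  r_obs <- colSums(B * E) / (n - 1)
  cutoffs <- stats::quantile(r_obs, c(0.05, 0.25, 0.75, 0.95),
                             names = FALSE)
  names(cutoffs) <- c("lower5", "lower25", "upper25", "upper5")
  count_tails <- function(r) {
    c(lower5 = sum(r <= cutoffs["lower5"]),
      lower25 = sum(r <= cutoffs["lower25"]),
      upper25 = sum(r >= cutoffs["upper25"]),
      upper5 = sum(r >= cutoffs["upper5"]))
  }
  obs_counts <- count_tails(r_obs)
  set.seed(seed)
  perm_counts <- matrix(0, n_perms, 4,
                        dimnames = list(NULL, names(obs_counts)))
  for (s in seq_len(n_perms)) {
    Ep <- E[sample.int(n), , drop = FALSE]
    perm_counts[s, ] <- count_tails(colSums(B * Ep) / (n - 1))
  }
  p <- (1 + colSums(sweep(perm_counts, 2, obs_counts, ">="))) / (n_perms + 1)
  structure(list(r = stats::setNames(r_obs, map$gene_id), cutoffs = cutoffs,
                 observed_counts = obs_counts,
                 permuted_mean_counts = colMeans(perm_counts),
                 p = p, n_perms = n_perms, seed = seed),
            class = "gene_correlation")
}

#' @export
print.gene_correlation <- function(x, ...) {
  cat("cross-individual methylation-expression correlation over",
      length(x$r), "genes; mean r =", signif(mean(x$r), 3), "\n")
  cat("tail enrichment p (", x$n_perms, " permutations): ",
      paste(names(x$p), signif(x$p, 3), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Sample control SNP sets matched on MAF and distance-to-probe
#'
#' Bins the case SNPs jointly on MAF (case-set deciles by default) and
#' |distance| (equal case-count bins, default 5) and draws `n_sets` control
#' sets from the pool with identical per-cell counts. Sampling is without
#' replacement within a set; a cell with fewer pool members than needed is
#' sampled with replacement and flagged.
#'
#' @param cases data.frame with `snp_id`, `maf`, `distance`.
#' @param pool data.frame with the same columns; case SNPs are excluded.
#' @param n_sets Number of control sets (default 8).
#' @param n_maf_bins MAF bins (default 10, case deciles).
#' @param n_distance_bins Distance bins (default 5, equal case counts).
#' @param seed Integer seed.
#' @return List with `sets` (list of data.frames), `flagged_cells`
#'   (character vector of cells sampled with replacement).
#' @export
matched_control_sets <- function(cases, pool, n_sets = 8, n_maf_bins = 10,
                                 n_distance_bins = 5, seed = 1L) {
  pool <- pool[!pool$snp_id %in% cases$snp_id, ]
  # bin edges from the case set's quantiles, with open outer bins so pool
  # members slightly outside the case range join the extreme bins
  qs <- function(x, k) {
    e <- unique(stats::quantile(x, seq(0, 1, length.out = k + 1)))
    e[1] <- -Inf; e[length(e)] <- Inf
    unique(e)
  }
  maf_edges <- qs(cases$maf, n_maf_bins)
  dist_edges <- qs(abs(cases$distance), n_distance_bins)
  bin_of <- function(df) {
    mb <- findInterval(df$maf, maf_edges, rightmost.closed = TRUE)
    db <- findInterval(abs(df$distance), dist_edges, rightmost.closed = TRUE)
    paste(mb, db, sep = ":")
  }
  case_bins <- bin_of(cases)
  pool_bins <- bin_of(pool)
  cell_counts <- table(case_bins)
  set.seed(seed)
  flagged <- character(0)
  sets <- vector("list", n_sets)
  for (s in seq_len(n_sets)) sets[[s]] <- list()
  for (cell in names(cell_counts)) {
    need <- cell_counts[[cell]]
    members <- which(pool_bins == cell)
    if (!length(members)) {
      stop("no pool SNPs in matched cell ", cell,
           " (maf_bin:distance_bin) occupied by ", need, " case SNP(s)")
    }
    replace_cell <- length(members) < need * n_sets
    if (replace_cell) flagged <- c(flagged, cell)
    for (s in seq_len(n_sets)) {
      pick <- if (length(members) >= need && !replace_cell) {
        sample(members, need)
      } else {
        sample(members, need, replace = length(members) < need)
      }
      sets[[s]][[cell]] <- pool[pick, , drop = FALSE]
    }
  }
  sets <- lapply(sets, function(sl) {
    out <- do.call(rbind, sl)
    rownames(out) <- NULL
    out
  })
  list(sets = sets, flagged_cells = flagged,
       maf_edges = maf_edges, dist_edges = dist_edges,
       case_bins = case_bins)
}

# assign each SNP the nearest gene TSS within a window
assign_nearest_gene <- function(snp_map, gene_positions, window_bp = 50000) {
  out <- rep(NA_character_, nrow(snp_map))
  for (i in seq_len(nrow(snp_map))) {
    cand <- which(gene_positions$chrom == snp_map$chrom[i] &
                    abs(gene_positions$tss - snp_map$pos[i]) <= window_bp)
    if (!length(cand)) next
    out[i] <- gene_positions$gene_id[
      cand[which.min(abs(gene_positions$tss[cand] - snp_map$pos[i]))]]
  }
  out
}

#' Test meQTL SNPs (and matched controls) as eQTLs
#'
#' Each case SNP is tested for association with its assigned gene's
#' expression (the gene whose promoter probe it is a meQTL for, when given;
#' otherwise the nearest gene TSS within the window); control SNPs get the
#' nearest gene within the window. Expression is rank-normalized per gene.
#' Returns the observed -log10 p sets for cases and each control set.
#'
#' @param meqtl data.frame with `snp_id` and optionally `gene_id`.
#' @param control_sets List of data.frames with `snp_id` (e.g. from
#'   [matched_control_sets()]).
#' @param expression Individual x gene matrix.
#' @param genotypes A `genotype_matrix`.
#' @param gene_positions data.frame with `gene_id`, `chrom`, `tss`.
#' @param window_bp Gene-assignment window (default 50,000).
#' @return List with `case` (sorted -log10 p), `controls` (list of sorted
#'   -log10 p), `n_skipped` (SNPs with no testable gene).
#' @export
meqtl_as_eqtl <- function(meqtl, control_sets, expression, genotypes,
                          gene_positions, window_bp = 50000) {
  inds <- intersect(rownames(expression), rownames(genotypes$dosage))
  E <- apply(expression[inds, , drop = FALSE], 2, rank_to_normal)
  G <- genotypes$dosage[inds, , drop = FALSE]
  skipped <- 0L
  test_set <- function(snps, genes = NULL) {
    if (is.null(genes)) {
      sm <- genotypes$map[match(snps, genotypes$map$snp_id), ]
      genes <- assign_nearest_gene(sm, gene_positions, window_bp)
    }
    p <- rep(NA_real_, length(snps))
    for (i in seq_along(snps)) {
      if (is.na(genes[i]) || !genes[i] %in% colnames(E) ||
          !snps[i] %in% colnames(G)) { skipped <<- skipped + 1L; next }
      fit <- fit_additive(G[, snps[i]], E[, genes[i]])
      p[i] <- fit$p
    }
    sort(-log10(p[!is.na(p)]), decreasing = TRUE)
  }
  case <- test_set(meqtl$snp_id,
                   if ("gene_id" %in% names(meqtl)) meqtl$gene_id else NULL)
  controls <- lapply(control_sets, function(cs) test_set(cs$snp_id))
  list(case = case, controls = controls, n_skipped = skipped)
}

#' Methylation-residual eQTL re-analysis
#'
#' Runs the cis-eQTL pipeline twice: (A) on per-gene rank-normalized
#' expression, and (B) on expression after per-gene least-squares regression
#' on the gene's promoter beta (residuals re-rank-normalized). Both
#' pipelines use the same cis window and permutation-FDR machinery; the
#' report gives the discovery-set overlap at each pipeline's own threshold
#' for the target FDR, plus per-gene best p before and after adjustment.
#' Genes whose promoter beta is constant are left unadjusted and flagged.
#'
#' @param expression Individual x gene matrix.
#' @param beta Individual x probe beta matrix.
#' @param genotypes A `genotype_matrix`.
#' @param gene_probe_map From [build_gene_probe_map()]; genes without a
#'   promoter probe are excluded.
#' @param gene_positions data.frame with `gene_id`, `chrom`, `tss`.
#' @param fdr_target Target FDR (default 0.10).
#' @param n_reps Permutation replicates (default 10).
#' @param seed Integer seed.
#' @param window_bp Cis window around the TSS (default 50,000).
#' @return An `overlap_report`: counts (`n_overlap`, `n_original_only`,
#'   `n_residual_only`), the two discovery sets, per-gene best p
#'   before/after, flagged genes, and the two `fdr_table`s.
#' @export
residual_eqtl_analysis <- function(expression, beta, genotypes,
                                   gene_probe_map, gene_positions,
                                   fdr_target = 0.10, n_reps = 10,
                                   seed = 1L, window_bp = 50000) {
  map <- gene_probe_map[gene_probe_map$gene_id %in% colnames(expression) &
                          gene_probe_map$probe_id %in% colnames(beta), ]
  inds <- intersect(rownames(expression), rownames(beta))
  inds <- intersect(inds, rownames(genotypes$dosage))
  E <- expression[inds, map$gene_id, drop = FALSE]
  B <- beta[inds, map$probe_id, drop = FALSE]
  EA <- apply(E, 2, rank_to_normal)
  rownames(EA) <- inds
  flagged <- character(0)
  EB <- EA
  for (j in seq_len(ncol(E))) {
    b <- B[, j]
    if (stats::var(b, na.rm = TRUE) == 0) {
      flagged <- c(flagged, map$gene_id[j])
      next
    }
    res <- stats::residuals(stats::lm(E[, j] ~ b, na.action =
                                        stats::na.exclude))
    EB[, j] <- rank_to_normal(res)
  }
  gene_pm <- data.frame(probe_id = map$gene_id,
                        chrom = gene_positions$chrom[
                          match(map$gene_id, gene_positions$gene_id)],
                        position = gene_positions$tss[
                          match(map$gene_id, gene_positions$gene_id)],
                        stringsAsFactors = FALSE)
  fdrA <- permutation_fdr(EA, genotypes, gene_pm, scan = "cis",
                          n_reps = n_reps, target_fdr = fdr_target,
                          seed = seed, window_bp = window_bp)
  fdrB <- permutation_fdr(EB, genotypes, gene_pm, scan = "cis",
                          n_reps = n_reps, target_fdr = fdr_target,
                          seed = seed, window_bp = window_bp)
  setA <- fdrA$discoveries$probe_id
  setB <- fdrB$discoveries$probe_id
  per_gene <- data.frame(
    gene_id = map$gene_id,
    p_original = fdrA$best$p[match(map$gene_id, fdrA$best$probe_id)],
    p_residual = fdrB$best$p[match(map$gene_id, fdrB$best$probe_id)],
    stringsAsFactors = FALSE)
  structure(list(n_overlap = length(intersect(setA, setB)),
                 n_original_only = length(setdiff(setA, setB)),
                 n_residual_only = length(setdiff(setB, setA)),
                 original = setA, residual = setB, per_gene = per_gene,
                 flagged = flagged, fdr_original = fdrA,
                 fdr_residual = fdrB),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("eQTL overlap at matched FDR:", x$n_overlap, "shared,",
      x$n_original_only, "original-only,", x$n_residual_only,
      "residual-only\n")
  invisible(x)
}
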