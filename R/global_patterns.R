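#' Classify probes into methylation states
#'
#' Per-probe mean beta over individuals is classified as unmethylated
#' (mean < 0.3), hemi-methylated (0.3 <= mean <= 0.7, both bounds inclusive)
#' or methylated (mean > 0.7), and the three fractions reported.
#'
#' @param beta Individual x probe beta matrix.
#' @param probe_subset Optional character vector of probe ids (columns) to
#'   restrict to.
#' @return A `state_fractions` list: `fraction_unmethylated`,
#'   `fraction_hemi`, `fraction_methylated` (summing to 1) plus `n_probes`.
#' @export
classify_states <- function(beta, probe_subset = NULL) {
  if (!is.null(probe_subset)) {
    beta <- beta[, intersect(probe_subset, colnames(beta)), drop = FALSE]
  }
  if (ncol(beta) == 0) stop("empty probe subset")
  m <- colMeans(beta, na.rm = TRUE)
  n <- length(m)
  structure(list(fraction_unmethylated = sum(m < 0.3) / n,
                 fraction_hemi = sum(m >= 0.3 & m <= 0.7) / n,
                 fraction_methylated = sum(m > 0.7) / n,
                 n_probes = n),
            class = "state_fractions")
}

#' @export
print.state_fractions <- function(x, ...) {
  cat(sprintf("methylation states over %d probes: %.1f%% unmethylated, %.1f%% hemi, %.1f%% methylated\n",
              x$n_probes, 100 * x$fraction_unmethylated,
              100 * x$fraction_hemi, 100 * x$fraction_methylated))
  invisible(x)
}

#' Running-median methylation profile around the TSS
#'
#' For each evaluation point, the median of per-probe mean beta over probes
#' whose signed TSS distance falls within a sliding window centered there.
#' Optionally stratified by gene groups (e.g. expression quartiles).
#'
#' @param beta Individual x probe beta matrix.
#' @param annotations Probe annotation data.frame with `probe_id`,
#'   `tss_distance`, `gene_id`.
#' @param window_bp Sliding-window width in bp (default 300).
#' @param at Evaluation grid of signed distances; defaults to a 50 bp grid
#'   over the observed distance range.
#' @param gene_groups Optional named vector mapping gene_id to a group label;
#'   when given the profile is computed per group.
#' @return data.frame with `distance`, `median_beta`, `n_probes` and (when
#'   stratified) `group`. Empty windows are omitted.
#' @export
tss_profile <- function(beta, annotations, window_bp = 300, at = NULL,
                        gene_groups = NULL) {
  ann <- annotations[match(colnames(beta), annotations$probe_id), ]
  if (anyNA(ann$tss_distance)) stop("tss_distance required for all probes")
  pm <- colMeans(beta, na.rm = TRUE)
  if (is.null(at)) {
    at <- seq(min(ann$tss_distance), max(ann$tss_distance), by = 50)
  }
  half <- window_bp / 2
  profile_one <- function(d, v) {
    res <- lapply(at, function(x) {
      sel <- abs(d - x) <= half
      if (!any(sel)) return(NULL)
      data.frame(distance = x, median_beta = stats::median(v[sel]),
                 n_probes = sum(sel))
    })
    do.call(rbind, res)
  }
  if (is.null(gene_groups)) {
    return(profile_one(ann$tss_distance, pm))
  }
  groups <- gene_groups[ann$gene_id]
  out <- lapply(sort(unique(stats::na.omit(groups))), function(gr) {
    sel <- !is.na(groups) & groups == gr
    p <- profile_one(ann$tss_distance[sel], pm[sel])
    if (!is.null(p)) p$group <- gr
    p
  })
  do.call(rbind, out)
}

#' Split genes into expression quartiles
#'
#' Genes are grouped into four quartiles of mean expression (1 = lowest,
#' 4 = highest); the quartiles partition the genes exhaustively and
#' disjointly.
#'
#' @param expression Individual x gene expression matrix.
#' @return Named integer vector of quartile labels per gene.
#' @export
expression_quartiles <- function(expression) {
  m <- colMeans(expression, na.rm = TRUE)
  q <- stats::quantile(m, c(0.25, 0.5, 0.75))
  out <- findInterval(m, q, left.open = TRUE) + 1L
  names(out) <- colnames(expression)
  out
}

#' Co-methylation decay with genomic distance
#'
#' Spearman rank correlation across individuals for every same-chromosome
#' probe pair within `max_dist_bp`, averaged within distance bins. Also
#' reported stratified by whether both probes are in a CpG island.
#'
#' @param values Individual x probe matrix (beta by default; any monotone
#'   per-individual transform gives identical results).
#' @param annotations Probe annotation data.frame with `probe_id`, `chrom`,
#'   `position` and `in_cgi`.
#' @param max_dist_bp Maximum pair distance (default 5000).
#' @param bin_bp Bin width in bp (default 100).
#' @return A `decay_curve` data.frame: `group` ("all", "both_cgi",
#'   "not_both_cgi"), `bin_left`, `mean_cor`, `n_pairs`. Pairs with fewer
#'   than 3 complete observations are skipped; their count is in
#'   `attr(, "n_skipped")`.
#' @export
comethylation_decay <- function(values, annotations, max_dist_bp = 5000,
                                bin_bp = 100) {
  ann <- annotations[match(colnames(values), annotations$probe_id), ]
  rk <- apply(values, 2, rank, na.last = "keep")
  pairs <- list(); skipped <- 0L
  for (ch in unique(ann$chrom)) {
    jj <- which(ann$chrom == ch)
    if (length(jj) < 2) next
    jj <- jj[order(ann$position[jj])]
    pos <- ann$position[jj]
    for (a in seq_len(length(jj) - 1L)) {
      for (b in (a + 1L):length(jj)) {
        d <- pos[b] - pos[a]
        if (d > max_dist_bp) break
        ok <- stats::complete.cases(rk[, jj[a]], rk[, jj[b]])
        if (sum(ok) < 3) { skipped <- skipped + 1L; next }
        r <- stats::cor(rk[ok, jj[a]], rk[ok, jj[b]], method = "pearson")
        pairs[[length(pairs) + 1L]] <-
          c(d = d, r = r, cgi = ann$in_cgi[jj[a]] && ann$in_cgi[jj[b]])
      }
    }
  }
  if (!length(pairs)) {
    out <- data.frame(group = character(), bin_left = numeric(),
                      mean_cor = numeric(), n_pairs = integer())
    attr(out, "n_skipped") <- skipped
    class(out) <- c("decay_curve", "data.frame")
    return(out)
  }
  pr <- as.data.frame(do.call(rbind, pairs))
  pr$bin <- floor(pr$d / bin_bp) * bin_bp
  summarize <- function(df, label) {
    if (!nrow(df)) return(NULL)
    agg <- stats::aggregate(df$r, by = list(bin_left = df$bin), FUN = mean)
    cnt <- stats::aggregate(df$r, by = list(bin_left = df$bin), FUN = length)
    data.frame(group = label, bin_left = agg$bin_left, mean_cor = agg$x,
               n_pairs = cnt$x)
  }
  out <- rbind(summarize(pr, "all"),
               summarize(pr[pr$cgi == 1, ], "both_cgi"),
               summarize(pr[pr$cgi == 0, ], "not_both_cgi"))
  attr(out, "n_skipped") <- skipped
  class(out) <- c("decay_curve", "data.frame")
  out
}

#' Estimate the half-distance of an exponential co-methylation decay
#'
#' Fits `log(mean_cor) = -d / l` by least squares on the positive bin means
#' of a decay curve and returns `l * log(2)`, the distance at which the
#' correlation halves.
#'
#' @param curve A `decay_curve` (uses the "all" group).
#' @return Half-distance in bp.
#' @export
decay_half_distance <- function(curve) {
  cv <- curve[curve$group == "all" & curve$mean_cor > 0, ]
  if (nrow(cv) < 2) stop("not enough positive bins to fit a decay")
  width <- min(diff(sort(unique(cv$bin_left))))
  mid <- cv$bin_left + width / 2
  fit <- stats::lm(log(cv$mean_cor) ~ 0 + mid, weights = cv$n_pairs)
  ell <- -1 / unname(stats::coef(fit)[1])
  ell * log(2)
}

#' Compare probe means or variances between two probe sets
#'
#' Two-sided Wilcoxon rank-sum test on per-probe mean beta (`"mean-level"`)
#' or per-probe variance (`"variance"`). Exact null for small untied groups,
#' normal approximation with tie correction otherwise (stats::wilcox.test
#' defaults).
#'
#' @param values_A,values_B Individual x probe beta matrices for the two
#'   probe sets (same individuals, different probes).
#' @param statistic `"mean-level"` or `"variance"`.
#' @return List with `p`, `statistic_name`, and the two per-probe summary
#'   vectors.
#' @export
compare_groups <- function(values_A, values_B,
                           statistic = c("mean-level", "variance")) {
  statistic <- match.arg(statistic)
  if (!ncol(values_A) || !ncol(values_B)) stop("both groups must be non-empty")
  f <- if (statistic == "mean-level") {
    function(m) colMeans(m, na.rm = TRUE)
  } else {
    function(m) apply(m, 2, stats::var, na.rm = TRUE)
  }
  a <- f(values_A); b <- f(values_B)
  # ties fall back to the tie-corrected normal approximation silently
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(p = wt$p.value, statistic_name = statistic, summary_A = a,
       summary_B = b)
}

#' Per-probe sex-difference scan
#'
#' Two-sided Wilcoxon rank-sum test of beta between the sexes for every
#' probe (optionally restricted to one chromosome), with Benjamini-Hochberg
#' correction within the scan.
#'
#' @param beta Individual x probe beta matrix.
#' @param sex Character/factor vector per individual with exactly 2 levels.
#' @param annotations Optional probe annotation (for `chromosome`).
#' @param chromosome Optional chromosome to restrict to.
#' @return data.frame with `probe_id`, `p`, `fdr`.
#' @export
sex_difference_scan <- function(beta, sex, annotations = NULL,
                                chromosome = NULL) {
  sex <- as.factor(sex)
  if (nlevels(droplevels(sex)) != 2) stop("both sexes must be represented")
  if (!is.null(chromosome)) {
    if (is.null(annotations)) stop("annotations needed to filter by chromosome")
    keep <- annotations$probe_id[sub("^chr", "", annotations$chrom) ==
                                   sub("^chr", "", chromosome)]
    beta <- beta[, intersect(colnames(beta), keep), drop = FALSE]
  }
  g1 <- sex == levels(droplevels(sex))[1]
  p <- apply(beta, 2, function(x) {
    suppressWarnings(stats::wilcox.test(x[g1], x[!g1])$p.value)
  })
  data.frame(probe_id = colnames(beta), p = unname(p),
             fdr = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE)
}
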