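#' Approximate Bayes factor for an association
#'
#' Asymptotic (Wakefield-style) Bayes factor comparing a normal effect prior
#' N(0, W) against the point null, computed from the estimated slope and its
#' standard error: `ABF = sqrt(se^2 / (se^2 + W)) * exp(z^2 W / (2 (se^2 +
#' W)))` with `z = slope / se`. Values above 1 favor an effect.
#'
#' @param slope Estimated effect(s).
#' @param se Standard error(s), > 0.
#' @param W Prior effect variance (default 0.15^2 on a standardized
#'   phenotype scale).
#' @return Numeric vector of Bayes factors.
#' @export
compute_abf <- function(slope, se, W = 0.15^2) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(W <= 0)) stop("W must be positive")
  z <- slope / se
  v <- se^2
  sqrt(v / (v + W)) * exp(z^2 * W / (2 * (v + W)))
}

#' Distance-bin design columns for SNP-probe pairs
#'
#' Bins |SNP - probe| distance into symmetric bins and returns indicator
#' columns for every bin except the first (nearest), which acts as the
#' reference level.
#'
#' @param distance Signed or unsigned distances in bp.
#' @param edges_bp Bin edges in bp (default `c(0, 1, 2.5, 5, 10, 25, 50) *
#'   1000`); the last bin is open-ended.
#' @return Matrix of 0/1 indicator columns named `dist_<lo>_<hi>kb`.
#' @export
make_distance_bins <- function(distance,
                               edges_bp = c(0, 1, 2.5, 5, 10, 25, 50) * 1000) {
  d <- abs(distance)
  bin <- findInterval(d, edges_bp, left.open = FALSE, rightmost.closed = TRUE)
  bin[bin < 1] <- 1L
  bin[bin >= length(edges_bp)] <- length(edges_bp) - 1L
  nb <- length(edges_bp) - 1L
  lab <- sprintf("dist_%g_%gkb", edges_bp[-length(edges_bp)] / 1000,
                 edges_bp[-1] / 1000)
  out <- matrix(0, length(d), nb, dimnames = list(NULL, lab))
  out[cbind(seq_along(d), bin)] <- 1
  out[, -1, drop = FALSE]  # nearest bin = reference
}

# log-likelihood of the hierarchical model at (lambda, p1):
# per probe j, L_j = (1 - p1) + p1 * sum_i pi_ij(lambda) ABF_ij
hier_loglik <- function(lambda, p1, abf, A, probe_idx) {
  eta <- drop(A %*% lambda)
  contrib <- numeric(length(probe_idx))
  for (j in seq_along(probe_idx)) {
    ii <- probe_idx[[j]]
    w <- exp(eta[ii] - max(eta[ii]))
    pi_ij <- w / sum(w)
    contrib[j] <- log((1 - p1) + p1 * sum(pi_ij * abf[ii]))
  }
  sum(contrib)
}

#' Fit the hierarchical enrichment model for meQTLs
#'
#' Model: each probe harbors at most one meQTL (shared prior probability
#' `p1`); given one exists, the prior that cis SNP i of probe j is the
#' causal SNP is `pi_ij proportional to exp(sum_k lambda_k a_ijk)` over the
#' probe's cis SNPs, where `a_ijk` are annotation indicators (distance bins
#' relative to the probe, TF-binding sites, histone marks, ...). The
#' per-probe marginal likelihood is `(1 - p1) + p1 sum_i pi_ij ABF_ij`;
#' `(lambda, p1)` are estimated by EM (the M-step for lambda is a weighted
#' conditional-logit fit), with 95% confidence intervals from the observed
#' information.
#'
#' @param abf Vector of approximate Bayes factors, one per (probe, SNP) pair.
#' @param annotations Numeric design matrix (same rows) of annotation
#'   columns; typically `cbind(make_distance_bins(d), tfbs = ..., ...)`.
#' @param probe Factor/character vector assigning each row to its probe.
#' @param max_iter Maximum EM iterations (default 200).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @return An `enrichment_fit`: `lambda` (data.frame with estimate, se and
#'   95% CI per annotation), `p1`, `loglik` (trace, non-decreasing),
#'   `converged`, `n_probes`.
#' @export
fit_hierarchical <- function(abf, annotations, probe, max_iter = 200,
                             tol = 1e-6) {
  A <- as.matrix(annotations)
  probe <- as.character(probe)
  stopifnot(length(abf) == nrow(A), length(probe) == nrow(A))
  probe_idx <- split(seq_along(abf), probe)
  if (length(probe_idx) < 20) stop("need at least 20 probes")
  if (any(vapply(probe_idx, length, 1L) < 1)) {
    stop("every probe needs at least one cis SNP")
  }
  p <- ncol(A)
  lambda <- rep(0, p)
  p1 <- 0.5
  trace <- hier_loglik(lambda, p1, abf, A, probe_idx)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step: posterior that probe j has a meQTL (w_j) and, jointly, that
    # SNP i is it (q_ij); sum_i q_ij = w_j
    eta <- drop(A %*% lambda)
    q <- numeric(length(abf))
    w <- numeric(length(probe_idx))
    for (j in seq_along(probe_idx)) {
      ii <- probe_idx[[j]]
      e <- exp(eta[ii] - max(eta[ii]))
      pi_ij <- e / sum(e)
      num <- p1 * pi_ij * abf[ii]
      denom <- (1 - p1) + sum(num)
      q[ii] <- num / denom
      w[j] <- sum(num) / denom
    }
    p1_new <- mean(w)
    # M-step for lambda: maximize sum_j sum_i q_ij log pi_ij(lambda),
    # a probe-weighted conditional-logit log-likelihood
    obj <- function(l) {
      eta <- drop(A %*% l)
      val <- 0
      for (j in seq_along(probe_idx)) {
        ii <- probe_idx[[j]]
        mx <- max(eta[ii])
        val <- val + sum(q[ii] * eta[ii]) -
          w[j] * (mx + log(sum(exp(eta[ii] - mx))))
      }
      -val
    }
    grad <- function(l) {
      eta <- drop(A %*% l)
      g <- numeric(p)
      for (j in seq_along(probe_idx)) {
        ii <- probe_idx[[j]]
        e <- exp(eta[ii] - max(eta[ii]))
        pi_ij <- e / sum(e)
        g <- g + drop(crossprod(A[ii, , drop = FALSE],
                                q[ii] - w[j] * pi_ij))
      }
      -g
    }
    opt <- stats::optim(lambda, obj, grad, method = "BFGS",
                        control = list(maxit = 100))
    lambda_new <- opt$par
    ll <- hier_loglik(lambda_new, p1_new, abf, A, probe_idx)
    if (ll + 1e-8 < trace[length(trace)]) {
      # EM guarantees ascent; a drop indicates an inner-optimizer failure
      warning("log-likelihood decreased at iteration ", it,
              "; keeping previous iterate")
      break
    }
    delta <- ll - trace[length(trace)]
    lambda <- lambda_new; p1 <- p1_new
    trace <- c(trace, ll)
    if (delta < tol) { converged <- TRUE; break }
  }
  # observed-information CIs on (lambda, logit p1)
  par <- c(lambda, stats::qlogis(min(max(p1, 1e-6), 1 - 1e-6)))
  nll <- function(th) {
    -hier_loglik(th[seq_len(p)], stats::plogis(th[p + 1]), abf, A, probe_idx)
  }
  se <- rep(NA_real_, p)
  H <- try(stats::optimHess(par, nll), silent = TRUE)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error")) {
      dv <- diag(V)[seq_len(p)]
      se[dv > 0] <- sqrt(dv[dv > 0])
    }
  }
  lam_tab <- data.frame(annotation = colnames(A), estimate = lambda,
                        se = se, lower = lambda - 1.96 * se,
                        upper = lambda + 1.96 * se,
                        stringsAsFactors = FALSE)
  structure(list(lambda = lam_tab, p1 = p1, loglik = trace,
                 converged = converged, n_probes = length(probe_idx)),
            class = "enrichment_fit")
}

#' @export
print.enrichment_fit <- function(x, ...) {
  cat("hierarchical enrichment fit over", x$n_probes, "probes; p1 =",
      signif(x$p1, 3),
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  print(x$lambda, digits = 3)
  invisible(x)
}

#' Association of meQTL SNPs with secondary probes in distance rings
#'
#' For each meQTL SNP, tests association against every other probe in
#' concentric distance rings around the SNP's original best-associated
#' probe, returning the per-ring p-value sets (QQ-style input). Empty rings
#' are recorded with zero counts.
#'
#' @param best_hits data.frame with `probe_id`, `snp_id` (one row per
#'   meQTL).
#' @param phenotypes Individual x probe residual matrix.
#' @param genotypes A `genotype_matrix`.
#' @param probe_map Probe annotation with `probe_id`, `chrom`, `position`.
#' @param ring_edges_bp Ring boundaries in bp (default 2 kb / 10 kb / 50 kb).
#' @return List with `p_values` (named list of numeric vectors per ring)
#'   and `counts`.
#' @export
secondary_probe_enrichment <- function(best_hits, phenotypes, genotypes,
                                       probe_map,
                                       ring_edges_bp = c(2000, 10000, 50000)) {
  edges <- c(0, sort(ring_edges_bp))
  ring_names <- sprintf("(%g,%g] kb", edges[-length(edges)] / 1000,
                        edges[-1] / 1000)
  pvals <- stats::setNames(vector("list", length(ring_names)), ring_names)
  for (r in seq_along(pvals)) pvals[[r]] <- numeric(0)
  inds <- intersect(rownames(phenotypes), rownames(genotypes$dosage))
  Y <- phenotypes[inds, , drop = FALSE]
  G <- genotypes$dosage[inds, , drop = FALSE]
  for (h in seq_len(nrow(best_hits))) {
    p0 <- best_hits$probe_id[h]
    snp <- best_hits$snp_id[h]
    i0 <- match(p0, probe_map$probe_id)
    if (is.na(i0) || !snp %in% colnames(G)) next
    d <- ifelse(probe_map$chrom == probe_map$chrom[i0],
                abs(probe_map$position - probe_map$position[i0]), Inf)
    for (r in seq_along(ring_names)) {
      sel <- which(d > edges[r] & d <= edges[r + 1] &
                     probe_map$probe_id != p0 &
                     probe_map$probe_id %in% colnames(Y))
      for (j in sel) {
        fit <- fit_additive(G[, snp], Y[, probe_map$probe_id[j]])
        if (!is.na(fit$p)) {
          pvals[[r]] <- c(pvals[[r]], fit$p)
        }
      }
    }
  }
  list(p_values = pvals, counts = vapply(pvals, length, 1L))
}
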