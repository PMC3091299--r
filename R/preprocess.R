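#' Beta value from methylated and unmethylated intensities
#'
#' Beta is the fraction of signal from the methylated beads over the sum of
#' methylated and unmethylated bead signals, `M / (M + U)`, in \[0, 1\].
#' A pair with zero total signal yields a missing value.
#'
#' @param methylated,unmethylated Non-negative intensity vectors.
#' @return Beta values in \[0, 1\]; `NA` where `M + U == 0`.
#' @export
compute_beta <- function(methylated, unmethylated) {
  if (any(methylated < 0, na.rm = TRUE) ||
      any(unmethylated < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative")
  }
  tot <- methylated + unmethylated
  out <- methylated / tot
  out[!is.na(tot) & tot == 0] <- NA_real_
  out
}

#' Convert an intensity-pairs table into per-replicate beta matrices
#'
#' @param intensities Long data.frame as returned by
#'   [read_methylation()] with `layout = "intensity-pairs"`.
#' @return Named list of individual x probe beta matrices, one per replicate.
#' @export
replicates_from_intensities <- function(intensities) {
  beta <- compute_beta(intensities$methylated, intensities$unmethylated)
  inds <- sort(unique(intensities$individual))
  probes <- unique(intensities$probe)
  out <- lapply(split(seq_len(nrow(intensities)), intensities$replicate),
                function(idx) {
                  m <- matrix(NA_real_, length(inds), length(probes),
                              dimnames = list(inds, probes))
                  m[cbind(match(intensities$individual[idx], inds),
                          match(intensities$probe[idx], probes))] <- beta[idx]
                  m
                })
  out
}

#' Quantile-normalize beta values across replicate arrays
#'
#' All arrays (every individual x replicate combination) are forced onto the
#' identical empirical distribution — the mean of the order statistics across
#' arrays — preserving within-array ranks; ties within an array receive the
#' mean of their target quantile values. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param replicates Named list of individual x probe beta matrices with
#'   identical dimnames.
#' @return List of the same shape with normalized values.
#' @export
quantile_normalize_replicates <- function(replicates) {
  if (length(replicates) < 2) stop("need at least 2 replicate arrays")
  dn <- dimnames(replicates[[1]])
  for (r in replicates) {
    if (!identical(colnames(r), dn[[2]]) || !identical(rownames(r), dn[[1]])) {
      stop("replicate arrays must share the same individuals and probes")
    }
  }
  # one array per (individual, replicate): probes in rows, arrays in columns
  n_ind <- nrow(replicates[[1]])
  big <- do.call(cbind, lapply(replicates, t))
  norm <- limma::normalizeQuantiles(big, ties = TRUE)
  out <- replicates
  for (r in seq_along(replicates)) {
    out[[r]] <- t(norm[, (r - 1L) * n_ind + seq_len(n_ind), drop = FALSE])
    dimnames(out[[r]]) <- dn
  }
  out
}

#' Combine replicate arrays into one beta matrix
#'
#' Per (individual, probe) mean over replicates, ignoring missing values;
#' missing only where every replicate is missing.
#'
#' @param replicates Named list of individual x probe beta matrices.
#' @return Individual x probe beta matrix.
#' @export
combine_replicates <- function(replicates) {
  acc <- matrix(0, nrow(replicates[[1]]), ncol(replicates[[1]]),
                dimnames = dimnames(replicates[[1]]))
  cnt <- acc
  for (r in replicates) {
    ok <- !is.na(r)
    acc[ok] <- acc[ok] + r[ok]
    cnt <- cnt + ok
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Rank-based inverse-normal transform
#'
#' Replaces each value by `qnorm((r - 0.5) / n)` where `r` is its average
#' rank among the `n` non-missing values, so the phenotype is marginally
#' standard normal. Monotone in the input; missing values stay missing.
#'
#' @param values Numeric vector with at least 3 non-missing, not all equal.
#' @return Transformed vector.
#' @export
rank_to_normal <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 non-missing values")
  x <- values[ok]
  if (max(x) == min(x)) stop("zero-variance phenotype: all values identical")
  r <- rank(x, ties.method = "average")
  out <- values
  out[ok] <- stats::qnorm((r - 0.5) / n)
  out
}

#' Principal-component correction of a phenotype matrix
#'
#' Computes principal components on the individual x probe matrix
#' (individuals as observations, probe-wise centering, no scaling) and
#' replaces each probe column by its least-squares residual on the first `k`
#' PC loading vectors. Missing values are mean-imputed per probe for the PCA
#' and restored afterwards. `k = 0` returns the input unchanged.
#'
#' @param normalized Individual x probe numeric matrix (typically the
#'   rank-normalized phenotypes).
#' @param k Number of leading components to remove (default 3).
#' @return List with `residual` (same shape as input), `pcs` (individual x
#'   component score matrix) and `var_share` (eigenvalue shares).
#' @export
pc_correct <- function(normalized, k = 3) {
  n <- nrow(normalized)
  if (k < 0) stop("k must be >= 0")
  if (k >= n) stop("k must be smaller than the number of individuals")
  if (k == 0) {
    return(list(residual = normalized,
                pcs = matrix(numeric(0), n, 0), var_share = numeric(0)))
  }
  X <- normalized
  na_idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na_idx)) {
    mu <- colMeans(X, na.rm = TRUE)
    X[na_idx] <- mu[na_idx[, 2L]]
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = k, nv = 0)
  S <- sv$u[, seq_len(k), drop = FALSE]           # orthonormal PC scores
  resid <- Xc - S %*% crossprod(S, Xc)
  dimnames(resid) <- dimnames(normalized)
  if (nrow(na_idx)) resid[na_idx] <- NA_real_
  rownames(S) <- rownames(normalized)
  colnames(S) <- paste0("PC", seq_len(k))
  list(residual = resid, pcs = S,
       var_share = (sv$d^2 / sum(sv$d^2))[seq_len(k)])
}

#' Run the full methylation preprocessing pipeline
#'
#' Fixed stage order: beta computation (if intensities are given), quantile
#' normalization across replicate arrays, replicate combination, per-probe
#' rank-based inverse-normal transform, and PC correction.
#'
#' @param replicates Named list of per-replicate individual x probe beta
#'   matrices (e.g. from [replicates_from_intensities()] or a `meth_sim`).
#' @param k Number of principal components to regress out (default 3).
#' @return A `methylation_set`: list with `beta_raw` (input replicates),
#'   `beta` (combined), `normalized` (rank-normal), `residual`
#'   (PC-corrected), `pcs`, `var_share` and `k`.
#' @export
preprocess_methylation <- function(replicates, k = 3) {
  qn <- quantile_normalize_replicates(replicates)
  beta <- combine_replicates(qn)
  normalized <- apply(beta, 2, rank_to_normal)
  dimnames(normalized) <- dimnames(beta)
  pc <- pc_correct(normalized, k)
  structure(list(beta_raw = replicates, beta = beta, normalized = normalized,
                 residual = pc$residual, pcs = pc$pcs,
                 var_share = pc$var_share, k = k),
            class = "methylation_set")
}

#' @export
print.methylation_set <- function(x, ...) {
  cat("methylation_set:", nrow(x$beta), "individuals x", ncol(x$beta),
      "probes;", x$k, "PCs removed\n")
  invisible(x)
}
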