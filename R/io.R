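#' Read a genotype dosage set
#'
#' Loads SNP genotypes as minor-allele dosages together with a SNP map
#' (chromosome, position, minor-allele frequency). Two formats are supported:
#' a tab-separated dosage matrix (individuals in rows, SNPs in columns, row
#' identifiers in column 1) with a companion map file, or a VCF (GT field
#' only). Missing hard calls are replaced by the per-SNP mean dosage, a
#' simple stand-in for posterior-mean imputed genotypes. Monomorphic SNPs are
#' dropped with a message.
#'
#' @param path Path to the dosage matrix or VCF file.
#' @param format One of `"dosage"` or `"vcf"`.
#' @param map For `format = "dosage"`, path to a tab-separated SNP map with
#'   columns `snp_id`, `chrom`, `pos` (1-based bp); alternatively a
#'   data.frame with those columns.
#' @return A `genotype_matrix`: list with `dosage` (individual x SNP matrix,
#'   values in \[0, 2\]) and `map` (data.frame `snp_id`, `chrom`, `pos`,
#'   `maf`).
#' @export
read_genotypes <- function(path, format = c("dosage", "vcf"), map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dosage") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             row.names = 1, check.names = FALSE)
    dosage <- as.matrix(tab)
    storage.mode(dosage) <- "double"
    if (is.character(map)) {
      map <- utils::read.table(map, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    }
    if (is.null(map)) {
      map <- data.frame(snp_id = colnames(dosage),
                        chrom = NA_character_, pos = NA_integer_,
                        stringsAsFactors = FALSE)
    }
    new_genotype_matrix(dosage, map)
  } else {
    read_genotypes_vcf(path)
  }
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  snp_id <- fix[, "ID"]
  no_id <- is.na(snp_id) | snp_id == "."
  snp_id[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  # allele count of the ALT allele from unphased or phased diploid GT
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), 0))
  }
  dosage <- t(apply(gt, 1, count_alt))
  dimnames(dosage) <- list(snp_id, colnames(gt))
  dosage <- t(dosage)  # individuals x SNPs
  map <- data.frame(snp_id = snp_id,
                    chrom = as.character(fix[, "CHROM"]),
                    pos = as.integer(fix[, "POS"]),
                    stringsAsFactors = FALSE)
  new_genotype_matrix(dosage, map)
}

#' Construct and validate a genotype_matrix
#'
#' Applies the load-time rules shared by all genotype readers: mean-fill of
#' missing dosages, exclusion of all-missing and monomorphic SNPs, and
#' re-orientation to minor-allele dosage so every MAF lies in (0, 0.5].
#'
#' @param dosage Numeric individual x SNP matrix with dimnames.
#' @param map data.frame with at least `snp_id`, `chrom`, `pos`.
#' @return A `genotype_matrix`.
#' @export
new_genotype_matrix <- function(dosage, map) {
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]")
  }
  if (!identical(colnames(dosage), as.character(map$snp_id))) {
    map <- map[match(colnames(dosage), map$snp_id), , drop = FALSE]
    if (anyNA(map$snp_id)) stop("SNP map does not cover all dosage columns")
  }
  all_missing <- colSums(!is.na(dosage)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " SNP(s) with all dosages missing dropped")
    dosage <- dosage[, !all_missing, drop = FALSE]
    map <- map[!all_missing, , drop = FALSE]
  }
  # mean-fill missing dosages per SNP
  if (anyNA(dosage)) {
    mu <- colMeans(dosage, na.rm = TRUE)
    idx <- which(is.na(dosage), arr.ind = TRUE)
    dosage[idx] <- mu[idx[, 2L]]
  }
  # flip to minor-allele dosage, drop monomorphic
  freq <- colMeans(dosage) / 2
  flip <- freq > 0.5
  dosage[, flip] <- 2 - dosage[, flip, drop = FALSE]
  maf <- colMeans(dosage) / 2
  mono <- maf <= 0 | apply(dosage, 2, stats::var) == 0
  if (any(mono)) {
    message(sum(mono), " monomorphic SNP(s) excluded")
    dosage <- dosage[, !mono, drop = FALSE]
    map <- map[!mono, , drop = FALSE]
    maf <- maf[!mono]
  }
  map$maf <- unname(maf)
  rownames(map) <- NULL
  dup <- duplicated(paste(map$chrom, map$pos)) & !is.na(map$pos)
  if (any(dup)) stop("duplicated (chromosome, position) in SNP map")
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "SNPs\n")
  invisible(x)
}

#' Read methylation data
#'
#' Reads either a beta-value matrix (individuals x probes, values in
#' \[0, 1\]) or a long table of per-replicate methylated/unmethylated
#' intensities keyed by (individual, replicate, probe).
#'
#' @param path Path to a tab-separated file.
#' @param layout `"beta-matrix"` or `"intensity-pairs"`.
#' @return For `"beta-matrix"`, a numeric matrix; for `"intensity-pairs"`, a
#'   data.frame with columns `individual`, `replicate`, `probe`,
#'   `methylated`, `unmethylated`.
#' @export
read_methylation <- function(path, layout = c("beta-matrix", "intensity-pairs")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (layout == "beta-matrix") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             row.names = 1, check.names = FALSE)
    beta <- as.matrix(tab)
    storage.mode(beta) <- "double"
    bad <- which(beta < 0 | beta > 1, arr.ind = TRUE)
    if (nrow(bad)) {
      stop("beta values outside [0, 1] at: ",
           paste(sprintf("%s/%s=%g", rownames(beta)[bad[, 1]],
                         colnames(beta)[bad[, 2]], beta[bad]),
                 collapse = ", "))
    }
    beta
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("individual", "replicate", "probe", "methylated", "unmethylated")
    if (!all(need %in% names(tab))) {
      stop("intensity-pairs file must have columns: ",
           paste(need, collapse = ", "))
    }
    key <- paste(tab$individual, tab$replicate, tab$probe, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicated (individual, replicate, probe) key in ", path)
    }
    tab[need]
  }
}

#' Write a beta (or any individual x probe) matrix as TSV
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat),
                   format(as.data.frame(mat), digits = 15, trim = TRUE,
                          scientific = NA),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#' @param path Input path.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  m
}

#' Read genomic intervals from a BED file
#'
#' BED coordinates are 0-based, half-open. Internally all positions are
#' 1-based, so a BED interval with start s and end e contains the 1-based
#' position p iff s < p <= e.
#'
#' @param path Path to a BED3+ file (whitespace-separated).
#' @return An `interval_set`: data.frame with `chrom`, `start`, `end`
#'   (original BED coordinates) and the source name.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("BED file needs at least 3 columns")
  iv <- data.frame(chrom = as.character(tab[[1]]),
                   start = as.numeric(tab[[2]]),
                   end = as.numeric(tab[[3]]),
                   stringsAsFactors = FALSE)
  bad <- which(iv$end <= iv$start)
  if (length(bad)) {
    stop("BED end <= start at line(s): ", paste(bad, collapse = ", "))
  }
  structure(iv, class = c("interval_set", "data.frame"),
            source = basename(path))
}

#' Query interval containment for 1-based points
#'
#' @param intervals An `interval_set` from [read_intervals()].
#' @param chrom Character vector of chromosomes.
#' @param pos Integer vector of 1-based positions (recycled against `chrom`).
#' @return Logical vector: is each point inside at least one interval?
#' @export
point_in_intervals <- function(intervals, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n)
  out <- logical(n)
  for (ch in unique(chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    sel <- which(chrom == ch)
    if (!nrow(iv)) next
    out[sel] <- vapply(pos[sel], function(p) any(iv$start < p & p <= iv$end),
                       logical(1))
  }
  out
}

#' Write an association result table
#'
#' Writes tab-separated results with a fixed header and deterministic row
#' order: probe, then p ascending, ties broken by snp_id.
#'
#' @param results data.frame with columns `probe_id`, `snp_id`, `distance`,
#'   `slope`, `se`, `stat`, `p`, `r2`.
#' @param path Output path.
#' @export
write_association_results <- function(results, path) {
  if (!nrow(results)) stop("results are empty")
  cols <- c("probe_id", "snp_id", "distance", "slope", "se", "stat", "p", "r2")
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols)) {
    stop("results missing columns: ", paste(missing_cols, collapse = ", "))
  }
  results <- results[order(results$probe_id, results$p, results$snp_id), cols]
  num <- vapply(results, is.numeric, logical(1))
  results[num] <- lapply(results[num],
                         function(x) format(x, digits = 15, trim = TRUE))
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an association result table written by [write_association_results()]
#' @param path Input path.
#' @return data.frame of association results.
#' @export
read_association_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
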