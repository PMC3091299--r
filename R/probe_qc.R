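#' Filter methylation probes on mapping and sequence-variant flags
#'
#' Retains probes that map uniquely to the genome, contain no known SNP and
#' overlap no copy-number variant. Removal is attributed sequentially —
#' multi-mapping first, then SNP-containing among the unique mappers, then
#' CNV-overlapping among the remainder — so the report's categories are
#' disjoint and the accounting identity
#' `n_retained = n_input - n_multimap - n_snp - n_cnv` holds exactly.
#'
#' @param annotations Probe annotation data.frame with logical columns
#'   `maps_uniquely`, `contains_snp`, `overlaps_cnv` and a `chrom` column.
#' @return List with `retained` (filtered annotation data.frame) and
#'   `report` (a `qc_report`).
#' @export
filter_probes <- function(annotations) {
  need <- c("maps_uniquely", "contains_snp", "overlaps_cnv")
  for (fl in need) {
    if (!fl %in% names(annotations)) stop("missing flag column: ", fl)
    bad <- is.na(annotations[[fl]])
    if (any(bad)) {
      stop("missing ", fl, " flag for probe(s): ",
           paste(utils::head(annotations$probe_id[bad], 5), collapse = ", "))
    }
  }
  n_input <- nrow(annotations)
  multimap <- !annotations$maps_uniquely
  snp <- annotations$contains_snp & !multimap
  cnv <- annotations$overlaps_cnv & !multimap & !snp
  keep <- !(multimap | snp | cnv)
  retained <- annotations[keep, , drop = FALSE]
  rownames(retained) <- NULL
  report <- structure(list(
    n_input = n_input,
    n_multimap_removed = sum(multimap),
    n_snp_removed = sum(snp),
    n_cnv_removed = sum(cnv),
    n_retained = sum(keep),
    n_autosomal_retained = sum(keep & is_autosomal(annotations$chrom))
  ), class = "qc_report")
  list(retained = retained, report = report)
}

# autosome test: chromosomes 1-22, with or without a "chr" prefix;
# X, Y and mitochondrial probes count as non-autosomal
is_autosomal <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom))
  ch %in% as.character(1:22)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("probe QC report\n")
  cat("  input probes:      ", x$n_input, "\n")
  cat("  multi-mapping:     -", x$n_multimap_removed, "\n")
  cat("  SNP-containing:    -", x$n_snp_removed, "\n")
  cat("  CNV-overlapping:   -", x$n_cnv_removed, "\n")
  cat("  retained:          ", x$n_retained,
      sprintf("(%d autosomal)\n", x$n_autosomal_retained))
  invisible(x)
}

#' Write a QC report as a machine-readable two-column summary
#' @param report A `qc_report`.
#' @param path Output path (TSV: field, value).
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(field = names(unclass(report)),
                   value = unlist(unclass(report)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
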