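#' Read / write spectral-count run tables as TSV
#'
#' Columns: `run_id`, `bait_id`, `is_control`, `tag_class`,
#' `biological_rep`, `technical_rep`, `prey_id`, `psm_count`.
#'
#' @param runs run table data.frame.
#' @param path file path.
#' @export
write_runs_tsv <- function(runs, path) {
  utils::write.table(runs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_runs_tsv
#' @export
read_runs_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("run_id", "bait_id", "is_control", "tag_class",
            "biological_rep", "technical_rep", "prey_id", "psm_count")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("run TSV misses column(s): ", paste(miss, collapse = ", "))
  x$is_control <- as.logical(x$is_control)
  x
}

#' Read / write a TSS table as TSV
#'
#' Columns: `gene_id`, `chrom`, `tss_position` (0-based), `strand`.
#'
#' @param tss TSS data.frame.
#' @param path file path.
#' @export
write_tss_tsv <- function(tss, path) {
  utils::write.table(tss, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tss_tsv
#' @export
read_tss_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss_position", "strand")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("TSS TSV misses column(s): ", paste(miss, collapse = ", "))
  x
}

#' Read / write a long expression table (gene, stage, RPKM) as TSV
#'
#' @param expression data.frame `gene_id`, `stage`, `rpkm`.
#' @param path file path.
#' @export
write_expression_tsv <- function(expression, path) {
  utils::write.table(expression, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "stage", "rpkm")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("expression TSV misses column(s): ", paste(miss, collapse = ", "))
  x
}
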