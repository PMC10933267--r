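# Give two GRanges a shared seqlevel set so cross-chromosome comparisons
# do not warn.
.harmonize <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}

# Coerce a BED-style data.frame (0-based half-open) or GRanges to GRanges.
.as_granges <- function(x, what = "intervals") {
  if (methods::is(x, "GRanges")) return(x)
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop("'", what, "' must be a GRanges or a data.frame with ",
         "chrom/start/end (0-based half-open)")
  if (any(x$start < 0) || any(x$start >= x$end))
    stop("invalid ", what, ": need 0 <= start < end")
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
  if ("name" %in% names(x)) names(gr) <- x$name
  if ("strand" %in% names(x)) GenomicRanges::strand(gr) <- x$strand
  gr
}

#' Read / write BED intervals
#'
#' Thin wrappers around [rtracklayer::import.bed()] /
#' [rtracklayer::export.bed()] returning/accepting the package's BED-style
#' data.frame convention (`chrom`, `start`, `end`, optional `name`,
#' `score`, `strand`; 0-based half-open coordinates).
#'
#' @param path BED file path.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) out$strand <- st
  out
}

#' @rdname read_bed
#' @param intervals BED-style data.frame.
#' @export
write_bed <- function(intervals, path) {
  rtracklayer::export(.as_granges(intervals), path, format = "BED")
  invisible(path)
}

#' Annotate peaks with TSS distance and feature category
#'
#' Each peak is reduced to its midpoint (summit columns are not guaranteed
#' in deposited peak files; pass `summit_col` to use one instead), the
#' nearest transcription start site is found, and the signed distance is
#' reported relative to the gene's strand: negative means upstream of the
#' TSS. Categories are assigned by the first matching rule: absolute
#' distance at most `proximal_bp` (default 1 kb) is a proximal promoter;
#' at most `promoter_bp` (default 3 kb) is the outer promoter window; else
#' a peak whose midpoint falls inside a supplied feature interval takes
#' that feature's class (collapsed to `gene_body` when no class column is
#' given), a midpoint within `downstream_bp` past a feature end is
#' `downstream`, and everything else is `intergenic`. Peaks on
#' chromosomes absent from the TSS table are `intergenic` and flagged
#' `no_tss`.
#'
#' @param peaks BED-style data.frame or GRanges.
#' @param tss data.frame `gene_id`, `chrom`, `tss_position` (0-based
#'   genomic coordinate of the TSS base), `strand`.
#' @param features optional BED-style data.frame of gene bodies (optional
#'   `class` column, e.g. exon/intron).
#' @param proximal_bp,promoter_bp promoter window bounds (bp).
#' @param downstream_bp downstream window past a feature (bp).
#' @param summit_col optional column of `peaks` holding summit positions
#'   to use instead of midpoints.
#' @return list with `peaks` (data.frame adding `midpoint`,
#'   `nearest_gene`, `tss_distance`, `category`, `no_tss`) and
#'   `proportions` (named percentages per category, summing to 100).
#' @export
annotate_peaks <- function(peaks, tss, features = NULL,
                           proximal_bp = 1000L, promoter_bp = 3000L,
                           downstream_bp = 3000L, summit_col = NULL) {
  if (!nrow(tss)) stop("TSS table is empty")
  if (proximal_bp > promoter_bp)
    stop("windows must be ordered: proximal_bp <= promoter_bp")
  pk_gr <- .as_granges(peaks, "peaks")
  pk <- data.frame(chrom = as.character(GenomicRanges::seqnames(pk_gr)),
                   start = GenomicRanges::start(pk_gr) - 1L,
                   end = GenomicRanges::end(pk_gr),
                   stringsAsFactors = FALSE)
  if (!is.null(names(pk_gr))) pk$name <- names(pk_gr)
  pk$midpoint <- if (!is.null(summit_col)) {
    as.integer(peaks[[summit_col]])
  } else {
    as.integer((pk$start + pk$end) %/% 2L)
  }

  # nearest TSS per peak, by absolute midpoint distance; the TSS table is
  # sorted first so tie-breaking is deterministic
  ord <- order(tss$chrom, tss$tss_position, tss$gene_id)
  tss <- tss[ord, , drop = FALSE]
  mid_gr <- GenomicRanges::GRanges(pk$chrom,
                                   IRanges::IRanges(pk$midpoint + 1L,
                                                    width = 1L))
  tss_gr <- GenomicRanges::GRanges(tss$chrom,
                                   IRanges::IRanges(tss$tss_position + 1L,
                                                    width = 1L))
  h <- .harmonize(mid_gr, tss_gr)
  mid_gr <- h[[1]]; tss_gr <- h[[2]]
  hit <- GenomicRanges::nearest(mid_gr, tss_gr, select = "arbitrary",
                                ignore.strand = TRUE)
  pk$nearest_gene <- ifelse(is.na(hit), NA_character_, tss$gene_id[hit])
  raw_d <- pk$midpoint - tss$tss_position[hit]
  on_minus <- !is.na(hit) & tss$strand[hit] == "-"
  pk$tss_distance <- ifelse(is.na(hit), NA_integer_,
                            ifelse(on_minus, -raw_d, raw_d))
  pk$no_tss <- is.na(hit)

  cat <- rep(NA_character_, nrow(pk))
  absd <- abs(pk$tss_distance)
  cat[!pk$no_tss & absd <= proximal_bp] <- "promoter_0-1kb"
  cat[is.na(cat) & !pk$no_tss & absd <= promoter_bp] <- "promoter_1-3kb"
  if (!is.null(features) && nrow(features)) {
    ft_gr <- .as_granges(features, "features")
    hf <- .harmonize(mid_gr, ft_gr)
    ov <- GenomicRanges::findOverlaps(hf[[1]], hf[[2]], select = "first",
                                      ignore.strand = TRUE)
    cls <- if ("class" %in% names(features))
      features$class[ov] else rep("gene_body", length(ov))
    cat[is.na(cat) & !is.na(ov)] <- cls[is.na(cat) & !is.na(ov)]
    # downstream: within downstream_bp past the feature 3' end
    dn_start <- ifelse(features$strand %||na% "+" == "-",
                       pmax(features$start - downstream_bp, 0),
                       features$end)
    dn <- GenomicRanges::GRanges(
      features$chrom,
      IRanges::IRanges(dn_start + 1L, width = downstream_bp))
    hd <- .harmonize(mid_gr, dn)
    ov_dn <- GenomicRanges::findOverlaps(hd[[1]], hd[[2]], select = "first",
                                         ignore.strand = TRUE)
    cat[is.na(cat) & !is.na(ov_dn)] <- "downstream_0-3kb"
  }
  cat[is.na(cat)] <- "intergenic"
  pk$category <- cat

  prop <- 100 * table(pk$category) / nrow(pk)
  list(peaks = pk, proportions = structure(as.numeric(prop),
                                           names = names(prop)))
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

#' Flag peaks overlapping enhancers and compute the overlap proportion
#'
#' Overlap means at least one shared base under half-open interval
#' arithmetic; abutting intervals do not overlap.
#'
#' @param peaks,enhancers BED-style data.frames or GRanges.
#' @return list with `overlaps` (logical per peak) and `proportion`
#'   (percentage of peaks overlapping at least one enhancer).
#' @export
enhancer_overlap <- function(peaks, enhancers) {
  pk <- .as_granges(peaks, "peaks")
  if (!length(pk)) stop("empty peak set: overlap proportion is undefined")
  if (is.data.frame(enhancers) && !nrow(enhancers)) {
    flags <- rep(FALSE, length(pk))
  } else {
    en <- .as_granges(enhancers, "enhancers")
    h <- .harmonize(pk, en)
    flags <- unname(GenomicRanges::countOverlaps(h[[1]], h[[2]],
                                                 ignore.strand = TRUE) > 0)
  }
  list(overlaps = flags, proportion = 100 * mean(flags))
}

#' Compare two peak sets by overlap
#'
#' A peak of one set is "shared" when it overlaps (at least one base,
#' i.e. closest-distance 0) any peak of the other set; each peak counts
#' once regardless of how many partners it overlaps, so the shared counts
#' of the two sides can differ and both are reported.
#'
#' @param a,b BED-style data.frames or GRanges.
#' @return named integer vector `a_only`, `shared_a`, `shared_b`,
#'   `b_only`.
#' @export
compare_peak_sets <- function(a, b) {
  ga <- .as_granges(a, "a")
  if (is.data.frame(b) && !nrow(b))
    return(c(a_only = length(ga), shared_a = 0L, shared_b = 0L, b_only = 0L))
  gb <- .as_granges(b, "b")
  h <- .harmonize(ga, gb)
  ga <- h[[1]]; gb <- h[[2]]
  sa <- GenomicRanges::countOverlaps(ga, gb, ignore.strand = TRUE) > 0
  sb <- GenomicRanges::countOverlaps(gb, ga, ignore.strand = TRUE) > 0
  c(a_only = sum(!sa), shared_a = sum(sa),
    shared_b = sum(sb), b_only = sum(!sb))
}
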