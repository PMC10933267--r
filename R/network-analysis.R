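#' Build a bait x prey AvgSpec matrix
#'
#' @param x a data.frame with `bait_id`, `prey_id` and `avg_spec` columns
#'   (scored or filtered interactions). A prey missing for a bait is 0.
#' @return numeric matrix, baits in rows, preys in columns, both sorted.
#' @export
interactome_matrix <- function(x) {
  baits <- sort(unique(x$bait_id))
  preys <- sort(unique(x$prey_id))
  m <- matrix(0, length(baits), length(preys),
              dimnames = list(baits, preys))
  m[cbind(match(x$bait_id, baits), match(x$prey_id, preys))] <- x$avg_spec
  m
}

#' Bait-bait correlation and Ward clustering of an interactome matrix
#'
#' Computes the Pearson correlation between bait abundance profiles and a
#' hierarchical clustering of the baits by Ward linkage (variance-increase
#' criterion, `ward.D2`) on Euclidean distances between the rows, the
#' convention used by interactome correlation heatmaps. Bait rows with zero
#' variance have undefined correlations: those entries are reported as `NA`
#' and the baits are excluded from the clustering with a warning.
#'
#' @param mat bait x prey matrix, e.g. from [interactome_matrix()].
#' @param log_transform apply `log1p` to the matrix first (off by default).
#' @return list of class `bait_clustering` with `correlation` (matrix),
#'   `hclust` (a [stats::hclust] object, `NULL` when < 2 usable baits),
#'   `newick` (Newick serialization of the dendrogram) and `excluded`
#'   (constant baits left out of the clustering).
#' @export
correlation_cluster <- function(mat, log_transform = FALSE) {
  if (nrow(mat) < 2) stop("need >= 2 baits to cluster")
  if (log_transform) mat <- log1p(mat)
  sds <- apply(mat, 1, stats::sd)
  corr <- suppressWarnings(stats::cor(t(mat)))
  corr[sds == 0, ] <- NA_real_
  corr[, sds == 0] <- NA_real_
  diag(corr) <- ifelse(sds == 0, NA_real_, 1)
  excluded <- rownames(mat)[sds == 0]
  if (length(excluded))
    warning("constant bait profile(s) excluded from clustering: ",
            paste(excluded, collapse = ", "))
  usable <- mat[sds > 0, , drop = FALSE]
  hc <- NULL; newick <- NA_character_
  if (nrow(usable) >= 2) {
    hc <- stats::hclust(stats::dist(usable), method = "ward.D2")
    newick <- ape::write.tree(ape::as.phylo(hc))
  }
  structure(list(correlation = corr, hclust = hc, newick = newick,
                 excluded = excluded),
            class = "bait_clustering")
}

#' @export
print.bait_clustering <- function(x, ...) {
  cat("Bait clustering over", nrow(x$correlation), "baits")
  if (length(x$excluded)) cat(" (", length(x$excluded), " excluded)", sep = "")
  cat("\n")
  invisible(x)
}

#' Overlap of unique preys between two interactome datasets
#'
#' @param bioid,apms data.frames of high-confidence interactions
#'   (`bait_id`, `prey_id`) from the two methods, or character vectors of
#'   prey identifiers.
#' @return named integer vector `c(only_bioid, both, only_apms)` over the
#'   unions of per-bait prey sets.
#' @export
method_overlap <- function(bioid, apms) {
  as_set <- function(x) if (is.data.frame(x)) unique(x$prey_id) else unique(x)
  a <- as_set(bioid); b <- as_set(apms)
  c(only_bioid = length(setdiff(a, b)),
    both = length(intersect(a, b)),
    only_apms = length(setdiff(b, a)))
}

#' Rank preys by the number of baits sharing them (hub analysis)
#'
#' @param hci data.frame of high-confidence interactions (`bait_id`,
#'   `prey_id`).
#' @return data.frame `prey_id`, `n_baits`, sorted by decreasing count and
#'   then lexicographically by prey; attribute `"hubs"` holds all preys at
#'   the maximal count.
#' @export
prey_sharing <- function(hci) {
  pairs <- unique(hci[, c("bait_id", "prey_id")])
  cnt <- table(pairs$prey_id)
  out <- data.frame(prey_id = names(cnt), n_baits = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_baits, out$prey_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "hubs") <- out$prey_id[out$n_baits == max(out$n_baits)]
  out
}

#' Annotate interactions as known or novel against reference PPI lists
#'
#' @param hci data.frame of interactions (`bait_id`, `prey_id`).
#' @param known_ppis a data.frame of known pairs (`bait_id`, `prey_id`) or
#'   a list of such data.frames (one per database); an interaction is
#'   "known" when present in at least one list.
#' @return list with `annotated` (the hci table with a logical `known`
#'   column) and `per_bait` (bait_id, n_known, n_novel).
#' @export
novelty_annotation <- function(hci, known_ppis) {
  if (is.data.frame(known_ppis)) known_ppis <- list(known_ppis)
  key <- function(d) paste(d$bait_id, d$prey_id, sep = "\r")
  known_keys <- unique(unlist(lapply(known_ppis, key)))
  hci$known <- key(hci) %in% known_keys
  baits <- sort(unique(hci$bait_id))
  per_bait <- data.frame(
    bait_id = baits,
    n_known = vapply(baits, function(b) sum(hci$known[hci$bait_id == b]), 1L),
    n_novel = vapply(baits, function(b) sum(!hci$known[hci$bait_id == b]), 1L),
    stringsAsFactors = FALSE)
  rownames(per_bait) <- NULL
  list(annotated = hci, per_bait = per_bait)
}

#' Per-prey Fisher enrichment of a study interactome against a reference
#'
#' For every prey detected in either collection, builds the 2x2 table of
#' (baits detecting the prey vs not) x (study set vs reference set), tests
#' it with a two-sided Fisher exact test (the conventional "sum of tables
#' with probability at most that of the observed" definition), adjusts
#' p-values across preys with Benjamini-Hochberg, and signs each prey by
#' its direction (over- or under-represented among study baits).
#'
#' @param study,reference lists mapping bait id to its character vector of
#'   detected preys (or data.frames with `bait_id`, `prey_id`).
#' @param preys optional prey universe to test; defaults to preys detected
#'   in either collection.
#' @param q_max reporting threshold on the adjusted p (records above it are
#'   still returned, flagged `significant = FALSE`).
#' @return data.frame `prey_id`, `a`, `b`, `c`, `d` (table cells:
#'   study-detecting, study-non-detecting, reference-detecting,
#'   reference-non-detecting), `odds_ratio`, `p`, `q`, `direction`,
#'   `significant`.
#' @export
fisher_vs_reference <- function(study, reference, preys = NULL,
                                q_max = 0.05) {
  as_sets <- function(x) {
    if (is.data.frame(x)) x <- split(x$prey_id, x$bait_id)
    lapply(x, unique)
  }
  study <- as_sets(study); reference <- as_sets(reference)
  if (!length(reference)) stop("zero-size reference set")
  if (length(intersect(names(study), names(reference))))
    stop("study and reference bait collections must be disjoint")
  n_s <- length(study); n_r <- length(reference)
  if (is.null(preys))
    preys <- sort(unique(c(unlist(study), unlist(reference))))
  a <- vapply(preys, function(p)
    sum(vapply(study, function(s) p %in% s, TRUE)), 1L)
  cc <- vapply(preys, function(p)
    sum(vapply(reference, function(s) p %in% s, TRUE)), 1L)
  res <- data.frame(prey_id = preys, a = a, b = n_s - a, c = cc,
                    d = n_r - cc, stringsAsFactors = FALSE)
  tests <- mapply(function(a, b, c, d) {
    ft <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
    c(ft$p.value, unname(ft$estimate))
  }, res$a, res$b, res$c, res$d)
  res$odds_ratio <- tests[2, ]
  res$p <- tests[1, ]
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$direction <- ifelse(res$a / n_s >= res$c / n_r, "over", "under")
  res$significant <- res$q < q_max
  rownames(res) <- NULL
  res
}

#' Cross-reference preys against stage-resolved expression
#'
#' Retains the preys whose expression exceeds `threshold` in at least one
#' stage of the window (strict `>` by default, matching an "RPKM > 1"
#' convention; set `strict = FALSE` for `>=`). Preys absent from the table
#' count as not expressed and are listed in `missing`.
#'
#' @param preys character vector of prey (gene) identifiers.
#' @param expression long data.frame `gene_id`, `stage`, `rpkm`.
#' @param stages stage window to consider.
#' @param threshold expression threshold.
#' @param strict strict (`>`) or inclusive (`>=`) comparison.
#' @return list with `retained` (character vector), `n` (its length) and
#'   `missing` (preys absent from the table).
#' @export
expression_crossref <- function(preys, expression,
                                stages = unique(expression$stage),
                                threshold = 1, strict = TRUE) {
  sub <- expression[expression$stage %in% stages &
                      expression$gene_id %in% preys, , drop = FALSE]
  mx <- tapply(sub$rpkm, sub$gene_id, max)
  ok <- if (strict) mx > threshold else mx >= threshold
  retained <- sort(names(mx)[ok])
  list(retained = retained, n = length(retained),
       missing = sort(setdiff(preys, expression$gene_id)))
}
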