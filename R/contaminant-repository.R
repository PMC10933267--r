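#' Quality-control filter for GFP control runs
#'
#' A control run passes quality control when it detects at least
#' `min_proteins` distinct preys (PSM > 0). The conventional thresholds are
#' 1000 detected proteins for BioID control purifications and 300 for AP-MS;
#' the boundary is inclusive in both cases.
#'
#' @param runs a run table (see [generate_runs()]) restricted to control
#'   runs, or a full table from which `is_control` rows are taken.
#' @param min_proteins minimum number of detected preys for a run to pass.
#' @return list with `passing` (run table of passing runs), `rejected`
#'   (character vector of rejected run ids) and `n_detected` (named vector
#'   of detected-protein counts per run).
#' @export
qc_filter_runs <- function(runs, min_proteins = 1000L) {
  if (!nrow(runs)) stop("'runs' is empty")
  if ("is_control" %in% names(runs)) runs <- runs[runs$is_control, , drop = FALSE]
  if (!nrow(runs)) stop("'runs' contains no control runs")
  if (min_proteins <= 0) stop("'min_proteins' must be positive")
  detected <- runs$psm_count > 0
  n_det <- tapply(runs$prey_id[detected], runs$run_id[detected],
                  function(p) length(unique(p)))
  all_ids <- unique(runs$run_id)
  n_detected <- structure(integer(length(all_ids)), names = all_ids)
  n_detected[names(n_det)] <- as.integer(n_det)
  pass_ids <- names(n_detected)[n_detected >= min_proteins]
  if (!length(pass_ids))
    stop("empty repository: no control run detected at least ",
         min_proteins, " proteins")
  list(passing = runs[runs$run_id %in% pass_ids, , drop = FALSE],
       rejected = setdiff(all_ids, pass_ids),
       n_detected = n_detected)
}

#' Build a tag-stratified contaminant repository from GFP control runs
#'
#' For every prey observed in at least one passing control run, tabulates -
#' per stratum - the percentage of runs in which the prey was detected, its
#' average spectral count over the runs where it was detected (not over all
#' runs), and its maximum spectral count. Strata are `All` (every control
#' run regardless of tag), `NLS` (nuclear-localization-tagged GFPs only)
#' and `MYR` (myristoylated GFPs only); NES-tagged and untagged runs
#' contribute to `All` only. A stratum with zero runs is omitted rather
#' than reported as zeros.
#'
#' @param runs control run table, normally pre-filtered with
#'   [qc_filter_runs()]. If `qc_min_proteins` is given, QC is applied here.
#' @param assay label recorded on the repository, `"BioID"` or `"AP-MS"`.
#' @param qc_min_proteins optional QC threshold; `NULL` skips QC.
#' @return An object of class `contaminant_repository`: a list with
#'   `entries` (data.frame: prey_id, stratum, n_runs, pct, avg_spec,
#'   max_spec), `n_runs` (named vector of run counts per stratum), `assay`
#'   and `qc_min_proteins`.
#' @export
#' @examples
#' sim <- generate_runs(sim_config(seed = 1, n_baits = 2, n_preys = 300))
#' repo <- build_repository(sim$runs[sim$runs$is_control, ], assay = "BioID")
#' repo
build_repository <- function(runs, assay = c("BioID", "AP-MS"),
                             qc_min_proteins = NULL) {
  assay <- match.arg(assay)
  if ("is_control" %in% names(runs)) runs <- runs[runs$is_control, , drop = FALSE]
  if (!nrow(runs)) stop("no control runs supplied")
  if (!is.null(qc_min_proteins))
    runs <- qc_filter_runs(runs, qc_min_proteins)$passing
  runs <- runs[runs$psm_count > 0, , drop = FALSE]

  run_tag <- tapply(runs$tag_class, runs$run_id, function(x) x[1])
  strata <- list(All = names(run_tag),
                 NLS = names(run_tag)[run_tag == "NLS"],
                 MYR = names(run_tag)[run_tag == "MYR"])
  strata <- strata[vapply(strata, length, 1L) > 0]

  entries <- do.call(rbind, lapply(names(strata), function(s) {
    ids <- strata[[s]]
    sub <- runs[runs$run_id %in% ids, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    n_runs <- length(ids)
    # detections per prey: count distinct runs; avg/max over detected runs
    n_det <- tapply(sub$run_id, sub$prey_id, function(r) length(unique(r)))
    avg <- tapply(sub$psm_count, sub$prey_id, mean)
    mx <- tapply(sub$psm_count, sub$prey_id, max)
    prey <- sort(names(n_det))
    data.frame(prey_id = prey, stratum = s, n_runs = n_runs,
               pct = 100 * as.numeric(n_det[prey]) / n_runs,
               avg_spec = as.numeric(avg[prey]),
               max_spec = as.numeric(mx[prey]),
               stringsAsFactors = FALSE)
  }))
  rownames(entries) <- NULL
  structure(list(entries = entries,
                 n_runs = vapply(strata, length, 1L),
                 assay = assay, qc_min_proteins = qc_min_proteins),
            class = "contaminant_repository")
}

#' @export
print.contaminant_repository <- function(x, ...) {
  cat("Contaminant repository (", x$assay, ")\n", sep = "")
  cat("  runs per stratum: ",
      paste(sprintf("%s=%d", names(x$n_runs), x$n_runs), collapse = ", "),
      "\n", sep = "")
  cat("  preys with entries:", length(unique(x$entries$prey_id)), "\n")
  invisible(x)
}

#' Look up a prey in a contaminant repository stratum
#'
#' @param repo a [build_repository()] object.
#' @param prey_id prey identifier.
#' @param stratum one of the repository's strata (`"All"`, `"NLS"`,
#'   `"MYR"`).
#' @return list with `pct`, `avg_spec`, `max_spec` and logical `absent`.
#'   A prey never seen in the stratum is reported with `pct = 0`,
#'   `avg_spec = 0`, `max_spec = 0` and `absent = TRUE`.
#' @export
flag_prey <- function(repo, prey_id, stratum = "All") {
  stopifnot(inherits(repo, "contaminant_repository"))
  if (!stratum %in% c("All", "NLS", "MYR"))
    stop("unknown stratum: ", stratum)
  hit <- repo$entries[repo$entries$prey_id == prey_id &
                        repo$entries$stratum == stratum, , drop = FALSE]
  if (!nrow(hit))
    return(list(pct = 0, avg_spec = 0, max_spec = 0, absent = TRUE))
  list(pct = hit$pct[1], avg_spec = hit$avg_spec[1],
       max_spec = hit$max_spec[1], absent = FALSE)
}

#' Serialize / read a contaminant repository as TSV
#'
#' The TSV carries columns `prey_id`, `stratum`, `n_runs`, `pct`,
#' `avg_spec`, `max_spec`; assay and QC threshold are stored in `#`-prefixed
#' header lines.
#'
#' @param repo a `contaminant_repository`.
#' @param path file path.
#' @return `write_repository_tsv` returns `path` invisibly;
#'   `read_repository_tsv` returns a `contaminant_repository`.
#' @export
write_repository_tsv <- function(repo, path) {
  stopifnot(inherits(repo, "contaminant_repository"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# assay=%s", repo$assay), con)
  writeLines(sprintf("# n_runs %s=%d", names(repo$n_runs), repo$n_runs), con)
  utils::write.table(repo$entries, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_repository_tsv
#' @export
read_repository_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  assay <- sub("^# assay=", "", hdr[startsWith(hdr, "# assay=")])
  runs_hdr <- hdr[startsWith(hdr, "# n_runs ")]
  kv <- strsplit(sub("^# n_runs ", "", runs_hdr), "=")
  n_runs <- vapply(kv, function(x) as.integer(x[2]), 1L)
  names(n_runs) <- vapply(kv, `[`, "", 1)
  entries <- utils::read.delim(textConnection(lines[!startsWith(lines, "#")]),
                               stringsAsFactors = FALSE)
  structure(list(entries = entries, n_runs = n_runs, assay = assay,
                 qc_min_proteins = NULL),
            class = "contaminant_repository")
}
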