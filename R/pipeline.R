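#' Configuration for an end-to-end pipeline run
#'
#' Two modes exist. Demo mode (`sim` supplied) generates every input with
#' the synthetic-data module before running the stages. File mode
#' (`runs_file` supplied) reads a run TSV instead. An externally produced
#' SAINT-format scoring TSV can be injected with `scoring_file`, in which
#' case the internal scoring stage is skipped and downstream stages
#' consume the injected file under the identical contract.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed recorded in the manifest and used for demo
#'   mode.
#' @param sim optional [sim_config()] for demo mode.
#' @param runs_file optional run TSV path (file mode).
#' @param scoring_file optional SAINT-format scoring TSV to inject.
#' @param policy a [filter_policy()].
#' @param qc_min_proteins control-run QC threshold for the repository
#'   stage.
#' @param stages character vector of stages to run, in dependency order
#'   chosen from `repository`, `scoring`, `filter`, `analytics`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = NULL,
                            runs_file = NULL, scoring_file = NULL,
                            policy = filter_policy(),
                            qc_min_proteins = 10L,
                            stages = c("repository", "scoring", "filter",
                                       "analytics")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(sim) && is.null(runs_file))
    stop("either 'sim' (demo mode) or 'runs_file' must be given")
  if (!is.null(runs_file) && !file.exists(runs_file))
    stop("runs_file does not exist: ", runs_file)
  if (!is.null(scoring_file) && !file.exists(scoring_file))
    stop("scoring_file does not exist: ", scoring_file)
  if ("filter" %in% stages && !"repository" %in% stages)
    stop("the 'filter' stage requires the 'repository' stage")
  if ("filter" %in% stages && !"scoring" %in% stages &&
      is.null(scoring_file))
    stop("the 'filter' stage requires 'scoring' or an injected scoring_file")
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 runs_file = runs_file, scoring_file = scoring_file,
                 policy = policy, qc_min_proteins = qc_min_proteins,
                 stages = stages),
            class = "pipeline_config")
}

#' Run the interactomics pipeline end to end
#'
#' Stages execute in dependency order: contaminant repository from the
#' control runs, interaction scoring, compound high-confidence filtering,
#' and downstream analytics (bait clustering, hub ranking, per-bait HCI
#' summary). Every intermediate is written as plain TSV/JSON under
#' `out_dir`, so two runs with the same configuration and seed produce
#' byte-identical outputs. A `manifest.json` records the package version,
#' seed, input checksums and per-stage row counts; if a stage fails, a
#' `FAILED` marker naming the stage is left and the error is re-thrown.
#'
#' @param config a [pipeline_config()].
#' @return list with `manifest` and the in-memory stage results
#'   (`repository`, `scored`, `filtered`, `analytics`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "proxitome",
                   version = as.character(utils::packageVersion("proxitome")),
                   seed = config$seed, stages = config$stages,
                   inputs = list(), row_counts = list())
  res <- list()
  stage <- "inputs"
  fail_marker <- file.path(config$out_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  tryCatch({
    if (!is.null(config$sim)) {
      sim_cfg <- config$sim
      sim_cfg$seed <- config$seed
      sim <- generate_runs(sim_cfg)
      runs <- sim$runs
      write_runs_tsv(runs, file.path(config$out_dir, "runs.tsv"))
      utils::write.table(sim$truth,
                         file.path(config$out_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      res$truth <- sim$truth
    } else {
      runs <- read_runs_tsv(config$runs_file)
      manifest$inputs$runs_file <-
        unname(tools::md5sum(config$runs_file))
    }
    manifest$row_counts$runs <- nrow(runs)

    if ("repository" %in% config$stages) {
      stage <- "repository"
      repo <- build_repository(runs, assay = config$policy$assay,
                               qc_min_proteins = config$qc_min_proteins)
      write_repository_tsv(repo,
                           file.path(config$out_dir, "repository.tsv"))
      manifest$row_counts$repository <- nrow(repo$entries)
      res$repository <- repo
    }

    if (!is.null(config$scoring_file)) {
      stage <- "scoring"
      scored <- read_scores_tsv(config$scoring_file)
      manifest$inputs$scoring_file <-
        unname(tools::md5sum(config$scoring_file))
      manifest$row_counts$scored <- nrow(scored)
      res$scored <- scored
    } else if ("scoring" %in% config$stages) {
      stage <- "scoring"
      scored <- score_interactions(runs)
      write_scores_tsv(scored, file.path(config$out_dir, "scores.tsv"))
      manifest$row_counts$scored <- nrow(scored)
      res$scored <- scored
    }

    if ("filter" %in% config$stages) {
      stage <- "filter"
      filt <- apply_hci_filter(res$scored, res$repository, config$policy)
      utils::write.table(filt$log,
                         file.path(config$out_dir, "filter_log.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(filt$hci,
                         file.path(config$out_dir, "hci.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summ <- summarize_hcis(filt$hci)
      jsonlite::write_json(
        list(total = summ$total, unique_preys = summ$unique_preys,
             per_bait = summ$per_bait),
        file.path(config$out_dir, "hci_summary.json"),
        auto_unbox = TRUE, digits = NA)
      manifest$row_counts$hci <- nrow(filt$hci)
      res$filtered <- filt
      res$summary <- summ
    }

    if ("analytics" %in% config$stages && !is.null(res$filtered) &&
        nrow(res$filtered$hci)) {
      stage <- "analytics"
      mat <- interactome_matrix(res$filtered$hci)
      analytics <- list(sharing = prey_sharing(res$filtered$hci))
      utils::write.table(analytics$sharing,
                         file.path(config$out_dir, "prey_sharing.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (nrow(mat) >= 2) {
        cl <- suppressWarnings(correlation_cluster(mat))
        utils::write.table(round(cl$correlation, 6),
                           file.path(config$out_dir, "correlation.tsv"),
                           sep = "\t", quote = FALSE)
        if (!is.na(cl$newick))
          writeLines(cl$newick,
                     file.path(config$out_dir, "clustering.nwk"))
        analytics$clustering <- cl
      }
      res$analytics <- analytics
    }
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               fail_marker)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
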