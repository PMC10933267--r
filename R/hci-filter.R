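#' Policy of the compound high-confidence-interaction filter
#'
#' Encodes the stringent filtering convention for spectral-count
#' interactomics: keep a scored bait-prey pair only if its BFDR is below
#' `bfdr_max` (strict), and the prey was seen in fewer than
#' `control_pct_max` percent of the control-repository experiments (strict)
#' unless the bait AvgSpec is at least `rescue_fold` times the repository
#' AvgSpec (inclusive). For BioID data, a prey flagged as a contaminant
#' (frequency at or above the threshold without rescue) in any of the
#' `elimination_strata` - conventionally `All` and `NLS` - is eliminated
#' outright.
#'
#' @param bfdr_max BFDR cutoff (strict `<`).
#' @param control_pct_max maximal control detection percentage (strict `<`).
#' @param rescue_fold abundance-rescue fold (inclusive `>=`).
#' @param assay `"BioID"` (elimination strata active) or `"AP-MS"`.
#' @param elimination_strata repository strata checked for the BioID
#'   elimination rule.
#' @param rescue_stratum stratum whose AvgSpec anchors the frequency/rescue
#'   clause.
#' @param exclude_self drop bait self-detections (prey equal to bait).
#' @return list of class `filter_policy`.
#' @export
filter_policy <- function(bfdr_max = 0.01, control_pct_max = 10,
                          rescue_fold = 3,
                          assay = c("BioID", "AP-MS"),
                          elimination_strata = c("All", "NLS"),
                          rescue_stratum = "All",
                          exclude_self = TRUE) {
  assay <- match.arg(assay)
  stopifnot(bfdr_max > 0, bfdr_max < 1,
            control_pct_max >= 0, control_pct_max <= 100,
            rescue_fold > 1)
  structure(list(bfdr_max = bfdr_max, control_pct_max = control_pct_max,
                 rescue_fold = rescue_fold, assay = assay,
                 elimination_strata = elimination_strata,
                 rescue_stratum = rescue_stratum,
                 exclude_self = exclude_self),
            class = "filter_policy")
}

# repository lookup vectorized over (prey, stratum): pct and avg_spec with
# absent preys as pct 0 / avg 0
.repo_lookup <- function(repo, preys, stratum) {
  sub <- repo$entries[repo$entries$stratum == stratum, , drop = FALSE]
  i <- match(preys, sub$prey_id)
  list(pct = ifelse(is.na(i), 0, sub$pct[i]),
       avg_spec = ifelse(is.na(i), 0, sub$avg_spec[i]),
       absent = is.na(i))
}

#' Apply the compound high-confidence filter to scored interactions
#'
#' Clauses are evaluated in first-fail order: (1) BFDR, (2) BioID
#' elimination strata, (3) control frequency with abundance rescue. The
#' decision log names, for every record, the single clause that fired (or
#' `"pass"` / `"rescued"` for retained records). Preys missing from the
#' repository are treated as frequency 0 (they pass the frequency clause)
#' and marked in the log.
#'
#' @param scored a `scored_interactions` data.frame (BFDR filled).
#' @param repo a [build_repository()] object whose assay matches the
#'   policy.
#' @param policy a [filter_policy()].
#' @return list with `hci` (retained records) and `log` (all records with
#'   `decision`, `clause`, `repo_absent` columns).
#' @export
#' @examples
#' sim <- generate_runs(sim_config(seed = 2, n_baits = 2, n_preys = 300))
#' repo <- build_repository(sim$runs, assay = "BioID", qc_min_proteins = 10)
#' scored <- score_interactions(sim$runs)
#' res <- apply_hci_filter(scored, repo, filter_policy())
#' table(res$log$clause)
apply_hci_filter <- function(scored, repo, policy = filter_policy()) {
  stopifnot(inherits(repo, "contaminant_repository"),
            inherits(policy, "filter_policy"))
  if (repo$assay != policy$assay)
    stop("repository assay (", repo$assay, ") does not match policy assay (",
         policy$assay, ")")
  if (!nrow(scored))
    return(list(hci = scored,
                log = cbind(scored, decision = character(0),
                            clause = character(0), repo_absent = logical(0))))

  n <- nrow(scored)
  clause <- rep(NA_character_, n)
  all_ref <- .repo_lookup(repo, scored$prey_id, policy$rescue_stratum)
  rescued_all <- scored$avg_spec >= policy$rescue_fold * all_ref$avg_spec &
    all_ref$avg_spec > 0

  if (policy$exclude_self) {
    self <- scored$prey_id == scored$bait_id
    clause[self & is.na(clause)] <- "bait_self"
  }
  fail_bfdr <- !(scored$bfdr < policy$bfdr_max)
  clause[fail_bfdr & is.na(clause)] <- "bfdr"

  if (policy$assay == "BioID") {
    for (s in policy$elimination_strata) {
      ref <- .repo_lookup(repo, scored$prey_id, s)
      flagged <- ref$pct >= policy$control_pct_max &
        !(scored$avg_spec >= policy$rescue_fold * ref$avg_spec)
      clause[flagged & is.na(clause)] <- paste0("contaminant_", s)
    }
  }

  fail_freq <- all_ref$pct >= policy$control_pct_max & !rescued_all
  clause[fail_freq & is.na(clause)] <- "frequency"

  retained <- is.na(clause)
  via_rescue <- all_ref$pct >= policy$control_pct_max & rescued_all
  clause[retained] <- ifelse(via_rescue[retained], "rescued", "pass")
  log <- scored
  log$decision <- ifelse(retained, "retained", "rejected")
  log$clause <- clause
  log$repo_absent <- all_ref$absent
  list(hci = scored[retained, , drop = FALSE], log = log)
}

#' Summarize high-confidence interactions per bait
#'
#' @param hci a data.frame of retained interactions (`bait_id`, `prey_id`),
#'   e.g. the `hci` element of [apply_hci_filter()].
#' @return list with `per_bait` (data.frame bait_id, n_hci), `total`
#'   (sum of per-bait counts) and `unique_preys` (size of the prey union).
#' @export
summarize_hcis <- function(hci) {
  baits <- sort(unique(hci$bait_id))
  if (!length(baits))
    return(list(per_bait = data.frame(bait_id = character(0),
                                      n_hci = integer(0)),
                total = 0L, unique_preys = 0L))
  per_bait <- data.frame(
    bait_id = baits,
    n_hci = as.integer(table(factor(hci$bait_id, levels = baits))),
    stringsAsFactors = FALSE)
  list(per_bait = per_bait, total = sum(per_bait$n_hci),
       unique_preys = length(unique(hci$prey_id)))
}
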