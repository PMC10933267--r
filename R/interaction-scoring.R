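#' Parameters of the two-component spectral-count scoring model
#'
#' The scorer models each prey's replicate PSM counts in a bait purification
#' as a mixture of a background component, parameterized from the control
#' runs, and a true-interaction component. Both components are negative
#' binomial with a shared dispersion estimated from the control runs by the
#' method of moments (pooled over preys); the background mean is the prey's
#' control average with a pseudocount, and the true-component mean is the
#' bait replicate mean, floored at `min_fold` times the background mean so
#' the two components never collapse. Each replicate count receives a
#' posterior probability of having arisen from the true component (equal
#' prior weights); the pair's probability is the mean of the replicate
#' posteriors, following the averaged-replicate convention of
#' spectral-count interaction scorers.
#'
#' @param pseudocount added floor for background means and fold-change
#'   denominators when the control average is zero.
#' @param min_fold minimum ratio of true-component mean to background mean.
#' @param nb_size negative-binomial size; `NULL` (default) estimates it
#'   from the control runs, falling back to `fallback_size` when the
#'   controls show no overdispersion.
#' @param fallback_size size used when moment estimation is impossible.
#' @return list of class `score_params`.
#' @export
score_params <- function(pseudocount = 0.1, min_fold = 2,
                         nb_size = NULL, fallback_size = 10) {
  stopifnot(pseudocount > 0, min_fold >= 1)
  structure(list(pseudocount = pseudocount, min_fold = min_fold,
                 nb_size = nb_size, fallback_size = fallback_size),
            class = "score_params")
}

# pooled method-of-moments NB size from per-prey control means/variances
# (zeros for runs where the prey is absent are counted analytically):
# var = mu + mu^2/size  =>  size = mean(mu^2) / mean(var - mu)
.control_nb_size <- function(control_runs, fallback) {
  n <- length(unique(control_runs$run_id))
  if (n < 2) return(fallback)
  s <- tapply(control_runs$psm_count, control_runs$prey_id, sum)
  ss <- tapply(as.numeric(control_runs$psm_count)^2,
               control_runs$prey_id, sum)
  mu <- as.numeric(s) / n
  v <- (as.numeric(ss) - n * mu^2) / (n - 1)
  ok <- !is.na(v) & v > mu & mu > 0
  if (!any(ok)) return(fallback)
  size <- mean(mu[ok]^2) / mean(v[ok] - mu[ok])
  if (!is.finite(size) || size <= 0) fallback else size
}

#' Score one bait's prey spectral counts against control runs
#'
#' Produces one record per prey observed with a nonzero count in at least
#' one bait replicate, carrying the replicate counts, the bait average
#' spectral count (AvgSpec, zeros included), the control average, the fold
#' change over controls, and the mixture-model interaction probability.
#' BFDR is filled by [compute_bfdr()].
#'
#' @param bait_runs run table rows for one bait (>= 2 replicate runs).
#' @param control_runs run table rows for the control runs (>= 2 runs).
#'   Preys absent from a control run are counted as zero there.
#' @param params a [score_params()] object.
#' @return data.frame of class `scored_interactions` with columns
#'   `bait_id`, `prey_id`, `counts` (pipe-joined per-replicate PSM counts),
#'   `avg_spec`, `control_avg`, `fold_change`, `probability`, `bfdr` (NA
#'   until [compute_bfdr()]).
#' @export
score_bait <- function(bait_runs, control_runs, params = score_params()) {
  if (!nrow(control_runs)) stop("zero control runs")
  bait_ids <- unique(bait_runs$bait_id)
  if (length(bait_ids) != 1)
    stop("'bait_runs' must contain exactly one bait; got: ",
         paste(bait_ids, collapse = ", "))
  rep_ids <- sort(unique(bait_runs$run_id))
  ctrl_ids <- unique(control_runs$run_id)
  if (length(rep_ids) < 2) stop("need >= 2 bait replicate runs")
  if (length(ctrl_ids) < 2) stop("need >= 2 control runs")

  # replicate count matrix over preys seen in >= 1 bait replicate
  preys <- sort(unique(bait_runs$prey_id[bait_runs$psm_count > 0]))
  if (!length(preys)) {
    out <- data.frame(bait_id = character(0), prey_id = character(0),
                      counts = character(0), avg_spec = numeric(0),
                      control_avg = numeric(0), fold_change = numeric(0),
                      probability = numeric(0), bfdr = numeric(0))
    class(out) <- c("scored_interactions", "data.frame")
    return(out)
  }
  cnt <- matrix(0, length(preys), length(rep_ids),
                dimnames = list(preys, rep_ids))
  keep <- bait_runs$prey_id %in% preys
  cnt[cbind(match(bait_runs$prey_id[keep], preys),
            match(bait_runs$run_id[keep], rep_ids))] <- bait_runs$psm_count[keep]

  # control means over all control runs (zeros included)
  n_ctrl <- length(ctrl_ids)
  ctrl_sum <- tapply(control_runs$psm_count, control_runs$prey_id, sum)
  control_avg <- numeric(length(preys))
  hit <- match(preys, names(ctrl_sum))
  control_avg[!is.na(hit)] <- as.numeric(ctrl_sum[hit[!is.na(hit)]]) / n_ctrl

  size <- params$nb_size
  if (is.null(size))
    size <- .control_nb_size(control_runs, params$fallback_size)

  mu_bg <- pmax(control_avg, params$pseudocount)
  avg_spec <- rowMeans(cnt)
  mu_true <- pmax(avg_spec, params$min_fold * mu_bg)

  # per-replicate posterior of the true component, equal priors
  post <- matrix(0, length(preys), length(rep_ids))
  for (j in seq_along(rep_ids)) {
    f_true <- stats::dnbinom(cnt[, j], mu = mu_true, size = size)
    f_bg <- stats::dnbinom(cnt[, j], mu = mu_bg, size = size)
    denom <- f_true + f_bg
    post[, j] <- ifelse(denom > 0, f_true / denom, 0.5)
  }
  probability <- rowMeans(post)

  out <- data.frame(bait_id = bait_ids, prey_id = preys,
                    counts = apply(cnt, 1, paste, collapse = "|"),
                    avg_spec = avg_spec, control_avg = control_avg,
                    fold_change = avg_spec / pmax(control_avg,
                                                  params$pseudocount),
                    probability = probability, bfdr = NA_real_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("scored_interactions", "data.frame")
  out
}

#' Score every bait in a run table
#'
#' Convenience wrapper: splits a mixed run table into per-bait replicate
#' sets and the control set, scores each bait independently with
#' [score_bait()], and fills BFDR per bait with [compute_bfdr()].
#'
#' @param runs a full run table (see [generate_runs()]).
#' @param params a [score_params()] object.
#' @return a `scored_interactions` data.frame over all baits, BFDR filled.
#' @export
score_interactions <- function(runs, params = score_params()) {
  ctrl <- runs[runs$is_control, , drop = FALSE]
  bait_tab <- runs[!runs$is_control, , drop = FALSE]
  if (is.null(params$nb_size))  # estimate the shared dispersion once
    params$nb_size <- .control_nb_size(ctrl, params$fallback_size)
  out <- lapply(sort(unique(bait_tab$bait_id)), function(b) {
    scored <- score_bait(bait_tab[bait_tab$bait_id == b, , drop = FALSE],
                         ctrl, params)
    compute_bfdr(scored)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("scored_interactions", "data.frame")
  res
}

#' Model-based false-discovery rate over probability-ranked interactions
#'
#' Sorts records by decreasing probability (ties broken by bait then prey
#' identifier for determinism) and sets the BFDR at rank k to the mean of
#' `1 - probability` over the top k records; records with tied
#' probabilities all share the BFDR of the last tied rank.
#'
#' @param scored a `scored_interactions` data.frame.
#' @return the same data.frame, original row order preserved, with `bfdr`
#'   filled.
#' @export
#' @examples
#' x <- data.frame(bait_id = "b", prey_id = c("p1", "p2", "p3"),
#'                 probability = c(0.99, 0.95, 0.50))
#' compute_bfdr(x)$bfdr  # 0.01 0.03 0.18667
compute_bfdr <- function(scored) {
  if (!nrow(scored)) {
    scored$bfdr <- numeric(0)
    return(scored)
  }
  ord <- order(-scored$probability, scored$bait_id, scored$prey_id)
  p <- scored$probability[ord]
  bfdr <- cumsum(1 - p) / seq_along(p)
  # tied probabilities share the bfdr of the last tied rank
  bfdr <- stats::ave(bfdr, cumsum(!duplicated(p)), FUN = function(x) x[length(x)])
  scored$bfdr[ord] <- bfdr
  scored
}

#' @export
print.scored_interactions <- function(x, ...) {
  cat("Scored interactions: ", nrow(x), " bait-prey pairs, ",
      length(unique(x$bait_id)), " bait(s)\n", sep = "")
  if (nrow(x) && !all(is.na(x$bfdr)))
    cat("  pairs at BFDR < 0.01: ", sum(x$bfdr < 0.01, na.rm = TRUE),
        "\n", sep = "")
  NextMethod()
}

#' Write / read scored interactions in the SAINT list layout
#'
#' The TSV uses the conventional column set `Bait`, `Prey`, `Spec`,
#' `AvgSpec`, `ctrlCounts` (here the control average), `FoldChange`,
#' `AvgP`, `BFDR`, so externally produced SAINT-style output can be
#' injected in place of the internal scorer's output (extra columns are
#' ignored on read; missing `Spec`/`FoldChange` are tolerated).
#'
#' @param scored a `scored_interactions` data.frame.
#' @param path file path.
#' @export
write_scores_tsv <- function(scored, path) {
  out <- data.frame(Bait = scored$bait_id, Prey = scored$prey_id,
                    Spec = scored$counts, AvgSpec = scored$avg_spec,
                    ctrlCounts = scored$control_avg,
                    FoldChange = scored$fold_change,
                    AvgP = scored$probability, BFDR = scored$bfdr)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("Bait", "Prey", "AvgSpec", "AvgP", "BFDR")
  if (!all(need %in% names(x)))
    stop("scoring TSV must carry columns: ", paste(need, collapse = ", "))
  out <- data.frame(bait_id = as.character(x$Bait),
                    prey_id = as.character(x$Prey),
                    counts = if ("Spec" %in% names(x))
                      as.character(x$Spec) else NA_character_,
                    avg_spec = x$AvgSpec,
                    control_avg = if ("ctrlCounts" %in% names(x))
                      x$ctrlCounts else NA_real_,
                    fold_change = if ("FoldChange" %in% names(x))
                      x$FoldChange else NA_real_,
                    probability = x$AvgP, bfdr = x$BFDR,
                    stringsAsFactors = FALSE)
  class(out) <- c("scored_interactions", "data.frame")
  out
}
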