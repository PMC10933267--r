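# Independent oracles used across the suite. Each deliberately takes the
# naive route (enumeration, all-pairs scans, direct definitions) so it
# shares no code path with the implementation it checks.

# Two-sided Fisher p by full hypergeometric enumeration over one margin.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  xs <- lo:hi
  lp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  probs <- exp(lp)
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Greedy Ward agglomeration computed from first principles: at each step
# merge the pair of clusters with minimal ESS increase
# n_i n_j / (n_i + n_j) * ||c_i - c_j||^2 ; report sqrt(2 * delta) heights
# (the ward.D2 height convention on Euclidean input).
oracle_ward_heights <- function(X) {
  clusters <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        ci <- clusters[[i]]; cj <- clusters[[j]]
        mu_i <- colMeans(X[ci, , drop = FALSE])
        mu_j <- colMeans(X[cj, , drop = FALSE])
        d <- length(ci) * length(cj) / (length(ci) + length(cj)) *
          sum((mu_i - mu_j)^2)
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, sqrt(2 * best_d))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# All-pairs half-open interval overlap scan.
oracle_overlaps <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(a$chrom[i] == b$chrom & a$start[i] < b$end & b$start < a$end[i])
  }, TRUE)
}

# Naive full rescan of a control run table for one prey and stratum.
oracle_repo_entry <- function(runs, prey, stratum) {
  runs <- runs[runs$psm_count > 0, , drop = FALSE]
  tag_of <- tapply(runs$tag_class, runs$run_id, function(x) x[1])
  ids <- switch(stratum,
                All = names(tag_of),
                names(tag_of)[tag_of == stratum])
  sub <- runs[runs$run_id %in% ids & runs$prey_id == prey, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  list(pct = 100 * length(unique(sub$run_id)) / length(ids),
       avg_spec = mean(sub$psm_count), max_spec = max(sub$psm_count))
}

# Brute-force sliding-window motif finder (exact string match).
oracle_find_motif <- function(sequence, motif) {
  w <- nchar(motif)
  hits <- integer(0)
  for (s in seq_len(nchar(sequence) - w + 1))
    if (substr(sequence, s, s + w - 1) == motif) hits <- c(hits, s)
  hits
}

# Brute-force pattern scan: positions where all 9 classes are satisfied.
oracle_find_motif_by_pattern <- function(sequence, pattern) {
  chars <- strsplit(sequence, "")[[1]]
  hits <- integer(0)
  for (s in seq_len(length(chars) - 8L)) {
    ok <- all(vapply(1:9, function(k)
      chars[s + k - 1L] %in% pattern$positions[[k]], TRUE))
    if (ok) hits <- c(hits, s)
  }
  hits
}

# Small deterministic run-table fixture used by several suites.
toy_sim <- function(seed = 42L, ...) {
  defaults <- list(seed = seed, n_baits = 3L, n_preys = 300L,
                   n_control_runs = c(none = 8L, MYR = 4L, NES = 2L,
                                      NLS = 5L),
                   n_true_per_bait = 10L)
  args <- utils::modifyList(defaults, list(...))
  generate_runs(do.call(sim_config, args))
}
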