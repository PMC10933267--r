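#' Nine-amino-acid transactivation-domain (9aaTAD) search patterns
#'
#' A 9aaTAD pattern is a set of per-position allowed amino-acid classes
#' over a 9-residue window, optionally with flanking constraints (allowed
#' residues immediately before/after the window). Two stringencies are
#' shipped: a moderately stringent pattern constraining all nine positions
#' (polar/acidic anchor positions and bulky hydrophobic core positions),
#' and a low-stringency pattern constraining only the hydrophobic core.
#' The shipped definitions are reconstructed from the published position
#' rules of the in silico 9aaTAD prediction tool and are deliberately
#' editable data, not code: see [read_tad_patterns()] and the
#' `tad_patterns.cfg` file under `inst/extdata`.
#'
#' @return list of pattern objects, each a list with `name`, `stringency`,
#'   `positions` (list of 9 character vectors of allowed residues) and
#'   optional `flank_before` / `flank_after`.
#' @export
tad_patterns <- function() {
  read_tad_patterns(system.file("extdata", "tad_patterns.cfg",
                                package = "proxitome"))
}

#' Read 9aaTAD patterns from a plain key-value configuration file
#'
#' Format: `[pattern-name]` section headers; inside each section,
#' `stringency = moderate|low`, `p1` .. `p9` giving the allowed amino
#' acids of each window position as an unseparated residue string, and
#' optional `flank_before` / `flank_after` residue strings. Blank lines
#' and `#` comments are ignored.
#'
#' @param path configuration file path.
#' @return list of pattern objects (see [tad_patterns()]).
#' @export
read_tad_patterns <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  pats <- list(); cur <- NULL; cur_name <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    pos <- lapply(sprintf("p%d", 1:9), function(k) {
      if (is.null(cur[[k]])) stop("pattern '", cur_name, "' misses ", k)
      strsplit(cur[[k]], "")[[1]]
    })
    if (any(!vapply(pos, length, 1L)))
      stop("pattern '", cur_name, "' has an empty position class")
    pat <- list(name = cur_name,
                stringency = cur[["stringency"]] %||% "moderate",
                positions = pos)
    if (!is.null(cur[["flank_before"]]))
      pat$flank_before <- strsplit(cur[["flank_before"]], "")[[1]]
    if (!is.null(cur[["flank_after"]]))
      pat$flank_after <- strsplit(cur[["flank_after"]], "")[[1]]
    pats[[cur_name]] <<- pat
  }
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      flush()
      cur_name <- sub("^\\[(.+)\\]$", "\\1", ln)
      cur <- list()
    } else {
      kv <- strsplit(ln, "\\s*=\\s*")[[1]]
      if (length(kv) != 2) stop("malformed pattern line: ", ln)
      cur[[kv[1]]] <- kv[2]
    }
  }
  flush()
  pats
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical consensus sequence of a 9aaTAD pattern
#'
#' The first allowed residue at each window position; a sequence equal to
#' the consensus matches the pattern at 100%.
#'
#' @param pattern a pattern object (see [tad_patterns()]).
#' @return 9-character string.
#' @export
tad_consensus <- function(pattern) {
  paste(vapply(pattern$positions, `[`, "", 1), collapse = "")
}

#' Scan protein sequences for 9aaTAD motifs
#'
#' Every 9-residue window of every sequence is scored against every
#' pattern; the percent match is 100 times the fraction of satisfied
#' constraints (the 9 position classes plus any flanking constraints that
#' apply at that window). Windows at or above `min_percent` are reported,
#' sorted by sequence and position. `X` residues never satisfy a
#' constraint; overlapping matches are all reported.
#'
#' @param sequences an [Biostrings::AAStringSet], named character vector,
#'   or single string.
#' @param patterns list of pattern objects, default [tad_patterns()].
#' @param min_percent minimal percent match to report.
#' @return data.frame `protein`, `start` (1-based), `window`,
#'   `stringency`, `pattern`, `percent_match`.
#' @export
#' @examples
#' pat <- tad_patterns()
#' scan_9aaTAD(tad_consensus(pat[["moderate"]]), pat)
scan_9aaTAD <- function(sequences, patterns = tad_patterns(),
                        min_percent = 80) {
  if (methods::is(sequences, "AAStringSet"))
    sequences <- as.character(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq_%03d", seq_along(sequences))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequences)
  if (any(bad))
    stop("sequence(s) contain letters outside the amino-acid alphabet: ",
         paste(names(sequences)[bad], collapse = ", "))
  out <- list()
  for (id in names(sequences)) {
    chars <- strsplit(sequences[[id]], "")[[1]]
    L <- length(chars)
    if (L < 9) next
    starts <- seq_len(L - 8L)
    for (pat in patterns) {
      sat <- matrix(FALSE, length(starts), 9)
      for (k in 1:9)
        sat[, k] <- chars[starts + k - 1L] %in% pat$positions[[k]]
      n_sat <- rowSums(sat)
      n_tot <- rep(9L, length(starts))
      if (!is.null(pat$flank_before)) {
        has <- starts > 1L
        n_tot[has] <- n_tot[has] + 1L
        n_sat[has] <- n_sat[has] +
          (chars[starts[has] - 1L] %in% pat$flank_before)
      }
      if (!is.null(pat$flank_after)) {
        has <- starts + 9L <= L
        n_tot[has] <- n_tot[has] + 1L
        n_sat[has] <- n_sat[has] +
          (chars[starts[has] + 9L] %in% pat$flank_after)
      }
      pct <- 100 * n_sat / n_tot
      keep <- pct >= min_percent
      if (any(keep))
        out[[length(out) + 1L]] <- data.frame(
          protein = id, start = starts[keep],
          window = vapply(starts[keep], function(s)
            paste(chars[s:(s + 8L)], collapse = ""), ""),
          stringency = pat$stringency, pattern = pat$name,
          percent_match = pct[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(protein = character(0), start = integer(0),
                      window = character(0), stringency = character(0),
                      pattern = character(0), percent_match = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$protein, res$start, res$pattern), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Summarize 9aaTAD matches per protein
#'
#' One row per protein. The best match is chosen by stringency first
#' (moderate beats low, mirroring the convention of trying the stringent
#' pattern first and falling back), then by percent match.
#'
#' @param matches output of [scan_9aaTAD()].
#' @param proteins optional character vector of all scanned proteins, so
#'   proteins without any match are reported with `"none"`.
#' @return data.frame `protein`, `best_stringency`, `best_percent`,
#'   `positions` (comma-joined starts at the best stringency).
#' @export
report_tads <- function(matches, proteins = NULL) {
  if (is.null(proteins)) proteins <- sort(unique(matches$protein))
  rows <- lapply(proteins, function(pr) {
    m <- matches[matches$protein == pr, , drop = FALSE]
    if (!nrow(m))
      return(data.frame(protein = pr, best_stringency = "none",
                        best_percent = NA_real_, positions = "",
                        stringsAsFactors = FALSE))
    lvl <- factor(m$stringency, levels = c("moderate", "low"))
    m <- m[order(lvl, -m$percent_match, m$start), , drop = FALSE]
    best <- m[m$stringency == m$stringency[1] &
                m$percent_match == m$percent_match[1], , drop = FALSE]
    data.frame(protein = pr, best_stringency = m$stringency[1],
               best_percent = m$percent_match[1],
               positions = paste(sort(unique(best$start)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
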