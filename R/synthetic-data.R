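#' Simulation configuration for spectral-count interactomics data
#'
#' Bundles every tunable of the synthetic bait/control run generator into a
#' validated list. The defaults mirror a typical MAC-tag BioID study design:
#' 21 nuclear transcription-factor baits run in two biological times two
#' technical replicates, against a GFP control compendium of 64 untagged,
#' 24 myristoylated (MYR), 4 nuclear-export (NES) and 26 nuclear-localization
#' (NLS) tagged runs.
#'
#' PSM counts follow a negative binomial: each biological replicate draws a
#' latent gamma abundance and technical replicates are Poisson around it, so
#' technical replicates are correlated within a biological replicate.
#' Background ("contaminant") preys each carry a per-run detection
#' probability drawn from a beta distribution; a configurable fraction of
#' them are detectable only in one localization-tag class, which is what
#' makes the All/NLS elimination rule of the high-confidence filter
#' testable. Bait purifications see the tag-agnostic background plus the
#' NLS-specific background (baits are nuclear).
#'
#' @param seed integer seed; every generator draw descends from it.
#' @param n_baits,n_preys numbers of baits and of preys in the universe.
#' @param n_control_runs named integer vector of GFP control runs per tag
#'   class; names must be `none`, `MYR`, `NES`, `NLS`.
#' @param n_bio_reps,n_tech_reps replicate design for bait purifications.
#' @param n_true_per_bait planted true interactors per bait.
#' @param lambda_true mean PSM count of a planted interaction.
#' @param lambda_bg mean PSM count of a detected background prey.
#' @param nb_size negative-binomial size (dispersion) shared by both
#'   components; large values approach Poisson.
#' @param contam_fraction fraction of the prey universe that belongs to the
#'   background (contaminant) pool.
#' @param contam_shape1,contam_shape2 beta parameters of the per-prey
#'   detection probability in control runs.
#' @param tag_specific_fraction fraction of background preys restricted to a
#'   single tag class (split evenly across MYR and NLS).
#' @param dropout probability that a planted interaction yields zero PSMs in
#'   a given replicate.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, n_baits = 3, n_preys = 200)
#' sim <- generate_runs(cfg)
#' head(sim$runs)
sim_config <- function(seed = 1L,
                       n_baits = 21L,
                       n_preys = 2000L,
                       n_control_runs = c(none = 64L, MYR = 24L, NES = 4L, NLS = 26L),
                       n_bio_reps = 2L,
                       n_tech_reps = 2L,
                       n_true_per_bait = 25L,
                       lambda_true = 20,
                       lambda_bg = 1,
                       nb_size = 4,
                       contam_fraction = 0.5,
                       contam_shape1 = 0.5,
                       contam_shape2 = 1.5,
                       tag_specific_fraction = 0.2,
                       dropout = 0.05) {
  tags <- c("none", "MYR", "NES", "NLS")
  if (is.null(names(n_control_runs)) || !setequal(names(n_control_runs), tags))
    stop("'n_control_runs' must be named with classes: ", paste(tags, collapse = ", "))
  n_control_runs <- n_control_runs[tags]
  cfg <- list(seed = as.integer(seed), n_baits = as.integer(n_baits),
              n_preys = as.integer(n_preys),
              n_control_runs = as.integer(n_control_runs),
              n_bio_reps = as.integer(n_bio_reps),
              n_tech_reps = as.integer(n_tech_reps),
              n_true_per_bait = as.integer(n_true_per_bait),
              lambda_true = lambda_true, lambda_bg = lambda_bg,
              nb_size = nb_size, contam_fraction = contam_fraction,
              contam_shape1 = contam_shape1, contam_shape2 = contam_shape2,
              tag_specific_fraction = tag_specific_fraction, dropout = dropout)
  names(cfg$n_control_runs) <- tags
  counts <- c(cfg$n_baits, cfg$n_preys, cfg$n_control_runs, cfg$n_bio_reps,
              cfg$n_tech_reps, cfg$n_true_per_bait)
  if (any(counts < 0) || any(is.na(counts)))
    stop("all counts in a sim_config must be non-negative")
  if (cfg$n_preys <= 0 || cfg$n_baits <= 0)
    stop("'n_preys' and 'n_baits' must be positive")
  probs <- c(cfg$contam_fraction, cfg$tag_specific_fraction, cfg$dropout)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$n_true_per_bait > 0 && cfg$lambda_true <= cfg$lambda_bg)
    stop("'lambda_true' must exceed 'lambda_bg' for planted interactors")
  class(cfg) <- "sim_config"
  cfg
}

# NB draw as gamma latent + Poisson, so technical replicates can share the
# gamma. size = Inf degenerates to Poisson.
.rnb_latent <- function(n, mu, size) {
  if (is.infinite(size)) return(rep(mu, n))
  stats::rgamma(n, shape = size, rate = size / mu)
}

.prey_ids <- function(n) sprintf("prey_%05d", seq_len(n))
.bait_ids <- function(n) sprintf("bait_%03d", seq_len(n))

#' Generate synthetic bait and GFP-control spectral-count runs
#'
#' Produces a long-format run table (one row per detected prey per run) plus
#' the ground-truth table of planted bait-prey interactions, sufficient to
#' compute sensitivity and false-discovery proportions of the downstream
#' scoring and filtering stages without inspecting generator internals.
#'
#' @param config a [sim_config()] object.
#' @return A list with elements
#'   \describe{
#'     \item{runs}{data.frame with columns `run_id`, `bait_id`, `is_control`,
#'       `tag_class`, `biological_rep`, `technical_rep`, `prey_id`,
#'       `psm_count`; only detected preys (PSM > 0) are listed.}
#'     \item{truth}{data.frame of planted pairs (`bait_id`, `prey_id`).}
#'     \item{contaminants}{data.frame of background preys with their
#'       detection probability and tag restriction (`tag_class` `"shared"`
#'       means detectable in every run).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_runs <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  set.seed(cfg$seed)

  preys <- .prey_ids(cfg$n_preys)
  baits <- .bait_ids(cfg$n_baits)

  n_contam <- round(cfg$contam_fraction * cfg$n_preys)
  contam_idx <- sort(sample.int(cfg$n_preys, n_contam))
  contam <- data.frame(prey_id = preys[contam_idx],
                       detect_prob = stats::rbeta(n_contam, cfg$contam_shape1,
                                                  cfg$contam_shape2),
                       stringsAsFactors = FALSE)
  n_spec <- round(cfg$tag_specific_fraction * n_contam)
  contam$tag_class <- "shared"
  if (n_spec > 0) {
    spec_idx <- sample.int(n_contam, n_spec)
    contam$tag_class[spec_idx] <- sample(c("MYR", "NLS"), n_spec, replace = TRUE)
  }

  # one control run = one purification; draw detection then abundance
  emit_background <- function(run_id, tag, bait_id, is_control, bio, tech) {
    visible <- contam$tag_class == "shared" | contam$tag_class == tag
    vis <- contam[visible, , drop = FALSE]
    det <- stats::runif(nrow(vis)) < vis$detect_prob
    if (!any(det)) return(NULL)
    cnt <- stats::rpois(sum(det), .rnb_latent(sum(det), cfg$lambda_bg, cfg$nb_size))
    cnt <- pmax(cnt, 1L)  # detection implies at least one PSM
    data.frame(run_id = run_id, bait_id = bait_id, is_control = is_control,
               tag_class = tag, biological_rep = bio, technical_rep = tech,
               prey_id = vis$prey_id[det], psm_count = as.integer(cnt),
               stringsAsFactors = FALSE)
  }

  out <- list()
  for (tag in names(cfg$n_control_runs)) {
    for (i in seq_len(cfg$n_control_runs[[tag]])) {
      rid <- sprintf("gfp_%s_%03d", tag, i)
      out[[length(out) + 1L]] <-
        emit_background(rid, tag, "GFP", TRUE, 1L, 1L)
    }
  }

  truth <- list()
  for (b in seq_len(cfg$n_baits)) {
    planted <- if (cfg$n_true_per_bait > 0)
      sort(sample(preys, cfg$n_true_per_bait)) else character(0)
    truth[[b]] <- data.frame(bait_id = rep(baits[b], length(planted)),
                             prey_id = planted, stringsAsFactors = FALSE)
    for (bio in seq_len(cfg$n_bio_reps)) {
      lat <- .rnb_latent(length(planted), cfg$lambda_true, cfg$nb_size)
      for (tech in seq_len(cfg$n_tech_reps)) {
        rid <- sprintf("%s_b%d_t%d", baits[b], bio, tech)
        bg <- emit_background(rid, "NLS", baits[b], FALSE, bio, tech)
        if (!is.null(bg)) bg$tag_class <- "none"  # baits carry no GFP tag
        sig <- NULL
        if (length(planted)) {
          cnt <- stats::rpois(length(planted), lat)
          cnt <- pmax(cnt, 1L)
          cnt[stats::runif(length(planted)) < cfg$dropout] <- 0L
          keep <- cnt > 0L
          if (any(keep))
            sig <- data.frame(run_id = rid, bait_id = baits[b],
                              is_control = FALSE, tag_class = "none",
                              biological_rep = bio, technical_rep = tech,
                              prey_id = planted[keep],
                              psm_count = as.integer(cnt[keep]),
                              stringsAsFactors = FALSE)
        }
        run <- rbind(bg, sig)
        if (!is.null(run)) {
          # planted prey may coincide with a detected contaminant: keep max
          run <- run[order(run$prey_id, -run$psm_count), , drop = FALSE]
          run <- run[!duplicated(run$prey_id), , drop = FALSE]
          out[[length(out) + 1L]] <- run
        }
      }
    }
  }

  runs <- do.call(rbind, out)
  rownames(runs) <- NULL
  list(runs = runs, truth = do.call(rbind, truth),
       contaminants = contam, config = cfg)
}

#' Generate protein sequences with planted motifs
#'
#' Background residues are drawn i.i.d. from average vertebrate amino-acid
#' frequencies; the requested motifs are then written over the background at
#' their recorded positions.
#'
#' @param n number of sequences.
#' @param length_aa length of each sequence (recycled to `n`).
#' @param planted optional data.frame with columns `seq_index`, `position`
#'   (1-based start) and `motif` (amino-acid string) describing motifs to
#'   plant.
#' @param seed integer seed.
#' @return list with `sequences` (a [Biostrings::AAStringSet]) and
#'   `planted` (the planted-position table).
#' @export
generate_sequences <- function(n, length_aa = 300L, planted = NULL, seed = 1L) {
  set.seed(seed)
  if (n == 0) {
    return(list(sequences = Biostrings::AAStringSet(), planted = planted))
  }
  length_aa <- rep_len(as.integer(length_aa), n)
  aa <- c(A = 0.074, R = 0.042, N = 0.044, D = 0.059, C = 0.033, Q = 0.037,
          E = 0.058, G = 0.074, H = 0.029, I = 0.038, L = 0.076, K = 0.072,
          M = 0.018, F = 0.040, P = 0.050, S = 0.081, T = 0.062, W = 0.013,
          Y = 0.033, V = 0.068)
  seqs <- vapply(length_aa, function(L)
    paste(sample(names(aa), L, replace = TRUE, prob = aa), collapse = ""),
    character(1))
  if (!is.null(planted) && nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      k <- planted$seq_index[i]
      pos <- planted$position[i]
      motif <- planted$motif[i]
      if (pos + nchar(motif) - 1L > length_aa[k])
        stop("motif longer than sequence (sequence ", k, ", position ", pos, ")")
      substr(seqs[k], pos, pos + nchar(motif) - 1L) <- motif
    }
  }
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- sprintf("protein_%03d", seq_len(n))
  list(sequences = ss, planted = planted)
}

#' Generate genomic interval fixtures with known peak categories
#'
#' Lays out evenly spaced genes on a small set of chromosomes, then plants
#' ChIP-seq-like peaks at controlled distances from transcription start
#' sites so every peak's intended annotation category is known, and an
#' enhancer set overlapping a chosen subset of peaks.
#'
#' @param seed integer seed.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param n_genes number of genes (TSSs), spread across chromosomes.
#' @param n_per_category named vector of peak counts to plant per intended
#'   category: `proximal` (0-1 kb), `promoter` (1-3 kb), `intergenic`.
#' @param peak_width width of every planted peak.
#' @param enhancer_fraction fraction of peaks that receive an overlapping
#'   enhancer interval.
#' @return list with data.frames `tss` (gene_id, chrom, tss_position,
#'   strand), `peaks` (BED-style, 0-based half-open, with a `name` column),
#'   `enhancers` (BED-style) and `truth` (peak name, intended category,
#'   intended enhancer flag).
#' @export
generate_genome_fixtures <- function(seed = 1L,
                                     chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                                     n_genes = 40L,
                                     n_per_category = c(proximal = 20L,
                                                        promoter = 20L,
                                                        intergenic = 20L),
                                     peak_width = 200L,
                                     enhancer_fraction = 0.2) {
  set.seed(seed)
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  chroms <- rep(names(chrom_lengths), length.out = n_genes)
  # genes spaced >= 20 kb apart so category windows never collide
  tss <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    idx <- which(chroms == ch)
    if (!length(idx)) return(NULL)
    pos <- seq(5e4, chrom_lengths[[ch]] - 5e4, length.out = length(idx))
    data.frame(gene_id = sprintf("gene_%03d", idx), chrom = ch,
               tss_position = as.integer(round(pos)),
               strand = sample(c("+", "-"), length(idx), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(tss) <- NULL

  make_peak <- function(center, chrom) {
    start <- as.integer(center - peak_width %/% 2)
    data.frame(chrom = chrom, start = start, end = start + peak_width,
               stringsAsFactors = FALSE)
  }
  peaks <- list(); truth <- list()
  add <- function(category, offset_range) {
    n <- n_per_category[[category]]
    if (is.null(n) || n == 0) return()
    g <- tss[sample.int(nrow(tss), n, replace = TRUE), , drop = FALSE]
    off <- sample(seq(offset_range[1], offset_range[2]), n, replace = TRUE) *
      sample(c(-1L, 1L), n, replace = TRUE)
    if (category == "intergenic") off <- abs(off) + 1e4L  # beyond 3 kb windows
    p <- make_peak(g$tss_position + off, g$chrom)
    p$name <- sprintf("%s_%03d", category, seq_len(n))
    peaks[[length(peaks) + 1L]] <<- p
    truth[[length(truth) + 1L]] <<-
      data.frame(name = p$name, category = category, stringsAsFactors = FALSE)
  }
  add("proximal", c(0L, 900L))
  add("promoter", c(1200L, 2800L))
  add("intergenic", c(1L, 5000L))
  peaks <- do.call(rbind, peaks)
  truth <- do.call(rbind, truth)
  if (any(peaks$start < 0) || any(peaks$end > chrom_lengths[peaks$chrom]))
    stop("planted peaks fall outside chromosome bounds")

  n_enh <- round(enhancer_fraction * nrow(peaks))
  truth$enhancer <- FALSE
  enhancers <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0))
  if (n_enh > 0) {
    hit <- sample.int(nrow(peaks), n_enh)
    enhancers <- data.frame(chrom = peaks$chrom[hit],
                            start = peaks$start[hit] + peak_width %/% 4,
                            end = peaks$end[hit] - peak_width %/% 4,
                            stringsAsFactors = FALSE)
    truth$enhancer[hit] <- TRUE
  }
  list(tss = tss, peaks = peaks, enhancers = enhancers, truth = truth)
}

#' Generate stage-resolved expression with an 8-cell peak
#'
#' Emulates a preimplantation RNA-seq table (RPKM by developmental stage).
#' A configurable fraction of genes is "expressed": their RPKM follows a
#' log-normal profile peaking at the 8-cell stage; the rest stay below the
#' detection threshold at every stage.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param seed integer seed.
#' @param stages ordered developmental stages.
#' @param expressed_fraction fraction of genes expressed above threshold.
#' @param peak_stage stage at which expressed genes peak.
#' @return data.frame with columns `gene_id`, `stage`, `rpkm`.
#' @export
generate_expression <- function(gene_ids, seed = 1L,
                                stages = c("oocyte", "zygote", "2cell",
                                           "4cell", "8cell", "morula"),
                                expressed_fraction = 0.8,
                                peak_stage = "8cell") {
  set.seed(seed)
  n <- length(gene_ids)
  expressed <- stats::runif(n) < expressed_fraction
  peak_idx <- match(peak_stage, stages)
  if (is.na(peak_idx)) stop("'peak_stage' must be one of 'stages'")
  shape <- exp(-0.5 * (seq_along(stages) - peak_idx)^2)
  rpkm <- matrix(0, n, length(stages))
  base <- exp(stats::rnorm(n, log(20), 0.8))
  noise <- matrix(exp(stats::rnorm(n * length(stages), 0, 0.25)),
                  n, length(stages))
  rpkm[expressed, ] <- outer(base[expressed], shape) * noise[expressed, ]
  rpkm[!expressed, ] <- matrix(stats::runif(sum(!expressed) * length(stages),
                                            0, 0.5),
                               sum(!expressed), length(stages))
  data.frame(gene_id = rep(gene_ids, times = length(stages)),
             stage = rep(stages, each = n),
             rpkm = as.vector(rpkm), stringsAsFactors = FALSE)
}

#' Generate marker reference profiles and bait profiles with known
#' compartments
#'
#' Builds an MS-microscopy-style localization fixture: each compartment owns
#' a block of signature preys with high reference abundance; each simulated
#' bait profile is a noisy copy of its (known) compartment's marker profile
#' plus unlocalized background preys.
#'
#' @param seed integer seed.
#' @param compartments compartment names.
#' @param n_markers_per signature preys per compartment.
#' @param n_baits number of bait profiles to simulate.
#' @param signal mean avg_spec of signature preys.
#' @param noise_sd log-normal noise sd applied to bait copies of marker
#'   abundances.
#' @param n_background background preys appearing in every bait profile.
#' @return list with `reference` (compartment, prey_id, avg_spec), `baits`
#'   (bait_id, prey_id, avg_spec) and `truth` (bait_id, compartment).
#' @export
generate_marker_reference <- function(seed = 1L,
                                      compartments = c("chromatin",
                                                       "nucleoplasm",
                                                       "cytoplasm",
                                                       "plasma_membrane"),
                                      n_markers_per = 30L,
                                      n_baits = 20L,
                                      signal = 20,
                                      noise_sd = 0.4,
                                      n_background = 10L) {
  set.seed(seed)
  ref <- do.call(rbind, lapply(seq_along(compartments), function(i) {
    data.frame(compartment = compartments[i],
               prey_id = sprintf("marker_%s_%02d", compartments[i],
                                 seq_len(n_markers_per)),
               avg_spec = exp(stats::rnorm(n_markers_per, log(signal), 0.5)),
               stringsAsFactors = FALSE)
  }))
  bg_ids <- sprintf("bg_%03d", seq_len(n_background))
  truth <- data.frame(bait_id = sprintf("bait_%03d", seq_len(n_baits)),
                      compartment = sample(compartments, n_baits,
                                           replace = TRUE),
                      stringsAsFactors = FALSE)
  baits <- do.call(rbind, lapply(seq_len(n_baits), function(b) {
    comp <- truth$compartment[b]
    m <- ref[ref$compartment == comp, , drop = FALSE]
    rbind(
      data.frame(bait_id = truth$bait_id[b], prey_id = m$prey_id,
                 avg_spec = m$avg_spec *
                   exp(stats::rnorm(nrow(m), 0, noise_sd)),
                 stringsAsFactors = FALSE),
      data.frame(bait_id = truth$bait_id[b], prey_id = bg_ids,
                 avg_spec = exp(stats::rnorm(n_background, log(2), 0.5)),
                 stringsAsFactors = FALSE))
  }))
  list(reference = ref, baits = baits, truth = truth)
}
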