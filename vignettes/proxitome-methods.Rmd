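---
title: "Models and methods behind proxitome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind proxitome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxitome)
```

This vignette is the package's own account of its statistics and
conventions: what each stage assumes, which tunables matter, why the
defaults are what they are, and what the synthetic-data experiments do
and do not demonstrate about real data.

## The setting

Proximity labeling (BioID) and affinity purification (AP-MS) read out a
bait protein's interactome as spectral counts: for each purification run,
a table of prey proteins with peptide-spectrum-match (PSM) counts. Two
problems dominate the analysis. First, abundant sticky proteins co-purify
with everything; a contaminant repository built from negative-control
(GFP) purifications is needed to recognize them. Second, counts are noisy
and overdispersed, so calling an interaction requires a probabilistic
score, not a threshold on raw counts. Nuclear baits add a twist: the
background depends on where the control GFP was sent, so the repository
is stratified by localization tag (untagged, membrane-anchored MYR,
nuclear-export NES, nuclear-import NLS), and filtering for nuclear baits
checks the NLS stratum specifically.

## Contaminant repository

Control runs first pass QC: a run must detect at least
`qc_min_proteins` distinct preys (default 1000 for BioID, 300 for AP-MS;
the boundary is inclusive in both assays for consistency). Weak runs
would otherwise dilute detection frequencies. For every prey seen in at
least one passing run, the repository records per stratum:

* `pct` — percentage of the stratum's runs detecting the prey;
* `avg_spec` — mean PSM over the runs **where the prey was detected**
  (not over all runs: a rarely seen but abundant prey should look
  abundant);
* `max_spec` — maximum PSM.

Strata are `All` (every passing control), `NLS` and `MYR`. NES-tagged
and untagged runs contribute to `All` only: with typically very few NES
controls, a dedicated NES stratum would be too unstable to filter on. A
stratum with zero runs is omitted, not reported as zeros — absence of
evidence is kept distinct from evidence of absence.

## Scoring model

The scorer is a deliberately small, fully specified two-component count
mixture, in the spirit of spectral-count interaction scorers but with no
hidden state:

* **Background component**: negative binomial with mean
  `mu_0 = max(control AvgSpec, 0.1)`. The pseudocount 0.1 keeps the
  likelihood proper for preys never seen in controls; it is small enough
  that a single observed count dominates it.
* **True component**: mean `mu_1 = max(bait AvgSpec, min_fold * mu_0)`
  with `min_fold = 2`. The floor stops the two components collapsing
  when the bait counts resemble the background, which would make the
  posterior uninformative; 2x is the weakest enrichment we are willing
  to call a distinct component.
* **Dispersion**: one negative-binomial size parameter shared by both
  components, estimated from the control compendium by the method of
  moments pooled over preys (`size = mean(mu^2) / mean(var - mu)` over
  preys with var > mu). Controls are the only place where many
  replicates of the same null process exist. If no prey shows
  overdispersion the size falls back to 10 (mildly overdispersed
  Poisson); `score_params(nb_size =)` overrides the estimate.

Each replicate count receives the posterior probability of the true
component under equal priors, and the pair's probability is the mean of
the replicate posteriors. Equal priors keep the score a pure likelihood
comparison; the prior belief about interaction frequency is expressed
downstream by the BFDR cutoff instead.

The model-based false-discovery rate sorts a bait's pairs by decreasing
probability and sets `BFDR_k = mean(1 - p_(1..k))`; tied probabilities
share the value of the last tied rank, and ordering ties are broken by
prey identifier so output is deterministic. Scoring and BFDR are per
bait: baits with rich interactomes should not subsidize the error budget
of sparse ones.

**Consequence worth knowing**: because the probability is a *mean* over
replicates, one empty replicate caps a 4-replicate pair near 0.75 and it
will not pass BFDR < 0.01 except at the top of a long, clean list. The
model therefore prizes reproducibility across replicates over peak
abundance. Recovery experiments (below) are run in the no-dropout limit
for exactly this reason; with stochastic replicate dropout the ceiling
on sensitivity is roughly the fraction of pairs observed in all
replicates.

## The compound filter

A scored pair becomes a high-confidence interaction (HCI) iff

1. `bfdr < 0.01` (strict, "lower than");
2. for BioID, the prey is not a flagged contaminant in **any**
   elimination stratum (default `All` and `NLS`), where flagged means
   repository `pct >= 10%` without abundance rescue;
3. repository `pct < 10%` (strict) in the rescue stratum, **or** bait
   `avg_spec >= 3 *` repository `avg_spec` (inclusive, "three times
   higher").

Strict/inclusive readings are configurable but these defaults follow the
conventional wording of each rule. The rescue comparison is anchored on
the `All` stratum, the most stable one; `filter_policy(rescue_stratum=)`
changes it. Clauses are evaluated in first-fail order
(BFDR → elimination strata → frequency/rescue) and the per-record log
names exactly the clause that fired, which makes filter behavior
auditable and the monotonicity/idempotence properties testable. Bait
self-detections are excluded by default; they are trivially present and
would inflate per-bait totals. Preys absent from the repository are
treated as frequency 0 — never seen in a control is the strongest
possible evidence of specificity — and marked in the log.

## Downstream analytics

* **Clustering**: Pearson correlation between bait AvgSpec profiles, and
  Ward-linkage clustering (`ward.D2`, the variance-increase criterion)
  on Euclidean distances between rows. Raw AvgSpec is the default
  (matching common interactome-viz practice); `log_transform = TRUE`
  applies log1p first. Constant bait rows have undefined correlations:
  reported as `NA` and excluded from the tree with a warning rather than
  silently imputed.
* **Fisher enrichment**: per prey, the 2x2 table of detecting vs
  non-detecting baits in the study vs a reference bait collection;
  two-sided exact test (sum of tables with probability at most the
  observed), BH adjustment across preys, direction by detection-rate
  comparison. Per-prey rather than aggregate testing because the
  scientific output is a list of preys.
* **Hubs**: preys ranked by how many baits carry them as HCIs; all preys
  at the maximal count are reported, ties lexicographic.
* **Expression cross-referencing**: a prey is "expressed" when its RPKM
  exceeds the threshold (strict `>` by default) in at least one stage of
  the window; preys absent from the table count as not expressed and are
  listed, not dropped silently.

## Localization profiling

The published MS-microscopy service does not print its scoring formula,
so this module's formula is the package's own, chosen to honor the
method's description (quantitative profile comparison against marker
references) and its printed 0-1 scale: per compartment, the Pearson
correlation between log1p bait and marker profiles over the union of
their preys (absent = 0), truncated at zero, then divided by the maximum
across compartments. log1p tames the heavy right tail of spectral
counts; truncation means "anti-correlated with a compartment" reads as
"not there", not negatively there; max-normalization makes profiles
comparable across baits with different overall signal. The truncation
and normalization preserve ranking under global rescaling of the bait
profile even though log1p itself is not exactly scale-free. This is a
stand-in for the external service, not a reproduction of its scores.

## 9aaTAD scanning

Transactivation-domain candidates are found by scoring every 9-residue
window against per-position allowed-residue classes; the percent match
is the fraction of satisfied constraints. Two stringencies are shipped
(`inst/extdata/tad_patterns.cfg`): the moderate pattern constrains all
nine positions (acidic/polar anchors, bulky hydrophobic core at 3-4 and
6-7, no internal prolines at the free positions), the low pattern only
the hydrophobic core. The shipped classes are reconstructed from the
cited prediction tool's published rules — the tool itself does not
export its patterns — and are deliberately data, not code: edit the
configuration to change the definition, no reinstallation needed. All
overlapping windows are reported; `X` never matches; there is no
reverse-strand notion for protein sequences.

## Interval conventions

All interval inputs are 0-based half-open (BED arithmetic); overlap
means at least one shared base, so abutting intervals do not overlap.
Peaks are reduced to midpoints for TSS distance (deposited peak files do
not reliably carry summits; `summit_col` switches). Distances are signed
relative to the gene's strand, negative upstream. Category windows:
|d| <= 1 kb proximal promoter, |d| <= 3 kb outer promoter, then feature
overlap (gene body, or the supplied feature class), then <= 3 kb
downstream of a feature end, else intergenic; proportions always sum to
100%. Peak-set comparison counts a peak as shared when its
closest-distance to the other set is 0, i.e. it overlaps by at least one
base; each peak counts once per side, so the two sides' shared counts
can differ and both are reported.

## What the synthetic data emulates — and what it does not

`generate_runs()` reproduces the statistical structure the pipeline
assumes: a GFP control compendium with per-prey detection probabilities
(beta-distributed, median well below the 10% filter threshold, with a
long tail of frequent contaminants), a fraction of tag-class-restricted
contaminants (which is what gives the All/NLS elimination rule work to
do), bait runs seeing the shared plus nuclear background, and planted
true interactors at negative-binomial counts around `lambda_true`.
Technical replicates share their biological replicate's latent gamma
abundance with independent Poisson sampling, so within-pair correlation
mirrors a 2x2 design. Defaults follow the emulated study design: 21
baits, control compendium of 64 untagged + 24 MYR + 4 NES + 26 NLS runs,
25 true interactors per bait, `lambda_true = 20` over a background of
`lambda_bg = 1`, 5% replicate dropout.

Not emulated: peptide-level identification and protein inference,
abundance-dependent detection efficiency, correlated contaminant blocks
(e.g. whole complexes co-purifying), batch effects between acquisition
days, and bait-dependent background intensity. Passing recovery tests
therefore shows the statistical machinery is correct under the stated
model, not that real data meet that model.

Test problem sizes were chosen to keep the full suite in the tens of
seconds while leaving no stage untested at scale: unit fixtures use 3-10
baits over a few hundred preys and ~20 control runs; the full-scale
recovery experiment uses 100 baits x 2000 preys with the default control
compendium (118 runs), where planted-interaction sensitivity at
BFDR < 0.01 is about 99% with realized FDR near 1% before and 0% after
the compound filter. Recovery experiments run at `dropout = 0`, the
no-dropout limit discussed above.

## Numerical choices and degenerate inputs

* Pseudocount 0.1 wherever a control average of zero would otherwise
  divide or degenerate a likelihood (fold changes, background means).
* BFDR ordering ties broken by bait then prey identifier; probability
  ties share the last tied rank's value.
* Empty inputs return empty, typed results (`compute_bfdr`,
  `summarize_hcis`, `scan_9aaTAD` on short sequences); an empty peak set
  is an error for overlap proportions (0/0 is undefined, not 0).
* All-zero or constant profiles: correlation-based scores report 0 (with
  a warning) rather than NA propagating silently.
* All control runs failing QC is an explicit "empty repository" error.

## Known limitations

* The scorer is sensitive to missing replicates by construction (mean of
  replicate posteriors); see the scoring section.
* The shared-dispersion assumption borrows strength across preys but
  misfits preys with unusual variance; a per-prey dispersion would need
  more control runs than are typical.
* The localization formula is a documented stand-in for an external
  service whose normalization is unpublished.
* The 9aaTAD pattern classes are reconstructed, not exported from the
  original tool; expect qualitative, not per-residue, agreement.
* Fisher enrichment treats baits as exchangeable; correlated baits
  (paralogs run in the same study) violate that silently.
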