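---
title: "metameth: models, parameters and design decisions"
author: "metameth authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metameth: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the generative
model behind the synthetic data, the signal-processing and statistical
procedures, the tunable parameters with their defaults and rationale, and
the places where the design was genuinely open and a choice had to be
made. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. The problem

Bacterial N6-methyladenine (6mA) is laid down by methyltransferases at
short sequence motifs (GATC, CCATC, ...), usually on both strands of
palindromic motifs, at per-motif *modification ratios* — the fraction of a
motif's genomic occurrences whose focal adenine is methylated. Nanopore
sequencing sees 6mA as a perturbation of the ionic-current levels of the
~6 bases occupying the pore. Recovering a methylome therefore requires:
segmenting the raw current into per-base events, aligning events to the
reference, classifying each candidate adenine on each read, aggregating
reads into per-site frequencies, and only then computing the biological
summaries — motif ratios, methylation-usage profiles, phage motif
depletion, CDS enrichment. `metameth` implements the full chain plus a
generator that produces signals with known truth, so each stage can be
validated by planted-signal recovery and null calibration rather than by
eye.

## 2. The signal generator and its reference study conditions

The generator's defaults define the conditions under which every
downstream contract is exercised. They are fixed once, here, and the
acceptance checks run under them.

* **Pore model** (`build_pore_model`): each of the 4096 6-mers gets an
  expected level ~ U[60, 120] (pA-like units), an event spread
  ~ U[1.5, 3.0], and — for every adenine offset within the 6-mer — a 6mA
  level shift with |shift| ~ U[`shift_min` = 2, `shift_scale` = 8] and
  random sign, all from one seeded stream. The random sign is deliberate:
  it forces any caller to learn magnitude-like (sign-symmetric) functions
  of the level deviation rather than a single direction.
* **Methylation truth** (`assign_methylation_states`): every
  strand-resolved motif occurrence is methylated independently at the
  motif's target ratio (a focal adenine shared by several motifs takes
  the maximum applicable ratio); all remaining adenines on both strands
  are methylated at `background_rate`. Truth lives in genome coordinates
  on the template strand.
* **Reads** (`simulate_read`): placements uniform, read lengths
  N(1000, 200) bp, strands random. Per base, the 6-mer context window
  puts the current base at offset 3; every methylated adenine inside the
  window adds its shift (additively when several overlap, mimicking a
  modified base perturbing ~6 neighbouring events). Dwells are
  1 + Geometric(1/`dwell_mean`) samples with `dwell_mean` = 9 (about
  4 kHz sampling at 450 bases/s); samples are Gaussian with
  `noise_sd` = 0.5. Minus-strand reads emit the reverse-complement
  sequence with signal in molecule order; truth stays in template
  coordinates, which forces all downstream code to handle strand
  explicitly.
* **Coverage**: `coverage_mean` = 20x for study samples; read count is
  chosen as `coverage * genome length / read length`.
* **Prophage mode**: a central sub-interval has motif occurrences thinned
  so each *span* survives with probability 1/`depletion_factor`
  (palindromic motifs occur on both strands over one span, so thinning
  spans rather than strand-resolved occurrences keeps the realised factor
  equal to the nominal one); killed occurrences are broken by mutating
  one non-focal motif position to a base the motif does not admit.
* **Cohort mode** (`simulate_cohort_usage`): each individual draws one
  Dirichlet perturbation (concentration 50) of the expected per-motif
  site weights and keeps it for all timepoints; each (individual,
  timepoint) sample then draws its methylated sites from the genomic
  occurrence pools by a multinomial over motifs. Between-individual
  differences therefore dominate within-individual multinomial noise,
  which is the structure the methDiff layer is designed to detect.

What the generator does *not* emulate: homopolymer stalls and skips,
basecall errors, amplicon bias, per-read level drift, or real pore
chemistry. Passing tests show the pipeline's contracts hold under the
generative model above — they are not evidence about any particular real
dataset.

## 3. Resquiggling

**Segmentation** (`segment_events`): boundaries are local maxima of the
two-sample Welch *t*-statistic between adjacent windows of `w` samples
that exceed a threshold `t`, accepted greedily left-to-right with a
minimum event length of 2 samples. The defaults are `w` = 2, `t` = 2.5.
We initially ran `w` = 4, `t` = 4 and measured boundary recovery on
simulated reads at the reference conditions (noise 0.5, shifts up to 8,
geometric dwells with mean 9): ~30% of dwells are three samples or
shorter and 4-sample windows smear them, capping recovery near 0.71 (0.80
even noiselessly). With `w` = 2, `t` = 2.5, recovery is ~0.92 within one
sample, at the price of ~1.7 events per base of over-segmentation — which
the alignment is explicitly designed to absorb, because segmentation
over-splitting is benign while under-splitting destroys per-base
statistics.

**Alignment** (`align_events_to_reference`): banded dynamic programming
assigns each event to one base, monotonically; bases receiving no event
are "skipped" at `skip_cost` each; the objective is the summed
|event mean − expected level| plus skip penalties, with cost ties broken
toward the diagonal. Two numerical choices matter:

* The band half-width defaults to `2 * sqrt(n_events)` (floor 16) rather
  than a fixed small constant. Event counts per base fluctuate, so the
  optimal path drifts off the straight diagonal like a random walk; on
  1000-base reads a fixed 10-event band truncated the true path and
  tripled the rate of badly-fit bases (fraction of per-base z-scores with
  |z| > 2: 0.37 at band 10 versus 0.145 at band ≥ 50).
* `skip_cost` defaults to a fixed 10 — a few times the typical event
  spread. A data-driven rule based on high quantiles of pre-alignment
  level mismatch priced skips so high that bases whose event had merged
  into a neighbour were force-fitted instead of skipped, which corrupted
  both bases (|z| > 2 fraction 0.145 versus 0.09 at skip cost 10).

After alignment, the mapping is collapsed so every base maps to at least
one event (skipped bases inherit the nearest earlier event), and per-base
pooled means, spreads and dwells are computed from event sufficient
statistics.

**Feature windows** (`extract_feature_windows`): one window per
template-strand adenine, `W` = 17 bases wide, 7 features per base — the
event-mean z-score against the *unmethylated* pore-model level (the
caller must learn the shift; modified levels are unknown a priori in real
data), the pooled event spread, log dwell, and a one-hot base encoding.
Windows whose centre is within `W %/% 2` bases of a read or contig edge
are skipped. `W` = 17 is a default of this package, not an established
constant.

## 4. The caller

A dense network — flattened W x 7 features, hidden layers 64 and 32 with
rectifier activations, sigmoid output — trained with mini-batch Adam
(batch 128, learning rate 1e-3), cross-entropy loss, and a positional
validation split: all windows centred on a held-out 20% of genomic
positions form the validation set, so a read of the same locus can never
leak its label into validation.

Four training details are load-bearing, and all were driven by a single
failure mode: **sequence context can substitute for signal**. A window's
17-base context identifies its genomic position almost uniquely; since
all reads covering a position share its methylation state, an
unconstrained learner can reach high validation scores by memorising
context → label, and a model trained on motif-patterned data simply calls
every motif occurrence methylated (modification ratios saturate at 1.0
regardless of truth). The safeguards:

1. **Training control** (`simulate_training_control`): the caller is
   trained on a separate randomly methylated sample — every adenine
   methylated independently at rate 0.1 — sharing the study pore model.
   Context then carries zero label information and the only generalising
   solution is the signal-level shift. The 0.1 rate keeps methylation
   sparse enough that a neighbouring methylated adenine rarely confounds
   a window's label. This mirrors the real-world practice of training
   modification callers on methylated/unmethylated control samples
   rather than native reads.
2. **Context decay**: first-layer weights fed by the binary one-hot
   inputs carry a strong decoupled L2 penalty (`context_decay` = 0.3,
   versus `weight_decay` = 1e-3 elsewhere), making context unable to
   out-compete signal even when the training data would allow it.
   One-hot columns are also left on their natural 0/1 scale —
   standardising a rare indicator inflates it into a high-magnitude
   input that drowns the continuous features.
3. **Mirrored initialisation**: the first layer is seeded with +/-
   column pairs so rectifier pairs start as magnitude detectors; the 6mA
   shift has a random sign per context, so |z|-like functions are what
   the layer must represent, and plain random initialisation found them
   slowly or not at all.
4. **Model selection on validation AUROC** (patience 12, cap 120
   epochs): validation loss can degrade through calibration drift while
   ranking quality is still improving, and the sign-symmetric structure
   takes tens of epochs to emerge.

A logistic-regression reference (`logistic_baseline`) on the same
features is kept as a permanent regression guard: being linear it cannot
represent sign-symmetric shifts, and the network must match or beat it.
The decision threshold tau defaults to 0.5 and is overridable.

## 5. Site aggregation and filters

Per-read binary calls are grouped by (contig, position, strand):
`n_total` covering calls, `n_meth` positives, frequency their ratio.
Depth and breadth are computed from read reference spans, not from
per-adenine calls. A genome is eligible for profiling iff mean depth
>= 10x **and** breadth >= 0.8 — both inclusive, reading the thresholds
as minima. A position is a called 6mA site iff `n_total` >= 5 and
frequency >= 0.5; this site rule is an operational definition of this
package (no standard exists), and both parameters are exposed
everywhere they matter.

## 6. Motif statistics

IUPAC motifs carry an explicit focal-adenine offset (required for
degenerate motifs such as RAATTY, where the leading R also admits A).
Scanning uses `Biostrings` ambiguity matching on the forward strand and
on the reverse complement, mapping focal adenines back to genome
coordinates; matches over `N` are discarded as uninformative. The
modification ratio of a motif counts, among occurrences whose focal
adenine has depth >= 5, the fraction that are called sites; when no
occurrence qualifies the ratio is reported as missing, never as zero.

"5-mer methylation usage" is implemented as the normalised distribution
of reference 5-mer contexts centred on called sites, reverse-complemented
for minus-strand sites so the focal adenine is always the central base
read on its own strand. Centred-on-focal-A was chosen because motif
tables report the focal adenine; this is one of several defensible
readings of a usage profile and is localised behind
`kmer_usage_vector()` should another be preferred.

The enrichment scanner is a deliberately simple enumerative stand-in for
probabilistic motif discovery: per k-mer (k = 5, 7), a one-sided binomial
test of its frequency among site-centred contexts against the
adenine-centred genome background, Benjamini–Hochberg corrected across
all tested k-mers. It recovers planted motifs and stays quiet on uniform
methylation (both properties are tested), but it does not merge
degenerate variants the way an EM motif model would.

## 7. The methDiff layer

The comparison framework for methylation-usage profiles is: pairwise
Bray–Curtis distances; a one-sided Wilcoxon rank-sum test of
within-individual versus between-individual distances (within smaller);
principal-coordinates ordination; and PERMANOVA with individuals as
groups. Individuals represented by a single sample are excluded from the
within/between comparison and from PERMANOVA, and logged.

Every statistic is written from its formula and cross-checked in the
test suite against an independent route:

* Bray–Curtis against the closed form and `vegan::vegdist`;
* PCoA against exact reconstruction of Euclidean configurations and
  `ape::pcoa` (eigenvalues and axes up to sign); negative eigenvalues
  are dropped with their total magnitude reported;
* PERMANOVA's pseudo-F against `vegan::adonis2`, and its permutation p
  against exhaustive enumeration of label assignments for small n
  (`exact = TRUE` enumerates; the sampled version uses
  `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`, so p is never 0);
* the rank-sum test against direct enumeration of rank splits when
  `n_x + n_y <= 12` without ties, and a tie- and continuity-corrected
  normal approximation otherwise, validated against `stats::wilcox.test`;
* paired t, one-way ANOVA and correlation against `stats` and
  brute-force sums.

Degenerate inputs have defined behaviour rather than errors where a
definition exists: all-equal distances give p = 1; zero within-group
variance in ANOVA warns and reports the 0 bound; zero-variance paired
differences are an error (a t-statistic does not exist).

Null calibration is part of acceptance: over 200 exchangeable-null seeded
runs, PERMANOVA (199 permutations) and the rank, t, ANOVA and correlation
tests must reject at 1–10% at alpha = 0.05; the planted-signal cohort
(5 individuals x 3 timepoints) must be detected in >= 90% of 20 seeds by
both PERMANOVA and the within/between test, and label shuffling must kill
the signal in >= 90% of seeds.

## 8. Context analyses

Phage motif depletion compares strand-pooled motif occurrences per kb
between prophage intervals and their host remainder with a one-sided
paired t-test (phage < host); pairs with zero host frequency are kept in
the test but dropped from the ratio summary. CDS territory is merged into
a disjoint union before any density is computed, so overlapping gene
models cannot double-count; every called site falls in exactly one of
CDS/non-CDS by position, either strand. "Methylation ratio" of coding
versus non-coding regions is implemented as called-site density per kb;
per-site mean frequency is a defensible alternative and the per-gene
table carries the counts needed to compute it. Expression input is taken
as already normalised; genes without expression are dropped with a log
line, and at least 10 usable genes are required for a correlation.

## 9. Problem sizes and runtime

The acceptance suite runs, on one CPU: the full calling pipeline on a
100 kb genome at 20x with a 100 kb / 4x training control (~2 minutes);
methDiff planted-signal and shuffled-null over 20 seeds each with 999
permutations; 200-run null calibration for all tests; 10 phage–host
pairs; format and segmentation fidelity checks. These sizes were chosen
so a full run stays in single-digit minutes while leaving every
statistical check enough resolution to be meaningful (e.g. 199–999
permutations bound attainable p-values well below the 0.05 thresholds
being asserted).

## 10. Known limitations

* The caller is a small dense network on hand-designed features; it is a
  testbed for the pipeline's contracts, not a competitive basecaller,
  and its accuracy under real pore physics is untested by construction.
* The generator draws independent uniform levels per 6-mer; real pore
  models have strong k-mer correlations, and real noise is non-Gaussian.
* Site-rule thresholds (depth 5, frequency 0.5) and the eligibility
  filter are sharp cutoffs; no uncertainty is propagated through them.
* methDiff here is the Bray–Curtis / Wilcoxon / PCoA / PERMANOVA
  reconstruction of a usage-profile comparison; variants (per-species
  stratification, alternative distances) are out of scope.
* The enrichment scanner tests non-degenerate k-mers only.
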