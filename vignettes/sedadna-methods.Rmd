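---
title: "Models and methods behind sedapipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sedapipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

sedapipe analyses shotgun-sequenced sedimentary ancient DNA (sedaDNA):
very short, chemically damaged DNA fragments recovered from lake
sediments and permafrost. This vignette documents the models the package
implements, the defaults it chooses where the underlying methodology
leaves a choice open, and what its synthetic validation does and does
not demonstrate about real data.

## The synthetic data generator

The generator is first-class, tested code: every downstream method is
validated against read sets whose origin, fragmentation and damage are
known exactly (the *truth table*).

**Fragment lengths.** Degraded sedaDNA fragment-length distributions are
right-skewed with most mass between 30 and 90 bp. We draw lengths from a
log-normal parameterized by its mean and standard deviation, truncated
by rejection to `[min_len, max_len]`. Defaults — mean 55 bp, sd 15 bp,
bounds [30, 150] — are conventional figures for permafrost and
lake-sediment ancient DNA rather than estimates from any one dataset;
they are arguments, not constants. Truncation slightly raises the
realized mean above the nominal one (by ~0.5 bp at the defaults); tests
account for this.

**Deamination damage.** Post-mortem cytosine deamination in
single-stranded overhangs is read as C→T near the 5′ end of a fragment
and, mirrored, as G→A near the 3′ end. We use the standard
single-exponential shape: position $i$ (1-based from the end) is
deaminated with probability $p_1 e^{-\lambda (i-1)}$. Defaults
$p_1 = 0.2$–$0.25$, $\lambda = 0.3$ give a terminal rate in the range
typically seen in Pleistocene permafrost samples and an interior rate
indistinguishable from the sequencing-error background
(`seq_error`, default $10^{-3}$ per base, uniform). Both strands of a
molecule are equally likely to be sequenced (`strand` is uniform), and
damage is applied to the fragment as sequenced, so it always sits at the
biological fragment ends.

**Reference genomes.** One genome per species; congeners are independent
per-site mutants (probability = the configured divergence, always to a
different base) of a shared random genus-ancestor sequence, so the
realized Hamming distance to the ancestor is Binomial(L, d) and is
recorded. Genera and families are unrelated random sequences — a
deliberately hard case for specificity, since there is no shared deep
homology to absorb near-misses.

**Mitochondrial panels.** A random rooted bifurcating tree whose first
tip is an outgroup; every branch except the outgroup's terminal edge
receives a fixed number of substitutions at distinct sites
(infinite-sites at generation time), so each branch carries unambiguous
diagnostic markers and the branch→site map is retained as truth. The
outgroup edge is left unmutated because it is the polarization
reference: in an outgroup-polarized analysis a mutation on that edge is
indistinguishable from one on the ingroup stem, and leaving it clean
makes marker recovery exactly checkable. Homoplasy can be injected
post-hoc in tests to exercise marker rejection.

**Seeding.** Every generator takes one integer seed and draws all its
randomness inside `withr::with_seed()`, so identical arguments and seed
give byte-identical output and the caller's RNG state is untouched.

## Classification

Reads are matched **gap-free** against every reference sequence, both
strands, reporting every placement within the mismatch budget. At 30–90
bp, indels are rare enough that gap-free matching loses little, and it
makes "100% similarity" exact and auditable; this is a documented
limitation for longer fragments. An `N` on either side never counts as a
match. Identical read sequences are collapsed before matching and
re-expanded afterwards (each unique sequence is assessed once).

Assignment is deliberately conservative: only perfect (zero-mismatch)
placements enter the call; a read hitting one taxon is assigned to it, a
read hitting several taxa is assigned to their **lowest common
ancestor**, and a read with no perfect hit stays unassigned. Rank-level
collation then moves each assignment to its ancestor at the chosen rank;
reads assigned *above* that rank go to an "above-rank" ledger rather
than being silently dropped, so
`matrix + above-rank + unassigned = reads in` always balances.

Authentication filters mirror conservative sedaDNA practice: taxa seen
in any laboratory control are removed wholesale; taxa absent from a
regional checklist are dropped and logged; per-sample counts below
`min_reads` (default 3) are zeroed and taxa left in fewer than
`min_samples` samples are dropped. The thresholds are config keys, not
constants. Animal detections can additionally be confirmed as
*exclusive alignments*: a perfect placement in the focal taxon and no
placement within 1–2 mismatches anywhere else, which makes confirmation
of two different taxa by the same read impossible by construction.

Internally the matcher uses Biostrings (`vmatchPattern`, and a
trusted-band `PDict` batch path for the exact-match case); mismatch
counts are always recomputed N-aware in package code. Positions are
1-based, the R/Bioconductor convention, throughout.

## Damage authentication

The damage profile tallies, per position from the 5′ end
(strand-corrected), reference-C sites read as T, and mirrored
reference-G read as A from the 3′ end. The decision rule is a stated
formalization of "confirmed by damage patterns": call a detection
ancient iff the terminal C→T fraction reaches `min_terminal_rate`
(default 0.05) **and** a one-sided exact binomial test of the position-1
T count against the pooled interior baseline (positions 11–25 by
default) rejects at `alpha = 0.05`. Fewer than `min_obs = 10` terminal
observations yield an *undetermined* decision, distinct from a negative
one. Note one exact symmetry of the coordinate convention: reverse
complementing every read (with its strand flag flipped) swaps the
molecule's ends, so the 5′ C→T tally of the flipped set equals the 3′
G→A tally of the original — profiles mirror, and are only statistically
identical when `p1_ga` mirrors `p1_ct`.

## Abundance correction

Raw assigned-read counts confound organism abundance with sequencing
depth, per-sample degradation and per-taxon identification efficiency
(taxa with shared genomes lose reads to the LCA; damaged reads fail the
perfect-identity filter). Efficiency is estimated by simulation: draw
`n_sim` reads from the taxon under the sample's (fragment, damage)
condition, run the classifier end-to-end, and take the fraction
recovered at the collation rank. The corrected abundance is the minimal
estimator satisfying all three corrections:
$$a_{t,s} = \frac{r_{t,s}/e_{t,s}}{\sum_u r_{u,s}/e_{u,s}}$$
— depth cancels in the within-sample normalization, degradation enters
through condition-matched efficiencies, and efficiency enters
multiplicatively. Whether a multiplicative per-taxon correction or a
joint model is the better choice is genuinely open; the multiplicative
form is transparent and exactly testable on mixtures with known
composition. Taxa with no efficiency estimate, or $e = 0$ with positive
counts, are flagged and excluded with a warning rather than imputed.
`fit_sample_condition()` summarizes a sample's degradation state (mean
fragment length, terminal damage rate, binned) for condition matching.

## Community dynamics

Shannon diversity is $-\sum p_i \ln p_i$ in nats. Beta-diversity
defaults to incidence-based Sørensen dissimilarity
$1 - 2a/(2a + b + c)$, with Jaccard and abundance-based Bray–Curtis
selectable; incidence is the default because binned assemblages are
presence/absence unions. Time bins are half-open $[t, t + w)$ anchored
at age 0, with 2,000-year (pan-regional) and 5,000-year (regional)
widths as conventional presets; empty bins are emitted as placeholders
so turnover series keep their spacing, and pairs involving them are
undefined rather than zero.

**NMDS** is implemented in-package because downstream checks need a
per-iteration stress trace and bit-reproducible solutions under a seed.
Each random start alternates isotonic regression of configuration
distances on dissimilarity ranks (primary tie handling: tied
dissimilarities are ordered by current distance, so ties carry no
penalty) with a Guttman majorization update; iteration stops when
Kruskal stress-1 improves by less than `tol` ($10^{-7}$), the iteration
cap is hit, or a step fails to improve, in which case the pre-step
configuration is kept — so the recorded stress trace is non-increasing
by construction. The lowest-stress start is reported, centred,
principal-axis rotated, with a deterministic sign convention. Defaults:
50 starts, 500 iterations; a 100,000-restart budget is a configuration
ceiling, not a default. vegan's `monoMDS` is used in the test suite as
an independent oracle (our stress must match or beat it within a small
margin), never as the implementation. All-equal dissimilarity matrices
are flagged degenerate.

Axis–variable association uses the Pearson correlation with
$t = r\sqrt{(n-2)/(1-r^2)}$ and a two-sided $p$ at $n - 2$ df,
significant at raw $p < 0.05$; an optional Benjamini–Hochberg toggle is
off by default to match standard practice in this literature.
Zero-variance variables are flagged and never significant. Growth-form
composition sums abundance by a genus→form trait table over a fixed
vocabulary (tree, shrub, dwarf-shrub, forb, graminoid, aquatic) and
renormalizes over classified genera, reporting unclassified genera
separately.

## Phylogenetic placement

Branch markers are called from the reference alignment by outgroup
polarization: a biallelic, gap-free column whose derived-allele tip set
equals exactly one clade's tip set becomes a marker on that clade's
subtending branch; multiallelic and homoplasious columns are skipped and
logged. Observations are majority-rule per marker position (exact ties
discarded — this avoids double-counting damage-heterogeneous tallies),
giving per-branch support (derived observed) and conflict (ancestral
observed). A sample is placed at the node maximizing
$$\sum_{b \in \text{path}} (s_b - c_b) \; - \sum_{b \notin \text{path}} s_b,$$
so derived alleles private to other clades actively penalize a
placement and chimeric mixtures surface as low-margin, flagged calls.
Score ties resolve toward the shallower node — conflicting signal in two
daughter clades therefore falls back to their shared parent — and
equal-depth ties resolve deterministically by label and are flagged
ambiguous. Placements with fewer than `min_markers` (default 10)
informative observations are "unplaced". The `transversions-only` mode
drops C/T and G/A markers (the deamination-confusable classes) and is
the recommended mode for damaged samples. Haplogroup labelling returns
the deepest labelled clade ancestral to the placement; a placement above
all labels (e.g. at the shared root of two labelled sister clades) is
"basal". The score is a support/conflict heuristic validated by recovery
properties on synthetic panels, not a likelihood model, and tree
inference itself is out of scope — the tree is an input.

## Chronology and orchestration

Ages are consumed as already-calibrated years BP; radiocarbon
calibration is out of scope. Age–depth modelling is piecewise-linear
interpolation between dated horizons, refusing stratigraphic inversions
(age decreasing with depth) and refusing to extrapolate beyond the dated
range; per-segment sedimentation rates (cm/yr) are reported. Bayesian
age–depth models are deliberately not reimplemented.

`run_pipeline()` ties the stages together from a single YAML config
(unknown keys are rejected before any computation), derives every stage
seed from the one global seed, logs counts in and out of every filter,
and writes an MD5 manifest of all artefacts; the same config always
reproduces the same bytes.

## What the validation shows — and what it cannot

The test suite and `scripts/acceptance.R` validate, on synthetic data:
exact agreement of the LCA with a brute-force oracle (1,000 random
cases); ≥99% lineage recovery with zero cross-family assignments for
10,000 clean reads on a 2-family/8-species world at 5% congener
divergence; mutual exclusivity of exclusive-alignment confirmation
(1,000 reads); damage-rate recovery within 3 binomial standard errors
and clean ancient/modern separation over 20 replicates each side; k-mer
coverage closed forms (including the 39/70 single-substitution case);
recovery of a 3-taxon mixture with genome-sharing-forced efficiencies
(~1, ~0.5, ~0.25) within 3 multinomial standard errors; community
closed forms; NMDS stress < 0.01 on metric 3-D data with a monotone
trace and bit-identical reseeded solutions; ~5% correlation type-I
error; ≥95% correct terminal-branch placement over 100 replicates at
5× coverage on an 8-tip panel; exact age–depth interpolation; and
byte-identical reruns of the bundled demo. Problem sizes (1,000-bp
genomes, 3,000-bp panels, 10,000-read samples) were chosen so each
property has adequate statistical resolution while the whole suite runs
in minutes on one CPU.

These checks demonstrate the *correctness of the machinery*, not field
performance. The generator does not model PCR duplicates, index-hopping,
genome-size-driven abundance skew, contamination with close modern
relatives, reference databases with biased or partial taxon coverage, or
indels — so passing tests bound what can go wrong in the code, not what
a real sediment core will do to the biology.
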