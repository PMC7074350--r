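---
title: "Testing repeat-abundance additivity in allopolyploids with polyrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing repeat-abundance additivity in allopolyploids with polyrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyrep)
```

## The question and the measurement

An allotetraploid inherits two complete repeatomes. Under strict
additivity, the abundance of every repeat family in the tetraploid is
the sum of the two parental abundances; departures — amplification of
large families, genome-wide loss, preferential erosion of one parental
subgenome — are the signal of post-polyploidy genome restructuring.

Repeat abundances are measured without assembly. Reads are sampled at a
fixed genome proportion: each species contributes reads whose total
bases equal the same fraction (default 2%) of its 1C genome size, so a
repeat family occupying the same number of base pairs in two genomes
yields the same expected read count in both, regardless of genome size.
Reads from the maternal parent, paternal parent and tetraploid are
tagged with five-letter species codes, pooled, and clustered by
similarity; per-cluster, per-species read counts are then the abundance
estimates everything downstream consumes.

## Pipeline stages and their parameters

**Read preparation.** Reads are discarded if any base has Phred quality
at or below 10 or if they carry more than 3 ambiguous bases, then
truncated to 91 bp (the 5' prefix; a standard convention — nothing
downstream depends on which end survives). The quality floor is
deliberately mild: satellite-like AT/GC-rich repeats tend to have lower
base qualities, and aggressive filtering biases their abundance
downward. Whether the floor applies per base (default) or to the read
mean is configurable (`per_read_mean`); the strict per-base reading is
the default because it is the literal form of the rule. Subsampling to
the genome proportion draws `round(proportion × 1C / read_length)`
reads uniformly without replacement; rounding is half-away-from-zero
everywhere counts are involved, because abundances are counts and the
symmetric rule keeps the additive arithmetic exact.

**Similarity graph.** Candidate pairs must share at least 2 distinct
17-mers; each candidate is scored by an ungapped overlap alignment
evaluated at every offset whose overlap covers at least 55% of the read
length, and an edge requires identity ≥ 0.90 in the best overlap, with
weight identity × coverage. Simulated reads contain substitutions only,
so the exhaustive offset scan *is* the exact banded alignment for this
error model; on real data with indels it is an approximation that
slightly understates identity. Comparison is strand-aware
(forward–forward), matching the single-strand simulation; real
libraries would need reverse-complement handling, which only the
contaminant screen implements (canonical k-mers), because its
references are real double-stranded genomes.

**Clustering.** Connected components first; components above 100
vertices are split by weighted fast-greedy modularity maximization.
Reads overlap only when their positions within a repeat unit are close,
so a single family's subgraph is a chain along the unit coordinate, and
raw modularity optimization cuts such chains into positional segments.
A split is therefore kept only where the cut is weak: communities still
joined by 10 or more edges are merged back. The two situations separate
cleanly — a genuine continuation of one unit produces an overlap band
of tens of edges across any positional cut, while distinct families
lumped by chance share isolated edges. Vertex order is lexicographic in
read id and the algorithm draws no random numbers, so cluster tables
are reproducible byte for byte.

**Filtering.** A species "has" a cluster when it contributes at least
`min_reads = 10` reads. The removal rules, applied in order with one
logged reason each: contaminant-flagged clusters (≥ 50% of member reads
sharing a canonical 17-mer with a reference); clusters present in fewer
than two species (species-specific); clusters absent from the
tetraploid. The presence rule has two defensible readings — the default
treats ≥ 10 reads as a per-species presence call and keeps clusters
present in at least two species including the tetraploid, which
guarantees positive counts wherever a log-regression uses them;
`require_all_species = TRUE` gives the strict all-three reading.
Clusters present in both parents but lost from the tetraploid are a
real downsizing signal; `keep_parents_only = TRUE` retains them, marked
usable for deviation curves only (with t = 0 they can never enter a log
regression), while the default drops them so that the default table
satisfies the per-species rule exactly.

**Additivity statistics.** E = m + p and D = t − E in exact integer
arithmetic. The cumulative curve ranks clusters by E ascending (ties by
cluster id) — E is the comparison baseline, though ranking by t or by
m + p + t is selectable — and plots cumulative D against the natural
log of cumulative E. The signed cumulative deviation is primary: only
it can show loss below zero; the absolute value is carried alongside
for reporting.

**Parental-bias statistics.** Log-log OLS fits are computed from
closed-form normal equations; `lm()` and `car::linearHypothesis()`
serve as independent oracles in the test suite, never as the
implementation. The slope comparison stacks the two parental datasets
with a paternal indicator and F-tests the interaction term with
1 and n − 4 degrees of freedom — the canonical realization of a
two-slope equality test, and the one that reproduces the published
schema (Sum of Sq., F, p). Stacking pools the residual variance across
the two halves; treating the parental fits as independent regressions
would estimate two variances, and the choice is recorded in the output
metadata. Clusters with any of m, p, t below the presence threshold are
excluded from the stacked test (their logs do not exist at zero), and
the exclusion count is reported.

## What the simulator emulates — and what it does not

`simulate_parents()` draws a shared family set with copy numbers from a
bounded power law (floored bounded Pareto on
[`min_copies`, `max_copies`], default exponent range fitting the
heavy-tailed family-size distributions of plant repeatomes), perturbs
each parent's copy numbers with lognormal noise, and diverges the
parental consensus sequences symmetrically. `apply_inheritance()`
builds the tetraploid under one of three regimes — additive,
parent-biased (t = m + round(ρ·p)), or size-dependent (families at or
above a copy threshold scaled by a factor) — emulating the empirical
spectrum from near-additivity through upsizing to downsizing. The
tetraploid keeps both parental consensus variants as separate subgenome
rows, so its reads carry subgenome-specific sequence. Reads fall wholly
within one repeat copy or the single-copy background (no junction
reads), which keeps per-read ground truth unambiguous for recovery
tests; the source copy's sequence is materialized at draw time by
mutating the consensus window at the family's per-copy divergence.
Base qualities are a constant placeholder Phred 35, which passes the
quality filter by construction unless a test deliberately lowers them.

Not emulated: indels and quality-score error models, paired-end
structure, junction/chimeric reads, nested or truncated repeat copies,
library and GC bias, and reverse-strand reads. Passing tests therefore
demonstrate the correctness of the statistics and the clustering logic
under a clean substitution-only error model — not robustness to every
artifact of real libraries.

## Calibration experiments and the noise-regime caveat

The stacked slope test reuses the same tetraploid response in both
halves, so the independence assumption behind the F reference
distribution is an approximation whose quality depends on what
dominates the residuals.

* In the *count-noise regime* (between-parent abundance divergence
  small, `perturb_sd = 0.25`; residuals dominated by multinomial
  sampling noise, which is independent between the maternal and
  paternal observations of a cluster), the test holds its nominal
  level: 4.6% rejection at α = 0.05 over 1000 additive datasets of 100
  families.
* In the *divergence-dominated regime* (`perturb_sd = 1.0`, parental
  family abundances differing by multiples, as expected for diploids
  separated by millions of years), the shared response makes the test
  conservative (empirical level ~0–2%). Power quoted under this regime
  is therefore a lower bound: a paternal bias of ρ = 0.5 is detected in
  93% of datasets with ~200 usable clusters.

Any analysis that stacks one tetraploid against each parent inherits
this behavior; it is a property of the design, not of this
implementation. The two regimes are reported separately by
`slope_test_experiment()` and the acceptance script.

Problem sizes used throughout the tests were chosen to estimate each
quantity to useful precision: 1000 replicates for the level (SE ≈
0.7%), 150–200 for power, 50,000 reads per species for the additivity
null (where the maximum |cumulative deviation| stays below 0.5% of the
total expectation, comfortably within the 2% bound binomial sampling
implies), and ~1200 reads for cluster recovery, where planted families
are recovered with adjusted Rand index ≥ 0.97 and the edge set equals a
brute-force all-pairs enumeration of the full edge rule.

## Numerical and degenerate-input conventions

* Rounding of counts: half away from zero, everywhere.
* Simulated repeat content exceeding the genome's repeat budget is
  rescaled proportionally with a message, never silently truncated.
* Cluster ranking ties: by the lexicographically smallest member read
  id (tabulation) or cluster id (curves), making all tables
  deterministic.
* Regressions require n ≥ 3 (plane: n ≥ 4) and positive predictor
  variance; collinear designs raise errors naming the degeneracy.
* Empty outcomes degrade gracefully: an empty read set after filtering
  warns and propagates; an empty cluster table yields a valid JSON
  report with figures skipped; a zero-read subsample warns.
* "Within-family divergence" is parameterized as the per-copy
  divergence from the family consensus; pairwise divergence between
  two family members is roughly twice that.

## Known limitations

The clustering stage is a deliberately simplified stand-in for
full-scale graph-based repeat clustering tools: no satellite detection,
no protein-domain annotation, no consensus assembly, no claim of
cluster-for-cluster agreement with any external tool — which is also
why published per-dataset test statistics, which depend on a specific
clusterer's output, are out of scope for numeric reproduction here.
Genome sizes enter as user-supplied 1C values; the pipeline does not
estimate them. And the slope-equality test, as published and as
implemented, compares pooled regression slopes — it localizes neither
which families drive a bias nor distinguishes bias in large families
from bias in many small ones; the deviation curve is the complementary
view for that.
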