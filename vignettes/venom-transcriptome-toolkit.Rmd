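---
title: "Methods: assembling and quality-filtering venom-gland transcriptomes"
author: "venomtx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembling and quality-filtering venom-gland transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A venom gland expresses tens of toxin transcripts at extreme abundance on
top of ordinary housekeeping transcripts. The medically and evolutionarily
important toxin families — metalloproteinases (SVMP), serine proteases
(SVSP), C-type lectins (CTL) — occur as multigene families whose paralogs
run at roughly 95–99% nucleotide identity. General-purpose assemblers
traverse graphs in which those paralogs share most of their k-mers, and so
either collapse a family into one contig or emit chimeras that join two
paralogs at a shared stretch. `venomtx` implements the toxin-focused
stages that address this: lane decontamination, a perfect-overlap
seed-and-extend assembler, an annotation cascade, coverage-based chimera
screening, completeness accounting, and a simulator that makes each stage
testable against known truth.

## Lane decontamination (57-mer cross-leakage filter)

Samples multiplexed in one lane exchange a small fraction of reads through
index misassignment. Because a hopped read carries the donor's sequence,
its k-mers are abundant in the donor and near-absent in the recipient. The
filter counts canonical 57-mers (the lexicographic minimum of a k-mer and
its reverse complement; k must be odd so no k-mer is its own reverse
complement) over all N-free windows, flags k-mers whose count differential
between a sample pair exceeds 500× (strict; a zero count is treated as 1
so that sequencing-error singletons cannot be flagged against), and
removes a read from the lower-count sample when at least 25% of its
usable windows are flagged. With more than two samples per lane every
ordered pair is processed independently and a read is removed if any
pairwise rule removes it.

One structural property matters when validating this filter: the counted
recipient includes the contamination itself, so for a hopping fraction
*f* the donor:recipient count ratio of a leaked k-mer is at most about
1/*f*. A ratio threshold of 500 therefore presupposes hopping rates below
1/500 = 0.2%; the package's recovery experiment spikes a realistic 0.1%
of one sample into another (two disjoint simulated transcriptomes,
100,000 read pairs each, skewed expression), where the detectability
condition holds for the well-covered transcripts that dominate the reads.
When one mate of a pair fails the filter only that read is removed; the
pipeline wrapper drops orphans before merging.

## Preprocessing

3′ quality trimming is the running-sum rule: cut at the suffix position
maximizing Σ(threshold − q) over the removed bases (threshold phred 5),
discard reads shorter than 75 nt afterwards. The operation is idempotent.
Pair merging reverse-complements the R2 read and scores every overlap of
length ≥ 10 nt with mismatch fraction ≤ 0.02 by matches − mismatches
(ties to the longest overlap); disagreeing columns take the
higher-quality base and merged qualities are the columnwise maximum.
These are deliberately minimal re-implementations so the pipeline runs
end-to-end; they do not attempt to reproduce any external trimmer's exact
output, and adapter handling is out of scope (the simulator produces
adapter-free reads).

## The seed-and-extend assembler

Parameters (defaults in parentheses) follow the published venom-gland
parameterization:

* `n_seeds` (1000): seed reads drawn uniformly without replacement from
  merged reads whose every base is ≥ phred 30 and whose length is at least
  the overlap length. An accepted seed claims all its 120-mers (both
  strands); later candidates sharing any of them are rejected, so two
  seeds cannot nucleate the same path.
* `overlap_len` (120 nt): the minimum *mismatch-free* overlap a read must
  share with the contig terminus to extend it, the core of paralog
  separation.
* `extend_min_quality` (20): reads with any base below this never enter
  the overlap index; reads containing N are never candidates.
* `replicates_per_direction` (20) and retention: a replicate repeatedly
  picks one candidate uniformly at random until none remains; a seed is
  retained only when, in each direction, at least
  max(2, ⌈0.2 × 20⌉) = 4 replicates extended. The published description
  states both an absolute two-extension minimum and a 20% fraction; the
  conjunction is the strictest reading consistent with both and is the
  package's choice.
* Consensus: the retained seed's flanks are the columnwise majority over
  the extended replicates' extensions, truncated at the first column with
  support below 2 or with a tied majority — no emitted base rests on a
  single replicate. How the original tool reduced replicates to one contig
  is not published; majority-with-truncation is the conservative choice.
* A 50 kb length cap guards repeat-induced loops; reads are reusable
  (coverage is not consumed). Exact-duplicate and exact-substring contigs
  are collapsed, keeping the longest.

The overlap index stores each eligible read in both orientations keyed by
its 5′-terminal 120-mer; candidate search slides that key across the
contig's terminal region and verifies the full overlap base-by-base. This
is memory-proportional to the read set (not to all windows) and
enumerates exactly the reads with a mismatch-free overlap ≥ 120 nt that
protrude past the contig end — the property the exhaustive-enumeration
oracle test asserts. All randomness (seed sampling, candidate choice)
runs on R's RNG, so `assemble()` is byte-deterministic given
`rng_seed`.

Why this separates paralogs: the simulator guarantees (and real SVMP
families typically satisfy) at least one divergent site in every 120 nt
window between any paralog pair, so a replicate would need a
mismatch-free 120 nt overlap spanning a divergent site to cross — which
is impossible with error-free overlaps. The seed-sampling side is
analytic: a transcript contributing a fraction *f* of the reads is seeded
at least once with probability 1 − (1 − *f*)^S; at *f* = 1000/10⁷ and
S = 1000 that is ≈ 0.095, which is why low-expression transcripts escape
the assembler and why complementary assemblers remain necessary.

## Annotation and deduplication

Contigs below 150 nt are discarded (no shorter venom gene is known in
snakes or scorpions). Each reference CDS is aligned to each contig strand
semi-globally — reference end-to-end, contig local — under unit scoring
(match +1, mismatch −1, gap −1); identity is matches divided by all
alignment columns of the aligned region, so an unmatched reference half
counts as gap columns and "covers only half the reference" fails the 80%
threshold while contig UTRs cost nothing. The single best reference wins,
with ties broken by longer reference then lexicographic name. Coding
regions are clustered greedily longest-first at ≥ 98% global identity
(either strand), mirroring the conventional behaviour of cd-hit-est but
with exact alignment identity instead of a word heuristic, so calls at
the printed threshold are exact. All interval arithmetic is 0-based
half-open.

## Chimera screening

Merged reads are mapped to each coding region as full-read exact
substrings (both strands, zero mismatches, multi-mapping reads counted at
every position — depth here is evidence of sequence support, not
fragment assignment). Three filters follow, in the printed inequality
directions: coverage > 0 at every base; max/min coverage strictly below
100; and a segmentation probability of non-chimerism strictly above 0.9.

The segmentation score is an explicit, testable surrogate for the
"segmentation probability" black box of assembly-evaluation tools:
per-base depths are transformed to log2(depth + 1), averaged into 30
equal-width bins, and two Gaussian models are compared — one segment
(mean + variance, 2 parameters) versus the best two-segment split over
all change points (two means + pooled variance + change point, 4
parameters) — by BIC weight, exp(−BIC₁/2)/(exp(−BIC₁/2) + exp(−BIC₂/2)),
in log space. Numerical choices that matter:

* **Variance floor 0.25** (sd 0.5 in log2 units ≈ 1.4-fold depth
  fluctuation): binned read coverage fluctuates this much under the null
  because neighbouring bins share reads; segmentation evidence must
  exceed it. The likelihood is evaluated at the floored-variance MLE,
  −B/2·(log 2πv̂ + 1), so when both models sit at the floor the data term
  cancels exactly and only the parameter penalty differs — sub-floor
  wiggles contribute zero evidence. Counting the change point as a
  parameter is essential: with only one extra parameter the weight could
  never exceed 1/(1 + B^(−1/2)) ≈ 0.85 < 0.9 and nothing would pass.
* **Edge trimming**: under strict full-read containment no read
  overhanging a CDS end can map, so coverage ramps structurally to ~0
  within one read length of each terminus. `classify_cds()` passes the
  median read length as `edge_trim`, capped at a quarter of the CDS per
  side, so the score judges the interior. The coverage > 0 filter still
  sees the full profile — which is precisely what catches chimeras, whose
  junction no read can span.
* Exactly uniform profiles return 1; the score is invariant to uniform
  depth scaling and non-increasing in step severity.

On 100 simulated genuine transcripts and 100 half-half chimeras with
parent-only reads at depth 50, the suite requires ≥ 95% of genuine
transcripts to pass all three filters and ≥ 95% of chimeras to fail at
least one; the dominant chimera signal is the junction coverage trough.

## Reporting

`family_counts()` partitions annotated CDS by family and verdict;
`length_class_counts()` uses a strict `< cutoff` with default 500 nt (the
published analyses print both 500 and 1000 nt; the cutoff is a
parameter). `presence_matrix()` marks a reference transcript present at
≥ 98% identity on either strand (inclusive, unlike the strict coverage
inequalities — both follow the printed directions), and
`best_combination()` searches all method subsets exhaustively, which is
exact at the scale of a dozen assemblers. `ols_regression()` wraps
`stats::lm` with the two-sided slope t-test and explicit degenerate
rules. `seed_sampling_probability()` uses the draws-with-replacement
approximation; the exact without-replacement form differs by under 10⁻⁴
at sequencing scale.

## The simulator, and what passing tests do not show

`simulate_family()` draws a uniform-random ancestor and mutates each
paralog independently at the per-site rate r solving
(1 − r)² + r²/3 = target identity, then patches any 120 nt window in
which a pair is identical (a substitution at the midpoint of the run,
differing from both), erroring for targets above 0.99 where the window
rule is unsatisfiable. The default transcriptome is one SVMP-like family
(6 paralogs, 1400–1800 nt), one SVSP-like (4, 700–800 nt), one CTL-like
(5, 400–500 nt), eight single-copy toxins of mixed lengths, and 50
nontoxins (500–3000 nt), with expression heavily skewed toward the toxin
families — the structure venom-gland reads actually have. Fragments are
Gaussian (mean 250, sd 25 nt) with starts drawn so fragments clip at
transcript boundaries, the way size-selected libraries pile fragment ends
at transcript termini; this keeps terminal coverage positive, which the
coverage > 0 filter presumes. Errors are i.i.d. substitutions; qualities
are two-level (default 97% at phred 38, 3% at phred 12), enough to
exercise the quality-30 seed and quality-20 extension gates.

Deliberate simplifications, hence limits on what green tests prove about
real data: no indels in either mutation or error model (the exact-overlap
and exact-mapping contracts under test are substitution-sensitive;
indel-tolerant alignment is out of scope), no adapter read-through, no
PCR duplicates, no splice isoforms, no empirical quality profiles, and
paralog divergence that is uniform along the sequence rather than
domain-structured. The assembler's separation guarantee is proven only
under the one-divergent-site-per-120-nt condition; real families with
long identical stretches between paralogs can still collapse.

## Problem sizes

The validation suite runs at desk scale, chosen so each experiment still
sits in the regime its method assumes: paralog recovery uses 200,000
error-free merged reads over a six-paralog 1600 nt family with 200 seeds;
the filter operating characteristics use 100 + 100 transcripts at depth
50; lane decontamination uses two 100,000-pair samples with 0.1%
hopping. `scripts/acceptance.R` re-runs all of these from scratch and
writes the resulting numbers as JSON.
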