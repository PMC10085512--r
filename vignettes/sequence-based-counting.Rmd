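---
title: "Sequence-based counting for small RNA sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based counting for small RNA sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The counting model

Feature-based RNA-seq pipelines align reads to one target genome and sum
them into features (genes, miRNAs), discarding the read sequences.  Two
reads with different lengths or different variants contribute to the same
feature count, and reads that fail to align — degradation products,
contaminants, sequences from other species — vanish silently.

pacseq instead keeps the exact read sequence as the unit of analysis.
After adapter trimming, identical insert sequences are tallied across
samples into a count table of *unique sequences*.  The table lives in a
PAC object of three aligned tables:

* **Pheno** — one row per sample (metadata, group labels, covariates);
* **Anno** — one row per unique sequence, keyed by the literal sequence
  string, starting with its length and growing annotation columns over
  time;
* **Counts** — an integer matrix, sequences × samples.

The structural contract is strict: the Counts row keys equal the Anno
keys in the same order, and the Counts column keys equal the Pheno sample
ids in the same order.  `pac_check()` verifies this contract and every
operation that returns a PAC re-establishes it, which is what makes late
re-annotation safe: annotation never overwrites counts, it only appends
columns keyed by sequence.

An *evidence filter* controls entry into the count table: a sequence must
reach `min_count` reads in at least `min_samples` samples (default 2 and
2 — a conservative noise filter; `evidence_filter(1, 1)` keeps every
read).  Row order is deterministic (total count descending, ties
lexicographic), so outputs are byte-reproducible.

## Adapter trimming

In a small-RNA library the insert (16–45 nt typically, seldom above
75 nt) is shorter than the read, so the read runs through the insert into
the 3′ adapter.  Detecting the adapter is therefore both how the insert
is delimited and evidence that the full insert was sequenced; reads
without a detectable adapter are discarded by default (`policy_no_adapter
= "keep"` is available for other library types).

The search is substitution-only, leftmost-first: the adapter start is the
smallest position `p` such that `read[p..]` matches a prefix of the
adapter with overlap ≥ `min_overlap` (default 10 nt) and at most
`floor(max_mismatch_fraction × overlap)` mismatches (default fraction
0.1).  Leftmost tie-breaking yields the shortest insert, which is
conservative against adapter read-through.  After cutting, filters apply
in a fixed order — no-adapter policy, insert size range (default 16–75
nt), ambiguous-base limit (default 0 `N`), mean-Phred threshold over the
insert (off by default) — and each read receives exactly one outcome, so
the per-sample report categories always partition the input reads.

A geometric consequence worth knowing: with 50-nt reads and
`min_overlap = 10`, inserts longer than 40 nt leave fewer than 10 adapter
bases visible and are unrecoverable by design (they are discarded as
"no adapter").  This mirrors real libraries, where the read length bounds
the recoverable insert size.  The end-to-end recovery tests therefore
simulate inserts of 16–40 nt; the simulator's default insert range
(16–45 nt) intentionally includes the unrecoverable tail.

## Alignment and hierarchical reannotation

Re-annotation aligns each unique sequence end-to-end (ungapped, Hamming
distance ≤ k, both strands) against any number of named reference sets.
Indel-free matching reflects the error model of very short reads; k is
capped at 3 because chance placements inflate rapidly with k (see below).
The aligner reports *all* placements — forcing a short repeated sequence
onto a single locus is arbitrary, so multimapping is resolved only at
class level.  Internally, perfect matches are batch-screened with
`Biostrings` PDict matching and mismatch placements use
`matchPattern`/`neditStartingAt`; the test suite holds both paths equal
to an independent sliding-window Hamming scan.

Per reference set the table records the *mismatch stratum* — `mis0` …
`mis3`, the minimum mismatch over all placements, or `no_hit` — plus the
number of placements at that stratum.  A user-declared hierarchy (an
ordered list of class → reference set(s)) then resolves one class per
sequence.  Two policies exist: `strict_hierarchy` (default; the first
class with any hit wins, e.g. rRNA outranks miRNA regardless of
mismatches) and `prefer_less_mismatch_within_class` (minimal stratum
wins, hierarchy breaks ties).  Unresolved sequences become `no_anno` —
they stay in the table, available for contamination analysis.

`false_positive_curve()` quantifies why k is capped: it draws completely
random sequences with a chosen length distribution, aligns them, and
reports the fraction placing at each k.  Because the hit set at k is a
subset of the hit set at k+1, this fraction is provably non-decreasing;
on random 20-mers against a random 100-kb reference the perfect-mapping
rate is essentially zero while k = 3 already places a measurable
fraction.  The inflation *ratio* (k = 3 vs k = 0) is only defined where
the k = 0 rate is non-zero, so the acceptance script computes it on
shorter probes (10–14 nt) where chance perfect placements occur at desk
scale.

## tRNA-derived fragment classification

tRF subtypes are positional: given a tRNA reference with a known
anticodon-loop interval, the placement of a fragment decides its label.
A terminus is *anchored* when it lies within `end_tolerance` nt of the
reference terminus (default 0; 1–2 absorbs non-templated additions).
Both termini anchored → `whole-tRNA`; 5′-anchored with the cleavage
point strictly inside the anticodon loop → `5p-half`, otherwise
`5p-tRF`; symmetrically `3p-half` / `3p-tRF`; neither → `i-tRF`.
"Strictly inside" means the half-open cut coordinate satisfies
`loop_start < cut < loop_end`; the loop interval is supplied per tRNA, so
any convention can be configured.  The six labels partition every
possible placement — the tests enumerate all substrings of a toy tRNA
and check each against an independently coded rule table.

The 3′ terminus is the end of the CCA-inclusive reference when the model
carries the post-transcriptional CCA: a fragment stopping at the body
end is then 3 nt short of the terminus and classifies as internal at
zero tolerance.  Classification uses only the model's coordinates —
no species-specific lookup table — and placements on several tRNAs are
either all reported (default) or condensed to a majority label with a
fixed-order tie-break.

## Composition, PCA and the yield-loss model

Normalization is counts per million (`count × 10⁶ / library size`);
variance-stabilizing alternatives are out of scope here.  PCA operates on
`log2(CPM + 1)`, samples as observations, centered but not scaled — the
standard transform for count ordination.  Components are computed by SVD;
signs are fixed so each loading vector's largest-magnitude element is
positive, making scores bit-reproducible across runs and platforms.
`var_explained` equals squared singular values over total variance and
sums to one at full rank.

When a contaminant occupies fraction *x* of a library it displaces target
reads, and the displacement saturates: once the contaminant dominates,
additional contamination changes composition little.  This is the same
saturating response weed scientists use for crop yield loss against weed
density, the rectangular hyperbola

$$y = \frac{I\,x}{1 + I\,x/A}$$

with initial slope *I* (response per unit contamination as x → 0) and
asymptote *A*.  `fit_yield_loss()` estimates (I, A) by bounded nonlinear
least squares (`minpack.lm`, A > 0) from three deterministic starts —
I from the median slope over the lowest-x quartile, A from max |y|, and
scaled variants — keeping the best residual sum of squares; the fit is
invariant to sample order.  `variance_vs_contamination()` orients PC1 so
its correlation with contamination is non-negative, reports the Pearson
correlation, and fits the model to PC1 shifted so its minimum is zero
(the model passes through the origin while PC scores are centered).
Constant contamination yields an explicit degenerate result rather than
an error.

## The synthetic experiment

The simulator emulates the structure such a study needs: several *source
pools* (e.g. host vs microbiota), per-sample mixture fractions, inserts
sliced uniformly from pool sequences, substitution errors at a per-base
rate, fixed 50-nt reads with adapter read-through, constant Phred-40
qualities (optionally uniform-random for quality-filter tests), and an
optional fraction of adapterless reads.  Every read carries a
ground-truth record (pool, source, coordinates, error-free insert), so
trimming, counting and annotation are checked exactly, not
approximately.  Identical specifications produce byte-identical FASTQ.

It deliberately does not model PCR duplication, GC bias, chemical
modifications or indels, and pool references are random sequences with no
homology between pools.  Passing tests therefore demonstrate the
machinery is exact under its stated error model, not that real genomes —
with repeats, homology and modification-induced mismatches — behave this
cleanly; on real data the hierarchy and mismatch strata are the tools for
exactly that murkiness.

The contamination experiment used by the tests and the acceptance script
runs 12 samples with contaminant fractions 0 to 0.55 in steps of 0.05,
2 000 reads per sample, two 150-nt sources per pool and 20–24-nt inserts.
These sizes give each unique sequence a workable expected count, which is
what lets composition dominate PC1; the PC1–contamination correlation
threshold (0.9) was calibrated on this design by simulation across seeds
(observed ≈ 0.99).  Other deliberate sizes: the aligner oracle panel is
500 queries × k ∈ {0..3} on a 2-kb reference (both strands), the
false-positive curve uses 2 000 random 20-mers on 100 kb, the structural
invariants run over 100 randomized operation sequences, and Monte-Carlo
yield-loss recovery uses 200 replicates at noise σ = 5 % of A.

## Numerical and design notes

* Coordinates are 0-based half-open everywhere (adapter positions,
  alignment, tRF intervals).
* The log2 fold-change pseudocount is 1 CPM, avoiding ±∞ on dropouts.
* `make_counts` breaks total-count ties lexicographically; all outputs
  are deterministic.
* The pipeline manifest records SHA-256 digests of every file read and
  written, and no timestamps — re-running an identical configuration is
  byte-identical, which the digest-level tests rely on.  A file rewritten
  by a later step (the PAC tables after reannotation) is verified against
  its last recorded digest.
* Paired-end reads, indel-tolerant matching, spliced alignment,
  genome-coordinate feature counting and differential-expression testing
  are out of scope; the PAC object is designed to hand off to the wider
  R ecosystem for the latter.
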