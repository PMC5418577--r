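---
title: "Sorting mixed-species RNA-seq reads: model, parameters and validation"
author: "sssort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting mixed-species RNA-seq reads: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sssort)
```

## The decision procedure and its assumptions

`sssort` assigns each read pair of a mixed-species RNA-seq sample to its
species of origin by comparing the pair's alignments against the two
candidate genomes. The procedure assumes that the *same* read set has been
mapped independently to each genome by a spliced aligner configured to
report all top-scoring alignments and only those (for STAR:
a very large `outFilterMultimapNmax` together with
`outFilterMultimapScoreRange 0`). The engine never rescores alignments;
"multimapping" means "more than `max_hits_per_genome` reported alignment
pairs for that genome", exactly as the aligner reported them.

The decision tree, in order:

1. Alignments to one genome only → provisional assignment to it.
2. Alignments to both genomes and more than `max_hits_per_genome`
   (default 1) reported pairs on either side → `REJECTED_MULTIMAP`.
3. Strictly fewer pair mismatches (`NM` summed over mates) on one side →
   provisional assignment to that side.
4. Mismatch tie → the structural criteria decide: full-length (unclipped)
   alignment with at least `min_junction_overhang` (default 5) aligned
   bases on each side of every splice junction. Exactly one side passes →
   provisional for that side; both pass → `REJECTED_AMBIGUOUS`; neither →
   `REJECTED_STRUCTURE`.
5. Finalization of any provisional call: at most `max_final_mismatches`
   (default 0) pair mismatches, structural criteria satisfied, and a
   single alignment to the chosen genome. Only then `ASSIGNED_*`.

The defaults are deliberately conservative: they minimize reads attributed
to the wrong species at the cost of discarding some attributable reads.
Every pair written to a species output file has one full-length,
splice-consistent alignment with zero mismatched bases to that genome
(`verify_assigned_soundness()` re-checks this on any output, and the test
suite runs the scan on every fixture).

Decisions taken where the procedure's description leaves room:

* **Half-mapped pairs.** A pair with only one mate mapped to a genome
  contributes *no* alignment to that genome: the comparison is defined at
  pair level (mismatch sums, structure of both mates), so a half aligned
  pair cannot participate. A pair half-mapped to genome B and fully mapped
  to genome A is therefore handled by the exclusive-mapping branch.
* **Junction overhang.** The overhang on one side of a junction is the
  *total* of reference-aligned query bases (`M`, `=`, `X` operations) on
  that side of the `N` within the mate, not only the run adjacent to the
  junction. A short internal exon between two junctions does not by itself
  violate the rule as long as each junction has five aligned bases
  somewhere on each side.
* **One-genome multimaps.** The multimap discard of step 2 literally
  applies only when both genomes have alignments, so a pair with two
  alignments to A and none to B is provisionally A. The finalization step
  additionally rejects such pairs (as `REJECTED_MULTIMAP`), which is what
  guarantees the single-alignment property of the output;
  `strict_paper_order = TRUE` disables that extra check and follows the
  literal branch order.
* **Candidate among several alignments.** When `max_hits_per_genome > 1`,
  the pair compared across genomes is the one with the fewest mismatches,
  ties broken by structural validity, then the primary flag, then input
  order. With the default of 1 this situation never survives to a
  comparison.
* **Mismatch aggregation.** Pair mismatches are the sum over mates; it is
  the only supported mode and is named explicitly
  (`compare_mismatches_by = "pair_sum"`) so alternatives could be added
  without ambiguity.
* **Exclusive-branch finalization.** The structural check applies to
  exclusively-mapping reads exactly as to compared reads, at finalization.

There is no randomness anywhere in the engine: identical inputs give
bit-identical verdicts, and relabelling the genomes (A↔B) swaps the two
assigned classes while leaving every rejection class unchanged.

### Input expectations

Both alignment files must be *name-sorted under byte-wise collation* of
normalized read names (mate suffixes `/1`, `/2` and Casava comments are
stripped). Grouping validates this on the fly and stops with the offending
record named; it is implemented as validated in-memory grouping, which at
the problem sizes this package targets (its own simulations, desk-scale
validation) is simpler and fast. Mismatch counts come from the `NM` tag,
or are recomputed from `MD` when `NM` is absent; a mapped record carrying
neither is a hard error, never a silent zero, because mismatch counts are
what assignment is decided on. Secondary alignments are kept while
grouping — they are the evidence of multimapping — but only the chosen
(primary) alignment of an assigned pair is ever written out.

## Quantification conventions

* **Counting** is pair-level, unstranded, over the union of all exons of
  all transcripts of a gene: a fragment counts for a gene if any aligned
  base of either mate overlaps the union; fragments overlapping more than
  one gene are discarded as ambiguous; `N`-gapped bases do not count. This
  reimplements the subset of featureCounts-default behaviour the workflow
  relies on, so the test loop needs no external binary; it is
  "featureCounts-default-compatible", not a clone. Counting conservation
  (`fragments = counted + ambiguous + no-feature`) is reported per run.
* **FPKM** uses the gene's *maximum transcript length* as length term, and
  as per-million denominator the number of fragments unambiguously
  assigned to this species in this sample — never raw sequencing depth.
  Tables also carry the union-exon length for transparency. Internally all
  interval arithmetic is on the 1-based closed GTF convention as imported
  by `rtracklayer`; outputs state lengths in nucleotides.
* **Strandedness** is off by default; the counting layer is unstranded
  because the sorting decision upstream is strand-agnostic.

## The misassignment control

A single-species control sample pushed through the full filter yields
per-gene cross-call rates `rate = crosscalled / total`. For a mixed
sample the spurious contribution to a gene's own-species count is
estimated as `rate × contaminant_count / mixed_count`, and genes above
the exclusion threshold (default 0.10) are dropped. The exact estimator
is a design choice — the workflow it follows states the threshold rule
but not the formula — and it is deliberately kept behind a single
function (`estimate_misassignment()`) so alternatives are swappable. It
is conservative in the regime that matters (contaminant expression
comparable to or above own expression) and anti-conservative when
cross-calling is so strong that it depletes the observed contaminant
count itself; the planted-gene validation below exercises the regime the
control is meant to catch. Cross-species gene correspondence is a
required input (a two-column map); it is never inferred.

## What the simulator emulates — and what it does not

`make_genome_pair()` draws genome A uniformly at random, one gene per
contig with `flank` (default 50 nt) intergenic margin, and derives genome
B by substituting every site independently with probability `d`
(substitutions never restore the original base; the divergent-site map is
exact, and `d = 0` yields byte-identical genomes). Annotations are
structurally identical across the two genomes. Optional introns split each
transcript into near-equal exons. Per-gene overrides plant control cases:

* `gene_divergence` fixes a gene's substitution rate (0 gives an identical
  paralog, whose reads are *ambiguous* — they can never be cross-called,
  because a tie at zero mismatches is rejected, not assigned);
* `conserved_tail` keeps a 3' fraction of the locus substitution-free;
* `truncate_b` removes a 3' fraction of the locus from the genome-B
  *assembly* (the organism's RNA stays full-length — truncation models
  incomplete assembly/annotation, the documented cause of real
  cross-calls). A gene whose conserved tail is also truncated produces
  deterministic cross-calls: reads from that region align cleanly and
  exclusively to the other genome.

`enumerate_reads()` produces *all* theoretical 50 nt paired-end reads at
150 nt insert size from a transcript (`L − 150 + 1` fragments for length
`L ≥ 150`), error-free, in FR orientation; "insert size" is the total
fragment span (outer distance), with an `insert_mode = "inner"`
alternative. These geometry defaults are typical of short-read RNA-seq
and make the assignment probability analytic: a pair covers `c = 100`
distinct genome sites, so under divergence `d` it is assignable iff at
least one covered site is divergent, with probability `1 − (1 − d)^c`.
`emit_truth_alignments()` then writes each fragment's true-locus alignment
against both genomes with exact mismatch counts (`NM` against the other
genome = divergent sites covered per mate) and annotation-consistent
CIGARs (`aMbNcM` across junctions), standing in for an aligner.

What the simulator does *not* model: sequencing error and base quality
(theoretical reads are error-free by design; a seeded substitution-error
option exists for stress tests but is off by default), indel divergence
(mismatch counts stay analytic; an extension), fragment-length variation
(enumeration is exhaustive, not sampled), paralogy within a genome
(multimaps are exercised by the scenario grid instead), reverse-strand
genes and expression-level variation. Passing the validation suite
therefore demonstrates that the *decision logic* is exact and that
assignment behaves analytically in divergence — it does not certify
performance on real libraries with sequencing errors, indels and
repetitive loci, where the aligner's behaviour dominates.

## Numerical and fixture choices

* The divergence benchmark uses transcripts of length exactly 150 nt —
  one fragment per transcript — so read pairs are statistically
  independent and the `±3` binomial-standard-error band around
  `1 − (1 − d)^100` is exact, not an approximation over correlated
  sliding windows. The suite runs 10,000 pairs per divergence level
  (d ∈ {0, 0.002, 0.01, 0.05}); at `d = 0` assignment is exactly zero and
  at every `d` the wrong-species assignment count is exactly zero, since a
  read's own genome always has zero mismatches and the other genome at
  least as many.
* The scenario grid (`make_scenario_grid()`, ~900 cases) crosses
  alignment multiplicities 0–2 per genome, mismatch sums 0–2, clipped and
  junction structures with overhangs 3–6, parameter variants (overhang
  threshold 4, mismatch cap 1, strict branch order) and half-mapped
  mates. Each case carries the verdict expected by construction; the test
  suite compares three independent voices case by case — that
  construction, an independently written brute-force oracle, and the
  engine (both the vectorized sample path and the per-read path).
* The planted-gene control uses 20 genes of 600 nt at `d = 0.03`, one of
  them with its conserved 3' half truncated from the companion assembly
  and expressed in the primary species at one twentieth of the
  contaminant level (a contaminant-enriched gene is exactly the case the
  exclusion exists for). Under these conditions the planted gene's
  estimated spurious fraction exceeds the 10% threshold with a wide
  margin across seeds while every normally diverged gene has a control
  rate of exactly zero and survives.
* Contamination mixing is deterministic by default (expected counts,
  rounded half-to-even); the stochastic mode draws one seeded multinomial
  over (transcript, origin) cells, so truth labels survive the draw.
  Degenerate inputs are errors, not guesses: a zero cell ratio sum, a
  zero FPKM denominator with nonzero counts, a mapped record without
  mismatch information, an alignment whose reference is missing from the
  output header.

## Known limitations

Two species only (no N-way generalization); no CRAM; no mate rescue of
half-mapped pairs; no quality-aware mismatch weighting; no isoform-level
quantification or differential expression (counts and FPKM feed external
tools); the misassignment estimator is one defensible reading of the
threshold rule, as discussed above. The CLI at `inst/cli/sssort.R` is a
thin veneer — the R functions are the interface of record.
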