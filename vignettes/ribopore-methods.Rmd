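---
title: "ribopore: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ribopore: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

ribopore profiles microbial communities from long (~4.2 kb) 16S-ITS-23S
rRNA operon amplicons sequenced on noisy long-read platforms. This
vignette records the model behind the synthetic data generator, the
algorithmic choices in the read-processing pipeline, and the reasoning
behind the heuristics, so that results can be interpreted and the
design revisited with its constraints in view.

## The operon model and the synthetic generator

The unit of simulation is a bacterial rRNA operon amplicon:

* 1500 bp of 16S, 300 bp of ITS, 2400 bp of 23S — 4200 bp total;
* a forward amplification primer `AGAGTTTGATCCTGGCTCAG` (27F) at the
  very start and a reverse primer `ACCGCCCCAGTHAAACT` (IUPAC `H`)
  whose reverse complement ends the amplicon;
* internal conserved windows at canonical priming offsets (343F, 518F,
  787F, 1099F in the 16S; two more in the 23S) which double as the QC
  primer panel.

`generate_reference_set(n_taxa, divergence, model, seed)` draws one
random ancestor operon, freezes the primer/anchor windows, and evolves
each taxon by independent substitutions at the non-conserved sites at
the requested divergence (capped at 0.30; above that the notion of a
"reference set of related taxa" stops being meaningful for this
aligner). Divergence 0.15 gives roughly species-to-genus-level spread:
pairwise identities around 72–78%, which is deliberately *harder* than
real 16S databases so that classification results are conservative.

Communities are lognormal: `sample_community(ids, sigma, seed)` draws
relative abundances as normalized `exp(N(0, sigma^2))`, with
`sigma = 2` producing the strongly skewed rank-abundance curves typical
of environmental samples — a handful of dominant taxa and a long tail.
Two independent end members mixed at fractions 0, 0.10, 0.20, 0.50,
0.75 and 1.00 in quadruplicate form the default mixture design
(`mixture_design()`), 24 samples of 500 reads each.

Reads are simulated by `simulate_reads()`: multinomial source draws
from the profile, random strand, then per-base errors at 12% total in
a 6 : 3 : 3 substitution : insertion : deletion split (`error_model()`).
A small junk fraction (random sequence of random length) exercises the
QC stage. Limitations worth keeping in mind: errors are i.i.d. per
base (no homopolymer-length bias, no quality correlation along the
read), chimeras are not simulated, and the reference taxa share one
ancestor (a star phylogeny), so the generator probes error tolerance
and abundance recovery, not phylogenetic structure.

## Read QC: two-tier primer anchoring

`find_primer_sites()` scans every panel primer (both strands, IUPAC
expanded) with a bit-parallel semi-global edit-distance search and
reports placements within `floor(0.25 * primer_length)` edits. The
permissive tier is needed for *counting*: at 12% read error a 20-mer
site carries ~2.4 expected errors, and requiring fewer than 5 edits
would reject genuine sites. But on kilobase-scale reads the permissive
tier also admits occasional chance placements.

The resolution is asymmetric, driven by what each anchor can do wrong:

* 23S-panel sites define the *end* of the extracted 16S, so a chance
  hit truncates the region — they must pass the strict tier
  (`<= 0.15 * primer_length` edits);
* 16S-panel sites define the *start* of the region as the 5'-most
  plus-strand site, so an extra hit can only move the start toward the
  read's 5' end, never truncate — they are accepted at the permissive
  tier. Without this, reads whose terminal 27F site drifts past the
  strict threshold would begin extraction at the 343F internal anchor
  and lose the first ~340 bp.

Orientation is a strict majority vote over the anchor-tier strands
(ties keep the read as given; the operation is idempotent), and the
16S region runs from the 5'-most plus-strand 16S site to
`min(start + 1600, first 23S site)`. On an error-free full amplicon
that is 1600 bp — the reference 16S plus 100 bp of ITS — because the
cap, not the 23S anchor at 1929, binds first; downstream alignment is
local, so the overhang is harmless.

## Classification: seeds, candidate floor, score-only ranking

The classifier (`classify_reads()` / `extend_alignment()`) is a
seed-and-extend local aligner built for high-error long reads:

1. **Discontiguous seeds.** The index hashes every reference position
   under the spaced template `111010010100110111` (18 columns, 11
   sampled). Ignoring 7 of 18 columns makes a seed hit survive
   isolated substitutions that would break a contiguous 11-mer, at the
   same specificity as an 11-mer.
2. **Chaining.** Query seed hits are binned per subject by diagonal
   (band width 100) and the heaviest co-diagonal chain is each
   subject's weight.
3. **Candidate floor.** Only subjects whose chain weight is at least
   `max(3, ceil(0.25 * best_weight))` survive, capped at the 12
   heaviest. The relative floor adapts to query length and error rate
   without a tuned absolute threshold; the absolute floor of 3 anchors
   suppresses chance single-seed subjects. If the floor would empty
   the list (very short or very noisy queries) the best chain is kept
   so the aligner still reports its one hypothesis.
4. **Score-only ranking, late traceback.** Candidates are ranked by a
   banded, X-drop, score-only affine local alignment (match 2,
   mismatch −3, gap open 5, extend 2); the full traceback — the
   expensive part — runs only for the winner and exact score ties.
   Ties are broken by percent identity, then lexicographic subject id,
   so results are independent of reference order.

Assignments below 70% identity or 500 aligned columns are reported as
unclassified rather than forced onto the nearest reference. Percent
identity counts matches over all alignment columns including gaps.
Every alignment component is cross-checked in the test suite against
`Biostrings::pairwiseAlignment` as an independent oracle; note that
co-optimal alignments can differ in column count, so the dual-route
checks compare scores exactly and identities within a tolerance.

## Consensus: batched iterative realignment

Per-OTU operon consensus (`consensus_build`) proceeds in stages: the
highest-scoring assigned reads are split into fixed-size batches; each
replicate builds a progressive-alignment draft from its batch, then
realigns growing read sets (its batch, the first 20, all 30) against
the current template, with the last stage repeated to a fixed point.
Within one realignment round, substitutions are called by per-column
plurality (ties keep the template base, then lexicographic base
order), but indels are deliberately *not* called by per-column
majority. A template that lacks or carries one surplus base of a short
repeat draws indel evidence from most reads, yet pairwise alignments
scatter that evidence — the indel lands at any equivalent position in
the repeat, and reads with errors nearby absorb it into mismatches —
so column-wise vote fractions systematically understate it. Instead,
indel *candidates* are collected at a low evidence bar (canonically
left-shifted insertion placements whose modal string reaches 15% of
covering reads; single-base runs whose pooled gap fraction reaches
15%) and each candidate is accepted only if applying it increases the
summed alignment score of the reads over a ±30 bp window around the
edit — a direct model comparison that pools every read's evidence
exactly. Batch composition is fixed by the read ranking rather than by
random draws, and the stage names recorded in the result make the
trajectory auditable. On error-free reads the scheme is exact: the
draft equals the source and every later stage is a fixed point. At 12%
read error and 30-read coverage, independently drawn read sets
reconstruct byte-identical consensuses in ≥95% of simulations, which
is the package's reproducibility criterion for the consensus stage.

Reproducibility is assessed by `replicate_consensus_identity()`:
independent read subsets of the same OTU are collapsed separately and
the pairwise identities of the resulting consensuses are reported.
The replicate-identity test suite runs on a 1200-bp scaled operon
(500 + 200 + 500 with proportionally moved anchors) rather than the
full 4200-bp model: the consensus algorithm is length-agnostic, the
scaled problem preserves the structure (two subunits, internal
anchors, 12% error) while keeping 20-seed × 4-replicate experiments
inside a CPU-minute budget, and the full-size behaviour is covered
separately by the error-free exactness tests and the end-to-end
pipeline run.

## Quantitation: aggregate-means regression

For the mixture experiment, each end member's top-4 OTUs (by mean
normalized frequency at that end member's pure samples) are regressed
against the input mixture percentage. The default regresses the
*replicate means* at the six design points rather than all 24 samples
individually: with balanced replication the OLS slope and intercept
are identical either way, but r² answers a different question —
"does the mean response track the input linearly?" rather than "how
noisy are individual 500-read samples?". The per-sample mode remains
available (`aggregate = "none"`) and both are tested. `top_k_response`
flags OTUs whose total count support is low, since a 4-point r² on a
rare taxon is fragile.

Rarefaction curves are computed by exact hypergeometric expectation
(no resampling), and the error-injection sensitivity ladder
(`sensitivity_run()`) measures, for spread-out source taxa, the lowest
identity level at which every injected copy still classifies to its
source — the package's operating-point summary for how much sequence
error the classifier tolerates.

## Determinism

Every stochastic operation takes an explicit integer seed, and
compound experiments derive per-stage seeds from a master seed with
`derive_seed(master, ...labels)` (a stable string hash), so whole
pipeline runs — including the command-line interface — are
byte-reproducible from a single `--seed`.
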