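---
title: "Detecting prophage induction from coverage, k-mer and alignment evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting prophage induction from coverage, k-mer and alignment evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inductr)
```

## The problem

A prophage that induces switches from a single integrated chromosomal copy
to dozens or hundreds of replicating episomal copies. In a shotgun
sequencing library of the lysogen (or of a viral-enriched supernatant),
that excess copy number appears as a block of elevated read coverage over
the prophage's coordinates. `inductr` turns that signal into calls: which
predicted prophage regions are induced in which samples, which phage
species are induced within a mixed community, how prevalent the induced
phages are across gut viromes, and how induced prophages differ genetically
from their non-induced, putatively cryptic relatives.

## Coverage model and induction statistics

Coverage is summarised as the mean per-base depth in consecutive 100-bp
bins (`bin_depth()`); the trailing partial bin keeps its per-base mean and
participates normally. Bins overlapping any predicted region by at least
1 bp are labelled with that region's id (`mask_regions()`); host bins are
all bins outside *every* prediction, not just outside the region under
test, so that a second induced prophage on the same genome cannot inflate
the null.

Three statistics compare a region's bins `x_p` with host bins `x_h`:

* **Average modified z-score.** `mean(0.6745 (x_p − x̃)/MAD)` with `x̃` the
  host median and `MAD = median(|x_h − x̃|)`. The MAD-based form is robust
  to the long right tail that other elevated regions produce in host
  coverage; 0.6745 is the usual consistency constant. When `MAD = 0` (flat
  host coverage) the z-score is undefined and is reported as `NA` rather
  than infinity; the decision then rests on the other clause.
* **Cohen's d.** `(mean(x_h) − mean(x_p)) / sqrt((S_h² + S_p²)/2)` with
  sample standard deviations. Written this way the statistic is *negative*
  for induced regions; the decision rule tests its magnitude. Both groups
  constant gives 0/0, reported as `NA`.
* **Fold change.** `mean(x_p)` over a host baseline. The baseline is the
  host *median* by default — consistent with the z-score's centre and
  robust to co-induced regions — with the mean available via
  `baseline = "mean"` since the convention is not fixed by the method's
  description.

The retention rule (`call_induction()`) is
`z_ave ≥ 3.5 OR (fold ≥ 2 AND |D| ≥ 0.7)`; an `NA` statistic fails only
its own clause. All three thresholds are exposed as arguments.

**Boundary refinement** (`refine_boundaries()`) trims flanking bins whose
depth is below 25% of the region's mean bin depth. The threshold is
computed once from the initial candidate and not recomputed as bins fall
away: recomputation would let the threshold creep upward while trimming a
long dim flank, making the result depend on trim order. Only flanking runs
are removed — interior dips (e.g. repeat-masked positions) do not split a
region. A corollary of the fixed 25% fraction is that the maximum bin
always survives, so the empty result is only reachable with a user-raised
fraction; it is still signalled, as a zero-row region with a warning.
Refinement is idempotent and never extends the candidate.

**Merging** (`merge_overlapping()`) treats coordinates as 0-based,
half-open (BED convention) and merges only on a true overlap of ≥ 1 bp:
regions that merely abut share no base and remain distinct. Merged regions
inherit the maximum completeness of their members, and quality is
recomputed (> 50% complete = high).

**Hallmark validation.** `derive_length_cutoff()` reproduces the cut-off
construction for hallmark-gene hits — half the mean of the lengths between
the 10th and 90th percentile (linear-interpolation percentile convention,
configurable) — and `filter_hallmarks()` applies per-class cut-offs, with
the published Caudoviricetes values (terminase large subunit 265 aa,
portal 245 aa, major head 186 aa) shipped as
`caudoviricetes_hallmark_cutoffs`.

## Dereplication and pair selection

`compute_ani_af()` follows the anicalc convention: blocks are resolved on
the query longest-first, with later blocks contributing only their
not-yet-covered span; ANI is the alignment-length-weighted mean identity
and AF is the merged aligned span over the *shorter* genome's length (the
denominator choice is configurable in effect by swapping lengths).
`cluster_dereplicate()` is greedy representative-linkage: genomes in
decreasing length order (ties broken lexicographically by id, so the
result is fully deterministic) join the first cluster whose representative
they match at both thresholds. Representative linkage rather than single
linkage keeps clusters from chaining through intermediate genomes and
matches the behaviour of the cited dereplication tooling; the chain
A~B~C with A≁C therefore yields two clusters with C alone.

`select_comparable_pairs()` implements the comparability filter for
induced vs non-induced analysis: besides the 95%/85% similarity floor, the
non-induced prophage's host must have been sequenced in at least one
condition under which the induced partner actually induced — otherwise
"not induced" could simply mean "never exposed to the trigger".

## Community-scale calling

`count_unique_kmers()` counts k-mers (k = 21 by default; odd k avoids
palindromic self-complements) unique to one genome of the database, after
canonicalising each k-mer to the lexicographic minimum of itself and its
reverse complement — read orientation is arbitrary, so strand-collapsed
counting is the only consistent choice. Windows containing N are skipped.
The implementation is a plain dictionary over substrings, adequate for the
genome sizes involved in testing and fixture work.

`detect_genome()` applies the per-replicate detection cut-offs (phage:
k-mer coverage ≥ 0.25, reads ≥ 10, unique k-mers ≥ 100; host: reads ≥ 10,
unique k-mers ≥ 18,000). `call_readmap_induction()` and
`call_kmer_induction()` then require the 2-fold excess (depth over the
host's length-weighted mean depth, or duplicity over the host's
length-weighted duplicity) in at least 3 of 5 replicates; both the
replicate count and quorum are arguments. Two readings of the quorum are
possible for multi-member species; we take the strict one — a single
member genome must itself pass in ≥ 3 replicates; passes are not pooled
across members — because pooling would let two marginal members
manufacture a species-level call. When a host falls below its detection
cut-offs in a replicate, the phage's fold is meaningless there; in the
k-mer caller such a replicate counts on phage detection alone (the
undetected-isolate rule), while the read-mapping caller fails a replicate
whose host is absent from the report.

## Virome profiling

`fractional_abundance()` computes
`(reads/length)/(total_reads/50000)` per genome per virome and normalizes
to sum to 1 within each virome. The 50,000 constant is a read-scaling
convention retained from the prior virome work this follows, and is
configurable; it cancels in the normalization and only matters for raw
values. Genomes with zero reads contribute zero and are excluded from the
normalization denominator, which also guards the all-zero virome (reported
as `NA` with a warning). `prevalence()` counts a genome present at
breadth ≥ 0.70, strictly: 0.69 is absent.

## Comparative genomics

`category_enrichment()` builds per-category 2×2 tables (category vs all
other genes, induced vs comparison set), in `"total"` mode counting genes
and in `"presence"` mode counting genomes containing the category, tests
each with a two-sided Fisher's exact test and adjusts with Hochberg's
method. The per-category frequency change `100 (f_cry − f_in)/f_in` is
attached; `f_in = 0` leaves it undefined (`NA`) rather than infinite.
Zero-margin tables are reported with p = 1 and flagged.

`call_gap_events()` reads the unaligned spans between adjacent collinear
alignment blocks. A span of ≥ 50 bp on *both* genomes is the signature of
a replacement — sequence lost and unrelated sequence gained, the
horizontal-transfer case; a span on exactly one genome is an insertion or
deletion. We adopt this two-sided/one-sided split as the interpretation of
the event definitions because it is the only reading that makes the two
event types mutually exclusive. Unaligned sequence before the first or
after the last block is never an event (terminal gaps are excluded as
unresolvable: truncation and genuine variation cannot be told apart
there). Blocks that are not collinear on the subject after sorting by
query — rearranged pairs — are excluded from event calling with a warning
rather than guessed at; overlapping blocks are rejected outright.

## Summaries

`summarize_induction()` aggregates a per-(isolate, region, condition)
ledger at the isolate, prediction or species level: the numerator counts
entities induced in ≥ 1 condition, and prediction/species denominators are
restricted to high-quality (> 50% complete) predictions. Percentages are
rounded half-up to integers (`percent_half_up()`), the convention that
reproduces the printed tallies this mirrors (e.g. 134/736 → 18%,
80/252 → 32%, 28/41 → 68%). `condition_overlap()` counts, per condition,
prophages induced there and the overlap with the standard-medium
(spontaneous) set; `polylysogeny_table()` tallies inducible prophages per
isolate, the polylysogen/single-lysogen 2×2 by phylum, and the
(co-resident count, inducing-condition count) pairs used downstream for
rank correlation. Those downstream significance tests are ordinary
`fisher.test` / `cor.test(method = "kendall")` calls on the emitted
tables and are deliberately not wrapped.

## The synthetic-data generators

The generators exist so that every stage of the pipeline can be exercised
against exact ground truth:

* `gen_lysogen()` — i.i.d. random sequence at a specified GC with phage
  segments inserted at given host offsets; the truth table records the
  final half-open coordinates. Repeats and compositional structure are not
  simulated, so mapping artefacts (a major source of false positives on
  real data) are out of the generators' reach — passing tests certify the
  statistics and decision logic, not robustness to mapping noise.
* `simulate_coverage()` — per-bin totals drawn negative-binomially with
  mean `base_depth × bin_width` (times `induction_fold` inside truth
  regions) and size `dispersion`, then divided by bin width. The negative
  binomial is the standard overdispersed model for sequencing coverage;
  the empirical dispersion of induction libraries is unreported, so the
  default `dispersion = 20` (per-bin coefficient of variation ≈ 22% at
  20× depth, comfortably wider than Poisson) is a documented, exposed
  guess, with `Inf` giving the Poisson limit. The pipeline's contract
  starts at depth tables; read-level simulation is deliberately omitted.
* `simulate_community_report()` — induced phages drawn with wide margins
  above every calling threshold in a configurable number of replicates,
  non-induced phages below; hosts always detectable. It validates caller
  logic, not detection limits.
* `gen_alignment_fixture()` — builds sequence B from A by replacing
  (HGT) or deleting (indel) planted segments, and emits the exact block
  decomposition; gap calling must recover the plant verbatim.

## Verification experiments and problem sizes

The test suite and `scripts/acceptance.R` run the pipeline end to end at
sizes chosen to make the checks statistically meaningful while remaining
quick: 1,000 random tracks for the vectorized-vs-naive oracle comparison
(agreement to 1e-9); 200 null simulations (60-kb genome, 30-bin region,
fold 1) for the false-positive rate of the decision rule (≤ 5% required;
observed essentially 0, as a mean z-score over 30 bins rarely approaches
3.5); 200 recovery simulations at fold 5 and 20× depth, where the
candidate handed to refinement is the planted region padded by one bin per
side — emulating a predictor whose boundaries are off by the binning
resolution — with recovery required within ±1 bin in ≥ 95% of runs; a
1,000-bin-per-group Kolmogorov–Smirnov calibration check that fold-1
"phage" bins are indistinguishable from host bins at α = 0.01; and exact
recovery demands on the k-mer, gap-event and community-caller fixtures.

## Known limitations

* Host bins assume predictions are the only elevated regions; unpredicted
  elevated elements (plasmids at high copy, phage-inducible chromosomal
  islands) would inflate the host tail, which the median/MAD statistics
  tolerate but the mean-based Cohen's d only partly.
* The unique-k-mer counter is an exact in-memory dictionary; it is not
  intended for databases of hundreds of full bacterial genomes, where the
  dedicated classifier tooling it mirrors should be used upstream and its
  report tables consumed here.
* Gap-event calling assumes collinearity; rearranged prophage pairs are
  excluded, not resolved.
* The generators make no attempt to simulate read mapping, sequencing
  error, or compositional bias; conclusions about real-data robustness
  require real data.
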