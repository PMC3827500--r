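---
title: "Junction-centric splicing analysis: models, filters and design choices"
author: "spliceward"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Junction-centric splicing analysis: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceward)
```

## The approach

RNA-Seq reads whose alignments contain a gap equal to an intron are direct
physical evidence of a splicing event: they unambiguously join two exons.
spliceward builds a complete analysis of alternative splicing on these
junction-spanning reads alone, in four stages:

1. **Simulation with empirical error models.** Reads are generated from
   transcript models with sequencing errors drawn from position-specific
   weight matrices estimated from a permissive ungapped alignment of real
   reads. Every simulated read's genomic origin is encoded in its
   identifier and in a perfect-alignment truth SAM, so aligner errors can
   be diagnosed exactly.
2. **Junction quantification with diagnostics.** Spliced alignments are
   streamed from SAM/BAM; each gap of at least the minimum intron length
   becomes a junction observation. Per junction the package reports
   coverage, the Shannon entropy of alignment offsets, MMES (minimum match
   on either side), shoulder repeat identity, motif-inferred strand, gene
   assignment and intron read-through.
3. **Pairwise event definition and PSI.** Transcript models are decomposed
   into splice graphs; pairwise events are bubbles — subgraphs sharing end
   nodes with no common interior nodes — mapped to disjoint inclusion and
   exclusion junction sets. Percent spliced in is computed per event from
   reads per junction.
4. **Comparison.** Events are compared between samples by a two-sided
   Fisher's exact test on the 2x2 table of inclusion/exclusion junction
   read totals, with Benjamini-Hochberg FDR control and conservative call
   gates.

## Coordinate conventions

All internal coordinates are 1-based inclusive, matching GTF and the
GRanges/IRanges containers the implementation is built on. A junction is
keyed by `(chrom, first intronic base, last intronic base, strand)` and
printed as `chrom:start-end`. GTF input therefore needs no coordinate
conversion; the donor dinucleotide occupies `start..start+1` and the
acceptor `end-1..end` on the forward strand, reverse-complemented for
minus-strand junctions so that a canonical intron always reports GT/AG.

## The error model

An error model holds, for reads of uniform length L:

* `mismatch_rate_by_pos` — the per-cycle mismatch frequency;
* `sub_weights` — an L x 4 x 4 array of substitution weights conditioned on
  both read position and reference base. The finest conditioning the data
  supports is used: positions with fewer than 10 observations for a
  reference base fall back to the position-marginal substitution matrix,
  and a base with no observations at all falls back to a uniform choice
  over the three alternatives at sampling time;
* `mismatch_count_dist` — the empirical distribution of per-read total
  mismatch counts, tabulated with no smoothing so a count never observed
  is never sampled;
* two consensus quality strings (matched and mismatched positions). The
  consensus is the per-position modal quality character, ties broken
  toward the higher quality; mode was chosen over mean because it is
  robust to heavy tails in quality distributions and exactly reproducible.

Reverse-strand alignment records are reflected into read orientation
(positions mirrored, bases complemented, qualities reversed) before
tallying, so the model describes the sequencing process, not the genome.
Multi-mapped records are tallied as they appear in the input; deduplication
is left to the aligner's reporting mode. Indels are not modeled —
substitutions dominate Illumina error profiles and gapped error modeling
would complicate the permissive-alignment input for little gain.

Two built-in models are provided: `uniform` (flat rate, default 1% per
position, truncated-Poisson count distribution) and `ramp`, which mimics
the empirically typical profile of a slight elevation over the first five
cycles and rates rising through the 3' end
(`0.002 + 0.003 exp(-(i-1)/2) + 0.018 (i/L)^4`).

## The simulator

Per-transcript pair counts are `round(X * length / (2 L))` in coverage
mode — i.e. coverage counts the bases of both mates against the spliced
template — or `round(RPK * length_kb)` in reads-per-kilobase mode.
Fragment lengths are drawn from a normal distribution (defaults: mean 200
bp, SD 20 bp, matching standard short-insert libraries); draws larger than
the template or smaller than the read length are redrawn up to 100 times,
after which the transcript is skipped with a warning. Fragment starts are
uniform over valid template positions; mate 2 is the reverse complement of
the fragment 3' end.

A configurable fraction of pairs (default 0.20) is drawn from the
unspliced, introns-included template of the parent gene. This deliberately
exceeds typical physiological intron-retention levels; its purpose is to
stress downstream alignment and filtering with reads that cross
exon/intron boundaries. These unspliced-template reads are attributed to
the parent transcript's truth counts but never to junction truth.

One seeded RNG drives every stochastic choice in a run (template kind,
fragment length, start position, error placement, in that order per
transcript), so runs are byte-reproducible. Both mates use the same
consensus quality model. Truth SAM records carry mapping quality 255 and
exact CIGAR blocks; pair identifiers encode transcript, template kind and
both mates' genomic blocks.

## Junction quantification and filters

The anchor (overhang) requirement defaults to 8 bp and is applied
identically to junction observations and to intron read-through. The
original tool documents the overhang as user-tunable without printing a
default; 8 bp is this package's documented choice, small enough to keep
sensitivity and large enough that random 8-mers rarely align by chance.
The minimum intron length defaults to 42 bp, mirroring a common
short-read-aligner setting for fly-sized introns; both are configurable.

The offset entropy of a junction is the Shannon entropy (log base 2) of
the distribution of left-anchor lengths of its supporting reads. Base 2 is
forced by the quantitative threshold semantics: at least four distinct,
equally weighted offsets are required to reach the 2-bit cutoff. Any
bijection of alignment start positions gives identical entropy, so the
left-anchor length is used as the offset without loss of generality. MMES
is aggregated to junction level as the maximum over reads of the per-read
minimum anchor; the underlying metric is per-read and the maximum asks
"does at least one read anchor this junction well on both sides?".

Repeat identity compares 10 bp windows (donor side: upstream of donor vs
upstream of acceptor; acceptor side: downstream of each) by Levenshtein
edit distance, reported as percent identity; junctions with either side
above 80% are flagged repeat-like. Gene assignment overlaps each junction
end with annotated gene spans on a compatible strand and requires
agreement; ties go to the gene with the greatest exonic overlap within one
overhang of the site, and unresolved ties or disagreements are flagged
ambiguous. These two flags plus the unannotated-minor-motif flag form the
qualitative filter; the entropy cutoff alone forms the quantitative
filter. Filters only flag — coverage values are never altered — and the
two modes can be applied independently or together.

When evaluating detections against simulation truth, false positives are
classified with the precedence wrong-strand > minor-form > paralog-join >
repeat-induced > shifted (shift window 50 bp, configurable; no window is
stated in the original description) > unidentified. False negatives are
split into alignment failures (a spanning read existed) and sampling (none
was generated).

## Events and PSI

Pairwise events are enumerated natively from the splice graph
(dimension-2 bubbles between transcript pairs, deduplicated by gene,
flanks and structure code); parsing AStalavista-style event files is an
interoperability path, not a dependency, and the dialect written and read
by the package is documented in `?parse_astalavista`. Terminal bubbles
yield events only when a splice site differs, so overlapping first exons
that differ only in their 5' ends are not events; alternative-promoter
(AltFE) events are enumerated, flagged `is_internal = FALSE`, and included
by default because alternative promoters are biologically relevant.
Events whose transcript termini differ on both sides simultaneously, or
whose structure matches none of the named patterns, are "Unclassified"
but still carry a deterministic structure code.

PSI is reads-per-junction of the inclusion path over the summed
reads-per-junction of both paths. The inclusion path is the one with more
interrogating junctions (ties: more interior nodes, then lexicographic
structure code) — for cassette exons this is the exon-included form, for
retained introns the spliced form. A retained-intron event has no
exclusion junction; its exclusion reads-per-junction is the mean of the
left and right intron read-through counts at the spliced junction, which
keeps the per-junction normalization symmetric. This denominator choice is
this package's design decision and is the one place PSI rests on
read-through rather than gapped reads; read-through counts windows of
2 x overhang while a junction collects roughly `L - 2(overhang - 1)`
spanning positions, so retained-intron PSI is not numerically
interchangeable with junction-only PSI and is best compared within event
type. Events where a non-retained path has no interrogating junction
(some terminal events) are flagged unquantifiable rather than guessed.
First-order neighbor coverage — junctions connecting an interior exon of
either path to exons outside the flanks — is reported per event as a
confounding indicator.

## Comparison and call gates

The Fisher's exact test is two-sided (the natural choice for a null of
equal proportions; the original text does not print the sidedness), on
integer junction-read totals. Degenerate tables (a zero margin) are
assigned p = 1 rather than NA so the BH input length is stable across
filtering choices. Only events with inclusion coverage detected in either
sample and exclusion coverage detected in either sample are testable. The
conservative call requires, with defaults: BH-adjusted p < 0.01, more
than 10 reads in each path in both samples, |delta PSI| > 0.20, and — when
replicate quantifications are supplied — a between-sample raw p smaller
than the smallest between-replicate raw p (the minimum across replicate
pairs, the most conservative reading). Delta PSI is oriented
`psi_b - psi_a`. Every gate's verdict is a column in the output, so the
thresholds are auditable. Multiple events per gene are tested
independently.

## The fixture generator: what it emulates, and what it does not

`make_toy_fixture()` builds the synthetic study system: genes with
randomized exon/intron structure on one chromosome, a configurable mix of
two-isoform events (cassette exon, alternative donor/acceptor in the
strand-aware transcript sense, retained intron, mutually exclusive exons,
alternative first/last exons), canonical GT-AG motifs planted at every
annotated intron, an optional proximal paralog (a duplicated gene body, as
arises from tandem duplication), and optional planted decoy junction
sites reproducing the diagnosable aligner error classes: a minus-strand
motif inside a plus-strand gene, an unannotated minor GC-AG motif, a
junction whose shoulder windows are sequence-identical (repeat-induced),
and a junction joining the paralog pair. Shoulder windows of true
junctions are actively de-similarized below 50% identity so that the
repeat filter's false-positive rate on true junctions is zero by
construction. `decoy_alignments()` fabricates the gapped alignments an
aligner would emit at those sites.

Defaults: 20 genes, 3-6 exons of 90-240 bp, introns of 70-220 bp,
intergenic gaps of 300-700 bp, and an event mix totalling 75% of genes —
sizes chosen so that a gene resembles a compact invertebrate gene and a
desk-scale run covers every code path. The fixture does not emulate:
overlapping genes, trans-splicing or antisense transcription (behavior of
the event builder on trans-spliced models is undefined and such models
should be removed from input annotations), GC-content or amplification
coverage bias, indel sequencing errors, or genuine low-complexity genomic
repeats beyond the planted decoys. Passing tests on fixtures therefore
demonstrates correctness of the algorithms under the stated error classes,
not performance on any real genome.

## Problem sizes used in the automated checks

The test suite and the acceptance script run entirely on fixtures: the
designed delta-PSI study uses 60 isolated events simulated at a total of
8000 RPK per gene split 1:3 and 3:1 (every path then exceeds 100 junction
reads, the regime in which PSI estimates are stable); the null-specificity
study uses about 200 events in two equal-abundance pools at 300 RPK; the
fragment and intron-retention checks use at least 1e5 and 1e4 pairs; the
error-model closure check rebuilds a model from 1e5 sampled reads. These
sizes keep each check well inside a few minutes on one CPU while leaving
Monte-Carlo tolerances (three standard errors) tight.

## Known limitations

* Retained-intron PSI depends on the read-through surrogate discussed
  above.
* Event enumeration is pairwise; higher-order event grouping (bubbles
  among three or more isoforms as a single unit) is out of scope, though
  structurally identical pairwise bubbles are merged.
* The comparison framework tests proportions per event; it does not model
  overdispersion across biological replicates beyond the replicate p-value
  gate.
* No realignment or junction rescue is attempted; the quantifier trusts
  the aligner's gaps, which is exactly why the post hoc filters exist.

## A minimal end-to-end run

```{r example, eval = FALSE}
fx <- make_toy_fixture(fixture_config(n_genes = 10), seed = 1)
sim <- simulate_reads(fx$annotation, fx$genome,
                      sim_config(coverage = 10, seed = 2))
files <- write_sim(sim, tempdir(), "demo")

st <- junction_stats(files[["truth_sam"]], fx$annotation, fx$genome)
st <- apply_filters(st, "qualitative")

ev <- enumerate_events(fx$annotation)
quant <- quantify_events(ev, st[st$pass, ])
head(quant[, c("event_id", "event_type", "inc_total", "exc_total", "psi")])
```
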