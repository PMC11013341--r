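---
title: "Ribotype pools, parsimony networks, and hybrid parentage: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ribotype pools, parsimony networks, and hybrid parentage: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopool)
```

## The model

Nuclear rDNA is a multicopy marker. In a hybrid or allopolyploid the copies
derived from different parental genomes have not (yet) been homogenised by
concerted evolution, so one individual's amplicon pool contains several
distinct variants — ribotypes — at appreciable frequencies. The analysis
implemented here treats each sample's sequenced pool as a multinomial draw
over its true ribotype composition, observed through sequencing error, and
asks three questions: which variants are *major* (abundant enough to be a
real genomic fraction rather than error or trace contamination), which major
variants are *identical across samples* (the parentage signal), and how the
variants relate mutationally (the network).

Identity, not similarity, is the sharing criterion: two ribotypes are "the
same" only when their full-length merged sequences match exactly, which is
also the dereplication criterion. Near-identical variants are related
through the network instead. This mirrors how shared ribotypes behave as
single nodes in published ribotype networks.

## Read processing

**Trimming.** Reads are scanned 5'→3' in windows of `window` bases (default
4). At the first window whose *mean* Phred quality falls below
`quality_threshold` (default 12; comparison is strict `<`, so a read of
uniform quality 12 passes intact), retention stops — but leading bases of
the failing window whose individual quality is still at or above the
threshold are kept, matching the behaviour of the widely used
sliding-window trimmers (a window mean can be dragged down by a bad tail
while its first bases are fine). Reads shorter than `min_length` (default
130) after cutting are rejected; a pair is dropped when either mate is
rejected. Trimming is idempotent, which the tests verify on random reads.

**Merging.** The merger reverse-complements the reverse mate and takes the
*largest* ungapped overlap whose mismatch fraction is at most
`max_mismatch_fraction` (default 0.05) and whose length is at least
`min_overlap` (default 20 nt). Within the overlap each position takes the
base with the higher Phred score, ties going to the forward read, and the
maximum of the two scores; flanks are concatenated unchanged. Searching
from the largest overlap downward makes the procedure deterministic and
finds the true overlap for amplicons covered by 2×300 chemistry; random
overlaps essentially never pass the mismatch bound. Pairs with no
admissible overlap are rejected and counted.

**Dereplication.** Case-insensitive exact identity; sequences containing
characters outside A/C/G/T (e.g. N) are excluded from the table and counted
separately, because exact-identity grouping would otherwise fragment
counts. Tables are sorted by count with lexicographic tie-break on the
sequence, so output is byte-stable. The pool's `total_reads` is the sum of
ribotype counts after this exclusion — the denominator of all percentages
is the post-processing pool size.

## Major/minor thresholds and percentages

A ribotype is **major** when its read count exceeds 1,000 in a pool of at
least 10,000 total reads, or reaches 100 in a shallower pool. The two
cutoffs are deliberately asymmetric in wording — strictly *more than* 1,000
versus *100 or more* — and `threshold_rule()` encodes them as the minimum
qualifying counts 1,001 and 100. Percentages are integer,
`round_half_up(100·count/total)`; this rounding convention reproduces all
53 internally consistent count/total/percent triples of the bundled
Alopecurinae survey table (a handful of its printed rows are internally
inconsistent — e.g. a percent column duplicated from a neighbouring sample
— and `audit_pool_table()` flags them rather than guessing intent; one
listed major sits at 80 reads, below its pool's cutoff, and is likewise
flagged, not silently promoted).

## The statistical-parsimony network

Pairwise distance is the Hamming distance for equal-length ribotypes. For
unequal lengths the pair is globally aligned to maximise matching columns
(ties resolved toward fewer mismatches and gap runs) and the step count is
the number of mismatch columns plus the number of contiguous gap runs — one
indel event of any length is one mutation, the usual haplotype-network
convention. A naive "gap run costs one, extension free" alignment objective
is degenerate (any two sequences would align at cost ≤ 2 by gapping each
out entirely), which is why the match-maximising formulation is used; both
an independent exhaustive recursion and planted-edit examples confirm it in
the tests.

**Connection limit.** Mutations are modelled as striking the *m* sites of
the marker uniformly at random, each changing the site to one of three
alternative states. A *j*-step connection stops being parsimonious when a
later mutation revisits an already-mutated site with the one state that
reverts the earlier change, making the pair look closer than its true
path. Neglecting the second-order case of several superimposed hits, the
*i*-th mutation is safe with probability `1 − (i−1)/(3m)`, giving

&nbsp;&nbsp;&nbsp;&nbsp;`P(j) = ∏_{i=1..j-1} (1 − i/(3m))`

and the 95% connection limit is the largest *j* with `P(j) ≥ 0.95`. `P(1) =
1`: single steps are always parsimonious, so a confidence approaching 1
forces a limit of 1. The limit is monotone in *m* and lands at the
magnitudes familiar from TCS-style analyses (12 steps for a 450-nt
amplicon, 13–14 for 600–700 nt). A Monte-Carlo simulation of the same
mutation process cross-checks the closed form in the test suite.

**Assembly.** All pairs one step apart are connected first (this may create
reticulations — loops are biological reality at one step). Then, at
increasing distance *d* up to the limit, pairs lying in different connected
components are joined through a chain of *d − 1* inferred intermediate
nodes; among candidates at the same *d*, the join touching the
highest-frequency observed node wins, then lexicographic node id. Because
each merge uses the smallest available inter-component distance, the
assembly is exactly Kruskal's algorithm on the observed haplotypes, so in
the absence of one-step reticulation and limit truncation the total path
length equals the minimum-spanning-tree weight — the oracle comparison the
acceptance tests make (with `igraph::mst` as the independent oracle).
Inferred intermediates carry no invented sequence: their states are
underdetermined, so they record only which join path they sit on and their
position along it. Node ids are assigned on the lexicographically sorted
unique sequences, making networks invariant to pool input order.
Ambiguity codes are rejected at this stage; upstream dereplication already
excludes them.

Deep pools at realistic error rates carry thousands of singleton error
ribotypes; `build_network(pools, majors_only = TRUE)` restricts the graph
to major ribotypes, which is how published ribotype networks are drawn.

## Parentage and introgression

The parental signal of a hybrid is read from its **major** ribotypes only:
each is assigned `from_a`/`from_b`/`from_both` when the identical sequence
occurs in the respective parent's pool at *any* status — matches to
parental minors count, since a parent's minor variant can be a hybrid's
major — or `hybrid_specific` when private (a candidate post-hybridization
derivative). The verdict is `both_parents_detected` when at least one major
comes from each side. Candidate parent pairs are scored independently; no
combinatorial search over all species is attempted. The introgression scan
reports every shared ribotype that is major in one sample and minor in the
other, with counts and percentages; published analyses narrate such cases
individually (75-, 73-, 41-read fractions), so no evidentiary read-count
threshold is imposed — interpretation stays with the user.

## The synthetic-data generator

`make_ribotype_family()` builds variants along a mutation chain with exact
planted Hamming distances. `pool_spec()` fixes a sample's ground truth:
member sequences, true proportions (must sum to 1), read-pair count, and a
per-base substitution error rate in [0, 0.05]. `make_hybrid_spec()` unions
two parents with weighted, renormalised proportions, merging sequences
present in both. `simulate_read_pairs()` draws each pair's source from a
seeded multinomial, emits the amplicon's 5' prefix and reverse-complemented
3' suffix at the chosen read length, and injects substitution errors
uniformly at the spec's error rate.

Defaults emulate the structure of real Alopecurinae rDNA surveys: 450-nt
amplicons (an ITS1-region scale fully coverable by overlapping 2×300
MiSeq pairs), pool depths in the thousands-to-tens-of-thousands of reads
(the published pools span ~1,700–26,200), 1–8 abundant ribotypes per sample
with main-ribotype fractions of ~20–56%, and minor tails below the
thresholds. Qualities follow a deterministic linear decay
(`Q(cycle) = clamp(round(35 − 0.02·(cycle−1)), 2, 41)`), Phred+33 encoded.
The model is substitution-only — no indels, no chimeras, no
quality-score miscalibration — so passing tests demonstrate correct
recovery of composition, sharing, and parentage under multinomial sampling
and point error, not robustness to structural artefacts of real PCR and
sequencing. One consequence used by the tests as an oracle: with a fixed
quality profile every merged position derives from exactly one mate, so a
member's reads dereplicate to its exact sequence with probability
`(1 − e)^L`.

Seeding: each `pool_spec` carries one seed; operations derive bounded
substream seeds from it, and the caller's RNG state is always restored, so
truth tables and FASTQ output are byte-stable under replay.

## Numerical and design choices

* Rounding of percentages is half-up, validated against the 53 consistent
  printed triples; no other rule (truncation, half-even) reproduces them.
* Sorting tie-breaks are lexicographic everywhere (dereplication tables,
  pool tables, node ids, shared ids), so all outputs are deterministic and
  order-invariant.
* Thresholds compare counts, not percentages; classification is idempotent
  and monotone (raising a count never demotes a ribotype), both tested as
  properties.
* The empty pool, the all-rejected pool, the major-less hybrid, and the
  zero-total percentage are all defined outcomes (empty table, empty
  table, verdict `neither`, error), not crashes.
* Problem sizes in the test suite: the seeded replicate study runs 20
  trios of 5,000 read pairs at error 0.001; network oracles use ≤ 8
  haplotypes over 400–450-nt markers, where exhaustive recounts are cheap.

## Limitations

* Sharing is exact identity; a single uncorrected error makes a read a new
  (singleton) ribotype, so parentage rests on abundant variants — as in
  the published analyses this follows.
* The parsimony probability is a first-order estimator derived from a
  uniform-hits model, not a coalescent calculation; it reproduces the
  customary limit magnitudes but is not a reimplementation of any
  particular historical program's internals.
* Merging is ungapped; amplicons whose mates disagree by indels will fail
  to merge and are counted as rejections rather than rescued.
* No chimera detection, adapter trimming, demultiplexing, or sub-100%
  identity clustering; inputs are assumed to be clean per-sample amplicon
  pairs.
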