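---
title: "Detecting repeat-mediated recombination in circular organellar genomes from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting repeat-mediated recombination in circular organellar genomes from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plant mitochondrial genomes map as single circular "master" molecules but
live in vivo as populations of isoforms. Homologous recombination between
the two copies of a dispersed repeat rearranges the circle: recombination
across an **inverted** repeat pair inverts the segment between the copies,
recombination across a **direct** pair excises part of the circle into two
subgenomic circles, and a **palindromic** (self-inverted) locus — a segment
that aligns to its own reverse complement at the same coordinates — can flip
in place. When the rearranged forms are rare (substoichiometric), assemblies
only show the master conformation, and the rearranged molecules are visible
solely as individual long reads that span a recombination junction.

`mtrecomb` implements this read-level inference end to end: repeat
discovery by genome self-alignment, construction of master and recombinant
reference sequences per repeat pair, two-stage read classification, and
per-pair recombination frequency estimation — plus the comparative
utilities that usually accompany such a study (plastid-derived insert
detection, conserved gene clusters, double-cut-and-join rearrangement
distance) and a synthetic-data module that makes every stage testable
without any external download.

## The model and its assumptions

For one repeat pair with copies $A$ and $B$ the master genome reads
$\ldots U_1\,R_A\,D_1 \ldots U_2\,R_B\,D_2\ldots$, where $U_i$ and $D_i$
are unique flanking sequences. A crossover inside the repeat exchanges the
flank pairings. The classifier therefore builds:

* **templates** — $U_1 R_A D_1$ and $U_2 R_B D_2$, extracted from the
  master genome with a fixed flank on each side;
* **recombinant references** — the junction structures the crossover would
  create: $(U_2, R, D_1)$ and $(U_1, R, D_2)$ for a direct pair, and
  $(U_1, R, \overline{U_2})$ and $(\overline{D_1}, R, D_2)$ for an inverted
  pair (overbars denote reverse complement).

Because the crossover point inside an imperfect repeat is unobservable, the
repeat portion of each junction is emitted in both copy variants when
identity $< 100$, giving four recombinant references; for identical copies
the variants coincide and two remain. A palindromic locus yields one
template and one recombinant (the in-place reverse complement); it is
classifiable precisely because its identity is below 100, so the flipped
sequence differs from the master at the mismatch positions.

A read supports a conformation when its best-scoring alignment to that
conformation's reference **qualifies**: blast-style identity (matches over
alignment columns, gaps counted) at or above the threshold *and* the
alignment extending at least the required span beyond both repeat
boundaries into unique flanking sequence. The per-pair recombination
frequency is $100 \cdot a/(a+m)$ over distinct informative reads — the
quantity printed in published per-repeat recombination tables, whose
master/alternative percentages sum to 100.

Assumptions worth keeping in mind: reads are treated as error-corrected
(accuracy well above the identity threshold); each pair is evaluated
independently (a read may inform several pairs); reads are never split or
trimmed; and no attempt is made to assemble full alternative genome
structures or to locate the crossover inside an imperfect repeat.

## Parameters, defaults, and why

| parameter | default | rationale |
|---|---|---|
| repeat self-search e-value | 1e-6 | conventional nucleotide-search cut-off for repeat inventories |
| seed word size (discovery) | 7 bp | sensitive short-word search, as used for organellar repeat scans |
| repeat length floor | 30 bp | shortest repeat considered analysable |
| repeat identity floor | 80% | conventional floor for "imperfect repeat" inventories |
| family clustering threshold | 0.8, word 5 | greedy incremental clustering at 80% identity over the shorter sequence (>= 80% coverage) |
| read recruitment e-value | 1e-100 | read-length hits only; guards against short chance matches |
| plastid purge coverage | > 85% (union over hits) | whole-read classification: a read is plastid-derived, not merely insert-carrying, when plastid alignments cover most of it |
| classification identity | 99.5% | must sit between repeat-copy divergence (<= ~98.5% for imperfect pairs) and read accuracy |
| flank requirement | >= 200 bp both sides | unique anchor beyond each repeat boundary; ">= " rather than ">" at the exact boundary |
| validation flank | 2000 bp | long-range context for stage-2 re-validation |
| scoring | +2/−3, gap 5+2k | blastn-like nucleotide preset; Karlin–Altschul lambda solved from the scheme, K = 0.41 (ungapped approximation) |

All of these are fields of `analysis_config()` and are echoed into the run
manifest.

## The alignment engine

Every stage shares one local-alignment engine (Rcpp): exact-word seeding,
ungapped X-drop extension into HSPs, greedy colinear chaining (which
bridges mismatch deserts in low-identity repeats and the occasional indel
in reads), and a banded affine-gap Smith–Waterman with traceback over each
chained region. E-values follow the Karlin–Altschul form
$E = K m n e^{-\lambda S}$. The engine is deliberately built in — no
external aligner binary is invoked — and sits behind the alignment-table
contract, so a different engine could be substituted without touching the
downstream modules. Circular sequences are searched across the origin by
doubling the subject (length $2L-1$) and canonicalising hits to start in
$[0, L)$; the trivial full-length self-hit is suppressed at the seed level
for self-searches.

Numerical choices: X-drop 25 (about seven consecutive mismatches at the
default scoring) with chaining as the safety net for longer deserts;
banding pad 48 diagonals around the chained seeds, ample for the ~0.1%
indel rate of corrected reads over multi-kilobase spans; identity is
100·matches/columns with gap columns counted (the "blast identity"
convention the thresholds assume); hits are reported deterministically
(score descending, then coordinates), and exact-coordinate duplicates are
collapsed while overlapping distinct hits are kept — repeat inventories of
highly repetitive genomes count copies "in an overlapping fashion", and
merging would change those counts.

## Read classification details and tie-breaking

A read is aligned on both strands against every reference of a pair; the
best qualifying alignment sets the verdict. Two conservative choices bias
the pipeline *against* calling recombinants: (i) equal best template and
recombinant scores give `uninformative`, and (ii) stage-2 validation
re-aligns every stage-1 alternative candidate against references rebuilt
with 2000-bp flanks and keeps it only if the best qualifying alignment is
still to a recombinant **and** covers the read's full overlap with that
reference (alignment ends within 30 bp of whichever sequence ends first,
on both sides).

The containment requirement is this package's reading of the ambiguous
instruction to remove recombinants "with undersized flanking regions", and
the design space here was genuinely open. Requiring only the same 200-bp
flank rule against longer references demotes nothing: a spurious candidate
whose 200-bp flanks were borrowed from another copy of a repeat family
still matches 200 bp into the extended flanks. Requiring full 2000-bp
flank coverage instead would demote genuine recombinant reads shorter than
the repeat plus 4 kb — a length filter applied to alternative reads but
not master reads, which would bias frequencies downward. Full-overlap
containment demotes the borrowed-flank artefact (its agreement with the
junction stops just beyond the screening flank while the read continues
inside the reference) yet is length-neutral for true recombinants, which
match the alternative conformation along their entire length. The
validation stage operates on reads, not pairs: a pair keeps its surviving
candidates even if others are demoted.

## What the synthetic data emulates — and what it does not

`build_genome()` plants repeat pairs into an i.i.d. background (default GC
45.1%, typical of early-angiosperm mitogenomes): copy B is copy A with
exactly `round((1 - identity/100) * length)` substitutions scattered
uniformly, reverse-complemented for inverted pairs; a palindromic locus is
$X$ followed by a mutated reverse complement of $X$. Realized identity is
therefore within rounding of the requested value, and planted geometry is
returned as ground truth in the same table layout the discovery stage
emits. The stock `demo_blueprint()` plants ten pairs whose lengths and
identities follow the ten recombinationally active pairs reported for the
*Nymphaea colorata* mitogenome (3293/100 … 72/97.22), three direct, six
inverted, one palindromic, on a 100-kb circle — scaled down from the
617-kb original so that complete runs take minutes; repeat geometry, not
genome size, is what the inference depends on.

`simulate_reads()` draws uniform start positions on each circular
conformation (reads wrap the origin), equiprobable strands, log-normal
lengths (default mean 7294 bp, sigma 0.4 — the mean follows the corrected
read pool the study conditions describe; the dispersion is a documented
choice, as only the mean is stated), and per-base errors at
substitution:insertion:deletion = 2:1:1. The default error total is 0.2%
(accuracy 99.8%). A note on this value: corrected long reads are described
as "above 99%" accurate, but a 99.5% identity threshold over multi-kilobase
spans is only passable when accuracy is comfortably above 99.5% — at a
uniform 1% error rate the probability that a read holds 99.5% identity
over a 3.4-kb informative span is about $10^{-3}$, and the classification
stage would be vacuous. The default therefore emulates what corrected
pools actually deliver (~99.8%), which is also the regime in which the
published pairing of a 99.5% threshold with corrected reads is coherent.

Not emulated: chimeric reads, quality strings, platform-specific error
profiles, higher-order sequence composition (the background is i.i.d.), and
real repeat families with many partial copies. Passing tests on this
generator therefore demonstrate the correctness of the inference given its
assumptions — not robustness to raw-read error profiles or to
low-complexity sequence, which real data would add.

## Statistical behaviour checked by the tests

Three properties anchor the acceptance suite, at problem sizes chosen to
run on one CPU in minutes: frequency recovery (100-kb circle, 3293-bp
identity-100 inverted pair, 300× reads; mixtures 8%, 1% and 0.25% must be
estimated within the exact binomial 99% interval at the observed
informative count, n ≈ 250–300); a sensitivity floor (a single recombinant
read among ≥ 1200 informative reads for a 462-bp direct pair on a 50-kb
ten-pair genome is reported with no false positives across the nine
quiescent pairs — the 1-in-1200 regime); and null soundness (pure-master
pools over all ten geometries, identities 81.5–100, yield zero alternative
calls at default thresholds, with every pair genuinely informative).
Deterministic oracles run alongside: brute-force maximal-exact-repeat
enumeration, bitmap union coverage, BFS over double-cut-and-join
operations, and independent cut-and-paste junction construction.

## Comparative utilities: design choices

The rearrangement distance is the DCJ distance, $n - c$ from the cycles of
the adjacency graph over common markers. Published comparisons of this
kind report "inversions and translocations" from tools that offer several
models; DCJ subsumes both operations and has the clean circular-genome
formula, so it is the model implemented, stated as such. Duplicated genes
(real mitogenomes may carry e.g. a duplicated *rps19* or *atp6*) are not
modelled: gene orders reject duplicate symbols, and handling duplicates
optimally is out of scope — drop or rename duplicates upstream. Conserved
cluster detection requires a run of ≥ 2 genes contiguous (as a unit,
flips allowed) in ≥ 2 focal taxa and ≥ 1 outgroup taxon; whether
orientation within the run must be preserved is exposed as the `signed`
switch (default `TRUE`), since published cluster tables do not state the
convention. Plastid-insert detection merges mito-side overlapping hits
into loci (union extent, length-weighted mean identity), with per-hit
output behind `merge = FALSE`.

## Degenerate inputs and edge behaviour

Empty sequences and non-ACGTN characters are rejected with the offending
position named; clustering an empty set returns an empty family list, and
sequences shorter than the clustering word found their own family with a
warning; a repeat pair whose copies overlap without being palindromic is
an unsupported geometry error in conformation surgery; flanks that overrun
a linear sequence error, while circular sequences wrap; a pair with no
informative reads reports its frequency as not-applicable rather than 0;
and an empty read set yields zeroed statistics with a warning.

## Known limitations

* Reads matching several repeat pairs are counted independently per pair;
  no apportioning is attempted (how published pipelines apportioned such
  reads is unstated).
* Frequency estimates carry binomial noise at the informative-read count;
  the package reports counts so users can compute intervals.
* The e-value calibration uses ungapped Karlin–Altschul parameters with a
  fixed K; e-values are comparable within a run but are approximations,
  not fitted to empirical score distributions.
* Absolute repeat-pair counts depend on engine details (seeding, X-drop,
  chaining); like the published inventories they should be read as
  convention-dependent, and only the planted-truth recovery, not absolute
  counts, is asserted by the tests.
* Published read-pool figures for studies of this kind are not always
  internally consistent (database read counts versus total-pool counts,
  average depth versus total bases over genome length). `db_stats()`
  therefore always recomputes its statistics from the read set in hand and
  never takes reported totals at face value.
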