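---
title: "Detecting TE polymorphisms and estimating their population frequency from pooled sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting TE polymorphisms and estimating their population frequency from pooled sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transposable elements (TEs) move. In a pooled DNA sequencing experiment —
many individuals sequenced together — every polymorphic insertion or
excision is present in only a fraction of the genomes in the tube, so a
caller designed for a single genome will either miss rare events or be
unable to say how common they are. `tepool` detects, relative to a
reference genome and a library of TE consensus sequences:

* **insertions** present in sample genomes but absent from the reference,
* **absences** of reference-annotated TE copies from sample genomes,

and for each event estimates the **population frequency** — the fraction of
pooled genomes carrying it — together with base-pair-resolution junctions
where soft-clipped reads permit.

## Detection model

**Insertions.** The primary signal is the discordant read pair: one mate
(the *anchor*) maps uniquely to the reference; the other is unmapped or
multi-mapping *away from* the anchor and matches a TE consensus. The family
is assigned by ungapped end-to-end comparison of the mate against every
consensus on both strands, taking the placement with fewest mismatches
(default cap 3); a tie between different families is ambiguous and
discarded rather than guessed. The insertion's orientation follows from the
anchor strand and the consensus strand of the mate under FR library
geometry: opposite strands imply a `+` insertion, equal strands `-`.

Each anchor bounds the junction: it must lie within one mean insert size of
the insertion-facing anchor end (the *interval estimate*). Supports of the
same family and orientation whose interval estimates overlap by at least
one nucleotide are single-linkage clustered, and the intersection of member
intervals is the refined interval. When a chain's global intersection is
empty (possible under single linkage) it is split greedily left-to-right
into maximal runs with a non-empty common intersection, so a reported
interval is always an intersection of its supports.

One numerical choice matters here. With a local aligner such as `bwa mem`,
anchors often extend exactly *to* the junction (the TE-derived tail is
soft-clipped) and a few bases beyond it wherever the inserted sequence
happens to continue the reference (microhomology); target site duplications
shift the two per-strand junctions apart as well. Taken literally, the
interval `[anchor_end, anchor_end + insert)` then excludes the junction by
a few bases, and left- and right-side supports stop overlapping. The
interval estimate is therefore widened on its junction-facing side by
`junction_pad` (default 20 bp, the same scale as the clip-collection
window). Without the pad, each insertion fractures into two events whose
intervals miss the true junction.

**Absences.** A reference TE copy missing from sample genomes leaves read
pairs whose mates map uniquely on either side of the copy with an outer
fragment span far above the library insert size. Pairs qualify when the
span exceeds `insert_mean + span_z * insert_sd` (default z = 3) but stays
below 10 kb (beyond which apparent long spans are overwhelmingly mapping
artifacts), at least one annotated copy lies fully inside the inner span,
and the span after subtracting the spanned TE lengths is again concordant
(within the same z band). Supports sharing an identical spanned copy set
form one event. Spans are *outer* fragment lengths throughout, matching the
definition of insert size as the outer mate distance; containment is tested
against the inner span, because only a copy with both junctions bracketed
is evidenced as absent. The caller cannot distinguish a true excision from
a reference-specific insertion polymorphism; both are reported as
`absence`.

## Junction refinement and TSDs

Interval estimates are extended by 20 bp on both sides and soft-clipped
reads whose clip point falls inside the window are collected. A clip is
accepted as junction evidence when it is at least 7 nt long and matches
perfectly — insertions: anywhere in the event family's consensus on either
strand (truncated copies create internal junctions); absences: the genomic
sequence continuing on the far side of the spanned TE. Per clip side the
junction is the clip point supported by most accepted clips, ties resolved
towards the smaller coordinate for determinism. Events without any
accepted clip fall back to the interval midpoint (insertions) or the
annotated boundaries (absences); those surrogates are never counted as
base-resolution estimates.

Reads clipped at their trailing end approach the junction from the left
and define `junction_plus`; leading clips define `junction_minus`. Their
signed difference is the target-site-duplication length: positive for a
duplication, negative for a target-site deletion. The sign convention is
pinned by simulation: planting an insertion that duplicates the `L` bases
upstream of the site yields `junction_plus - junction_minus = L` exactly on
error-free reads, provided the junctions carry no microhomology (with
microhomology the clip points shift by the homology length on each side
independently — a genuine ambiguity of the sequence, not an estimation
error, and the reason junction accuracy is assessed with a 5 nt window).

## Frequency estimation

For each event, `T` counts distinct read pairs supporting it (discordant
pairs plus accepted clips; a pair contributing both counts once) and `R`
counts concordant, both-unique pairs whose fragment brackets the estimated
junction with at least `ref_flank` (default 7, mirroring the minimum clip)
bases on each side; pairs already in `T` are excluded. The frequency
estimate is `T / (T + R)`.

For absence events both annotated boundaries are junctions in the
reference frame while the sample genome has a single joined junction. The
two per-boundary spanning-pair counts are therefore averaged rather than
summed: each boundary measures the same local reference-genome coverage,
and summing them would double `R` relative to the single-junction geometry
of `T`, halving estimated frequencies.

`T` integrates evidence over windows on both sides of the junction while
`R` integrates over fragments bracketing a single point, so the two rates
per unit coverage are not identical and the estimator carries a modest
upward bias at intermediate frequencies; on the built-in benchmark it
contributes most of the observed mean absolute error (~0.03–0.09 depending
on design), comparable to the published behaviour of this class of
estimator. No confidence intervals are attached.

## The simulator: what it emulates, and what it does not

`make_te_library`, `make_synthetic_reference`, `mutate_genome`,
`simulate_reads` and `mix_pools` reproduce the evaluation design the method
was published with, without external downloads:

* uniform random background genome with full-length consensus copies
  substituted at non-overlapping uniform positions (round-robin families, so
  every family has multiple identical reference copies and TE-derived reads
  genuinely multi-map);
* insertions of complete consensus sequences at uniform sites (optional
  designed TSD, default 0) and excisions of entire annotated copies;
* 90 nt FR pairs, insert size Normal(500, 50) truncated below at twice the
  read length, substitution errors at 1e-4 per base, no indels, no GC or
  quality structure (qualities are constant `I`);
* pooling either by concatenating reads from independently mutated genomes
  (each event then segregates at 1/n) or by binomial mixing of variant and
  reference pools at a designed frequency.

Defaults follow the published simulation protocol (read length, insert
distribution, error rate, event counts). The synthetic genome is simpler
than a real one in ways that matter for interpreting benchmark numbers: it
has no repeat landscape beyond the planted copies, no diverged or truncated
TE copies, and every annotated copy has unique flanks. Detection and
precision on it are therefore upper bounds on real-data performance —
absence sensitivity in particular saturates near 100%, where the published
figure on a real chromosome arm (93%) reflects excised copies whose
neighbourhoods are themselves repetitive. Consensus lengths default to
0.8–3 kb so that an excised copy plus one insert size stays far below the
10 kb artifact cap.

## Benchmark harnesses and problem sizes

Two harnesses drive all performance claims (`sim_pooled_arm`,
`sim_frequency_sweep`), both mapping with single-threaded `bwa mem` and
scoring with the package's evaluator: an insertion is recovered when the
reported interval contains the true junction with family and orientation
correct; an absence when the corresponding annotated copy is reported; a
base junction estimate is correct within 5 nt; false positives are binned
by their estimated frequency.

The shipped configuration uses a 2 Mb reference with 20 TE copies from a
10-family library, five independently mutated genomes (10 insertions + 10
excisions each) at 5X pooled to 25X apparent coverage for the
pooled-replicate design, and a 1 Mb reference at 20X for the ten-step
designed-frequency sweep. These sizes keep a complete benchmark round in
the minutes range on one CPU while leaving per-event support counts (tens
of pairs per event) at the same order as the published full-scale runs;
they are the package's chosen operating point, and all rates are reported
with their underlying counts so the resolution limit (1–2% per arm) is
visible.

## Other numerical and design choices

* *Uniqueness* is mapping quality ≥ 20 by default — portable across
  aligners, unlike aligner-specific tags.
* All internal coordinates are 0-based half-open; outputs are
  BED-compatible. Event tables sort by (contig, start, family) with fixed
  tie-breaks, so identical inputs give byte-identical outputs.
* Sequences are uppercased at load; `N` matches anything during consensus
  assignment by default (`n_is_wildcard`), and never participates in exact
  clip validation.
* A multi-mapping mate placed properly beside its anchor is local, not
  distant, evidence and is not discordant; without this rule every
  annotated reference copy edge would seed a false insertion call.
* Reads shorter than 20 nt are never assigned to a family; a tie between
  families is logged as ambiguous rather than resolved arbitrarily.
* Minimum cluster size to emit an event is 1; reporting filters
  (`min_reads`, `min_freq`) are a separate, explicit stage, with the
  published pooled-human operating point available as
  `filter_events(ev, min_reads = 9, min_freq = 0.2)`.
* The Wright–Fisher drift null (`wf_change_tail`) is one generation of
  binomial resampling of `n` chromosomes, maximised over the parental
  frequency grid and summed exactly in log space, so sub-1e-15 tails are
  exact rather than floating-point noise. It deliberately conditions on
  nothing but `n`: the maximisation makes it conservative for every
  parental frequency.
* Mendelian frequency change (`frequency_change`) computes
  `fc = f - (h + w)/2` only for events parental under the 10% threshold;
  junction composition counts mono- and dinucleotides in ±15 bp windows
  around the junction midpoint against 100 bp flanking backgrounds and
  writes the 30 bp windows as FASTA for external motif tools.

## Known limitations

* No de-novo TE discovery: events are only called against the supplied
  consensus library.
* No internal-deletion or partial-loss detection; absence means the entire
  annotated copy.
* Ungapped consensus matching: highly diverged or indel-bearing copies will
  be missed (a divergent-library mode is out of scope by design).
* Frequencies carry the window-asymmetry bias described above and have no
  uncertainty estimates.
* CRAM is not supported; alignments are consumed, never written.
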