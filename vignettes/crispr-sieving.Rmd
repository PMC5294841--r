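---
title: "Sieving real CRISPRs from CRISPR-mimicking elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sieving real CRISPRs from CRISPR-mimicking elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprsieve)
```

## The problem

A CRISPR array is a run of nearly identical direct repeats (21--47 bp)
separated by unique spacers of similar size, usually sitting next to a
locus of *cas* genes. Detection tools that look only for the
repeat--spacer pattern also report other periodic elements -- tandem
repeats, *Staphylococcus aureus* repeat (STAR)-like elements, and simple
low-complexity runs -- as CRISPRs. `crisprsieve` annotates genomes end to
end and, crucially, separates real CRISPRs from these mimics using two
orthogonal lines of evidence: genomic context (*cas* co-location,
propagated through repeat clusters) and spacer diversity.

## The pipeline

1. **Array detection** (`find_arrays`). CRT-style seed and extend: an
   exact `seed_kmer` (default 8 bp) word recurring at spacings compatible
   with one repeat plus one spacer (39--119 bp at the defaults) seeds a
   chain of candidate repeat copies; the repeat window is then widened one
   column at a time on whichever side at least 75% of the copies agree
   with the column majority. Candidates are validated against the repeat
   bounds (21--47 bp), spacer bounds (18--72 bp), a per-copy mismatch
   tolerance (20% of the repeat length) and a minimum of
   `min_repeat_count` (3) copies; overlapping candidates are resolved in
   favour of more repeats, then longer span, then smaller start.
2. **Partial terminal repeats** (`extend_partial_repeats`). A truncated
   copy of the consensus one spacer beyond either array end is annexed
   when it matches at least half the consensus. Candidate partials are
   scored as `matches - 3*mismatches` over each admissible spacer gap, so
   random continuation beyond the true partial is penalised rather than
   absorbed.
3. **Merging** (`merge_arrays`). Arrays at most 200 bp apart
   (inter-interval distance `start2 - end1`) whose consensus repeats share
   at least 90% identity are unioned; a gap with a spacer-compatible
   length becomes a spacer, anything else is kept as an annotated
   insertion. Applied to transitive closure; idempotent.
4. **Repeat clustering** (`cluster_repeats`). Greedy incremental
   clustering at 90% identity in CD-HIT-EST style: sequences are visited
   longest-first and join the first cluster whose representative they
   match. Identity is always counted over the best global alignment and
   divided by the shorter sequence length (the CD-HIT denominator).
   Repeats on opposite strands stay in distinct clusters unless
   `both_strands = TRUE`, mirroring how oppositely oriented repeat pairs
   are treated as separate families.
5. **Spacer diversity** (`is_diverse`). Spacers are clustered at 70%
   identity; an array is DIVERSE when the cluster count reaches
   `ceiling(n/2)` **and** is at least 2. The second condition is needed
   because a pair of identical spacers would otherwise pass (1 cluster
   >= ceiling(2/2)); a two-spacer array without diversity is SHORT, larger
   non-diverse arrays are NOT_DIVERSE. A pair at exactly 70% identity
   falls in one cluster, as CD-HIT's threshold semantics imply.
6. **Cas loci** (`group_cas_genes`, `validate_locus`, `assign_type`).
   Annotated cas genes (from a TSV/GFF3 table or an hmmscan domain table
   reduced to the best-scoring family per protein) are chained at a 1,000
   bp intergenic gap -- the grouping distance is a package choice, exposed
   in the configuration. A valid locus has >= 3 cas genes including at
   least one adaptation gene (cas1/cas2) or core interference component
   (cas5, cas7, cas8, cas10, csf1, cas9, cpf1). The type call is the type
   with most signature genes present (shipped as an editable TSV mapping);
   >= 3 type-consistent signature genes make it confident, except type V,
   which is assigned confidently from cpf1 alone.
7. **Co-location** (`classify_colocation`). An array and a locus within
   10,000 bp (edge of the array to the edge of the nearest cas gene, on
   the same record) are CO_LOCATED; a partner elsewhere in the genome --
   beyond the window or on another contig of the same assembly -- makes
   the element ISOLATED_REMOTE; no partner at all makes it an ORPHAN.
   Distances are measured on the linear sequence by default;
   `circular = TRUE` takes the shorter way around the replicon.
8. **Real/false classification** (`classify_element`). A repeat cluster
   containing at least one co-located array is real, and all members
   inherit the label; a candidate-false consensus within 5 mismatches of
   any real repeat (best ungapped end-free alignment; length differences
   and unaligned overhang count as mismatches) is rescued as real.
   Everything else cascades through the false-element detectors.

## Classifying false elements

* **STAR** -- the 14-position signature `T[G/A/T]TGTTG[G/T]GGCCC[C/A]` is
  scanned exactly, on both strands, over the array region and its
  consensus repeat. The motif admits 3 x 2 x 2 = 12 concrete strings per
  strand, so a random 14-mer matches with probability 24/4^14 ~ 9e-8 over
  both strands -- specific enough that a single hit is decisive.
* **TANDEM** -- a Tandem Repeat Finder style scorer: candidate periods
  come from the distance histogram of repeated 4-mers (short periods are
  always tried), and the region is aligned to cyclic copies of each
  candidate unit by local wraparound dynamic programming (match +2,
  mismatch -7, indel -7; implemented in C++). Because the alignment may
  start anywhere in the unit, the score is invariant under unit rotation.
  A call needs score >= 50, coverage >= 0.8 of the region and >= 2 copies.
* **SIMPLE** -- a single nucleotide at >= 40% of the region, a tandem unit
  of <= 6 bp covering >= 80%, or mononucleotide entropy <= 1.5 bits. The
  mononucleotide check runs first: a noisy homopolymer also satisfies the
  period-1 tandem criterion, but its base bias is the better description.
* **UNKNOWN** -- none of the detectors fire.

Two ordering decisions matter and are deliberate. First, the default
cascade tests STAR before TANDEM: STAR elements are themselves tandem
arrays of conserved units, so a generic periodicity test run first would
absorb nearly all of them, whereas the signature scan has a ~1e-7
false-positive rate per 14-mer and loses nothing by going first. The
precedence is configurable (`precedence` in `sieve_config()`). Second, a
winning tandem call whose unit is itself low-complexity (unit entropy at
or below `entropy_max`, or unit length <= `simple_max_unit`) is not
labelled TANDEM; such regions -- homopolymer runs score best as long
noisy units under the TRF weights -- fall through to the SIMPLE detector,
which matches how short-unit elements such as a 6 bp unit repeated 12
times are conventionally described as simple repeats.

Spacer diversity is reported as evidence (the d+/d-/short vocabulary of
the cluster matrix) but does not veto a cas-rescued cluster by default;
`strict_diversity = TRUE` withholds the mismatch rescue from cas-absent,
non-diverse clusters.

## Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `min_repeat_len`/`max_repeat_len` | 21/47 | bp | repeat length bounds |
| `min_spacer_len`/`max_spacer_len` | 18/72 | bp | spacer length bounds |
| `min_repeat_count` | 3 | copies | minimum repeats per array |
| `seed_kmer` | 8 | bp | exact seed word |
| `max_repeat_mismatch_frac` | 0.2 | fraction | per-copy divergence cap |
| `partial_min_match` | 0.5 | fraction | minimum partial-repeat match |
| `merge_gap_bp` | 200 | bp | array merge distance |
| `window_bp` | 10000 | bp | co-location window |
| `repeat_cluster_identity` | 0.90 | fraction | repeat clustering |
| `spacer_cluster_identity` | 0.70 | fraction | spacer clustering |
| `min_locus_genes` | 3 | genes | valid locus size |
| `min_signature_genes` | 3 | genes | confident type call |
| `rescue_mismatch_limit` | 5 | mismatches | similarity rescue |
| `collection_identity`/`coverage` | 0.90/0.90 | fraction | external collections |
| `locus_gap_bp` | 1000 | bp | cas gene chaining |
| `tandem_min_score` | 50 | score | TRF-style call floor |
| `simple_max_unit` | 6 | bp | simple-repeat unit cap |
| `mono_frac` | 0.40 | fraction | mononucleotide trigger |
| `entropy_max` | 1.5 | bits | low-complexity trigger |

The repeat bounds, merge gap, window, identities, locus rules, rescue
limit and collection rule are the screening rules themselves; the
detector internals (seed size, mismatch tolerance, spacer bounds, TRF
weights with their published defaults 2/-7/-7 and minimum score 50) are
tool parameters with the stated defaults, all reachable from the YAML
configuration and echoed in the run summary.

## The synthetic benchmark

`generate_genome()` plants elements into i.i.d. background of configurable
GC content (`gc`), separated by at least twice the longest element block
and by more than the co-location window, so no planted element sits in
another block's cas neighbourhood. Element models:

* CRISPR: `n_spacers + 1` repeat copies; spacer lengths track the repeat
  length within +-5 bp; spacer content diverse, duplicated or constant;
  per-copy substitution noise optional.
* cas locus: coordinate stubs (900 bp genes, 50 bp gaps) carrying the
  gene complement of one type; sequence content is random because the
  annotation table, not the sequence, is the input contract.
* STAR: conserved units embedding one uniformly sampled motif
  instantiation (either strand) with identical linkers.
* tandem: exact head-to-tail copies of a random 66--100 bp unit. The unit
  range is a modelling choice: a CRISPR-mimicking tandem must offer a
  21--47 bp conserved stretch plus a spacer-sized remainder per copy,
  otherwise no repeat-spacer detector would report it in the first place.
  Short-unit tandems are planted separately as the SIMPLE kind.
* simple: a mononucleotide run with 5% substitution noise.

GC presets up to 72% GC or 85% AT emulate composition-biased genomes
where low-complexity false positives concentrate.

What passing the planted-truth tests shows -- and what it does not. The
benchmark establishes that each detector recovers its own element model
and that the real/false cascade routes clean, well-separated elements
correctly. Real genomes add degraded arrays, overlapping features, mobile
elements, composition bias and incomplete cas annotations; recall and
precision there cannot be inferred from the synthetic rates.

## Numerical choices and degenerate inputs

* Identity is computed from the best global alignment (match +1, mismatch
  -1, gap open 4, extend 2) with the shorter-sequence denominator; `N`
  mismatches everything including `N`, so matches never cross `N` runs,
  and seeds containing `N` are skipped.
* Consensus voting breaks column ties by the first-occurring base among
  the tied candidates; copies deviating more than 20% from the modal
  length are excluded from the vote, the rest are aligned end-gap-free.
* Sequences shorter than the minimal array footprint return an empty
  result rather than an error; an empty FASTA yields a zero-count
  summary.
* The wraparound DP sweeps each row twice to close the cyclic insertion
  dependency; ties between tandem calls go to the higher score, then the
  smaller period, then the earlier phase. Distinct unit phases per period
  are capped at 64; for exact tandems all rotations score identically, so
  the cap is immaterial there.
* Greedy clustering visits sequences longest-first with input order as
  the tie-break, making results deterministic.
* In dense low-complexity regions the exhaustive seed-chain enumeration
  is capped (256 chains per seed word) and falls back to deterministic
  greedy chaining.

## Problem sizes

The shipped tests run the detector against a brute-force enumeration on
one hundred random sequences of up to 5 kb, compare the tandem scorer
with an exhaustive wraparound oracle on regions of ~100 bp, enumerate all
spacer multisets of up to 8 spacers over four dissimilar toy spacers for
the diversity rule, and evaluate planted-truth recovery on fifty ~80 kb
synthetic genomes (one complete system plus three false elements each).
`scripts/acceptance.R` recomputes the recovery rates, diversity fraction
and median CRISPR-cas distance from fifty fresh genomes per run.

## Known limitations

* Array orientation and leader-sequence identification are out of scope.
* Subtype-level typing is only as fine as the signature table provided;
  the shipped table covers the five main types.
* The hmmscan adapter consumes search output; it does not run searches or
  ship profile models.
* The tandem scorer reports the best single call per region; nested or
  mixed-period structures are summarised by whichever call scores best.
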