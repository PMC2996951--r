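---
title: "tRNA-anchored primer design and COI barcode QC: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tRNA-anchored primer design and COI barcode QC: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnanchor)
```

## The problem

PCR recovery of the 5' COI barcode region fails in some arthropod groups
(scale insects are the notorious case) because the standard primer binding
sites inside COI have diverged. An alternative is to prime not inside COI
but in a conserved gene upstream of it. Mitochondrial tRNA genes are short
(60-68 bp) and partially conserved, but both their genomic position and
their orientation move around between lineages, so a usable anchor gene
must be (i) almost always present immediately upstream of the target,
(ii) always in forward orientation relative to it, and (iii) close enough
that the extra amplicon length stays sequenceable. In hexapod mitogenomes
the tRNA-Trp gene satisfies all three: it sits upstream of COI in the vast
majority of genomes, always forward, within 200 bp (the occasional tRNA-Cys
and tRNA-Tyr genes between it and COI are each only 60-68 bp). `trnanchor`
packages that whole chain of reasoning as code: survey gene arrangements,
select the anchor, group the anchor sequences, emit degenerate primers,
predict amplification in silico, and QC the recovered reads.

## Pipeline overview

1. **Survey** (`tabulate_arrangements`, `select_anchor`): signed gene-order
   strings upstream of the target (`"W,-C,-Y"` notation; a minus sign is
   reverse orientation relative to the target). Candidates are ranked
   lexicographically by presence fraction, forward-orientation fraction,
   then ascending median distance, with the gene token as a final
   deterministic tie-break. A weighted score would need weights we have no
   basis to choose; the lexicographic order encodes the priority argument
   directly. Eligibility requires forward orientation in every genome where
   the gene occurs and a median 3' gap of at most
   `max_anchor_distance_bp = 200`.
2. **Cluster** (`center_star_msa`, `partition_groups`): anchor gene
   sequences are aligned and partitioned into homogeneity groups over a
   central window; each group gets an IUPAC degenerate consensus
   (`degenerate_consensus`).
3. **Design** (`design_primer`): a primer core is cut from each consensus,
   preferring a 3'-terminal G/C (a 3' G or C clamps extension and
   measurably improves priming).
4. **In-silico PCR** (`scan_primer`, `predict_amplification`): IUPAC-aware
   matching of primer cores against templates with a 3'-weighted failure
   rule.
5. **Barcode QC** (`trim_upstream`, `call_initiation_codon`,
   `translate_mito`, `numt_screen`, `detect_indels`): trim the upstream
   tRNA segment off each read, call the initiation codon, translate under
   genetic code table 5, screen for NUMT signatures and locate amino-acid
   indels.

A worked end-to-end run on simulated data:

```{r pipeline, eval = FALSE}
cfg <- sim_config(seed = 1)
corp <- generate_corpus(cfg)
res <- run_pipeline(corp$genomes, out_dir = tempdir(), seed = 1)
res$groups
```

## Alignment: center-star, and why its scoring matters

Anchor tRNAs are 20-100 nt and near-equal length, a regime where center-star
multiple alignment (align everything to the sequence with minimal summed
Levenshtein distance, merge under "once a gap, always a gap") is accurate
and dependency-free. Two numerical choices deserve a note:

* **Pairwise scoring is match +1, mismatch -1, gap -3.** With unit-cost
  edit distance, several optimal paths usually tie and single point
  mutations flip which one is chosen, so homologous rows end up with gaps
  in different columns. Making a gap clearly more expensive than a mismatch
  anchors gap placement on conserved blocks and guarantees that
  equal-length sequences differing at three or fewer sites align without
  gaps at all. Traceback ties resolve deterministically
  (diagonal, then gap-in-second, then gap-in-first).
* **Group identity is computed by pairwise re-alignment of the window
  segments**, scored as matches over aligned (mutually ungapped) positions.
  The discriminating window sits exactly where the groups diverge, which is
  also where any multiple-alignment gap placement is least reliable; raw
  column-wise identity would double-count such placement noise as
  mismatches and complete linkage would then shear off spuriously shifted
  rows as singleton groups.

`partition_groups` merges complete-linkage style: the pair of clusters with
the highest minimum cross-pair identity merges first (ties break on the
smallest member id), and merging stops when no merge keeps all
within-cluster identities at or above the threshold. The default threshold
0.75 and the default central 19-column window are parameters, not claims:
the original grouping of anchor sequences was done by eye, so we expose
the knobs and choose defaults under which full-expansion fixtures of the
two published consensus groups separate cleanly (the worst within-group
pair of the 21-nt group-2 consensus expansions has identity 16/21 = 0.76).

## Consensus and primers

`degenerate_consensus` collects, per column, the bases with frequency at
least `min_freq` among non-gap symbols (`N` contributes 1/4 to each base)
and writes the unique IUPAC code for that set. `min_freq = 0.05` by
default: a base seen in fewer than 5% of members is treated as noise; with
`min_freq = 0` the consensus over a full expansion of an IUPAC string
returns that string exactly, which is the property the tests pin.

`design_primer` ends the core at the rightmost G/C/S column when
`prefer_3prime_GC` is set. Two published-primer quirks are handled by
explicit arguments rather than hidden rules, because neither is derivable
from the consensus alone: `resolution_map` collapses chosen degenerate
positions to a single base (e.g. W→A, N→T going from the group-1 consensus
to tRWF1), and `extend_3prime` appends unconditioned 3' bases (the group-2
primer is one base longer than its consensus). The melting-temperature
report is the Wallace rule `2(A+T) + 4(G+C)` over the minimum- and
maximum-GC expansions of the core — an operator convenience, deliberately
not a thermodynamic model.

```{r primers}
g <- anchor_consensus_groups()
design_primer(g[["group1"]], name = "tRWF1",
              resolution_map = c("7" = "A", "8" = "T"),
              tail = reference_primers()$m13_tail)
```

## In-silico PCR failure rule

Empirically, amplification fails once more than three primer-template
substitutions accumulate, and failures usually involve substitutions close
to the primer 3' end. Those two observations are operationalized as one
deterministic score: each mismatch counts once, mismatches within the last
`three_prime_window_nt = 10` core positions count twice, a mismatch at the
3'-terminal base fails outright, and a site fails when the weighted score
exceeds `mismatch_fail_count = 3`. All constants live in
`default_thresholds()` and are overridable. The rule is monotone by
construction: adding a substitution can never turn a predicted failure into
a success (a property the tests verify). Amplicon lengths are reported with
both primer footprints included and 5' tails excluded, matching how
sequenced amplicon lengths are stated. Template ambiguity codes match any
compatible primer code; compatibility is base-set intersection, symmetric
in both arguments.

## Barcode QC

**Trimming** is ORF-anchored rather than tRNA-model-based (no covariance
model in scope, and the contract stays testable): every codon-start within
the first `trim_band + 30` bp whose codon is an acceptable initiator and
whose downstream frame is stop-free for at least 150 nt is a candidate, and
the winner has the longest stop-free run, compared after capping at
`barcode_min_len_bp`. The cap matters: an open frame covering the full
barcode length is already maximal evidence for a start, and without it a
reading frame censored by the read end (hence with no observable stop) can
outscore a complete ORF by a couple of nucleotides. Ties resolve 5'-most.

**Initiation calling** accepts the canonical mitochondrial starts
(ATA/ATT/ATC/ATG as class `ATN`, plus TTG and GTG) directly. The
non-canonical starts TCG/CCG (class `TCG_type`) and CGA (`CGA_type`) are
accepted only in the documented context: the in-frame codon immediately 5'
is a TAA/TAG stop and no canonical initiator occurs in frame within
`initiator_scan_window_bp = 30` bp downstream of that stop. The window is
measured from the first base after the stop — the source description does
not say which end of the stop codon anchors it, so we fixed one reading and
documented it. Quadruplet starts (ATAA/TTAA/TTAG/ATTA) are annotated in an
attribute but never returned as calls; the evidence for them is weaker than
for TCG/CGA and we mirror that skepticism.

**Translation** uses NCBI genetic code table 5 (invertebrate mitochondrial:
AGA/AGG = Ser, TGA = Trp, ATA = Met; TAA/TAG the only stops) via the
Biostrings code table; degenerate codons translate to `X` unless all
expansions agree.

**NUMT screening** flags internal stops from the frame-0 translation,
frameshifts from a global nucleotide alignment against a reference CDS
(any gap whose length is not a multiple of 3; the alignment itself is
Biostrings' pairwise aligner — a standard step we buy rather than build),
and `SHORT` below `barcode_min_len_bp = 500`. The 500 bp default is the
community convention for formal barcode status; it is configurable because
the convention, not a derivation, is its justification.

**Indel detection** aligns query and reference proteins with match +1,
mismatch -1, gap -2 (linear), no penalty on trailing gaps so a shorter 3'
tail is free, and an identity floor of 50% below which the input is
rejected as the wrong gene or frame. Traceback is "sticky": on score ties
it prefers extending the current gap run over re-opening one, so an
equal-score indel stays contiguous instead of splitting around a repeated
residue. Deletion positions are reference residue coordinates counted from
the initiation codon, 1-based; runs touching the alignment ends are not
reported as events.

## The simulator: what it emulates, and what it does not

`sim_config`/`generate_mitogenome`/`generate_read` produce annotated
genomes and reads that embody the structural facts the analyses rely on:
the upstream arrangement mix (default 126 genomes of which 120 carry the
anchor, dominated by `"W,-C,-Y"`), anchor sequences drawn uniformly from
the expansions of the two consensus groups (92/28 split) embedded in fixed
flanks with 2% substitution noise, tRNA lengths of 60-68 bp, intergenic
gaps of 0-20 bp, a COI gene back-translated from a fixed 230-residue
reference protein with a planted initiation codon, optional planted
deletions/frameshifts/stops, reads with 70-200 bp of upstream filler and
total lengths inside 730-870 bp. Counts given as integers are planted
exactly and deterministically; the whole corpus is a pure function of
`(seed, index)`.

Deliberate non-realism, so that passing tests are read correctly: base
composition is uniform (the anchor flanks are even GC-rich on purpose, so
block alignment is unambiguous), codon usage is uniform across synonymous
codons, and there is no substitution model linking the genomes. Tests
passing on these fixtures demonstrate that the operations recover what was
planted under the stated structural conditions; they say nothing about
alignment quality on compositionally biased real sequences, which is why
externally aligned FASTA is accepted wherever an aligned block is.

Two generator details exist purely to keep ground truth recoverable. With
`clean_filler = TRUE`, upstream regions are re-drawn until no position
upstream of the planted start holds an acceptable initiator whose
(capped) stop-free run ties or beats the planted one — exactly the
"no-confounder" precondition under which the recovery invariants are
stated; the flag is off by default. And the stop planted before a
non-canonical initiator is TAG, not TAA, because TAA abutting TCG embeds a
canonical ATC in the -1 frame that no redraw could remove.

## Problem sizes and runtime envelope

The shipped tests and the acceptance script use a 126-genome survey corpus
(the scale at which the anchor statistics are quoted), 1,000 reads for the
QC-recovery rates, 200 random IUPAC strings for the consensus round-trip,
and exhaustive enumeration for the 15x15 compatibility table and the
union-of-expansions scan oracle (degeneracy capped at 16). These sizes were
chosen as the smallest at which the quoted proportions (120/126, 92/28) are
representable exactly and rate estimates have single-read resolution; the
full suite runs in well under a minute on one core.

## Known limitations

* Center-star alignment degrades when inputs are not near-equal-length
  homologs; it is not a general-purpose MSA.
* Origin-spanning features are rejected rather than handled; the anchor
  window of interest is linear and short.
* The in-silico PCR rule is a deterministic heuristic, not a hybridization
  model; it does not see primer dimers, hairpins, or non-specific
  amplification beyond multiple-hit reporting.
* GenBank parsing covers the simple subset needed here (no joins, fuzzy
  coordinates, or qualifier semantics beyond `/gene` and `/product`).
* `UNCERTAIN` initiation calls arise only from the classification rules;
  sequencing-quality effects (e.g. missing bidirectional coverage) are out
  of scope.
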