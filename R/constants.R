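# Built-in sequence assets of the tRNA-anchored barcoding method.

#' The two tRNA-W anchor consensus groups
#'
#' Hexapod mitochondrial tRNA-Trp genes fall into two homogeneity groups over
#' the central segment used for primer placement: a dominant group and a
#' minority group that diverges over six central nucleotides. These IUPAC
#' consensus strings seed primer design and the simulator.
#'
#' @return named character vector with elements `group1` and `group2`.
#' @export
anchor_consensus_groups <- function() {
  c(group1 = "AAACTAWNARCCTTCAAAG",
    group2 = "AAACTANWRATYTTCAAAATY")
}

#' Reference primers of the tRNA-anchored method
#'
#' The two anchor (tRNA-W) forward primers, the scale-insect rescue forward
#' primer, and the universal M13 sequencing tail. tRWF1/tRWF2 resolve the two
#' anchor consensus groups (with documented base resolutions at the degenerate
#' positions that are not algorithmically forced); PcoF1 targets the standard
#' forward-primer binding region inside COI 5', degenerate where scale insects
#' vary.
#'
#' @return named list of [primer_spec()] objects plus `m13_tail` (character).
#' @export
reference_primers <- function() {
  tail <- "TGTAAAACGACGGCCAGT"
  list(
    tRWF1 = primer_spec("tRWF1", "AAACTAATARCCTTCAAAG", tail = tail),
    tRWF2 = primer_spec("tRWF2", "AAACTAATAATYTTCAAAATTA", tail = tail),
    PcoF1 = primer_spec("PcoF1", "CCTTCAACTAATCATAAAAATATYAG"),
    m13_tail = tail
  )
}

# Fixed 230-residue COI-like reference protein used by the simulator as the
# back-translation template and by indel detection as the reference profile.
# Residues 2-10 avoid Met/Ile so that, combined with initiator-free codon
# choices there, no canonical initiator can appear in frame just downstream
# of a planted non-canonical start.
.reference_protein_string <- paste0(
  "MSWKVQCSKGKSWALNNYTFFHWPSHMLQMWFTCFYGVGSYVMMTKSKKHPMVMAQECACESWVSFFPLCMQKCIITHLS",
  "FTRVWQDIEGPHAEYCSVALVWDFTKAYFWPFDTDVPGLKGCGTPMWVYTAIWNGESGSLVTKGHMDYYQCIWEFSEPLD",
  "PNVRMKFHHYQNRHIDWLWVEPNKSNNYNYQDSYRFNQAWFGCRIECKKEDVQQFEIQLIGYCGQQCAQF"
)

#' Reference COI-like protein profile
#'
#' A fixed 230-residue protein used as the simulator's coding template and as
#' the default reference for [detect_indels()]. It is synthetic: a stand-in
#' profile, not a biological COI sequence.
#'
#' @return single character string of 230 amino acids.
#' @export
reference_protein <- function() .reference_protein_string

# Synthetic reverse-primer binding scheme for the simulator: the simulator
# plants the reverse complement of this 22-mer downstream of the COI stop so
# that a reverse primer has a defined site. Standard published reverse primers
# are not bundled; they enter via configuration.
.synthetic_reverse_core <- "TGGTGGAAGAGCTAGCCAAACT"

#' Synthetic reverse primer matching the simulator's planted site
#'
#' @return a [primer_spec()] with direction `"reverse"`.
#' @export
synthetic_reverse_primer <- function() {
  primer_spec("synthR1", .synthetic_reverse_core, direction = "reverse")
}
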