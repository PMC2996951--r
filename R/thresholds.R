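#' Analysis thresholds
#'
#' Bundles the tunable cutoffs used across the toolkit. Defaults encode the
#' empirical regularities of hexapod mitogenomes that motivate tRNA-anchored
#' priming: the anchor tRNA sits within 200 bp upstream of COI, intervening
#' tRNA genes are 60-68 bp, amplification fails once more than three
#' (3'-weighted) primer-template mismatches accumulate or the terminal 3'
#' base mismatches, reads carry 70-200 bp of upstream tRNA sequence to trim,
#' and sequenced amplicons run 730-870 bp.
#'
#' @param max_anchor_distance_bp maximum gap (bp) between the anchor gene's
#'   3' end and the target start for the anchor to be primer-eligible.
#' @param trna_len_range expected tRNA gene length range (bp).
#' @param mismatch_fail_count amplification is predicted to fail when the
#'   3'-weighted mismatch score exceeds this count.
#' @param three_prime_window_nt mismatches within this many nt of the primer
#'   3' end count double.
#' @param initiator_scan_window_bp window (bp) downstream of an upstream stop
#'   codon that must be free of canonical initiators before a non-canonical
#'   initiation codon (TCG/CCG/CGA) is accepted.
#' @param barcode_min_len_bp minimum trimmed length for formal barcode status.
#' @param trim_band_bp expected length band of the upstream (tRNA) segment of
#'   a read.
#' @param amplicon_band_bp expected sequenced amplicon length band.
#' @return an object of class `trna_thresholds` (a validated list).
#' @export
default_thresholds <- function(max_anchor_distance_bp = 200,
                               trna_len_range = c(60, 68),
                               mismatch_fail_count = 3,
                               three_prime_window_nt = 10,
                               initiator_scan_window_bp = 30,
                               barcode_min_len_bp = 500,
                               trim_band_bp = c(70, 200),
                               amplicon_band_bp = c(730, 870)) {
  th <- list(
    max_anchor_distance_bp = as.integer(max_anchor_distance_bp),
    trna_len_range = as.integer(trna_len_range),
    mismatch_fail_count = as.integer(mismatch_fail_count),
    three_prime_window_nt = as.integer(three_prime_window_nt),
    initiator_scan_window_bp = as.integer(initiator_scan_window_bp),
    barcode_min_len_bp = as.integer(barcode_min_len_bp),
    trim_band_bp = as.integer(trim_band_bp),
    amplicon_band_bp = as.integer(amplicon_band_bp)
  )
  scalars <- th[c("max_anchor_distance_bp", "mismatch_fail_count",
                  "three_prime_window_nt", "initiator_scan_window_bp",
                  "barcode_min_len_bp")]
  if (any(unlist(scalars) <= 0)) stop("all threshold values must be positive", call. = FALSE)
  for (b in c("trna_len_range", "trim_band_bp", "amplicon_band_bp")) {
    if (length(th[[b]]) != 2L || any(th[[b]] <= 0) || th[[b]][1] > th[[b]][2]) {
      stop(sprintf("%s must be a positive (lower, upper) pair", b), call. = FALSE)
    }
  }
  structure(th, class = "trna_thresholds")
}
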