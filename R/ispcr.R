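# IUPAC-aware primer-template matching and amplification prediction.
#
# Failure heuristic: amplification fails on a site when the 3'-terminal core
# base mismatches, or when the 3'-weighted mismatch score (every mismatch
# counts once, mismatches within the 3'-proximal window count twice) exceeds
# the failure cutoff. Only the core participates in matching; 5' tails are
# inert.

.match_result <- function(template_pos, flags, strand, core_len) {
  mism <- which(flags)
  structure(list(
    template_pos = as.integer(template_pos),
    strand = strand,
    core_length = as.integer(core_len),
    per_pos_mismatch = flags,
    mismatch_count = length(mism),
    min_dist_to_3prime = if (length(mism)) core_len - max(mism) else NA_integer_,
    terminal_mismatch = length(mism) > 0 && max(mism) == core_len
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> pos %d (%s): %d mismatch(es)%s\n",
              x$template_pos, x$strand, x$mismatch_count,
              if (x$terminal_mismatch) ", 3'-terminal" else ""))
  invisible(x)
}

#' Scan a primer along a template
#'
#' Slides the primer core over every footprint of the template (the reverse
#' complement for `strand = "-"`, with positions mapped back to the forward
#' strand) and records the per-position IUPAC mismatch profile. Template
#' ambiguity codes (e.g. `N`) match any compatible primer code.
#'
#' @param primer a [primer_spec()] or IUPAC string.
#' @param template template DNA (IUPAC alphabet).
#' @param strand `"+"` or `"-"`.
#' @param max_mismatch report only footprints with at most this many
#'   mismatches.
#' @return list of `match_result` objects sorted by template position
#'   (0-based, leftmost footprint base on the forward strand); empty when
#'   there is no hit.
#' @export
scan_primer <- function(primer, template, strand = c("+", "-"), max_mismatch = 3) {
  strand <- match.arg(strand)
  core <- if (inherits(primer, "primer_spec")) primer$core else
    .assert_iupac(primer, "primer")
  template <- .assert_iupac(toupper(template), "template")
  tpl <- if (strand == "-") revcomp(template) else template
  pv <- strsplit(core, "")[[1]]
  tv <- strsplit(tpl, "")[[1]]
  k <- length(pv); L <- length(tv)
  if (L < k) stop("template shorter than primer core", call. = FALSE)
  hits <- list()
  for (p in 0:(L - k)) {
    win <- tv[(p + 1):(p + k)]
    flags <- !.compat_matrix[cbind(pv, win)]
    if (sum(flags) <= max_mismatch) {
      pos <- if (strand == "-") L - (p + k) else p
      hits[[length(hits) + 1L]] <- .match_result(pos, flags, strand, k)
    }
  }
  hits[order(vapply(hits, `[[`, 0L, "template_pos"))]
}

# 3'-weighted mismatch score: each mismatch counts once, plus once more when
# it falls within the 3'-proximal window
.weighted_score <- function(hit, three_prime_window_nt) {
  mism <- which(hit$per_pos_mismatch)
  in_window <- sum(hit$core_length - mism < three_prime_window_nt)
  hit$mismatch_count + in_window
}

#' Predict amplification from a forward and a reverse binding site
#'
#' Each primer passes unless its 3'-terminal base mismatches or its
#' 3'-weighted mismatch score exceeds `mismatch_fail_count`. The amplicon is
#' reported with both primer footprints included (outer coordinates) and
#' tails excluded, matching how sequenced amplicon lengths are reported.
#'
#' @param fwd_hit forward-primer `match_result` (or `NULL` for no site).
#' @param rev_hit reverse-primer `match_result` (or `NULL`).
#' @param thresholds see [default_thresholds()].
#' @return object of class `amplicon_prediction`: `success`, `reasons`
#'   (subset of NO_SITE, NO_REVERSE_SITE, TOO_MANY_MISMATCHES,
#'   TERMINAL_3PRIME_MISMATCH), `amplicon` `(start, end)` 0-based half-open,
#'   `length_bp`, and the per-primer weighted scores.
#' @export
predict_amplification <- function(fwd_hit, rev_hit,
                                  thresholds = default_thresholds()) {
  reasons <- character(0)
  if (is.null(fwd_hit)) reasons <- c(reasons, "NO_SITE")
  if (is.null(rev_hit)) reasons <- c(reasons, "NO_REVERSE_SITE")
  fwd_score <- rev_score <- NA_integer_
  if (!length(reasons)) {
    if (rev_hit$template_pos < fwd_hit$template_pos + fwd_hit$core_length) {
      stop("reverse footprint is not 3' of the forward footprint", call. = FALSE)
    }
    for (side in c("fwd", "rev")) {
      hit <- if (side == "fwd") fwd_hit else rev_hit
      score <- .weighted_score(hit, thresholds$three_prime_window_nt)
      if (side == "fwd") fwd_score <- score else rev_score <- score
      if (hit$terminal_mismatch) reasons <- c(reasons, "TERMINAL_3PRIME_MISMATCH")
      if (score > thresholds$mismatch_fail_count) reasons <- c(reasons, "TOO_MANY_MISMATCHES")
    }
    reasons <- unique(reasons)
  }
  success <- !length(reasons)
  amplicon <- NULL; length_bp <- NA_integer_
  if (!is.null(fwd_hit) && !is.null(rev_hit)) {
    amplicon <- c(start = fwd_hit$template_pos,
                  end = rev_hit$template_pos + rev_hit$core_length)
    length_bp <- unname(amplicon[2] - amplicon[1])
  }
  structure(list(success = success, reasons = reasons,
                 amplicon = amplicon,
                 length_bp = length_bp,
                 fwd_score = fwd_score, rev_score = rev_score),
            class = "amplicon_prediction")
}

#' @export
print.amplicon_prediction <- function(x, ...) {
  if (x$success) {
    cat(sprintf("<amplicon_prediction> success, %d bp [%d, %d)\n",
                x$length_bp, x$amplicon[1], x$amplicon[2]))
  } else {
    cat(sprintf("<amplicon_prediction> FAIL: %s\n", paste(x$reasons, collapse = ", ")))
  }
  invisible(x)
}

#' Predict amplification of a template by a primer pair
#'
#' Convenience wrapper: scans the forward primer on `+` and the reverse
#' primer on `-`, picks each primer's best site (fewest mismatches, then
#' leftmost/rightmost respectively), and calls [predict_amplification()].
#'
#' @param fwd,rev [primer_spec()] objects.
#' @param template template DNA.
#' @param thresholds see [default_thresholds()].
#' @param max_mismatch site-reporting cutoff for the scans.
#' @return an `amplicon_prediction`.
#' @export
predict_pair <- function(fwd, rev, template, thresholds = default_thresholds(),
                         max_mismatch = 6) {
  fh <- scan_primer(fwd, template, "+", max_mismatch)
  rh <- scan_primer(rev, template, "-", max_mismatch)
  pick <- function(hits, rightmost = FALSE) {
    if (!length(hits)) return(NULL)
    mm <- vapply(hits, `[[`, 0L, "mismatch_count")
    best <- hits[mm == min(mm)]
    best[[if (rightmost) length(best) else 1L]]
  }
  fwd_hit <- pick(fh, rightmost = FALSE)
  rev_hit <- pick(rh, rightmost = TRUE)
  if (!is.null(fwd_hit) && !is.null(rev_hit) &&
      rev_hit$template_pos < fwd_hit$template_pos + fwd_hit$core_length) {
    return(predict_amplification(fwd_hit, NULL, thresholds))
  }
  predict_amplification(fwd_hit, rev_hit, thresholds)
}

#' Tabulate primer-template substitutions at the binding site
#'
#' For each template the single best footprint (fewest mismatches) is taken;
#' a tie between footprints is an error because the binding site would be
#' ambiguous. One row is emitted per mismatch.
#'
#' @param primer a [primer_spec()].
#' @param templates named character vector of templates.
#' @param strand strand to scan.
#' @return data.frame (template_id, position = 1-based primer coordinate,
#'   primer_code, template_base, in_3prime_window).
#' @export
profile_binding_site <- function(primer, templates, strand = "+",
                                 thresholds = default_thresholds()) {
  core <- if (inherits(primer, "primer_spec")) primer$core else primer
  k <- nchar(core)
  ids <- names(templates)
  if (is.null(ids)) ids <- paste0("template", seq_along(templates))
  out <- list()
  for (i in seq_along(templates)) {
    hits <- scan_primer(primer, templates[[i]], strand, max_mismatch = k)
    mm <- vapply(hits, `[[`, 0L, "mismatch_count")
    best <- which(mm == min(mm))
    if (length(best) > 1L) {
      pos <- vapply(hits[best], `[[`, 0L, "template_pos")
      stop(sprintf("template '%s': ambiguous best footprint at positions %s",
                   ids[i], paste(pos, collapse = ", ")), call. = FALSE)
    }
    hit <- hits[[best]]
    tpl <- if (strand == "-") revcomp(toupper(templates[[i]])) else toupper(templates[[i]])
    p_in_scan <- if (strand == "-") nchar(tpl) - (hit$template_pos + k) else hit$template_pos
    win <- substr(tpl, p_in_scan + 1, p_in_scan + k)
    for (j in which(hit$per_pos_mismatch)) {
      out[[length(out) + 1L]] <- data.frame(
        template_id = ids[i], position = j,
        primer_code = substr(core, j, j),
        template_base = substr(win, j, j),
        in_3prime_window = (k - j) < thresholds$three_prime_window_nt,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(template_id = character(0), position = integer(0),
                      primer_code = character(0), template_base = character(0),
                      in_3prime_window = logical(0)))
  }
  do.call(rbind, out)
}
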