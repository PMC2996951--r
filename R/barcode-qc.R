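# Post-amplification barcode QC: upstream-tRNA trimming, initiation-codon
# calling (canonical and non-canonical under the upstream-stop context rule),
# invertebrate-mitochondrial translation, NUMT screening, and amino-acid
# indel detection against a reference profile.

.canonical_initiators <- c("ATA", "ATT", "ATC", "ATG", "TTG", "GTG")
.stop_codons5 <- c("TAA", "TAG")

# genetic code table 5 (invertebrate mitochondrial): AGA/AGG = Ser,
# TGA = Trp, ATA = Met
.code5 <- local({
  gc <- Biostrings::getGeneticCode("5")
  names(gc) <- toupper(names(gc))
  gc
})

#' Translate DNA under the invertebrate mitochondrial code
#'
#' NCBI genetic code table 5: AGA/AGG encode Ser, TGA encodes Trp, ATA
#' encodes Met; TAA/TAG are the stops, rendered `*`. A trailing partial codon
#' is dropped. Degenerate codons translate to their unique product when all
#' expansions agree, else `X`.
#'
#' @param dna DNA string (IUPAC alphabet).
#' @param frame 0, 1 or 2: offset of the first codon.
#' @return amino-acid string.
#' @export
translate_mito <- function(dna, frame = 0) {
  dna <- .assert_iupac(toupper(dna))
  s <- substr(dna, frame + 1, nchar(dna))
  n_codon <- nchar(s) %/% 3
  if (n_codon == 0) return("")
  starts <- seq(1, by = 3, length.out = n_codon)
  codons <- substring(s, starts, starts + 2)
  aa <- .code5[codons]
  amb <- which(is.na(aa))
  for (i in amb) {
    prods <- unique(.code5[expand_iupac(codons[i])])
    aa[i] <- if (length(prods) == 1L) prods else "X"
  }
  paste(aa, collapse = "")
}

#' Call the translation initiation codon
#'
#' Classification of the first codon of `sequence`, in priority order:
#' canonical starts ATA/ATT/ATC/ATG (`"ATN"`), `"TTG"`, `"GTG"`; then the
#' non-canonical TCG (including CCG, class `"TCG_type"`) and CGA
#' (`"CGA_type"`), which are accepted only when the in-frame codon
#' immediately 5' (taken from `upstream`, the untrimmed context) is a TAA or
#' TAG stop and no canonical initiator occurs in frame within
#' `initiator_scan_window_bp` downstream of that stop (the window is counted
#' from the first base after the stop). Anything else is `"uncertain"`.
#'
#' Quadruplet starts (ATAA/TTAA/TTAG/ATTA) are reported in the `quadruplet`
#' attribute for annotation only; they are never returned as the call.
#'
#' @param sequence DNA beginning at the candidate codon.
#' @param upstream untrimmed context immediately 5' of `sequence` (may be
#'   empty).
#' @param thresholds see [default_thresholds()].
#' @return one of `"ATN"`, `"TTG"`, `"GTG"`, `"TCG_type"`, `"CGA_type"`,
#'   `"uncertain"`.
#' @export
call_initiation_codon <- function(sequence, upstream = "",
                                  thresholds = default_thresholds()) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 3) stop("sequence shorter than one codon", call. = FALSE)
  first <- substr(sequence, 1, 3)
  quad <- substr(sequence, 1, 4)
  call <- if (first %in% c("ATA", "ATT", "ATC", "ATG")) "ATN"
  else if (first == "TTG") "TTG"
  else if (first == "GTG") "GTG"
  else if (first %in% c("TCG", "CCG", "CGA")) {
    upstream <- toupper(upstream)
    prev <- if (nchar(upstream) >= 3)
      substr(upstream, nchar(upstream) - 2, nchar(upstream)) else ""
    if (!prev %in% .stop_codons5) {
      "uncertain"
    } else {
      # scan the window downstream of the stop for a canonical initiator
      w <- thresholds$initiator_scan_window_bp
      window <- substr(sequence, 1, min(w, nchar(sequence)))
      starts <- seq(1, by = 3, length.out = nchar(window) %/% 3)
      codons <- substring(window, starts, starts + 2)
      if (any(codons %in% .canonical_initiators)) "uncertain"
      else if (first == "CGA") "CGA_type" else "TCG_type"
    }
  } else "uncertain"
  attr(call, "quadruplet") <- if (quad %in% c("ATAA", "TTAA", "TTAG", "ATTA")) quad else NA_character_
  call
}

# positions (0-based) of in-frame stop codons for each frame of an A/C/G/T
# read; returns list of integer vectors indexed by frame 0..2
.stop_positions <- function(read) {
  L <- nchar(read)
  out <- vector("list", 3)
  for (f in 0:2) {
    n_codon <- (L - f) %/% 3
    if (n_codon <= 0) { out[[f + 1]] <- integer(0); next }
    starts <- seq(f + 1, by = 3, length.out = n_codon)
    codons <- substring(read, starts, starts + 2)
    out[[f + 1]] <- starts[codons %in% .stop_codons5] - 1L
  }
  out
}

#' Trim upstream tRNA sequence off a barcode read
#'
#' Reads begin with 70-200 bp of tRNA-derived sequence that must be excised
#' before the COI segment. Trimming is ORF-anchored: every codon-start
#' position within the search limit (upper trim band + 30 bp) whose codon is
#' an acceptable initiator (canonical, or non-canonical passing the
#' upstream-stop context rule of [call_initiation_codon()]) and whose
#' downstream reading frame is stop-free for at least `min_orf_nt` is a
#' candidate; the candidate with the longest stop-free downstream run wins,
#' where runs are compared after capping at `barcode_min_len_bp` (an open
#' frame covering the full barcode length is maximal evidence; nucleotides
#' beyond it add none, and would otherwise let reading frames censored by
#' the read end outscore a complete ORF by a hair). Ties resolve 5'-most,
#' so the true start dominates later in-frame starts.
#'
#' @param read untrimmed read (A/C/G/T).
#' @param thresholds see [default_thresholds()].
#' @param min_orf_nt minimum stop-free open reading frame downstream of an
#'   acceptable start.
#' @return list with `coi_start` (0-based offset of the initiation codon),
#'   `trimmed` (read from the initiation codon on) and `initiation_call`.
#' @export
trim_upstream <- function(read, thresholds = default_thresholds(),
                          min_orf_nt = 150) {
  read <- toupper(read)
  if (nchar(read) < 300) stop("read shorter than 300 nt", call. = FALSE)
  L <- nchar(read)
  stops <- .stop_positions(read)
  limit <- min(thresholds$trim_band_bp[2] + 30L, L - min_orf_nt)
  cap <- max(min_orf_nt, thresholds$barcode_min_len_bp)
  run_len <- function(p) {
    f <- p %% 3
    nxt <- stops[[f + 1]]
    nxt <- nxt[nxt >= p]
    min((if (length(nxt)) min(nxt) else L) - p, cap)
  }
  best_p <- -1L; best_run <- -1L
  for (p in 0:limit) {
    codon <- substr(read, p + 1, p + 3)
    ok <- codon %in% .canonical_initiators
    if (!ok && codon %in% c("TCG", "CCG", "CGA")) {
      cl <- call_initiation_codon(substr(read, p + 1, L),
                                  upstream = substr(read, 1, p), thresholds)
      ok <- cl %in% c("TCG_type", "CGA_type")
    }
    if (!ok) next
    r <- run_len(p)
    if (r >= min_orf_nt && r > best_run) {
      best_run <- r; best_p <- p
    }
  }
  if (best_p < 0L) {
    stop("UNTRIMMABLE: no acceptable initiation codon opens a stop-free frame of >= ",
         min_orf_nt, " nt", call. = FALSE)
  }
  trimmed <- substr(read, best_p + 1, L)
  list(coi_start = best_p, trimmed = trimmed,
       initiation_call = call_initiation_codon(trimmed,
                                               upstream = substr(read, 1, best_p),
                                               thresholds))
}

#' Screen a trimmed barcode sequence for NUMT signatures
#'
#' Nuclear copies of mitochondrial genes betray themselves through internal
#' stop codons and frame-shifting indels. Flags: `INTERNAL_STOP` when `*`
#' occurs before the final codon of the frame-0 translation; `FRAMESHIFT`
#' when the global nucleotide alignment against `reference_cds` (when given)
#' requires a gap whose length is not a multiple of 3; `SHORT` when the
#' trimmed length is below `barcode_min_len_bp`.
#'
#' @param trimmed trimmed DNA starting at the initiation codon.
#' @param reference_cds optional reference coding sequence for frameshift
#'   detection.
#' @param thresholds see [default_thresholds()].
#' @return character vector of flags (possibly empty).
#' @export
numt_screen <- function(trimmed, reference_cds = NULL,
                        thresholds = default_thresholds()) {
  flags <- character(0)
  protein <- translate_mito(trimmed)
  body <- substr(protein, 1, nchar(protein) - 1L)
  if (grepl("\\*", body)) flags <- c(flags, "INTERNAL_STOP")
  if (!is.null(reference_cds)) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(trimmed), Biostrings::DNAString(reference_cds),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE),
      gapOpening = 5, gapExtension = 2)
    widths <- c(
      BiocGenerics::width(Biostrings::indel(Biostrings::pattern(al))[[1]]),
      BiocGenerics::width(Biostrings::indel(Biostrings::subject(al))[[1]]))
    if (any(widths %% 3 != 0)) flags <- c(flags, "FRAMESHIFT")
  }
  if (nchar(trimmed) < thresholds$barcode_min_len_bp) flags <- c(flags, "SHORT")
  flags
}

# global protein alignment: match +1, mismatch -1, gap -2 (linear), with free
# trailing gaps so a shorter 3' tail is not penalized; deterministic
# traceback diagonal > up > left
.protein_align <- function(query, reference) {
  qv <- strsplit(query, "")[[1]]; rv <- strsplit(reference, "")[[1]]
  n <- length(qv); m <- length(rv)
  S <- matrix(0L, n + 1L, m + 1L)
  S[, 1] <- -2L * (0:n); S[1, ] <- -2L * (0:m)
  for (i in seq_len(n)) {
    diag_ <- S[i, 1:m] + ifelse(qv[i] == rv, 1L, -1L)
    up <- S[i, 2:(m + 1)] - 2L
    row <- integer(m)
    left <- S[i + 1L, 1L]
    for (j in seq_len(m)) {
      v <- max(diag_[j], up[j], left - 2L)
      row[j] <- v
      left <- v
    }
    S[i + 1L, 2:(m + 1)] <- row
  }
  # free end gaps: best cell on the last row or last column
  last_col <- S[, m + 1L]; last_row <- S[n + 1L, ]
  if (max(last_col) >= max(last_row)) {
    i <- which.max(last_col) - 1L; j <- m
  } else {
    i <- n; j <- which.max(last_row) - 1L
  }
  qa <- character(0); ra <- character(0)
  if (i < n) { qa <- qv[(i + 1):n]; ra <- rep("-", n - i) }       # free query tail
  if (j < m) { qa <- rep("-", m - j); ra <- rv[(j + 1):m] }       # free reference tail
  end_i <- i; end_j <- j
  # sticky-gap traceback: on score ties, extending the current gap run is
  # preferred over re-opening, so equal-score indels stay contiguous
  prev <- "d"
  while (i > 0 || j > 0) {
    can_d <- i > 0 && j > 0 &&
      S[i + 1, j + 1] == S[i, j] + (if (qv[i] == rv[j]) 1L else -1L)
    can_u <- i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 2L
    can_l <- j > 0 && S[i + 1, j + 1] == S[i + 1, j] - 2L
    order <- switch(prev, u = c("u", "d", "l"), l = c("l", "d", "u"),
                    c("d", "u", "l"))
    ok <- c(d = can_d, u = can_u, l = can_l)
    mv <- order[ok[order]][1]
    if (mv == "d") {
      qa <- c(qv[i], qa); ra <- c(rv[j], ra); i <- i - 1; j <- j - 1
    } else if (mv == "u") {
      qa <- c(qv[i], qa); ra <- c("-", ra); i <- i - 1
    } else {
      qa <- c("-", qa); ra <- c(rv[j], ra); j <- j - 1
    }
    prev <- mv
  }
  list(query = qa, reference = ra, end_i = end_i, end_j = end_j)
}

#' Detect amino-acid indels against a reference profile
#'
#' Globally aligns the query protein to a same-gene reference (match +1,
#' mismatch -1, gap -2, trailing gaps on the shorter 3' tail free) and
#' reports contiguous gap runs: gaps in the query are deletions, gaps in the
#' reference are insertions. Positions are reference residue coordinates
#' counted from the initiation codon (1-based). Runs touching the free
#' alignment tail are not events.
#'
#' @param query_protein query amino-acid string (>= 50 residues).
#' @param reference_protein reference profile (>= 50 residues).
#' @return data.frame (aa_position, length_aa, kind) with kind in
#'   `"deletion"`/`"insertion"`; zero rows when the proteins are colinear.
#' @export
detect_indels <- function(query_protein, reference_protein) {
  query_protein <- sub("\\*+$", "", toupper(query_protein))
  reference_protein <- sub("\\*+$", "", toupper(reference_protein))
  if (nchar(query_protein) < 50 || nchar(reference_protein) < 50) {
    stop("both proteins must be at least 50 residues", call. = FALSE)
  }
  al <- .protein_align(query_protein, reference_protein)
  qa <- al$query; ra <- al$reference
  aligned <- qa != "-" & ra != "-"
  ident <- sum(qa[aligned] == ra[aligned]) / max(1L, sum(aligned))
  if (ident < 0.5) {
    stop(sprintf("alignment identity %.2f below 0.5: wrong gene or frame", ident),
         call. = FALSE)
  }
  events <- list()
  L <- length(qa)
  ref_pos <- cumsum(ra != "-")  # reference coordinate at each column
  runs <- rle(ifelse(qa == "-", "del", ifelse(ra == "-", "ins", "m")))
  col <- cumsum(runs$lengths) - runs$lengths + 1L  # run start columns
  for (k in seq_along(runs$values)) {
    kind <- runs$values[k]
    if (kind == "m") next
    start_col <- col[k]; len <- runs$lengths[k]
    if (start_col + len - 1L == L || start_col == 1L) next  # end gaps: not events
    pos <- if (kind == "del") ref_pos[start_col]  # first deleted ref residue
    else ref_pos[start_col] + 1L                  # insertion after this ref residue
    events[[length(events) + 1L]] <- data.frame(
      aa_position = as.integer(pos), length_aa = as.integer(len),
      kind = if (kind == "del") "deletion" else "insertion",
      stringsAsFactors = FALSE)
  }
  if (!length(events)) {
    return(data.frame(aa_position = integer(0), length_aa = integer(0),
                      kind = character(0)))
  }
  do.call(rbind, events)
}

#' Full QC of one barcode read
#'
#' Runs the QC chain: trim, call the initiation codon, translate, screen for
#' NUMT signatures, and (when a reference is supplied) detect indels.
#'
#' @param read untrimmed read.
#' @param thresholds see [default_thresholds()].
#' @param reference_protein optional reference for indel detection (defaults
#'   to [reference_protein()] when `use_default_reference`).
#' @param reference_cds optional reference coding DNA for frameshift
#'   screening.
#' @return object of class `barcode_read`: raw, coi_start, initiation_call,
#'   trimmed, protein, flags, barcode_compliant, indels.
#' @export
qc_read <- function(read, thresholds = default_thresholds(),
                    reference_protein = NULL, reference_cds = NULL) {
  tr <- trim_upstream(read, thresholds)
  protein <- translate_mito(tr$trimmed)
  flags <- numt_screen(tr$trimmed, reference_cds, thresholds)
  indels <- NULL
  if (!is.null(reference_protein) && !("FRAMESHIFT" %in% flags)) {
    body <- sub("\\*.*$", "", protein)
    if (nchar(body) >= 50) indels <- detect_indels(body, reference_protein)
  }
  compliant <- nchar(tr$trimmed) >= thresholds$barcode_min_len_bp &&
    !length(setdiff(flags, "SHORT"))
  structure(list(raw = toupper(read), coi_start = tr$coi_start,
                 initiation_call = as.character(tr$initiation_call),
                 trimmed = tr$trimmed, protein = protein, flags = flags,
                 barcode_compliant = compliant, indels = indels),
            class = "barcode_read")
}

#' @export
print.barcode_read <- function(x, ...) {
  cat(sprintf("<barcode_read> coi_start %d, initiator %s, %d nt trimmed, flags: %s%s\n",
              x$coi_start, x$initiation_call, nchar(x$trimmed),
              if (length(x$flags)) paste(x$flags, collapse = ",") else "none",
              if (isTRUE(x$barcode_compliant)) " [barcode-compliant]" else ""))
  invisible(x)
}
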