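# Pairwise and center-star multiple alignment for short anchor tRNA genes.
#
# Center-star is adequate here: inputs are 20-100 nt, near-equal-length, and
# share a conserved core, so the star around the sequence with minimal summed
# edit distance approximates the optimal MSA well. Externally aligned FASTA
# is accepted anywhere an aligned block is, as an escape hatch.

# Global pairwise alignment, similarity-maximizing (match +1, mismatch -1,
# gap -3 by default: gaps cost clearly more than mismatches, so equal-length
# near-identical sequences align gap-free and gap placement is
# anchored by conserved blocks rather than drifting with point mutations).
# Deterministic traceback: ties resolved diagonal > up (gap in b) > left.
nw_align <- function(a, b, match = 1L, mismatch = -1L, gap = -3L) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0L, n + 1L, m + 1L)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    diag_ <- S[i, 1:m] + ifelse(av[i] == bv, match, mismatch)
    up <- S[i, 2:(m + 1)] + gap
    row <- integer(m)
    left <- S[i + 1L, 1L]
    for (j in seq_len(m)) {
      v <- max(diag_[j], up[j], left + gap)
      row[j] <- v
      left <- v
    }
    S[i + 1L, 2:(m + 1)] <- row
  }
  ga <- character(0); gb <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      ga <- c(av[i], ga); gb <- c(bv[j], gb); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ga <- c(av[i], ga); gb <- c("-", gb); i <- i - 1
    } else {
      ga <- c("-", ga); gb <- c(bv[j], gb); j <- j - 1
    }
  }
  list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""),
       score = S[n + 1, m + 1])
}

#' Construct an aligned block
#'
#' @param rows equal-length gapped sequences over A/C/G/T/N/-.
#' @param ids row identifiers (defaults to names of `rows`).
#' @return object of class `aligned_block`.
#' @export
aligned_block <- function(rows, ids = names(rows)) {
  rows <- toupper(unname(unlist(rows)))
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  if (length(unique(nchar(rows))) != 1L) {
    stop("all rows of an aligned block must have equal length", call. = FALSE)
  }
  structure(list(ids = as.character(ids), rows = rows), class = "aligned_block")
}

#' @export
print.aligned_block <- function(x, ...) {
  cat(sprintf("<aligned_block> %d rows x %d columns\n",
              length(x$rows), nchar(x$rows[1])))
  invisible(x)
}

#' Center-star multiple sequence alignment
#'
#' The center is the sequence minimizing its summed pairwise edit distance to
#' all others (ties: first in input order). Every other sequence is globally
#' aligned to the center and the pairwise alignments are merged under the
#' "once a gap, always a gap" rule, so the final column count is at least the
#' longest input length.
#'
#' @param sequences character vector (2-500 sequences, each 20-100 nt
#'   recommended); names become row ids.
#' @return an [aligned_block()] with rows in input order.
#' @export
center_star_msa <- function(sequences) {
  sequences <- toupper(unlist(sequences))
  if (length(sequences) < 2L) stop("need at least 2 sequences to align", call. = FALSE)
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  n <- length(sequences)
  # summed edit distance per sequence; utils::adist is the Levenshtein metric
  dm <- utils::adist(sequences)
  center <- which.min(rowSums(dm))

  master <- strsplit(sequences[center], "")[[1]]  # center with accumulated gaps
  rows <- vector("list", n)
  done <- logical(n)

  insert_gap_cols <- function(v, at) {
    # insert "-" at positions `at` expressed in FINAL (post-insertion)
    # coordinates, strictly increasing: ascending insertion keeps earlier
    # positions consistent
    for (k in seq_along(at)) {
      v <- append(v, "-", after = at[k] - 1L)
    }
    v
  }

  for (i in seq_len(n)) {
    if (i == center) next
    pa <- nw_align(sequences[center], sequences[i])
    cg <- strsplit(pa$a, "")[[1]]  # center, gapped for this pair
    sg <- strsplit(pa$b, "")[[1]]
    # merge cg's gap pattern with the master gap pattern
    j <- 1L; k <- 1L
    out_master <- character(0); out_rows_gap_at <- integer(0)
    out_sg <- character(0)
    Lm <- length(master); Lc <- length(cg)
    col <- 0L
    while (j <= Lm || k <= Lc) {
      col <- col + 1L
      if (j <= Lm && master[j] == "-" && (k > Lc || cg[k] != "-")) {
        # master-only gap column: existing rows keep their symbol, new row gets '-'
        out_master <- c(out_master, "-")
        out_sg <- c(out_sg, "-")
        j <- j + 1L
      } else if (k <= Lc && cg[k] == "-" && (j > Lm || master[j] != "-")) {
        # new gap column: insert into master and all previously aligned rows
        out_master <- c(out_master, "-")
        out_sg <- c(out_sg, sg[k])
        out_rows_gap_at <- c(out_rows_gap_at, col)
        k <- k + 1L
      } else if (j <= Lm && k <= Lc && master[j] == "-" && cg[k] == "-") {
        # both alignments insert relative to the center here: the column is
        # shared, and the new row contributes its inserted character
        out_master <- c(out_master, "-")
        out_sg <- c(out_sg, sg[k])
        j <- j + 1L; k <- k + 1L
      } else {
        out_master <- c(out_master, master[j])
        out_sg <- c(out_sg, sg[k])
        j <- j + 1L; k <- k + 1L
      }
    }
    if (length(out_rows_gap_at)) {
      for (r in which(done)) {
        rows[[r]] <- insert_gap_cols(rows[[r]], out_rows_gap_at)
      }
    }
    master <- out_master
    rows[[i]] <- out_sg
    done[i] <- TRUE
  }
  rows[[center]] <- master
  aligned_block(vapply(rows, paste, "", collapse = ""), ids)
}
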