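# Homogeneity grouping of aligned anchor genes and IUPAC consensus derivation.

.block_window <- function(block, window) {
  L <- nchar(block$rows[1])
  if (is.null(window)) {
    # default: the central 19 columns (or everything for short blocks)
    w <- min(19L, L)
    start <- (L - w) %/% 2L + 1L
    window <- c(start, start + w - 1L)
  }
  window <- as.integer(window)
  if (length(window) != 2L || window[1] < 1L || window[2] > L || window[1] > window[2]) {
    stop(sprintf("window [%d, %d] outside block columns 1..%d",
                 window[1], window[2], L), call. = FALSE)
  }
  window
}

# pairwise identity over a column window. The gap-stripped window segments
# are re-aligned pairwise and identity is matches over aligned (mutually
# ungapped) positions: grouping is then insensitive to gap-placement noise
# in the multiple alignment, which matters when the window spans the very
# segment that separates the groups. Identical segments short-circuit.
.pairwise_identity <- function(rows_mat, window) {
  sub <- rows_mat[, window[1]:window[2], drop = FALSE]
  n <- nrow(sub)
  segs <- vapply(seq_len(n), function(i) {
    paste(sub[i, sub[i, ] != "-"], collapse = "")
  }, "")
  id <- matrix(1, n, n)
  if (n < 2) return(id)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- segs[i]; b <- segs[j]
    id[i, j] <- id[j, i] <- if (!nchar(a) || !nchar(b)) {
      0
    } else if (a == b) {
      1
    } else {
      al <- nw_align(a, b)
      av <- strsplit(al$a, "")[[1]]; bv <- strsplit(al$b, "")[[1]]
      aligned <- av != "-" & bv != "-"
      if (any(aligned)) sum(av[aligned] == bv[aligned]) / sum(aligned) else 0
    }
  }
  id
}

#' Derive an IUPAC degenerate consensus from aligned rows
#'
#' Per column, base frequencies are computed over non-gap symbols (an `N`
#' contributes weight 1/4 to each base); the consensus code is the unique
#' IUPAC letter for the set of observed bases with frequency at least
#' `min_freq`. With `min_freq = 0` every observed base enters, so the
#' consensus over the full expansion of an IUPAC string returns that string.
#'
#' @param rows character vector of equal-length (gapped) sequences, or an
#'   [aligned_block()].
#' @param window `(first, last)` columns, 1-based inclusive; `NULL` = all
#'   columns.
#' @param min_freq minimum base frequency for inclusion, in `[0, 1)`. Bases
#'   seen in fewer than this fraction of members are treated as noise.
#' @return object of class `degenerate_consensus`: list with `iupac`, `freq`
#'   (4 x L base-frequency matrix) and `window`.
#' @export
degenerate_consensus <- function(rows, window = NULL, min_freq = 0.05) {
  if (inherits(rows, "aligned_block")) rows <- rows$rows
  rows <- toupper(rows)
  if (!length(rows)) stop("need at least one row", call. = FALSE)
  if (min_freq < 0 || min_freq >= 1) stop("min_freq must be in [0, 1)", call. = FALSE)
  L0 <- unique(nchar(rows))
  if (length(L0) != 1L) stop("rows must have equal length", call. = FALSE)
  if (is.null(window)) window <- c(1L, L0)
  mat <- do.call(rbind, strsplit(rows, ""))
  window <- as.integer(window)
  if (window[1] < 1L || window[2] > L0 || window[1] > window[2]) {
    stop("window outside row columns", call. = FALSE)
  }
  cols <- window[1]:window[2]
  bases <- c("A", "C", "G", "T")
  freq <- matrix(0, 4, length(cols), dimnames = list(bases, NULL))
  code <- character(length(cols))
  for (k in seq_along(cols)) {
    col <- mat[, cols[k]]
    col <- col[col != "-"]
    if (!length(col)) {
      stop(sprintf("column %d is all gaps", cols[k]), call. = FALSE)
    }
    w <- c(A = 0, C = 0, G = 0, T = 0)
    for (ch in col) {
      if (ch == "N") {
        w <- w + 0.25
      } else if (ch %in% bases) {
        w[ch] <- w[ch] + 1
      } else if (ch %in% .iupac_codes) {
        s <- .iupac_sets[[ch]]
        w[s] <- w[s] + 1 / length(s)
      } else {
        stop(sprintf("disallowed symbol '%s' in column %d", ch, cols[k]), call. = FALSE)
      }
    }
    f <- w / sum(w)
    keep <- names(f)[f > 0 & f >= min_freq]
    if (!length(keep)) {
      stop(sprintf("min_freq %.2f excludes every base at column %d", min_freq, cols[k]),
           call. = FALSE)
    }
    code[k] <- iupac_code(keep)
    freq[, k] <- f
  }
  structure(list(iupac = paste(code, collapse = ""), freq = freq, window = window),
            class = "degenerate_consensus")
}

#' @export
print.degenerate_consensus <- function(x, ...) {
  cat(sprintf("<degenerate_consensus> %s (degeneracy %d)\n",
              x$iupac, iupac_degeneracy(x$iupac)))
  invisible(x)
}

#' Partition aligned sequences into homogeneity groups
#'
#' Complete-linkage agglomerative clustering on pairwise identity over a
#' column window: the pair of clusters whose minimum cross-pair identity is
#' highest is merged first (ties broken by the lexicographically smallest
#' member id), and merging stops when no merge keeps every within-cluster
#' pairwise identity at or above `identity_threshold`. The result is a
#' partition: every row lands in exactly one group, independent of input
#' order.
#'
#' @param block an [aligned_block()].
#' @param window `(first, last)` columns of the homogeneity segment; default
#'   the central 19 columns.
#' @param identity_threshold minimum within-group pairwise identity.
#' @param min_freq passed to [degenerate_consensus()] for each group.
#' @return list of class `homogeneity_groups`; each element has `member_ids`,
#'   `central_window` and `consensus`. Groups are ordered by decreasing size,
#'   then smallest member id.
#' @export
partition_groups <- function(block, window = NULL, identity_threshold = 0.75,
                             min_freq = 0.05) {
  stopifnot(inherits(block, "aligned_block"))
  window <- .block_window(block, window)
  n <- length(block$rows)
  mat <- do.call(rbind, strsplit(block$rows, ""))
  id <- .pairwise_identity(mat, window)

  # order-independent: process rows by id rank
  rank_order <- order(block$ids)
  clusters <- as.list(rank_order)
  # cluster-level complete linkage = min pairwise identity between members
  link <- id[rank_order, rank_order, drop = FALSE]
  diag(link) <- -Inf
  while (length(clusters) > 1L) {
    best <- which(link == max(link), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    if (!nrow(best) || max(link) < identity_threshold) break
    # deterministic tie-break: smallest member id of the pair
    key <- apply(best, 1, function(rc) {
      min(block$ids[c(clusters[[rc[1]]], clusters[[rc[2]]])])
    })
    pick <- best[order(key, best[, 1], best[, 2])[1], ]
    i <- pick[1]; j <- pick[2]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    newrow <- pmin(link[i, ], link[j, ])
    link[i, ] <- newrow; link[, i] <- newrow
    link[i, i] <- -Inf
    clusters[[j]] <- NULL
    link <- link[-j, -j, drop = FALSE]
  }
  sizes <- vapply(clusters, length, 1L)
  first_id <- vapply(clusters, function(cl) min(block$ids[cl]), "")
  ord <- order(-sizes, first_id)
  groups <- lapply(clusters[ord], function(cl) {
    cl <- cl[order(block$ids[cl])]
    # columns that are gaps in every member carry no sequence for this
    # group (they belong to other groups' insertions): drop them before
    # deriving the group consensus
    sub <- mat[cl, window[1]:window[2], drop = FALSE]
    keep <- colSums(sub != "-") > 0L
    rows <- apply(sub[, keep, drop = FALSE], 1, paste, collapse = "")
    list(member_ids = block$ids[cl],
         central_window = window,
         consensus = degenerate_consensus(rows, min_freq = min_freq))
  })
  structure(groups, class = "homogeneity_groups")
}

#' @export
print.homogeneity_groups <- function(x, ...) {
  cat(sprintf("<homogeneity_groups> %d group(s)\n", length(x)))
  for (i in seq_along(x)) {
    cat(sprintf("  group %d: %d members, consensus %s\n",
                i, length(x[[i]]$member_ids), x[[i]]$consensus$iupac))
  }
  invisible(x)
}
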