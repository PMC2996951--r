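# IUPAC nucleotide code arithmetic used throughout: degenerate primers are
# treated as mixtures of their expansions, and primer-template compatibility
# is base-set intersection.

.iupac_sets <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(m, function(x) strsplit(x, "")[[1]])
})

.iupac_codes <- names(.iupac_sets)

# reverse map: sorted base-set string -> code
.iupac_rev <- local({
  key <- vapply(.iupac_sets, function(s) paste(sort(s), collapse = ""), "")
  stats::setNames(names(key), key)
})

.assert_iupac <- function(x, what = "sequence") {
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- which(!chars %in% .iupac_codes)
  if (length(bad)) {
    stop(sprintf("non-IUPAC character '%s' at position %d in %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  }
  invisible(paste(chars, collapse = ""))
}

#' Base set of an IUPAC nucleotide code
#'
#' @param code a single IUPAC nucleotide letter.
#' @return character vector of the unambiguous bases the code stands for.
#' @export
iupac_bases <- function(code) {
  code <- toupper(code)
  s <- .iupac_sets[[code]]
  if (is.null(s)) stop(sprintf("'%s' is not an IUPAC nucleotide code", code), call. = FALSE)
  s
}

#' IUPAC code for a set of bases
#'
#' @param bases character vector over A/C/G/T.
#' @return the unique IUPAC letter whose base set equals `bases`.
#' @export
iupac_code <- function(bases) {
  bases <- unique(toupper(bases))
  if (!length(bases) || !all(bases %in% c("A", "C", "G", "T"))) {
    stop("bases must be a non-empty subset of {A,C,G,T}", call. = FALSE)
  }
  unname(.iupac_rev[[paste(sort(bases), collapse = "")]])
}

#' Are two IUPAC codes compatible?
#'
#' Two codes are compatible when their base sets intersect, i.e. at least one
#' unambiguous base is represented by both. The relation is symmetric; `N`
#' is compatible with everything.
#'
#' @param a,b single IUPAC nucleotide letters.
#' @return logical scalar.
#' @export
iupac_compatible <- function(a, b) {
  length(intersect(iupac_bases(a), iupac_bases(b))) > 0L
}

# 15x15 compatibility lookup, computed once at load
.compat_matrix <- local({
  n <- length(.iupac_codes)
  m <- matrix(FALSE, n, n, dimnames = list(.iupac_codes, .iupac_codes))
  for (i in .iupac_codes) for (j in .iupac_codes) {
    m[i, j] <- length(intersect(.iupac_sets[[i]], .iupac_sets[[j]])) > 0L
  }
  m
})

#' Degeneracy of an IUPAC string
#'
#' Product over positions of the IUPAC base-set sizes: the number of distinct
#' unambiguous sequences the string represents.
#'
#' @param x IUPAC nucleotide string.
#' @return integer (may overflow to double for extreme strings).
#' @export
iupac_degeneracy <- function(x) {
  x <- .assert_iupac(x)
  chars <- strsplit(x, "")[[1]]
  prod(vapply(chars, function(c) length(.iupac_sets[[c]]), 1L))
}

#' Expand an IUPAC string into all unambiguous sequences
#'
#' @param x IUPAC nucleotide string.
#' @param max_degeneracy guard against combinatorial blow-up.
#' @return character vector of all expansions (lexicographic order).
#' @export
expand_iupac <- function(x, max_degeneracy = 65536) {
  x <- .assert_iupac(x)
  d <- iupac_degeneracy(x)
  if (d > max_degeneracy) {
    stop(sprintf("degeneracy %d exceeds max_degeneracy %d", d, max_degeneracy), call. = FALSE)
  }
  sets <- lapply(strsplit(x, "")[[1]], function(c) .iupac_sets[[c]])
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste, collapse = ""))
}

#' Reverse complement of an IUPAC string
#'
#' @param x IUPAC nucleotide string (gaps `-` preserved).
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  comp <- chartr("ACGTRYSWKMBDHVN-", "TGCAYRSWMKVHDBN-", x)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# random unambiguous DNA, used by the simulator
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# draw one expansion of an IUPAC string uniformly at random
sample_expansion <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  paste(vapply(chars, function(c) {
    s <- .iupac_sets[[c]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, ""), collapse = "")
}
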