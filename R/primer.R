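# Degenerate primer construction from IUPAC consensi.

#' Construct a primer specification
#'
#' @param name primer name.
#' @param core IUPAC core sequence (the part that matches the template).
#' @param tail optional 5' tail (e.g. the M13 sequencing tail); never matched
#'   against the template.
#' @param direction `"forward"` or `"reverse"`.
#' @return object of class `primer_spec` with fields `name`, `core`, `tail`,
#'   `direction`, `degeneracy` (product of per-position IUPAC set sizes over
#'   the full oligo) and `three_prime_base`.
#' @export
primer_spec <- function(name, core, tail = NULL, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  core <- .assert_iupac(core, "primer core")
  if (!is.null(tail)) tail <- .assert_iupac(tail, "primer tail")
  oligo <- paste0(if (is.null(tail)) "" else tail, core)
  structure(list(name = as.character(name), core = core, tail = tail,
                 direction = direction,
                 degeneracy = iupac_degeneracy(oligo),
                 three_prime_base = substr(core, nchar(core), nchar(core))),
            class = "primer_spec")
}

#' @export
print.primer_spec <- function(x, ...) {
  cat(sprintf("<primer_spec> %s (%s): 5'-%s%s-3' (degeneracy %d)\n",
              x$name, x$direction,
              if (is.null(x$tail)) "" else paste0("[", x$tail, "]"),
              x$core, x$degeneracy))
  invisible(x)
}

#' Design a primer from a degenerate consensus
#'
#' The core is the consensus window ending at the rightmost position whose
#' code is G, C or S when `prefer_3prime_GC` is set and such a position
#' exists (a 3'-terminal G/C enhances priming efficiency); otherwise it ends
#' at the consensus 3' end. A `resolution_map` may replace degenerate codes
#' by a single member base at chosen positions, for the cases where the
#' mixture is collapsed by design rather than by rule; each replacement is
#' validated against the code's base set. An optional unconditioned
#' `extend_3prime` string is appended after the core.
#'
#' @param consensus a [degenerate_consensus()] or IUPAC string.
#' @param name primer name.
#' @param core_length core length; default: from the consensus 5' end to the
#'   chosen 3' terminus.
#' @param resolution_map named character vector, names = 1-based positions in
#'   core coordinates, values = replacement bases.
#' @param tail optional 5' tail.
#' @param prefer_3prime_GC end the core at the rightmost G/C/S position when
#'   possible.
#' @param extend_3prime IUPAC string appended 3' of the core (default none).
#' @param direction primer direction.
#' @return a [primer_spec()].
#' @export
design_primer <- function(consensus, name = "primer", core_length = NULL,
                          resolution_map = NULL, tail = NULL,
                          prefer_3prime_GC = TRUE, extend_3prime = "",
                          direction = "forward") {
  s <- if (inherits(consensus, "degenerate_consensus")) consensus$iupac else
    .assert_iupac(consensus, "consensus")
  chars <- strsplit(s, "")[[1]]
  end <- length(chars)
  if (isTRUE(prefer_3prime_GC)) {
    gc <- which(chars %in% c("G", "C", "S"))
    if (length(gc)) end <- max(gc)
  }
  if (is.null(core_length)) core_length <- end
  core_length <- as.integer(core_length)
  if (core_length > end || core_length < 1L) {
    stop(sprintf("core_length %d does not fit the consensus (3' terminus at %d)",
                 core_length, end), call. = FALSE)
  }
  core <- chars[(end - core_length + 1L):end]
  if (!is.null(resolution_map)) {
    pos <- as.integer(names(resolution_map))
    if (anyNA(pos) || any(pos < 1L) || any(pos > length(core))) {
      stop("resolution_map positions must be 1-based core positions", call. = FALSE)
    }
    for (k in seq_along(pos)) {
      base <- toupper(resolution_map[[k]])
      allowed <- iupac_bases(core[pos[k]])
      if (!all(iupac_bases(base) %in% allowed)) {
        stop(sprintf("resolution '%s' at position %d is not within code '%s' = {%s}",
                     base, pos[k], core[pos[k]], paste(allowed, collapse = ",")),
             call. = FALSE)
      }
      core[pos[k]] <- base
    }
  }
  if (nchar(extend_3prime)) {
    extend_3prime <- .assert_iupac(extend_3prime, "extend_3prime")
    core <- c(core, strsplit(extend_3prime, "")[[1]])
  }
  primer_spec(name, paste(core, collapse = ""), tail = tail, direction = direction)
}

#' Derive a rescue primer from failing templates
#'
#' When templates escape an existing primer because their binding region has
#' diverged, a replacement is read off the observed diversity: the binding
#' window is cut from each template, the (gap-free) windowed block is
#' collapsed to a degenerate consensus, and that consensus becomes the new
#' forward primer.
#'
#' @param templates named character vector of template 5' sequences.
#' @param binding_window `(start, end)` 1-based inclusive window on the
#'   templates.
#' @param min_freq consensus inclusion threshold, see [degenerate_consensus()].
#' @param name primer name.
#' @return a [primer_spec()] with direction `"forward"`.
#' @export
derive_rescue_primer <- function(templates, binding_window, min_freq = 0.05,
                                 name = "rescue") {
  if (length(templates) < 2L) stop("need at least 2 templates", call. = FALSE)
  ids <- names(templates)
  if (is.null(ids)) ids <- paste0("template", seq_along(templates))
  binding_window <- as.integer(binding_window)
  short <- which(nchar(templates) < binding_window[2])
  if (length(short)) {
    stop(sprintf("binding window [%d, %d] not covered by: %s",
                 binding_window[1], binding_window[2],
                 paste(ids[short], collapse = ", ")), call. = FALSE)
  }
  rows <- substr(toupper(templates), binding_window[1], binding_window[2])
  cons <- degenerate_consensus(rows, min_freq = min_freq)
  primer_spec(name, cons$iupac, direction = "forward")
}

#' Melting-temperature range of a degenerate primer (Wallace rule)
#'
#' `Tm = 2(A+T) + 4(G+C)` evaluated over the minimum-GC and maximum-GC
#' expansions of the core; the tail is excluded. Intended as an operator
#' convenience, not a thermodynamic model.
#'
#' @param primer a [primer_spec()].
#' @return named numeric `c(min_tm, max_tm)` in degrees Celsius.
#' @export
primer_tm <- function(primer) {
  stopifnot(inherits(primer, "primer_spec"))
  chars <- strsplit(primer$core, "")[[1]]
  if (length(chars) < 10L) stop("core length must be >= 10 for a Tm estimate", call. = FALSE)
  can_at <- vapply(chars, function(c) any(iupac_bases(c) %in% c("A", "T")), TRUE)
  can_gc <- vapply(chars, function(c) any(iupac_bases(c) %in% c("G", "C")), TRUE)
  min_gc <- sum(!can_at)   # forced G/C positions
  max_gc <- sum(can_gc)
  L <- length(chars)
  c(min_tm = 2 * L + 2 * min_gc, max_tm = 2 * L + 2 * max_gc)
}
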