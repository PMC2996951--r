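# Signed gene-order analysis upstream of a target gene, and anchor selection.
#
# Arrangement notation: tokens 5'->3' toward the target, tRNA genes written as
# their single-letter amino-acid code (trnW -> W), a leading "-" marking
# reverse orientation relative to the target, e.g. "W,-C,-Y".

.short_token <- function(name) {
  ifelse(grepl("^trn", name), sub("^trn", "", name), name)
}

.long_token <- function(tok) {
  ifelse(nchar(tok) <= 2 & toupper(tok) == tok, paste0("trn", tok), tok)
}

#' Render an arrangement as its string notation
#'
#' @param tokens data.frame with columns `token`, `sign` (+1/-1).
#' @return single string, e.g. `"W,-C,-Y"`; empty arrangement renders as `""`.
#' @export
render_arrangement <- function(tokens) {
  if (!nrow(tokens)) return("")
  paste0(ifelse(tokens$sign < 0, "-", ""), tokens$token, collapse = ",")
}

#' Parse arrangement string notation
#'
#' Inverse of [render_arrangement()]: `parse_arrangement(render_arrangement(x))`
#' recovers `x`.
#'
#' @param x arrangement string such as `"W,-C,-Y"`.
#' @return data.frame with columns `token`, `sign`.
#' @export
parse_arrangement <- function(x) {
  if (is.na(x) || x == "") {
    return(data.frame(token = character(0), sign = integer(0)))
  }
  parts <- strsplit(x, ",")[[1]]
  data.frame(token = sub("^-", "", parts),
             sign = ifelse(grepl("^-", parts), -1L, 1L),
             stringsAsFactors = FALSE)
}

#' Extract the signed gene arrangement upstream of a target gene
#'
#' Scans the window immediately 5' of the target's start (after reorienting
#' the record if the target lies on the reverse strand, so orientation signs
#' are always relative to the target). A feature belongs to the arrangement
#' when its 3'-most base lies inside the window; partially overlapping
#' features are therefore included if their 3' end is. Tokens run distal to
#' proximal.
#'
#' @param genome a [mito_genome()].
#' @param target target gene token (default `"COI"`).
#' @param window_bp scan window upstream of the target start.
#' @return object of class `arrangement`: list with `string`, `tokens`
#'   (token, sign, distance_bp = gap from the feature's 3'-proximal edge to
#'   the target start) and `target_start`.
#' @export
extract_upstream_arrangement <- function(genome, target = "COI", window_bp = 200) {
  f <- genome$features
  hits <- which(f$name == target)
  if (!length(hits)) {
    stop(sprintf("genome '%s': target '%s' not found", genome$id, target), call. = FALSE)
  }
  if (length(hits) > 1) {
    where <- paste(sprintf("[%d,%d)", f$start[hits], f$end[hits]), collapse = " and ")
    stop(sprintf("genome '%s': target '%s' present %d times, at %s",
                 genome$id, target, length(hits), where), call. = FALSE)
  }
  if (f$strand[hits] < 0) {
    genome <- rc_genome(genome)
    f <- genome$features
    hits <- which(f$name == target)
  }
  tstart <- f$start[hits]
  others <- f[-hits, , drop = FALSE]
  # 3'-most base of each feature in genome coordinates
  three_prime <- ifelse(others$strand > 0, others$end - 1L, others$start)
  keep <- three_prime >= tstart - window_bp & three_prime < tstart
  sel <- others[keep, , drop = FALSE]
  sel <- sel[order(sel$start), , drop = FALSE]
  tokens <- data.frame(token = .short_token(sel$name),
                       sign = sel$strand,
                       distance_bp = tstart - sel$end,
                       stringsAsFactors = FALSE)
  structure(list(string = render_arrangement(tokens), tokens = tokens,
                 target_start = tstart),
            class = "arrangement")
}

#' @export
print.arrangement <- function(x, ...) {
  cat(sprintf("<arrangement> \"%s\" (target start %d)\n", x$string, x$target_start))
  invisible(x)
}

#' Tabulate upstream arrangements over a genome set
#'
#' @param genomes list of [mito_genome()] records.
#' @param target target gene token.
#' @param window_bp scan window.
#' @return object of class `arrangement_tab`: `$table` (arrangement, count,
#'   fraction; genomes lacking the target fall in a `"<no target>"` row),
#'   `$anchors` (per upstream gene: occurrence and forward-orientation counts,
#'   fractions over all genomes, and median 3'-gap distance), `$n_genomes`.
#' @export
tabulate_arrangements <- function(genomes, target = "COI", window_bp = 200) {
  if (!length(genomes)) stop("need at least one genome", call. = FALSE)
  strings <- character(length(genomes))
  per_gene <- list()
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    if (!any(g$features$name == target)) {
      strings[i] <- "<no target>"
      next
    }
    arr <- extract_upstream_arrangement(g, target, window_bp)
    strings[i] <- arr$string
    if (nrow(arr$tokens)) {
      per_gene[[length(per_gene) + 1L]] <- cbind(arr$tokens, genome = g$id)
    }
  }
  counts <- sort(table(strings), decreasing = TRUE)
  tab <- data.frame(arrangement = names(counts),
                    count = as.integer(counts),
                    fraction = as.numeric(counts) / length(genomes),
                    stringsAsFactors = FALSE)
  anchors <- data.frame(gene = character(0), n_present = integer(0),
                        n_forward = integer(0), frac_present = numeric(0),
                        frac_forward = numeric(0), median_distance = numeric(0))
  if (length(per_gene)) {
    occ <- do.call(rbind, per_gene)
    # one vote per genome per gene (a duplicated gene counts once)
    occ1 <- occ[!duplicated(occ[c("token", "genome")]), , drop = FALSE]
    sp <- split(occ1, occ1$token)
    anchors <- do.call(rbind, lapply(names(sp), function(tok) {
      d <- sp[[tok]]
      data.frame(gene = .long_token(tok),
                 n_present = nrow(d),
                 n_forward = sum(d$sign > 0),
                 frac_present = nrow(d) / length(genomes),
                 frac_forward = sum(d$sign > 0) / nrow(d),
                 median_distance = stats::median(d$distance_bp),
                 stringsAsFactors = FALSE)
    }))
    anchors <- anchors[order(-anchors$frac_present, -anchors$frac_forward,
                             anchors$median_distance, anchors$gene), , drop = FALSE]
    rownames(anchors) <- NULL
  }
  structure(list(table = tab, anchors = anchors, n_genomes = length(genomes),
                 n_no_target = sum(strings == "<no target>")),
            class = "arrangement_tab")
}

#' @export
print.arrangement_tab <- function(x, ...) {
  cat(sprintf("<arrangement_tab> %d genomes (%d without target)\n",
              x$n_genomes, x$n_no_target))
  print(x$table)
  invisible(x)
}

#' Rank candidate anchor genes
#'
#' Candidates are ranked lexicographically by presence fraction, then
#' forward-orientation fraction, then ascending median distance, with the
#' gene token as a deterministic tie-break. A candidate is eligible when it
#' is forward-oriented in every genome where it occurs and its median 3' gap
#' to the target does not exceed `max_anchor_distance_bp`.
#'
#' @param tab an [tabulate_arrangements()] result.
#' @param thresholds see [default_thresholds()].
#' @return data.frame of ranked candidates (gene, n_present, n_forward,
#'   frac_present, frac_forward, median_distance, eligible). Empty (with a
#'   warning) when no candidate is eligible.
#' @export
select_anchor <- function(tab, thresholds = default_thresholds()) {
  a <- tab$anchors
  if (!nrow(a)) {
    warning("no upstream genes found; empty anchor ranking")
    a$eligible <- logical(0)
    return(a)
  }
  a$eligible <- a$n_forward == a$n_present &
    a$median_distance <= thresholds$max_anchor_distance_bp
  if (!any(a$eligible)) {
    warning("no eligible anchor candidate (forward-oriented within the distance cutoff)")
    return(a[0, , drop = FALSE])
  }
  a
}
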