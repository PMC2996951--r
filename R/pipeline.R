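# End-to-end pipeline and report writers. TSV (tab, no quoting, header row)
# is the canonical report format; a JSON manifest mirrors the run metadata.

.write_report <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full tRNA-anchored primer pipeline
#'
#' Executes survey (arrangement tabulation and anchor ranking) then cluster
#' (anchor-gene alignment and homogeneity grouping) then design (one
#' degenerate primer per group) on the genomes; then, when reads are
#' supplied, in-silico PCR predictions and barcode QC on each read. One
#' summary TSV per stage plus a JSON manifest are written to `out_dir`.
#'
#' @param genomes list of [mito_genome()] records.
#' @param reads optional named character vector of untrimmed barcode reads.
#' @param target target gene token.
#' @param window_bp upstream scan window.
#' @param thresholds see [default_thresholds()].
#' @param identity_threshold,min_freq clustering/consensus parameters.
#' @param reverse_primer [primer_spec()] used (with each designed forward
#'   primer) for in-silico PCR on the reads' source templates; default the
#'   simulator-matched [synthetic_reverse_primer()].
#' @param reference_protein_seq reference profile for indel detection.
#' @param out_dir output directory (created if needed).
#' @param seed recorded in the manifest.
#' @return invisible list with the stage objects (`survey`, `anchor`,
#'   `groups`, `primers`, `ispcr`, `qc`) and `manifest`.
#' @export
run_pipeline <- function(genomes, reads = NULL, target = "COI", window_bp = 200,
                         thresholds = default_thresholds(),
                         identity_threshold = 0.75, min_freq = 0.05,
                         reverse_primer = synthetic_reverse_primer(),
                         reference_protein_seq = reference_protein(),
                         out_dir = ".", seed = NA) {
  if (!length(genomes)) stop("no input genomes", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tab <- .stage("survey", tabulate_arrangements(genomes, target, window_bp))
  .write_report(tab$table, file.path(out_dir, "survey_arrangements.tsv"))
  anchor <- .stage("survey", select_anchor(tab, thresholds))
  .write_report(anchor, file.path(out_dir, "survey_anchor_ranking.tsv"))
  if (!nrow(anchor)) stop("stage 'survey' failed: no eligible anchor gene", call. = FALSE)
  anchor_gene <- anchor$gene[1]

  groups <- .stage("cluster", {
    seqs <- character(0)
    for (g in genomes) {
      f <- g$features
      hit <- which(f$name == anchor_gene)
      if (!length(hit)) next
      s <- substr(g$sequence, f$start[hit[1]] + 1, f$end[hit[1]])
      if (f$strand[hit[1]] < 0) s <- revcomp(s)
      seqs[g$id] <- s
    }
    if (length(seqs) < 2) stop("fewer than 2 anchor sequences")
    block <- center_star_msa(seqs)
    partition_groups(block, identity_threshold = identity_threshold,
                     min_freq = min_freq)
  })
  .write_report(
    data.frame(group = seq_along(groups),
               n_members = vapply(groups, function(g) length(g$member_ids), 1L),
               consensus = vapply(groups, function(g) g$consensus$iupac, "")),
    file.path(out_dir, "cluster_groups.tsv"))

  primers <- .stage("design", lapply(seq_along(groups), function(i) {
    design_primer(groups[[i]]$consensus, name = sprintf("anchorF%d", i),
                  prefer_3prime_GC = TRUE)
  }))
  .write_report(
    do.call(rbind, lapply(primers, function(p) {
      tm <- tryCatch(primer_tm(p), error = function(e) c(NA, NA))
      data.frame(name = p$name, core = p$core,
                 tail = if (is.null(p$tail)) "" else p$tail,
                 direction = p$direction, degeneracy = p$degeneracy,
                 min_tm = tm[1], max_tm = tm[2])
    })),
    file.path(out_dir, "design_primers.tsv"))

  ispcr <- NULL; qc <- NULL
  if (length(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    ispcr <- .stage("ispcr", do.call(rbind, lapply(seq_along(reads), function(i) {
      do.call(rbind, lapply(primers, function(p) {
        pred <- predict_pair(p, reverse_primer, reads[[i]], thresholds)
        data.frame(template = ids[i], fwd_primer = p$name,
                   rev_primer = reverse_primer$name,
                   success = pred$success,
                   reasons = paste(pred$reasons, collapse = ";"),
                   amplicon_bp = pred$length_bp)
      }))
    })))
    .write_report(ispcr, file.path(out_dir, "ispcr_predictions.tsv"))

    qc <- .stage("qc", do.call(rbind, lapply(seq_along(reads), function(i) {
      b <- qc_read(reads[[i]], thresholds,
                   reference_protein = reference_protein_seq)
      ind <- if (is.null(b$indels) || !nrow(b$indels)) "" else
        paste(sprintf("%s@%d+%d", b$indels$kind, b$indels$aa_position,
                      b$indels$length_aa), collapse = ";")
      data.frame(id = ids[i], coi_start = b$coi_start,
                 initiation_call = b$initiation_call,
                 trimmed_bp = nchar(b$trimmed),
                 flags = paste(b$flags, collapse = ";"),
                 barcode_compliant = b$barcode_compliant,
                 indels = ind)
    })))
    .write_report(qc, file.path(out_dir, "qc_reads.tsv"))
  }

  manifest <- list(
    n_genomes = length(genomes),
    n_reads = length(reads),
    target = target, window_bp = window_bp,
    anchor_gene = anchor_gene,
    thresholds = unclass(thresholds),
    identity_threshold = identity_threshold, min_freq = min_freq,
    seed = seed,
    package_version = as.character(utils::packageVersion("trnanchor")))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(survey = tab, anchor = anchor, groups = groups,
                 primers = primers, ispcr = ispcr, qc = qc,
                 manifest = manifest))
}
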