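# Seeded simulator: annotated mitogenomes and barcode reads with planted
# ground truth, so every analysis operation can be tested against known
# answers without external downloads.
#
# What is emulated: the upstream gene arrangements and their observed
# proportions across hexapod mitogenomes, tRNA gene lengths of 60-68 bp, the
# two anchor (tRNA-W) consensus groups, short intergenic gaps, a COI gene
# back-translated from a fixed reference protein under the invertebrate
# mitochondrial code with a chosen initiation codon, and reads whose first
# 70-200 bp are upstream tRNA sequence and whose total length falls in the
# 730-870 bp amplicon band. Not emulated: realistic base composition, codon
# usage, or an evolutionary substitution model.

# evaluate `expr` under a temporary deterministic RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.mix_seed <- function(seed, index, salt = 0L) {
  (as.numeric(seed) * 48271 + index * 131 + salt * 7919) %% 2147483629
}

# conserved anchor tRNA flanks shared by both groups (the two groups diverge
# only over the central consensus segment, as in real anchor tRNAs). The
# flanks are deliberately dissimilar from the AT-rich central block so that
# alignment of the block is unambiguous; compositional realism is a stated
# non-goal of the simulator.
.anchor_flank5 <- "GCGGTCGTGGCGTCCTTGGCG"
.anchor_flank3 <- "CCGGTGCTGGCGTTCGGATCG"

#' Simulator configuration
#'
#' Defaults encode the study conditions the toolkit is built around: 126
#' genomes of which 120 carry the anchor tRNA-W upstream of COI (arrangement
#' mix dominated by `"W,-C,-Y"`), anchor sequences split 92/28 between the
#' two consensus groups, tRNA genes of 60-68 bp, intergenic gaps of 0-20 bp,
#' read filler of 70-200 bp and amplicons of 730-870 bp. Counts given as
#' integers are planted exactly and deterministically.
#'
#' @param seed integer master seed; every generated record is a pure function
#'   of `(seed, index)`.
#' @param n_genomes number of genomes.
#' @param arrangement_counts named integer vector of upstream arrangement
#'   patterns (`"none"` = anchor absent); must sum to `n_genomes`.
#' @param group_counts named integer vector `c(group1=, group2=)` splitting
#'   the anchor-bearing genomes between the two consensus groups.
#' @param trna_len_range tRNA gene length range (bp).
#' @param intergenic_gap_range gap range (bp) between upstream genes.
#' @param coi_initiator single codon-class name or named weights over
#'   `c("ATN","TTG","GTG","TCG","CCG","CGA")`.
#' @param planted_indels data.frame (aa_position, length_aa) of amino-acid
#'   deletions planted into the COI gene, or `NULL`.
#' @param planted_primer_mismatches data.frame (position, base): overrides at
#'   1-based positions of the anchor consensus block, or `NULL`.
#' @param planted_frameshift_at nt offset within COI for a planted 1-bp
#'   deletion (NUMT emulation), or `NULL`.
#' @param planted_stop_at aa position replaced by a TAA codon, or `NULL`.
#' @param filler_band read upstream-filler band (bp).
#' @param amplicon_band read total-length band (bp).
#' @param flank_mut_rate per-site substitution rate applied to the anchor
#'   tRNA flanks (within-group variation).
#' @param clean_filler when `TRUE`, upstream regions are re-drawn until they
#'   contain no canonical initiator in frame with the planted COI start, so
#'   initiator-recovery tests have no spurious closer start.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genomes = 126,
                       arrangement_counts = c("W,-C,-Y" = 96, "W,-Y" = 12,
                                              "W,-C" = 8, "W" = 4, "none" = 6),
                       group_counts = c(group1 = 92, group2 = 28),
                       trna_len_range = c(60, 68),
                       intergenic_gap_range = c(0, 20),
                       coi_initiator = "ATN",
                       planted_indels = NULL,
                       planted_primer_mismatches = NULL,
                       planted_frameshift_at = NULL,
                       planted_stop_at = NULL,
                       filler_band = c(70, 200),
                       amplicon_band = c(730, 870),
                       flank_mut_rate = 0.02,
                       clean_filler = FALSE) {
  if (any(arrangement_counts < 0) || sum(arrangement_counts) != n_genomes) {
    stop("arrangement_counts must be non-negative and sum to n_genomes", call. = FALSE)
  }
  n_anchor <- sum(arrangement_counts[names(arrangement_counts) != "none"])
  if (any(group_counts < 0) || sum(group_counts) != n_anchor) {
    stop(sprintf("group_counts must sum to the %d anchor-bearing genomes", n_anchor),
         call. = FALSE)
  }
  if (filler_band[1] > filler_band[2] || amplicon_band[1] > amplicon_band[2]) {
    stop("bands must be (lower, upper) pairs", call. = FALSE)
  }
  cls <- c("ATN", "TTG", "GTG", "TCG", "CCG", "CGA")
  if (is.character(coi_initiator) && length(coi_initiator) == 1L) {
    stopifnot(coi_initiator %in% cls)
    w <- stats::setNames(rep(0, length(cls)), cls); w[coi_initiator] <- 1
    coi_initiator <- w
  } else {
    stopifnot(all(names(coi_initiator) %in% cls), all(coi_initiator >= 0),
              sum(coi_initiator) > 0)
    w <- stats::setNames(rep(0, length(cls)), cls)
    w[names(coi_initiator)] <- coi_initiator
    coi_initiator <- w
  }
  structure(list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
                 arrangement_counts = arrangement_counts,
                 group_counts = group_counts,
                 trna_len_range = as.integer(trna_len_range),
                 intergenic_gap_range = as.integer(intergenic_gap_range),
                 coi_initiator = coi_initiator,
                 planted_indels = planted_indels,
                 planted_primer_mismatches = planted_primer_mismatches,
                 planted_frameshift_at = planted_frameshift_at,
                 planted_stop_at = planted_stop_at,
                 filler_band = as.integer(filler_band),
                 amplicon_band = as.integer(amplicon_band),
                 flank_mut_rate = flank_mut_rate,
                 clean_filler = isTRUE(clean_filler)),
            class = "sim_config")
}

# deterministic per-index assignment of arrangement pattern and anchor group
.assignments <- function(config) {
  arr <- rep(names(config$arrangement_counts), config$arrangement_counts)
  has_anchor <- arr != "none"
  grp <- rep(NA_character_, config$n_genomes)
  grp[has_anchor] <- rep(names(config$group_counts), config$group_counts)
  list(arrangement = arr, group = grp)
}

# inverse of genetic code table 5, without stops
.codons_by_aa <- local({
  split(names(.code5), .code5)
})

# back-translate a protein; codons for residues in `no_initiator_at` avoid
# canonical initiator codons so no spurious in-frame start lands there
.back_translate <- function(protein, no_initiator_at = integer(0)) {
  aas <- strsplit(protein, "")[[1]]
  vapply(seq_along(aas), function(i) {
    choices <- .codons_by_aa[[aas[i]]]
    if (i %in% no_initiator_at) {
      ok <- setdiff(choices, .canonical_initiators)
      if (length(ok)) choices <- ok
    }
    if (length(choices) == 1L) choices else sample(choices, 1L)
  }, "")
}

.initiator_codon <- function(class) {
  switch(class,
         ATN = sample(c("ATA", "ATT", "ATC", "ATG"), 1L),
         TTG = "TTG", GTG = "GTG", TCG = "TCG", CCG = "CCG", CGA = "CGA")
}

.initiator_class_call <- function(class) {
  switch(class, TCG = "TCG_type", CCG = "TCG_type", CGA = "CGA_type", class)
}

# anchor tRNA gene: conserved flanks + one expansion of the group consensus,
# with light substitution noise on the flanks
.anchor_trna <- function(group, config) {
  block <- sample_expansion(anchor_consensus_groups()[[group]])
  if (!is.null(config$planted_primer_mismatches)) {
    pm <- config$planted_primer_mismatches
    for (k in seq_len(nrow(pm))) {
      substr(block, pm$position[k], pm$position[k]) <- toupper(pm$base[k])
    }
  }
  mutate <- function(s) {
    chars <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(chars)) < config$flank_mut_rate)
    for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    paste(chars, collapse = "")
  }
  list(seq = paste0(mutate(.anchor_flank5), block, mutate(.anchor_flank3)),
       block = block)
}

# does the assembled genome contain a spurious start upstream of the planted
# COI start that would win ORF-anchored trimming? A position confounds when
# its codon is an acceptable initiator (canonical, or TCG/CCG/CGA passing
# the upstream-stop context rule) and its stop-free downstream run is at
# least as long as the planted start's (ties go 5'-most in the trimmer).
.has_confounder <- function(sequence, coi_start, limit = 230L,
                            thresholds = default_thresholds()) {
  if (coi_start <= 0L) return(FALSE)
  L <- nchar(sequence)
  stops <- .stop_positions(sequence)
  cap <- thresholds$barcode_min_len_bp  # mirror the trimmer's run capping
  run_len <- function(p) {
    nxt <- stops[[p %% 3 + 1L]]
    nxt <- nxt[nxt >= p]
    min((if (length(nxt)) min(nxt) else L) - p, cap)
  }
  true_run <- run_len(coi_start)
  for (p in max(0L, coi_start - limit):(coi_start - 1L)) {
    codon <- substr(sequence, p + 1, p + 3)
    ok <- codon %in% .canonical_initiators
    if (!ok && codon %in% c("TCG", "CCG", "CGA")) {
      cl <- call_initiation_codon(substr(sequence, p + 1, L),
                                  upstream = substr(sequence, 1, p), thresholds)
      ok <- cl %in% c("TCG_type", "CGA_type")
    }
    if (ok && run_len(p) >= true_run) return(TRUE)
  }
  FALSE
}

#' Generate one annotated mitogenome with its truth record
#'
#' Deterministic under `(config$seed, index)`. The genome carries the
#' configured upstream arrangement (anchor tRNA-W drawn from the assigned
#' consensus group), intervening tRNAs and gaps, a COI gene with the planted
#' initiation codon and any planted indels/frameshift/stop, a planted
#' reverse-primer site just downstream of COI, and flanking filler.
#'
#' @param config a [sim_config()].
#' @param index genome index in `1..n_genomes`.
#' @return list with `genome` (a [mito_genome()]) and `truth` (planted
#'   arrangement string, group, anchor distance, COI start/end, initiator
#'   codon and expected call class, anchor block, indels).
#' @export
generate_mitogenome <- function(config, index) {
  stopifnot(inherits(config, "sim_config"),
            index >= 1, index <= config$n_genomes)
  asg <- .assignments(config)
  pattern <- asg$arrangement[index]
  group <- asg$group[index]
  with_seed(.mix_seed(config$seed, index), {
    init_class <- sample(names(config$coi_initiator), 1L,
                         prob = config$coi_initiator)
    init_codon <- .initiator_codon(init_class)
    noncanonical <- init_class %in% c("TCG", "CCG", "CGA")

    # COI coding sequence: planted initiator + back-translated reference
    prot <- strsplit(reference_protein(), "")[[1]]
    if (!is.null(config$planted_indels)) {
      pi_ <- config$planted_indels[order(-config$planted_indels$aa_position), , drop = FALSE]
      for (k in seq_len(nrow(pi_))) {
        a <- pi_$aa_position[k]; l <- pi_$length_aa[k]
        prot <- prot[-(a:(a + l - 1))]
      }
    }
    body <- .back_translate(paste(prot[-1], collapse = ""), no_initiator_at = 1:9)
    if (!is.null(config$planted_stop_at)) {
      body[config$planted_stop_at - 1L] <- "TAA"
    }
    coi <- paste0(init_codon, paste(body, collapse = ""), "TAA")
    if (!is.null(config$planted_frameshift_at)) {
      at <- config$planted_frameshift_at
      coi <- paste0(substr(coi, 1, at - 1), substr(coi, at + 1, nchar(coi)))
    }

    build_upstream <- function() {
      pre <- random_dna(sample(250:350, 1L))
      feats <- list(); cursor <- nchar(pre)
      anchor_block <- NA_character_; anchor_end <- NA_integer_
      tokens <- if (pattern == "none") data.frame(token = character(0), sign = integer(0))
      else parse_arrangement(pattern)
      seqs <- pre
      for (t in seq_len(nrow(tokens))) {
        tok <- tokens$token[t]; sign <- tokens$sign[t]
        if (tok == "W" && !is.na(group)) {
          tr <- .anchor_trna(group, config)
          s <- tr$seq; anchor_block <- tr$block
        } else {
          s <- random_dna(sample(config$trna_len_range[1]:config$trna_len_range[2], 1L))
        }
        if (sign < 0) s <- revcomp(s)
        feats[[length(feats) + 1L]] <- gene_feature(
          paste0("trn", tok), cursor, cursor + nchar(s), sign)
        if (tok == "W") anchor_end <- cursor + nchar(s)
        seqs <- paste0(seqs, s)
        cursor <- cursor + nchar(s)
        gap <- sample(config$intergenic_gap_range[1]:config$intergenic_gap_range[2], 1L)
        if (t == nrow(tokens) && noncanonical) gap <- max(gap, 3L)
        seqs <- paste0(seqs, random_dna(gap))
        cursor <- cursor + gap
      }
      if (pattern == "none" && noncanonical) {
        # still need room for the upstream stop context
        seqs <- paste0(seqs, random_dna(3L)); cursor <- cursor + 3L
      }
      if (noncanonical) {
        # plant the in-frame stop immediately 5' of the start; TAG rather
        # than TAA, because TAA abutting a TCG initiator would embed a
        # canonical ATC codon (..TA|ATC|G..) in the -1 frame that no filler
        # redraw could ever remove
        substr(seqs, cursor - 2, cursor) <- "TAG"
      }
      list(seqs = seqs, feats = feats, coi_start = cursor, anchor_end = anchor_end,
           anchor_block = anchor_block)
    }

    downstream <- paste0(revcomp(.synthetic_reverse_core),
                         random_dna(sample(80:160, 1L)))
    up <- build_upstream()
    sequence <- paste0(up$seqs, coi, downstream)
    if (config$clean_filler) {
      tries <- 0L
      while (.has_confounder(sequence, up$coi_start) && tries < 300L) {
        up <- build_upstream()
        sequence <- paste0(up$seqs, coi, downstream)
        tries <- tries + 1L
      }
    }
    feats <- up$feats
    feats[[length(feats) + 1L]] <- gene_feature(
      "COI", up$coi_start, up$coi_start + nchar(coi), 1L)
    genome <- mito_genome(sprintf("sim%03d", index), sequence,
                          do.call(rbind, feats))
    truth <- list(index = index, id = genome$id,
                  arrangement = if (pattern == "none") "" else pattern,
                  has_anchor = pattern != "none",
                  group = group,
                  anchor_distance = if (is.na(up$anchor_end)) NA_integer_
                  else up$coi_start - up$anchor_end,
                  coi_start = up$coi_start,
                  coi_end = up$coi_start + nchar(coi),
                  initiator_codon = init_codon,
                  initiator_class = .initiator_class_call(init_class),
                  anchor_block = up$anchor_block,
                  indels = config$planted_indels)
    list(genome = genome, truth = truth)
  })
}

#' Generate the full genome corpus
#'
#' @param config a [sim_config()].
#' @return list with `genomes` (list of [mito_genome()]) and `truth` (list of
#'   truth records, parallel to `genomes`).
#' @export
generate_corpus <- function(config) {
  out <- lapply(seq_len(config$n_genomes), function(i) generate_mitogenome(config, i))
  list(genomes = lapply(out, `[[`, "genome"),
       truth = lapply(out, `[[`, "truth"))
}

#' Generate a sequencer-style read from a simulated genome
#'
#' The read is a window of the genome: upstream filler (tRNA-derived
#' sequence, length drawn from the filler band) followed by the COI gene, so
#' its total length falls inside the amplicon band. The truth record carries
#' the planted `coi_start` offset and initiator class.
#'
#' @param genome a simulated [mito_genome()].
#' @param truth its truth record from [generate_mitogenome()].
#' @param config the [sim_config()] used.
#' @param primer_pair optional list(fwd, rev) of [primer_spec()]; when given,
#'   the pair must have a predicted amplification success on the genome,
#'   otherwise an error is raised.
#' @return list with `read` (DNA string) and `truth` (coi_start, initiator
#'   class, read length).
#' @export
generate_read <- function(genome, truth, config, primer_pair = NULL) {
  if (!is.null(primer_pair)) {
    pred <- predict_pair(primer_pair$fwd, primer_pair$rev, genome$sequence)
    if (!pred$success) {
      stop(sprintf("genome '%s': primer pair predicts no amplification (%s)",
                   genome$id, paste(pred$reasons, collapse = ", ")), call. = FALSE)
    }
  }
  with_seed(.mix_seed(config$seed, truth$index, salt = 1L), {
    coi_len <- truth$coi_end - truth$coi_start
    max_filler <- min(config$filler_band[2], truth$coi_start,
                      config$amplicon_band[2] - coi_len)
    min_filler <- max(config$filler_band[1],
                      config$amplicon_band[1] - coi_len)
    if (min_filler > max_filler) {
      stop("filler and amplicon bands are inconsistent with the COI length", call. = FALSE)
    }
    filler <- sample(min_filler:max_filler, 1L)
    read <- substr(genome$sequence, truth$coi_start - filler + 1, truth$coi_end)
    list(read = read,
         truth = list(index = truth$index, id = truth$id, coi_start = filler,
                      initiator_class = truth$initiator_class,
                      read_length = nchar(read)))
  })
}
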