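# Shared fixture builders; everything is generated in code.

# hand-built genome: upstream features at explicit gaps before a COI gene
make_genome <- function(id = "g1", upstream = list(), gaps = NULL,
                        coi_strand = 1L, coi_len = 90L, lead = 30L) {
  # upstream: list of list(name, len, strand); gaps[i] is the gap after
  # feature i (the last one separates it from COI)
  if (is.null(gaps)) gaps <- rep(5L, length(upstream) + 1L)
  set.seed(99)
  seqs <- paste(sample(c("A", "C", "G", "T"), lead, replace = TRUE), collapse = "")
  feats <- list()
  cursor <- lead
  for (i in seq_along(upstream)) {
    u <- upstream[[i]]
    s <- paste(sample(c("A", "C", "G", "T"), u$len, replace = TRUE), collapse = "")
    feats[[length(feats) + 1L]] <- gene_feature(u$name, cursor, cursor + u$len, u$strand)
    seqs <- paste0(seqs, s)
    cursor <- cursor + u$len
    g <- paste(sample(c("A", "C", "G", "T"), gaps[i], replace = TRUE), collapse = "")
    seqs <- paste0(seqs, g); cursor <- cursor + gaps[i]
  }
  if (length(upstream) == 0L && length(gaps) == 1L) {
    g <- paste(sample(c("A", "C", "G", "T"), gaps[1], replace = TRUE), collapse = "")
    seqs <- paste0(seqs, g); cursor <- cursor + gaps[1]
  }
  coi <- paste(sample(c("A", "C", "G", "T"), coi_len, replace = TRUE), collapse = "")
  feats[[length(feats) + 1L]] <- gene_feature("COI", cursor, cursor + coi_len, 1L)
  seqs <- paste0(seqs, coi, "ACGTACGTAC")
  g <- mito_genome(id, seqs, do.call(rbind, feats))
  if (coi_strand < 0) g <- rc_genome(g) else g
}

# random IUPAC string with bounded degeneracy
random_iupac <- function(max_len = 12, max_degeneracy = 256) {
  codes <- names(Biostrings::IUPAC_CODE_MAP)
  repeat {
    s <- paste(sample(codes, sample(4:max_len, 1), replace = TRUE,
                      prob = c(rep(6, 4), rep(1, 11))), collapse = "")
    if (iupac_degeneracy(s) <= max_degeneracy) return(s)
  }
}

# independent IUPAC base sets, written out by hand (oracle)
oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T"))
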