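test_that("translation agrees with an independent table-5 oracle on all 64 codons", {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  got <- vapply(codons, translate_mito, "")
  want <- vapply(codons, function(cd) {
    aa <- seqinr::translate(strsplit(cd, "")[[1]], numcode = 5)
    if (aa == "*") "*" else aa
  }, "")
  expect_identical(got, want)
})

test_that("the diagnostic codon substitutions translate as expected", {
  expect_identical(translate_mito("GGA"), "G")
  expect_identical(translate_mito("AGA"), "S")  # Gly->Ser via G->A, table 5
  expect_identical(translate_mito("GAT"), "D")
  expect_identical(translate_mito("AAT"), "N")  # Asp->Asn via G->A
  expect_identical(translate_mito("TGA"), "W")
  expect_identical(translate_mito("ATA"), "M")
})

test_that("frames, partial codons, and degenerate codons are handled", {
  expect_identical(translate_mito("TATGAAA", frame = 1), "MK")
  expect_identical(translate_mito("ATGAA"), "M")     # trailing partial dropped
  expect_identical(translate_mito("GCN"), "A")        # unambiguous product
  expect_identical(translate_mito("RAT"), "X")        # AAT=N vs GAT=D
  expect_error(translate_mito("AUG"), "non-IUPAC")
})

test_that("canonical initiation codons are called directly", {
  for (cd in c("ATA", "ATT", "ATC", "ATG")) {
    expect_identical(as.character(call_initiation_codon(paste0(cd, "AAACCC"))), "ATN")
  }
  expect_identical(as.character(call_initiation_codon("TTGAAACCC")), "TTG")
  expect_identical(as.character(call_initiation_codon("GTGAAACCC")), "GTG")
  expect_error(call_initiation_codon("AT"), "shorter than one codon")
})

test_that("TCG/CCG/CGA require an upstream stop and a clear 30-bp window", {
  thr <- default_thresholds()
  clear <- strrep("CCC", 12)
  expect_identical(as.character(call_initiation_codon(paste0("TCG", clear),
                                                      upstream = "AAATAA", thr)),
                   "TCG_type")
  expect_identical(as.character(call_initiation_codon(paste0("CCG", clear),
                                                      upstream = "AAATAG", thr)),
                   "TCG_type")
  expect_identical(as.character(call_initiation_codon(paste0("CGA", clear),
                                                      upstream = "AAATAA", thr)),
                   "CGA_type")
  # no upstream stop: not acceptable
  expect_identical(as.character(call_initiation_codon(paste0("TCG", clear),
                                                      upstream = "AAACCC", thr)),
                   "uncertain")
  # a canonical initiator 12 bp downstream inside the scan window wins instead
  with_att <- paste0("CGA", "CCCCCCCCC", "ATT", strrep("C", 21))
  expect_identical(as.character(call_initiation_codon(with_att,
                                                      upstream = "AAATAA", thr)),
                   "uncertain")
  # the same sequence with the window shortened below 12 bp accepts CGA
  thr12 <- default_thresholds(initiator_scan_window_bp = 12)
  expect_identical(as.character(call_initiation_codon(with_att,
                                                      upstream = "AAATAA", thr12)),
                   "CGA_type")
})

test_that("quadruplet starts are annotated but never called", {
  call <- call_initiation_codon("ATAACCCGGG")
  expect_identical(as.character(call), "ATN")
  expect_identical(attr(call, "quadruplet"), "ATAA")
  call2 <- call_initiation_codon("TTAACCCGGG")
  expect_identical(as.character(call2), "uncertain")
  expect_identical(attr(call2, "quadruplet"), "TTAA")
})

# a read with `filler` bp of initiator-free junk followed by an ORF encoding
# the reference protein
make_read <- function(filler_len, initiator = "ATG", seed = 81,
                      upstream_stop = FALSE) {
  set.seed(seed)
  body <- trnanchor:::.back_translate(substr(reference_protein(), 2, 230),
                                      no_initiator_at = 1:9)
  coi <- paste0(initiator, paste(body, collapse = ""), "TAA")
  repeat {
    filler <- paste(sample(c("A", "C", "G", "T"), filler_len, replace = TRUE),
                    collapse = "")
    if (upstream_stop && filler_len >= 3) {
      substr(filler, filler_len - 2, filler_len) <- "TAA"
    }
    read <- paste0(filler, coi)
    if (!trnanchor:::.has_confounder(read, filler_len)) return(read)
  }
}

test_that("trimming recovers planted offsets across the trim band", {
  r120 <- make_read(120)
  tr <- trim_upstream(r120)
  expect_identical(tr$coi_start, 120L)
  expect_identical(as.character(tr$initiation_call), "ATN")
  expect_identical(tr$trimmed, substr(r120, 121, nchar(r120)))

  r0 <- make_read(0)
  expect_identical(trim_upstream(r0)$coi_start, 0L)

  r200 <- make_read(200, seed = 82)
  expect_identical(trim_upstream(r200)$coi_start, 200L)

  rtcg <- make_read(150, initiator = "TCG", seed = 83, upstream_stop = TRUE)
  trt <- trim_upstream(rtcg)
  expect_identical(trt$coi_start, 150L)
  expect_identical(as.character(trt$initiation_call), "TCG_type")
})

test_that("reads without a stop-free ORF raise UNTRIMMABLE", {
  expect_error(trim_upstream(strrep("ATGTAA", 60)), "UNTRIMMABLE")
  expect_error(trim_upstream(strrep("A", 200)), "shorter than 300")
})

test_that("NUMT screening flags planted lesions and passes clean reads", {
  set.seed(84)
  body <- trnanchor:::.back_translate(substr(reference_protein(), 2, 230))
  clean <- paste0("ATG", paste(body, collapse = ""), "TAA")
  set.seed(85)
  ref_cds <- paste0("ATG", paste(trnanchor:::.back_translate(
    substr(reference_protein(), 2, 230)), collapse = ""), "TAA")

  expect_identical(numt_screen(clean, reference_cds = ref_cds), character(0))

  stop_in <- clean
  substr(stop_in, 301, 303) <- "TAA"
  expect_true("INTERNAL_STOP" %in% numt_screen(stop_in))

  shift <- paste0(substr(clean, 1, 400), substr(clean, 402, nchar(clean)))
  expect_true("FRAMESHIFT" %in% numt_screen(shift, reference_cds = ref_cds))

  expect_identical(numt_screen(substr(clean, 1, 450)), "SHORT")
})

test_that("indel detection recovers the planted deletions exactly", {
  ref <- reference_protein()
  q131 <- paste0(substr(ref, 1, 130), substr(ref, 134, 230))
  ev <- detect_indels(q131, ref)
  expect_identical(ev$aa_position, 131L)
  expect_identical(ev$length_aa, 3L)
  expect_identical(ev$kind, "deletion")

  q175 <- paste0(substr(ref, 1, 174), substr(ref, 177, 230))
  ev2 <- detect_indels(q175, ref)
  expect_identical(ev2$aa_position, 175L)
  expect_identical(ev2$length_aa, 2L)

  expect_identical(nrow(detect_indels(ref, ref)), 0L)
})

test_that("insertions are reported symmetrically and junk is rejected", {
  ref <- reference_protein()
  ins <- paste0(substr(ref, 1, 100), "WW", substr(ref, 101, 230))
  ev <- detect_indels(ins, ref)
  expect_identical(ev$kind, "insertion")
  expect_identical(ev$aa_position, 101L)
  expect_identical(ev$length_aa, 2L)

  set.seed(86)
  junk <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 120,
                       replace = TRUE), collapse = "")
  expect_error(detect_indels(junk, ref), "identity")
  expect_error(detect_indels("ACDE", ref), "at least 50")
})

test_that("random planted deletions with conserved flanks are recovered exactly", {
  set.seed(87)
  ref <- reference_protein()
  for (k in 1:30) {
    pos <- sample(20:200, 1)
    len <- sample(1:4, 1)
    q <- paste0(substr(ref, 1, pos - 1), substr(ref, pos + len, 230))
    ev <- detect_indels(q, ref)
    expect_identical(nrow(ev), 1L, label = sprintf("pos %d len %d", pos, len))
    expect_identical(ev$length_aa, len, label = sprintf("pos %d len %d", pos, len))
    # with repeated residues at the boundary the leftmost equivalent
    # placement is reported; position matches up to that ambiguity
    expect_lte(ev$aa_position, pos)
    expect_gte(ev$aa_position + ev$length_aa, pos)
  }
})

test_that("qc_read assembles the full record with compliance", {
  r <- make_read(120)
  b <- qc_read(r, reference_protein = reference_protein())
  expect_identical(b$coi_start, 120L)
  expect_identical(b$initiation_call, "ATN")
  expect_true(b$barcode_compliant)
  expect_identical(length(b$flags), 0L)
  expect_identical(nrow(b$indels), 0L)
  expect_identical(substr(b$protein, 2, 50), substr(reference_protein(), 2, 50))
})
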