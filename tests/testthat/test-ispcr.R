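test_that("a degenerate primer matches any of its expansions on the template", {
  set.seed(71)
  core <- reference_primers()$tRWF1$core  # AAACTAATARCCTTCAAAG
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")
  tpl <- paste0(flank(50), "AAACTAATAGCCTTCAAAG", flank(50))
  hits <- scan_primer(core, tpl, "+", max_mismatch = 0)
  expect_length(hits, 1)
  expect_identical(hits[[1]]$template_pos, 50L)
  expect_identical(hits[[1]]$mismatch_count, 0L)
  expect_false(hits[[1]]$terminal_mismatch)
})

test_that("a primer matches its own reverse complement on the minus strand", {
  set.seed(72)
  core <- "TGGTGGAAGAGCTAGCCAAACT"
  tpl <- paste0(strrep("CA", 30), revcomp(core), strrep("GT", 25))
  hits <- scan_primer(core, tpl, "-", max_mismatch = 0)
  expect_length(hits, 1)
  expect_identical(hits[[1]]$template_pos, 60L)
  expect_identical(hits[[1]]$mismatch_count, 0L)
})

test_that("max_mismatch filters out sites with more substitutions", {
  set.seed(73)
  core <- "ACGTACGTACGTACGTACG"
  tpl <- paste0(strrep("T", 40), core, strrep("T", 40))
  mutated <- tpl
  substr(mutated, 45, 45) <- "C"   # footprint position 5 (A->C)
  substr(mutated, 51, 51) <- "A"   # footprint position 11 (G->A)
  hits1 <- scan_primer(core, mutated, "+", max_mismatch = 1)
  expect_length(hits1, 0)
  hits2 <- scan_primer(core, mutated, "+", max_mismatch = 3)
  expect_length(hits2, 1)
  expect_identical(hits2[[1]]$mismatch_count, 2L)
})

test_that("degenerate scan equals the union of expansion scans", {
  set.seed(74)
  for (k in 1:15) {
    primer <- random_iupac(max_len = 10, max_degeneracy = 16)
    while (nchar(primer) < 6) primer <- random_iupac(max_len = 10, max_degeneracy = 16)
    tpl <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    # plant one exact expansion so the union is non-trivial
    ex <- expand_iupac(primer)
    at <- sample(1:(200 - nchar(primer)), 1)
    substr(tpl, at, at + nchar(primer) - 1) <- ex[sample(length(ex), 1)]
    m <- sample(0:2, 1)
    got <- vapply(scan_primer(primer, tpl, "+", max_mismatch = m),
                  `[[`, 0L, "template_pos")
    # oracle: per expansion, positions with hamming distance <= m (pure ACGT)
    tv <- strsplit(tpl, "")[[1]]
    want <- integer(0)
    for (e in ex) {
      ev <- strsplit(e, "")[[1]]
      for (p in 0:(200 - length(ev))) {
        if (sum(ev != tv[(p + 1):(p + length(ev))]) <= m) want <- c(want, p)
      }
    }
    expect_identical(got, sort(unique(want)), label = sprintf("%s m=%d", primer, m))
  }
})

test_that("minus-strand scanning equals plus-strand scanning of the reverse complement", {
  set.seed(75)
  for (k in 1:10) {
    primer <- random_iupac(max_len = 12, max_degeneracy = 8)
    tpl <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
    minus <- scan_primer(primer, tpl, "-", max_mismatch = 2)
    plus_rc <- scan_primer(revcomp(primer), tpl, "+", max_mismatch = 2)
    expect_identical(vapply(minus, `[[`, 0L, "template_pos"),
                     vapply(plus_rc, `[[`, 0L, "template_pos"))
    expect_identical(vapply(minus, `[[`, 0L, "mismatch_count"),
                     vapply(plus_rc, `[[`, 0L, "mismatch_count"))
  }
})

# build a forward/reverse hit pair on a synthetic template with controlled
# substitutions at chosen forward-primer footprint positions (1-based)
.pair_hits <- function(fwd_core, rev_core, sub_at = integer(0), span = 800) {
  set.seed(76)
  mid <- paste(sample(c("A", "C", "G", "T"),
                      span - nchar(fwd_core) - nchar(rev_core), replace = TRUE),
               collapse = "")
  site <- fwd_core
  for (p in sub_at) {
    old <- substr(site, p, p)
    substr(site, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  tpl <- paste0(strrep("T", 20), site, mid, revcomp(rev_core), strrep("T", 20))
  fh <- scan_primer(fwd_core, tpl, "+", max_mismatch = length(sub_at) + 1)
  rh <- scan_primer(rev_core, tpl, "-", max_mismatch = 0)
  list(fwd = fh[[1]], rev = rh[[length(rh)]], template = tpl)
}

test_that("more than three substitutions predict failure", {
  fwd <- "ACGTACGTACGTACGTACGTGCA"
  rev <- "TGGTGGAAGAGCTAGCCAAACT"
  h <- .pair_hits(fwd, rev, sub_at = c(2, 4, 6, 8))  # 4 mismatches, none 3'-proximal
  pred <- predict_amplification(h$fwd, h$rev)
  expect_false(pred$success)
  expect_identical(pred$reasons, "TOO_MANY_MISMATCHES")
  expect_identical(pred$fwd_score, 4L)
})

test_that("a clean pair succeeds with the outer-coordinate amplicon length", {
  fwd <- "ACGTACGTACGTACGTACGTGCA"
  rev <- "TGGTGGAAGAGCTAGCCAAACT"
  h <- .pair_hits(fwd, rev, span = 800)
  pred <- predict_amplification(h$fwd, h$rev)
  expect_true(pred$success)
  expect_identical(pred$length_bp, 800L)
  expect_identical(unname(pred$amplicon), c(20L, 820L))
})

test_that("3'-proximal mismatches count double", {
  fwd <- "ACGTACGTACGTACGTACGTGCA"  # length 23
  rev <- "TGGTGGAAGAGCTAGCCAAACT"
  # two mismatches within the last 10 nt (but not terminal): score 4 > 3
  h <- .pair_hits(fwd, rev, sub_at = c(15, 18))
  pred <- predict_amplification(h$fwd, h$rev)
  expect_false(pred$success)
  expect_identical(pred$fwd_score, 4L)
  expect_identical(pred$reasons, "TOO_MANY_MISMATCHES")
  # same two mismatches outside the window pass
  h2 <- .pair_hits(fwd, rev, sub_at = c(2, 5))
  expect_true(predict_amplification(h2$fwd, h2$rev)$success)
})

test_that("a terminal 3' mismatch alone predicts failure", {
  fwd <- "ACGTACGTACGTACGTACGTGCA"
  rev <- "TGGTGGAAGAGCTAGCCAAACT"
  h <- .pair_hits(fwd, rev, sub_at = nchar(fwd))
  pred <- predict_amplification(h$fwd, h$rev)
  expect_false(pred$success)
  expect_true("TERMINAL_3PRIME_MISMATCH" %in% pred$reasons)
})

test_that("prediction is monotone: extra substitutions never rescue a failure", {
  fwd <- "ACGTACGTACGTACGTACGTGCA"
  rev <- "TGGTGGAAGAGCTAGCCAAACT"
  positions <- c(3, 7, 12, 16, 20, 23)
  prev_success <- TRUE
  for (n in 0:length(positions)) {
    h <- .pair_hits(fwd, rev, sub_at = positions[seq_len(n)])
    s <- predict_amplification(h$fwd, h$rev)$success
    expect_false(!prev_success && s,
                 label = sprintf("monotone at %d substitutions", n))
    prev_success <- s
  }
})

test_that("missing sites are reported as such", {
  fwd <- "ACGTACGTACGTACGTACGTGCA"
  rev <- "TGGTGGAAGAGCTAGCCAAACT"
  h <- .pair_hits(fwd, rev)
  expect_identical(predict_amplification(NULL, h$rev)$reasons, "NO_SITE")
  expect_identical(predict_amplification(h$fwd, NULL)$reasons, "NO_REVERSE_SITE")
  expect_error(predict_amplification(h$rev, h$fwd), "not 3' of")
})

test_that("binding-site profiling reports each substitution once", {
  set.seed(77)
  core <- "AAACTAATAGCCTTCAAAG"
  clean <- paste0(strrep("C", 30), core, strrep("C", 30))
  mut <- clean
  substr(mut, 32, 32) <- "T"  # footprint position 2 (A->T)
  tab <- profile_binding_site(primer_spec("p", core),
                              c(clean = clean, mut = mut))
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$template_id, "mut")
  expect_identical(tab$position, 2L)
  expect_identical(tab$primer_code, "A")
  expect_identical(tab$template_base, "T")
  expect_false(tab$in_3prime_window)

  # two equally good footprints are ambiguous
  twice <- paste0(strrep("C", 10), core, strrep("C", 10), core, strrep("C", 10))
  expect_error(profile_binding_site(primer_spec("p", core), c(t = twice)),
               "ambiguous best footprint")
})

test_that("failing templates with many substitutions contribute full mismatch rows", {
  set.seed(78)
  core <- "AAACTAATAGCCTTCAAAG"
  tpls <- character(0)
  for (i in 1:5) {
    t <- paste0(strrep("C", 25), core, strrep("C", 25))
    at <- 25 + sample(nchar(core), 4)
    for (p in at) {
      old <- substr(t, p, p)
      substr(t, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    tpls[paste0("fail", i)] <- t
  }
  tab <- profile_binding_site(primer_spec("p", core), tpls)
  counts <- table(tab$template_id)
  expect_true(all(counts >= 4))
})
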