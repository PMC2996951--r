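test_that("the canonical three-tRNA arrangement renders as W,-C,-Y", {
  g <- make_genome(upstream = list(
    list(name = "trnW", len = 64, strand = 1L),
    list(name = "trnC", len = 62, strand = -1L),
    list(name = "trnY", len = 66, strand = -1L)))
  arr <- extract_upstream_arrangement(g, "COI", 200)
  expect_identical(arr$string, "W,-C,-Y")
})

test_that("single reverse-oriented anchor renders as -W and empty windows as \"\"", {
  g <- make_genome(upstream = list(list(name = "trnW", len = 64, strand = -1L)))
  expect_identical(extract_upstream_arrangement(g)$string, "-W")
  g2 <- make_genome(upstream = list())
  expect_identical(extract_upstream_arrangement(g2)$string, "")
})

test_that("reverse-strand targets are reoriented before extraction", {
  g <- make_genome(coi_strand = -1L, upstream = list(
    list(name = "trnW", len = 64, strand = 1L),
    list(name = "trnC", len = 62, strand = -1L)))
  expect_identical(extract_upstream_arrangement(g)$string, "W,-C")
})

test_that("missing or duplicated targets are reported", {
  g <- make_genome(upstream = list(list(name = "trnW", len = 64, strand = 1L)))
  expect_error(extract_upstream_arrangement(g, target = "COII"), "not found")
  f <- rbind(g$features, gene_feature("COI", 5, 20, 1L))
  g2 <- mito_genome("dup", g$sequence, f)
  expect_error(extract_upstream_arrangement(g2), "present 2 times")
})

test_that("parse and render are mutually inverse on random arrangements", {
  set.seed(31)
  toks <- c("W", "C", "Y", "Q", "A", "N")
  for (k in 1:50) {
    n <- sample(0:4, 1)
    d <- data.frame(token = sample(toks, n, replace = TRUE),
                    sign = sample(c(1L, -1L), n, replace = TRUE))
    s <- render_arrangement(d)
    back <- parse_arrangement(s)
    expect_identical(back$token, d$token)
    expect_identical(back$sign, d$sign)
  }
})

test_that("tabulation counts distinct arrangements and no-target genomes", {
  gs <- c(
    lapply(1:8, function(i) make_genome(sprintf("a%d", i), upstream = list(
      list(name = "trnW", len = 64, strand = 1L),
      list(name = "trnC", len = 62, strand = -1L),
      list(name = "trnY", len = 66, strand = -1L)))),
    lapply(1:2, function(i) make_genome(sprintf("b%d", i), upstream = list(
      list(name = "trnW", len = 64, strand = 1L)))))
  tab <- tabulate_arrangements(gs)
  expect_identical(tab$table$arrangement, c("W,-C,-Y", "W"))
  expect_identical(tab$table$count, c(8L, 2L))
  expect_equal(tab$table$fraction, c(0.8, 0.2))
  w <- tab$anchors[tab$anchors$gene == "trnW", ]
  expect_identical(w$n_present, 10L)
  expect_identical(w$n_forward, 10L)

  one <- tabulate_arrangements(gs[1])
  expect_equal(one$table$fraction, 1.0)

  # a genome without the target gets its own row rather than an error
  no_target <- mito_genome("nt", strrep("ACGT", 100),
                           gene_feature("trnW", 0, 64, 1L))
  tab2 <- tabulate_arrangements(c(gs, list(no_target)))
  expect_identical(tab2$n_no_target, 1L)
  expect_true("<no target>" %in% tab2$table$arrangement)
})

test_that("anchor selection applies the forward-and-near eligibility rule", {
  gs <- lapply(1:5, function(i) make_genome(sprintf("g%d", i), upstream = list(
    list(name = "trnW", len = 64, strand = 1L),
    list(name = "trnC", len = 62, strand = -1L)), gaps = c(4L, 6L, 8L)))
  tab <- tabulate_arrangements(gs)
  rank <- select_anchor(tab)
  expect_identical(rank$gene[1], "trnW")
  expect_true(rank$eligible[rank$gene == "trnW"])
  expect_false(rank$eligible[rank$gene == "trnC"])  # reverse-oriented

  # an anchor beyond the distance cutoff is ineligible
  far <- make_genome("far", upstream = list(list(name = "trnW", len = 64, strand = 1L)),
                     gaps = 250L)
  tabf <- tabulate_arrangements(list(far), window_bp = 400)
  expect_warning(rf <- select_anchor(tabf), "no eligible")
  expect_identical(nrow(rf), 0L)
})

test_that("eligibility is monotone in the distance cutoff", {
  gs <- lapply(1:4, function(i) make_genome(sprintf("g%d", i), upstream = list(
    list(name = "trnW", len = 64, strand = 1L)), gaps = 60L))
  tab <- tabulate_arrangements(gs)
  eligible_at <- function(cutoff) {
    r <- suppressWarnings(select_anchor(tab, default_thresholds(max_anchor_distance_bp = cutoff)))
    if (!nrow(r)) character(0) else r$gene[r$eligible]
  }
  prev <- eligible_at(400)
  for (cutoff in c(200, 100, 61, 60, 59, 30)) {
    cur <- eligible_at(cutoff)
    expect_true(all(cur %in% prev),
                label = sprintf("cutoff %d keeps eligibility monotone", cutoff))
    prev <- cur
  }
})

test_that("reported anchor distances equal the planted gaps plus intervening genes", {
  cfg <- sim_config(seed = 5, n_genomes = 12,
                    arrangement_counts = c("W,-C,-Y" = 8, "W" = 4),
                    group_counts = c(group1 = 9, group2 = 3))
  corp <- generate_corpus(cfg)
  thr <- default_thresholds()
  for (i in seq_len(12)) {
    arr <- extract_upstream_arrangement(corp$genomes[[i]])
    w <- arr$tokens[arr$tokens$token == "W", ]
    expect_identical(w$distance_bp, corp$truth[[i]]$anchor_distance)
    # W,-C,-Y bound: two 60-68 bp tRNAs plus three gaps of at most 20 bp
    if (corp$truth[[i]]$arrangement == "W,-C,-Y") {
      expect_lte(w$distance_bp, 68 + 68 + 3 * 20)
    }
  }
})
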