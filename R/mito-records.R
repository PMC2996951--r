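# Domain containers and readers for annotated mitogenomes.
#
# Coordinates are 0-based half-open internally; GenBank/TSV 1-based inclusive
# coordinates are converted at the I/O boundary. Origin-spanning features are
# rejected: the region of interest is a short linear window upstream of the
# target gene.

#' Gene-name synonym table
#'
#' GenBank annotation of mitochondrial genes is inconsistent (`COX1`, `CO1`,
#' `COI`, `tRNA-Trp`, `trnW`, ...). Tokens are normalized through a synonym
#' map before any comparison. The default map covers the cytochrome oxidase /
#' tRNA names needed for upstream-arrangement analysis; a custom two-column
#' (alias, token) TSV can be supplied instead.
#'
#' @return named character vector: `names()` are upper-cased aliases, values
#'   are normalized tokens.
#' @export
default_gene_synonyms <- function() {
  aa3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
           Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
           Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
           Tyr = "Y", Val = "V")
  syn <- c(COX1 = "COI", CO1 = "COI", COI = "COI", COXI = "COI",
           COX2 = "COII", CO2 = "COII", COII = "COII",
           COX3 = "COIII", CO3 = "COIII", COIII = "COIII")
  trna <- character(0)
  for (nm in names(aa3)) {
    tok <- paste0("trn", aa3[[nm]])
    trna[toupper(c(tok, paste0("tRNA-", nm), paste0("trn", nm)))] <- tok
  }
  c(syn, trna)
}

#' Read a synonym table from TSV
#'
#' @param path two-column TSV (alias, token), no header required to be named.
#' @return named character vector usable as `synonyms` everywhere.
#' @export
read_gene_synonyms <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "")
  if (ncol(d) < 2) stop("synonym TSV needs columns (alias, token)", call. = FALSE)
  stats::setNames(as.character(d[[2]]), toupper(as.character(d[[1]])))
}

#' Normalize a gene token
#'
#' Idempotent: normalizing a normalized token returns it unchanged. Unknown
#' names pass through untouched.
#'
#' @param x character vector of gene names.
#' @param synonyms synonym map, see [default_gene_synonyms()].
#' @export
normalize_gene_token <- function(x, synonyms = default_gene_synonyms()) {
  hit <- synonyms[toupper(x)]
  unname(ifelse(is.na(hit), x, hit))
}

#' Construct a gene feature table row
#'
#' @param name gene token; @param start 0-based inclusive; @param end 0-based
#'   exclusive; @param strand +1 or -1.
#' @return one-row data.frame.
#' @export
gene_feature <- function(name, start, end, strand) {
  data.frame(name = as.character(name), start = as.integer(start),
             end = as.integer(end), strand = as.integer(strand),
             stringsAsFactors = FALSE)
}

#' Construct an annotated mitogenome record
#'
#' @param id record identifier.
#' @param sequence DNA string over A/C/G/T/N (case-normalized to upper).
#' @param features data.frame with columns name, start, end, strand
#'   (0-based half-open, strand in {+1, -1}); sorted by start on construction.
#' @param circular logical; the molecule is circular, but features may not
#'   span the origin.
#' @return object of class `mito_genome`.
#' @export
mito_genome <- function(id, sequence, features = NULL, circular = TRUE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("sequence must be non-empty", call. = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop(sprintf("genome '%s': disallowed character '%s' at position %d",
                 id, chars[bad[1]], bad[1]), call. = FALSE)
  }
  if (is.null(features)) {
    features <- data.frame(name = character(0), start = integer(0),
                           end = integer(0), strand = integer(0))
  }
  stopifnot(all(c("name", "start", "end", "strand") %in% names(features)))
  if (nrow(features)) {
    if (any(features$start < 0) || any(features$end <= features$start)) {
      stop(sprintf("genome '%s': feature with end <= start or negative start", id),
           call. = FALSE)
    }
    if (any(features$end > nchar(sequence))) {
      stop(sprintf("genome '%s': feature extends past sequence end (origin-spanning features are not supported)", id),
           call. = FALSE)
    }
    if (!all(features$strand %in% c(1L, -1L))) {
      stop(sprintf("genome '%s': strand must be +1 or -1", id), call. = FALSE)
    }
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(id = as.character(id), sequence = sequence,
                 circular = isTRUE(circular), features = features),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %d bp, %s, %d features\n", x$id,
              nchar(x$sequence), if (x$circular) "circular" else "linear",
              nrow(x$features)))
  invisible(x)
}

#' Reverse-complement a mitogenome record
#'
#' Remaps feature coordinates and flips strands, so analyses defined relative
#' to a forward-strand target can be applied after reorienting the record.
#'
#' @param genome a [mito_genome()].
#' @return reoriented `mito_genome`.
#' @export
rc_genome <- function(genome) {
  L <- nchar(genome$sequence)
  f <- genome$features
  if (nrow(f)) {
    new_start <- L - f$end
    new_end <- L - f$start
    f <- data.frame(name = f$name, start = new_start, end = new_end,
                    strand = -f$strand, stringsAsFactors = FALSE)
  }
  mito_genome(genome$id, revcomp(genome$sequence), f, genome$circular)
}

#' Read FASTA sequences
#'
#' @param path FASTA file.
#' @return named character vector of upper-cased sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[[i]]) == 0) {
      stop(sprintf("record '%s' has an empty sequence", names(seqs)[i]), call. = FALSE)
    }
    .assert_iupac(seqs[[i]], what = sprintf("record '%s'", names(seqs)[i]))
  }
  seqs
}

#' Write FASTA sequences
#'
#' @param records named character vector.
#' @param path output file.
#' @param width wrap width.
#' @export
write_fasta <- function(records, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# --- GenBank flat-file subset -----------------------------------------------

.parse_gb_location <- function(loc, lineno) {
  loc <- gsub("\\s", "", loc)
  strand <- 1L
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\(", "", loc)
    loc <- sub("\\)$", "", loc)
  }
  if (grepl("join|order", loc)) {
    stop(sprintf("line %d: compound locations (join/order) are not supported", lineno),
         call. = FALSE)
  }
  if (!grepl("^[<>]?\\d+\\.\\.[<>]?\\d+$", loc)) {
    stop(sprintf("line %d: malformed coordinates '%s'", lineno, loc), call. = FALSE)
  }
  ends <- as.integer(gsub("[<>]", "", strsplit(loc, "\\.\\.")[[1]]))
  if (ends[2] < ends[1]) {
    stop(sprintf("line %d: feature end %d < start %d", lineno, ends[2], ends[1]),
         call. = FALSE)
  }
  # GenBank 1-based inclusive -> 0-based half-open
  list(start = ends[1] - 1L, end = ends[2], strand = strand)
}

#' Read a subset of a GenBank flat file
#'
#' Minimal parser for the needs of upstream-arrangement analysis: `LOCUS`
#' identifier, `FEATURES` entries with keys `gene`, `tRNA` or `CDS` (simple or
#' `complement()` locations only; `/gene` preferred over `/product` for the
#' name), and the `ORIGIN` sequence block. Gene names are normalized through
#' the synonym table; identical (name, interval, strand) duplicates arising
#' from paired gene/CDS entries are collapsed.
#'
#' @param path GenBank flat file (may hold several records).
#' @param synonyms synonym map, see [default_gene_synonyms()].
#' @return list of [mito_genome()] records.
#' @export
read_genbank_subset <- function(path, synonyms = default_gene_synonyms()) {
  lines <- readLines(path, warn = FALSE)
  genomes <- list()
  id <- NULL; feats <- list(); seq_chunks <- character(0)
  pending <- NULL  # feature awaiting qualifiers
  in_features <- FALSE; in_origin <- FALSE
  keys <- c("gene", "tRNA", "CDS")

  flush_pending <- function() {
    if (!is.null(pending)) {
      nm <- pending$gene
      if (is.null(nm)) nm <- pending$product
      if (is.null(nm)) nm <- pending$key
      feats[[length(feats) + 1L]] <<- gene_feature(
        normalize_gene_token(nm, synonyms),
        pending$loc$start, pending$loc$end, pending$loc$strand)
      pending <<- NULL
    }
  }
  flush_record <- function() {
    flush_pending()
    if (!is.null(id)) {
      f <- do.call(rbind, feats)
      if (!is.null(f)) f <- unique(f)
      genomes[[length(genomes) + 1L]] <<- mito_genome(
        id, paste(seq_chunks, collapse = ""), f)
    }
    id <<- NULL; feats <<- list(); seq_chunks <<- character(0)
    in_features <<- FALSE; in_origin <<- FALSE
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^LOCUS", ln)) {
      id <- strsplit(trimws(sub("^LOCUS", "", ln)), "\\s+")[[1]][1]
    } else if (grepl("^FEATURES", ln)) {
      in_features <- TRUE
    } else if (grepl("^ORIGIN", ln)) {
      flush_pending(); in_features <- FALSE; in_origin <- TRUE
    } else if (grepl("^//", ln)) {
      flush_record()
    } else if (in_origin) {
      seq_chunks <- c(seq_chunks, gsub("[^A-Za-z]", "", ln))
    } else if (in_features) {
      m <- regmatches(ln, regexec("^\\s{2,}(\\S+)\\s+(\\S+)\\s*$", ln))[[1]]
      if (length(m) == 3 && m[2] %in% keys) {
        flush_pending()
        pending <- list(key = m[2], loc = .parse_gb_location(m[3], i))
      } else if (!is.null(pending)) {
        q <- regmatches(ln, regexec("^\\s+/(gene|product)=\"([^\"]*)\"", ln))[[1]]
        if (length(q) == 3) pending[[q[2]]] <- q[3]
      }
    }
  }
  flush_record()  # tolerate a missing trailing //
  genomes
}

# --- minimal TSV annotation dialect -----------------------------------------

#' Read mitogenomes from a TSV annotation plus FASTA sequences
#'
#' The tabular dialect has columns `genome_id`, `feature_name`, `start`,
#' `end`, `strand` with 1-based inclusive coordinates and strand `+`/`-`
#' (or +1/-1). Sequences come from a FASTA keyed by `genome_id`.
#'
#' @param tsv_path annotation TSV with a header row.
#' @param fasta_path FASTA of genome sequences.
#' @param synonyms synonym map.
#' @return list of [mito_genome()] records (order of first appearance).
#' @export
read_annotation_tsv <- function(tsv_path, fasta_path,
                                synonyms = default_gene_synonyms()) {
  d <- utils::read.table(tsv_path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "")
  need <- c("genome_id", "feature_name", "start", "end", "strand")
  if (!all(need %in% names(d))) {
    stop(sprintf("annotation TSV must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  strand <- ifelse(d$strand %in% c("+", "1", "+1"), 1L,
                   ifelse(d$strand %in% c("-", "-1"), -1L, NA_integer_))
  if (anyNA(strand)) {
    stop(sprintf("unknown strand symbol '%s'", d$strand[which(is.na(strand))[1]]),
         call. = FALSE)
  }
  if (any(d$end < d$start)) {
    bad <- which(d$end < d$start)[1]
    stop(sprintf("row %d: feature end %d < start %d", bad, d$end[bad], d$start[bad]),
         call. = FALSE)
  }
  seqs <- read_fasta(fasta_path)
  ids <- unique(d$genome_id)
  missing <- setdiff(ids, names(seqs))
  if (length(missing)) {
    stop(sprintf("no sequence for genome id(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  lapply(ids, function(g) {
    rows <- d[d$genome_id == g, , drop = FALSE]
    f <- data.frame(name = normalize_gene_token(rows$feature_name, synonyms),
                    start = as.integer(rows$start) - 1L,
                    end = as.integer(rows$end),
                    strand = strand[d$genome_id == g],
                    stringsAsFactors = FALSE)
    mito_genome(g, seqs[[g]], f)
  })
}

#' Write mitogenome annotations to the TSV dialect
#'
#' @param genomes list of [mito_genome()] records.
#' @param tsv_path annotation TSV output.
#' @param fasta_path optional FASTA output of the sequences.
#' @export
write_annotation_tsv <- function(genomes, tsv_path, fasta_path = NULL) {
  rows <- do.call(rbind, lapply(genomes, function(g) {
    f <- g$features
    if (!nrow(f)) return(NULL)
    data.frame(genome_id = g$id, feature_name = f$name,
               start = f$start + 1L, end = f$end,
               strand = ifelse(f$strand > 0, "+", "-"),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta_path)) {
    write_fasta(stats::setNames(vapply(genomes, `[[`, "", "sequence"),
                                vapply(genomes, `[[`, "", "id")), fasta_path)
  }
  invisible(tsv_path)
}
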