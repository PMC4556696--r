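#' @useDynLib mirtrons, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rbinom rlnorm rnorm runif sd setNames
#' @importFrom utils read.delim write.table head
NULL

# All genomic coordinates in this package are 0-based half-open, BED style.
# All arm / terminus logic downstream works in sense-of-host-gene
# orientation; this module is the only place genome strand flips happen.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a genome FASTA into a named vector of uppercase DNA strings
#'
#' @param path path to an (optionally gzipped) FASTA file.
#' @return named character vector, one element per chromosome, alphabet
#'   restricted to A/C/G/T/N.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  gen <- toupper(as.character(ss))
  names(gen) <- sub("\\s.*$", "", names(ss))
  validate_genome(gen)
  gen
}

#' Write a genome to FASTA
#' @param genome named character vector of chromosome sequences.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  validate_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

validate_genome <- function(genome) {
  if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == ""))
    stop("genome sequences must be named by chromosome")
  if (any(nchar(genome) == 0L)) stop("empty chromosome sequence")
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad))
    stop("non-ACGTN characters in chromosome(s): ",
         paste(names(genome)[bad], collapse = ", "))
  invisible(genome)
}

#' Extract genomic sequence in sense orientation
#'
#' Coordinates are 0-based half-open.  For `strand == "-"` the
#' reverse complement of the plus-strand slice is returned, so the result
#' always reads 5' to 3' on the requested strand.
#'
#' @param genome named character vector from [read_genome_fasta()].
#' @param chrom,start,end interval (vectorised).
#' @param strand "+" or "-" (vectorised).
#' @return character vector of sequences.
#' @export
genome_fetch <- function(genome, chrom, start, end, strand = "+") {
  n <- max(length(chrom), length(start), length(end), length(strand))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n)
  end <- rep_len(end, n); strand <- rep_len(strand, n)
  if (any(!chrom %in% names(genome)))
    stop("unknown chromosome: ", paste(setdiff(chrom, names(genome)), collapse = ", "))
  if (any(end < start)) stop("end < start in genome_fetch")
  if (any(start < 0) || any(end > nchar(genome)[match(chrom, names(genome))]))
    stop("interval outside chromosome bounds")
  out <- substr(genome[chrom], start + 1L, end)
  neg <- strand == "-"
  if (any(neg)) out[neg] <- revcomp(out[neg])
  unname(out)
}

#' Reverse complement DNA strings
#' @param x character vector of DNA sequences.
#' @return reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read intron annotations from BED6
#'
#' The BED name field must encode `host_gene|intron_index|host_intron_count`
#' with `intron_index` the 1-based ordinal of the intron in transcription
#' order.  Malformed name fields are rejected with a warning; `end <= start`
#' is a hard error naming the offending line.
#'
#' @param path BED6 file, 0-based half-open coordinates.
#' @param genome optional genome; when given, donor/acceptor splice
#'   dinucleotides are annotated immediately (see [annotate_splice_sites()]).
#' @return data.frame with columns chrom, start, end, strand, host_gene,
#'   intron_index, host_intron_count, intron_id (and donor/acceptor when a
#'   genome is supplied), sorted by (chrom, start).
#' @export
read_introns_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")]
  if (length(lines) == 0L) return(empty_introns())
  f <- strsplit(lines, "\t| +")
  nf <- lengths(f)
  if (any(nf < 6L)) stop("BED line with fewer than 6 fields: line ",
                         which(nf < 6L)[1])
  m <- do.call(rbind, lapply(f, `[`, 1:6))
  start <- as.integer(m[, 2]); end <- as.integer(m[, 3])
  bad_coord <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad_coord))
    stop("intron with end <= start (or unparsable coordinates) at line ",
         bad_coord[1], ": ", lines[bad_coord[1]])
  name_parts <- strsplit(m[, 4], "|", fixed = TRUE)
  ok <- lengths(name_parts) == 3L &
    !is.na(suppressWarnings(vapply(name_parts, function(p) as.integer(p[2]), 1L))) &
    !is.na(suppressWarnings(vapply(name_parts, function(p) as.integer(p[3]), 1L)))
  if (any(!ok))
    warning(sum(!ok), " BED line(s) with malformed name field rejected ",
            "(expected host_gene|intron_index|host_intron_count)")
  if (!any(ok)) return(empty_introns())
  keep <- which(ok)
  introns <- data.frame(
    chrom = m[keep, 1],
    start = start[keep],
    end = end[keep],
    strand = m[keep, 6],
    host_gene = vapply(name_parts[keep], `[`, "", 1),
    intron_index = vapply(name_parts[keep], function(p) as.integer(p[2]), 1L),
    host_intron_count = vapply(name_parts[keep], function(p) as.integer(p[3]), 1L),
    stringsAsFactors = FALSE
  )
  if (!all(introns$strand %in% c("+", "-")))
    stop("intron strand must be + or -")
  if (any(introns$host_intron_count < introns$intron_index))
    stop("host_intron_count < intron_index in intron annotation")
  introns <- introns[order(introns$chrom, introns$start), , drop = FALSE]
  rownames(introns) <- NULL
  introns$intron_id <- paste0(introns$host_gene, "|", introns$intron_index)
  if (!is.null(genome)) introns <- annotate_splice_sites(introns, genome)
  introns
}

empty_introns <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), host_gene = character(),
             intron_index = integer(), host_intron_count = integer(),
             intron_id = character(), stringsAsFactors = FALSE)
}

#' Annotate donor/acceptor splice dinucleotides in sense orientation
#'
#' Canonical introns read GT...AG on the sense strand of the host gene.
#' Non-canonical dinucleotides trigger a warning but are kept, so annotation
#' errors can still be processed.
#'
#' @param introns data.frame from [read_introns_bed()].
#' @param genome named character vector.
#' @return introns with `donor` and `acceptor` columns added.
#' @export
annotate_splice_sites <- function(introns, genome) {
  if (nrow(introns) == 0L) {
    introns$donor <- character(0); introns$acceptor <- character(0)
    return(introns)
  }
  sense <- genome_fetch(genome, introns$chrom, introns$start, introns$end,
                        introns$strand)
  introns$donor <- substr(sense, 1L, 2L)
  introns$acceptor <- substr(sense, nchar(sense) - 1L, nchar(sense))
  ncan <- introns$donor != "GT" | introns$acceptor != "AG"
  if (any(ncan))
    warning(sum(ncan), " intron(s) with non-canonical splice dinucleotides ",
            "(kept): ", paste(head(introns$intron_id[ncan], 5), collapse = ", "))
  introns
}

#' Read a library manifest
#'
#' @param path TSV with columns library_id, species, tissue, lib_class
#'   (one of total, ago_ip, control_ip, input); an optional `adapter` column
#'   carries per-library 3' adapter sequences.
#' @return data.frame, one row per library.
#' @export
read_manifest <- function(path) {
  man <- read.delim(path, stringsAsFactors = FALSE)
  validate_manifest(man)
}

validate_manifest <- function(man) {
  need <- c("library_id", "species", "tissue", "lib_class")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(man$library_id))
    stop("duplicate library_id in manifest")
  bad <- setdiff(unique(man$lib_class), c("total", "ago_ip", "control_ip", "input"))
  if (length(bad)) stop("unknown lib_class: ", paste(bad, collapse = ", "))
  man
}

#' Read a small RNA library (FASTQ or collapsed FASTA) into a read batch
#'
#' Collapsed FASTA headers carry read counts as `id_xN`; a header without
#' the `_xN` suffix defaults to count 1 with a notice.  FASTQ records count
#' 1 each.  U is normalized to T at ingest.  When an adapter is given, the
#' leftmost exact occurrence is located and everything from it onward is
#' clipped.  Reads shorter than `min_len` after clipping, and reads with
#' characters outside ACGTUN, are dropped and tallied.
#'
#' @param path FASTA/FASTQ file (extension .fq/.fastq[.gz] selects FASTQ).
#' @param library_id library identifier stamped on every read species.
#' @param adapter 3' adapter DNA string, or NULL for pre-clipped input.
#' @param min_len minimum retained read length after clipping (default 17).
#' @return data.frame (sequence, count, library_id), duplicates collapsed,
#'   with attributes `n_dropped_short` and `n_dropped_badchar`.
#' @export
read_small_rna <- function(path, library_id, adapter = NULL, min_len = 17L) {
  is_fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path)
  if (is_fastq) {
    ss <- Biostrings::readDNAStringSet(path, format = "fastq")
    seqs <- toupper(as.character(ss))
    counts <- rep(1L, length(seqs))
  } else {
    ss <- Biostrings::readBStringSet(path)
    seqs <- toupper(as.character(ss))
    ids <- sub("\\s.*$", "", names(ss))
    m <- regmatches(ids, regexpr("_x([0-9]+)$", ids))
    counts <- rep(NA_integer_, length(ids))
    has <- grepl("_x[0-9]+$", ids)
    counts[has] <- as.integer(sub("^.*_x", "", ids[has]))
    if (any(!has) && length(ids) > 0) {
      message(sum(!has), " FASTA header(s) without _xN count; defaulting to 1")
      counts[!has] <- 1L
    }
  }
  read_batch(seqs, counts, library_id, adapter = adapter, min_len = min_len)
}

#' Build a collapsed read batch from raw sequences and counts
#'
#' Workhorse behind [read_small_rna()]; exported so simulated reads can be
#' ingested without touching disk.
#'
#' @inheritParams read_small_rna
#' @param seqs character vector of read sequences (DNA or RNA).
#' @param counts integer vector of per-record counts.
#' @return see [read_small_rna()].
#' @export
read_batch <- function(seqs, counts, library_id, adapter = NULL, min_len = 17L) {
  seqs <- toupper(seqs)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- grepl("[^ACGTN]", seqs)
  n_badchar <- sum(counts[bad])
  seqs <- seqs[!bad]; counts <- counts[!bad]
  if (!is.null(adapter) && length(seqs)) {
    adapter <- gsub("U", "T", toupper(adapter), fixed = TRUE)
    pos <- regexpr(adapter, seqs, fixed = TRUE)  # leftmost exact occurrence
    hit <- pos > 0L
    seqs[hit] <- substr(seqs[hit], 1L, pos[hit] - 1L)
  }
  short <- nchar(seqs) < min_len
  n_short <- sum(counts[short])
  seqs <- seqs[!short]; counts <- counts[!short]
  if (length(seqs)) {
    agg <- rowsum(as.numeric(counts), group = seqs)
    batch <- data.frame(sequence = rownames(agg),
                        count = as.integer(agg[, 1]),
                        library_id = library_id,
                        stringsAsFactors = FALSE)
    batch <- batch[order(batch$sequence), , drop = FALSE]
    rownames(batch) <- NULL
  } else {
    batch <- data.frame(sequence = character(), count = integer(),
                        library_id = character(), stringsAsFactors = FALSE)
  }
  if (any(batch$count < 1L)) stop("read counts must be >= 1")
  attr(batch, "n_dropped_short") <- as.integer(n_short)
  attr(batch, "n_dropped_badchar") <- as.integer(n_badchar)
  batch
}

#' Write a collapsed read batch as count-encoded FASTA
#' @param batch data.frame from [read_batch()].
#' @param path output FASTA path.
#' @param rna write sequences in RNA space (T -> U) instead of DNA.
#' @export
write_small_rna <- function(batch, path, rna = FALSE) {
  seqs <- batch$sequence
  if (rna) seqs <- gsub("T", "U", seqs, fixed = TRUE)
  ids <- sprintf("r%06d_x%d", seq_len(nrow(batch)), batch$count)
  writeLines(paste0(">", ids, "\n", seqs), path)
  invisible(path)
}

#' Write a result table as deterministic TSV
#'
#' Tab-separated, header row, UTF-8; rows sorted on `key` columns so output
#' is byte-stable across runs; numeric columns rendered with 7 significant
#' digits so a round-trip through [read_result_table()] agrees within 1e-6
#' relative.
#'
#' @param table data.frame.
#' @param path output path.
#' @param key character vector of column names used as the primary sort key
#'   (defaults to all columns, left to right).
#' @export
write_table <- function(table, path, key = names(table)) {
  stopifnot(is.data.frame(table))
  if (nrow(table) > 0L && length(key)) {
    ord <- do.call(order, unname(table[key]))
    table <- table[ord, , drop = FALSE]
  }
  num <- vapply(table, is.double, TRUE)
  table[num] <- lapply(table[num], signif, digits = 7L)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_table()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
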