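# Readers and writers for the external formats (FASTA/FASTQ, GFF3, BLAST
# tabular, bedGraph) and the shared coordinate model. All internal
# coordinates are 0-based half-open on the forward strand; strand is carried
# separately. GFF3 and BLAST tabular are 1-based inclusive on disk and are
# converted on the way in and out.

#' Read sequences from FASTA or FASTQ
#'
#' Residues are uppercased and `U` is mapped to `T`. Ambiguity codes other
#' than `N` are rejected with an error, because alignment scoring downstream
#' is defined over `{A,C,G,T,N}`.
#'
#' @param path Path to the file.
#' @param format `"fasta"` or `"fastq"`.
#' @param topology `"linear"` or `"circular"`, attached to every record.
#' @param compartment One of `"mitochondrial"`, `"plastid"`, `"read"`,
#'   `"contig"`, `"other"`.
#' @return A tibble with columns `id`, `residues`, `length`, `topology`,
#'   `compartment`.
#' @export
read_sequences <- function(path, format = c("fasta", "fastq"),
                           topology = "linear", compartment = "other") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) {
    return(tibble(id = character(), residues = character(),
                  length = integer(), topology = character(),
                  compartment = character()))
  }
  if (format == "fastq") validate_fastq_lines(path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format),
    error = function(e) abort(sprintf("malformed %s in %s: %s",
                                      format, path, conditionMessage(e))))
  res <- unname(toupper(chartr("Uu", "Tt", as.character(set))))
  check_dna(res, what = sprintf("record in %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    abort(sprintf("duplicate sequence ids in %s", path))
  tibble(id = ids, residues = res, length = nchar(res),
         topology = topology, compartment = compartment)
}

validate_fastq_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    abort(sprintf("malformed fastq in %s: %d lines is not a multiple of 4",
                  path, length(lines)))
  hdr <- seq(1L, length(lines), by = 4L)
  bad <- hdr[!startsWith(lines[hdr], "@")]
  if (length(bad))
    abort(sprintf("malformed fastq record in %s at line %d: header must start with '@'",
                  path, bad[1]))
  sep <- seq(3L, length(lines), by = 4L)
  bad <- sep[!startsWith(lines[sep], "+")]
  if (length(bad))
    abort(sprintf("malformed fastq record in %s at line %d: separator must start with '+'",
                  path, bad[1]))
  invisible(TRUE)
}

#' Write sequences to FASTA or FASTQ
#'
#' @param seqs Sequence tibble (see [read_sequences()]).
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`. FASTQ writes a constant quality.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  set <- Biostrings::BStringSet(setNames(seqs$residues, seqs$id))
  if (format == "fasta") {
    Biostrings::writeXStringSet(set, path, format = "fasta", width = 70L)
  } else {
    qual <- Biostrings::BStringSet(vapply(nchar(seqs$residues), function(n)
      paste(rep("I", n), collapse = ""), character(1)))
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(seqs))) {
      writeLines(c(paste0("@", seqs$id[i]), seqs$residues[i], "+",
                   as.character(qual[[i]])), con)
    }
  }
  invisible(path)
}

#' Convert coordinates between conventions
#'
#' Internal coordinates are 0-based half-open `[start, end)`; GFF3 and BLAST
#' tabular use 1-based inclusive `[first, last]`. The two functions are
#' inverses of each other.
#'
#' @param start,end 0-based half-open interval.
#' @param first,last 1-based inclusive interval.
#' @return A tibble with the converted pair.
#' @export
to_one_based <- function(start, end) {
  stopifnot(all(end > start))
  tibble(first = as.integer(start + 1L), last = as.integer(end))
}

#' @rdname to_one_based
#' @export
to_zero_based <- function(first, last) {
  if (any(last < first)) abort("interval end before start")
  tibble(start = as.integer(first - 1L), end = as.integer(last))
}

#' Read feature annotations from GFF3
#'
#' Multi-segment features (for example trans-exonic CDS parts) are grouped by
#' their `ID` (or `Parent`) attribute: rows sharing an identifier become
#' segments of one feature, ordered along the forward strand with a `segment`
#' index running 5' to 3' on the feature strand.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with one row per segment: `feature_id`, `seq_id`, `kind`,
#'   `name`, `strand`, `start`, `end` (0-based half-open), `segment`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  gff <- tryCatch(rtracklayer::readGFF(path),
                  error = function(e) abort(sprintf(
                    "malformed GFF3 in %s: %s", path, conditionMessage(e))))
  gff <- as.data.frame(gff)
  if (nrow(gff) == 0L)
    return(tibble(feature_id = character(), seq_id = character(),
                  kind = character(), name = character(), strand = character(),
                  start = integer(), end = integer(), segment = integer()))
  if (any(gff$end < gff$start))
    abort(sprintf("malformed GFF3 in %s: end < start", path))
  strand <- as.character(gff$strand)
  if (any(!strand %in% c("+", "-")))
    abort(sprintf("malformed GFF3 in %s: unknown strand symbol", path))
  parent <- if ("Parent" %in% names(gff)) {
    vapply(gff$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(gff))
  id <- if ("ID" %in% names(gff)) as.character(gff$ID) else rep(NA_character_, nrow(gff))
  fid <- dplyr::coalesce(id, parent,
                         paste0("feat", seq_len(nrow(gff))))
  name <- if ("Name" %in% names(gff)) as.character(gff$Name) else fid
  out <- tibble(
    feature_id = fid,
    seq_id = as.character(gff$seqid),
    kind = as.character(gff$type),
    name = dplyr::coalesce(name, fid),
    strand = strand,
    start = as.integer(gff$start - 1L),
    end = as.integer(gff$end)
  )
  out <- out |>
    group_by(.data$feature_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(segment = if (dplyr::first(.data$strand) == "+")
      seq_len(dplyr::n()) else rev(seq_len(dplyr::n()))) |>
    ungroup() |>
    arrange(match(.data$feature_id, unique(fid)), .data$start)
  out
}

#' Write feature annotations to GFF3
#'
#' @param features Feature tibble (see [read_features()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  if (nrow(features) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = features$seq_id,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$type <- features$kind
  S4Vectors::mcols(gr)$ID <- features$feature_id
  S4Vectors::mcols(gr)$Name <- features$name
  S4Vectors::mcols(gr)$source <- "orgdecay"
  # CDS rows need a phase column for a clean GFF3 export
  S4Vectors::mcols(gr)$phase <- ifelse(features$kind == "CDS", 0L, NA_integer_)
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read homology hits in BLAST 12-column tabular format
#'
#' The `outfmt 6` dialect: 1-based inclusive coordinates, percent identity,
#' and minus-strand subject hits encoded as `sstart > send`. On the way in,
#' coordinates become 0-based half-open with `s_start < s_end` and the strand
#' stored explicitly; `pident` is stored as a fraction.
#'
#' @param path Path to a tab-separated 12-column file (no header).
#' @return A tibble with columns `query_id`, `subject_id`, `identity`,
#'   `aln_length`, `mismatches`, `gap_opens`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `strand`, `evalue`, `score`.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) return(empty_hits())
  raw <- readr::read_tsv(path, col_names = BLAST6_COLS,
                         col_types = "ccdiiiiiiidd", progress = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0L)
    abort(sprintf("malformed BLAST tabular in %s at line %d: expected 12 columns",
                  path, probs$row[1]))
  minus <- raw$sstart > raw$send
  tibble(
    query_id = raw$qseqid,
    subject_id = raw$sseqid,
    identity = raw$pident / 100,
    aln_length = raw$length,
    mismatches = raw$mismatch,
    gap_opens = raw$gapopen,
    q_start = as.integer(raw$qstart - 1L),
    q_end = as.integer(raw$qend),
    s_start = as.integer(ifelse(minus, raw$send, raw$sstart) - 1L),
    s_end = as.integer(ifelse(minus, raw$sstart, raw$send)),
    strand = ifelse(minus, "-", "+"),
    evalue = raw$evalue,
    score = raw$bitscore
  )
}

empty_hits <- function() {
  tibble(query_id = character(), subject_id = character(),
         identity = double(), aln_length = integer(), mismatches = integer(),
         gap_opens = integer(), q_start = integer(), q_end = integer(),
         s_start = integer(), s_end = integer(), strand = character(),
         evalue = double(), score = double())
}

#' Write homology hits in BLAST 12-column tabular format
#'
#' Inverse of [read_hits()]: minus-strand hits are emitted with
#' `sstart > send`, coordinates go back to 1-based inclusive and identity to
#' percent.
#'
#' @param hits Hit tibble (see [read_hits()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  minus <- hits$strand == "-"
  out <- data.frame(
    qseqid = hits$query_id,
    sseqid = hits$subject_id,
    pident = sprintf("%.2f", hits$identity * 100),
    length = hits$aln_length,
    mismatch = hits$mismatches,
    gapopen = hits$gap_opens,
    qstart = hits$q_start + 1L,
    qend = hits$q_end,
    sstart = ifelse(minus, hits$s_end, hits$s_start + 1L),
    send = ifelse(minus, hits$s_start + 1L, hits$s_end),
    evalue = format(hits$evalue, digits = 3, scientific = TRUE),
    bitscore = hits$score
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write per-base coverage as bedGraph
#'
#' A coverage track is a tibble with one row per genome position: `seq_id`,
#' `pos` (0-based), `depth`. bedGraph stores runs of equal depth in 0-based
#' half-open intervals.
#'
#' @param path bedGraph path.
#' @param genome_length Total genome length; positions absent from the file
#'   get depth 0.
#' @param seq_id Sequence identifier for the returned track (defaults to the
#'   one in the file).
#' @return A coverage track tibble.
#' @export
read_coverage <- function(path, genome_length = NULL, seq_id = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  sid <- seq_id %||% (if (length(gr)) as.character(GenomicRanges::seqnames(gr)[1]) else "seq")
  L <- genome_length %||% (if (length(gr)) max(GenomicRanges::end(gr)) else 0L)
  depth <- integer(L)
  if (length(gr)) {
    st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
    sc <- as.integer(S4Vectors::mcols(gr)$score)
    for (i in seq_along(gr)) depth[st[i]:en[i]] <- sc[i]
  }
  new_coverage_track(sid, depth)
}

#' @rdname read_coverage
#' @param track Coverage track tibble.
#' @export
write_coverage <- function(track, path) {
  r <- rle(track$depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- TRUE
  gr <- GenomicRanges::GRanges(
    seqnames = track$seq_id[1],
    ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]),
    score = r$values[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

new_coverage_track <- function(seq_id, depth) {
  out <- tibble(seq_id = seq_id, pos = seq_along(depth) - 1L,
                depth = as.integer(depth))
  class(out) <- c("coverage_track", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
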