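# Local seed-and-extend alignment (a blastn-like search used wherever the
# pipeline needs homology hits), hit filtering at the standard thresholds,
# and affine-gap semi-global alignment for the disruption classifier.

#' Alignment parameters
#'
#' Defaults mirror blastn-style nucleotide scoring: match +2, mismatch -3,
#' a gap of
#' length L costing `gap_open + (L - 1) * gap_extend` (so a single-base gap
#' costs `gap_open`), word size 11. `x_drop` bounds how far a gapped extension may sink below its
#' running best before it is abandoned; `band_width` bounds the diagonal
#' drift (net indel length) of an extension. `exact_limit` is the input size
#' below which every seed is extended (no diagonal suppression), which makes
#' results on short inputs exact at the cost of redundant work.
#'
#' E-values use the ungapped Karlin-Altschul form
#' `E = K * m * n * exp(-lambda * S)` with the standard ungapped blastn
#' constants `lambda = 1.33`, `K = 0.621`; `m` is the query length and `n`
#' the effective database length (`db_length`, defaulting to the subject
#' length).
#'
#' @param word_size Seed k-mer length (4-12).
#' @param match,mismatch Match/mismatch scores; `match > 0 > mismatch`.
#' @param gap_open,gap_extend Gap penalties, both `<= 0`.
#' @param x_drop X-drop threshold for extensions (positive).
#' @param band_width Maximum diagonal drift during extension.
#' @param min_evalue Default e-value ceiling carried along for filtering.
#' @param db_length Effective search-space length; `NULL` means subject length.
#' @param min_raw_score Minimum raw score for a reported hit; `NULL` means
#'   `word_size * match` (a bare seed).
#' @param exact_limit Input length below which seed suppression is disabled.
#' @return A list of class `align_params`.
#' @export
align_params <- function(word_size = 11L, match = 2L, mismatch = -3L,
                         gap_open = -5L, gap_extend = -2L, x_drop = 40L,
                         band_width = 32L, min_evalue = 10,
                         db_length = NULL, min_raw_score = NULL,
                         exact_limit = 1000L) {
  stopifnot(word_size >= 4L, word_size <= 12L, match > 0L, mismatch < 0L,
            gap_open <= 0L, gap_extend <= 0L, x_drop > 0L, band_width >= 1L)
  structure(list(word_size = as.integer(word_size), match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 x_drop = as.integer(x_drop),
                 band_width = as.integer(band_width),
                 min_evalue = min_evalue, db_length = db_length,
                 min_raw_score = min_raw_score,
                 exact_limit = as.integer(exact_limit)),
            class = "align_params")
}

KARLIN_LAMBDA <- 1.33
KARLIN_K <- 0.621

karlin_evalue <- function(score, query_length, db_length) {
  KARLIN_K * as.numeric(query_length) * as.numeric(db_length) *
    exp(-KARLIN_LAMBDA * as.numeric(score))
}

#' Local alignment of two sequences
#'
#' Seed-and-extend search on both strands: exact `word_size` seeds are found
#' with a k-mer index of the subject and extended in both directions with a
#' gapped x-drop extension. Overlapping hits on the same diagonal are
#' suppressed/merged; hits are reported sorted by descending score.
#'
#' @param query,subject Sequence tibbles (single row) or DNA strings.
#' @param params [align_params()].
#' @param self Set `TRUE` when aligning a genome against itself: the trivial
#'   full-length self-hit is excluded and symmetric duplicate pairs are
#'   canonicalised so `q_start <= s_start`.
#' @return A hit tibble (see [read_hits()]) with query/subject ids, 0-based
#'   half-open coordinates, strand, fractional identity, alignment length,
#'   raw score and e-value.
#' @export
local_align <- function(query, subject, params = align_params(), self = FALSE) {
  q <- toupper(get_residues(query, "query"))
  s <- toupper(get_residues(subject, "subject"))
  check_dna(q, "query"); check_dna(s, "subject")
  if (nchar(q) == 0L || nchar(s) == 0L) abort("sequences must be non-empty")
  qid <- get_seq_id(query, "query")
  sid <- get_seq_id(subject, if (self) qid else "subject")
  min_raw <- params$min_raw_score %||% (params$word_size * params$match)
  raw <- cpp_local_align(q, s, params$word_size, params$match, params$mismatch,
                         params$gap_open, params$gap_extend, params$x_drop,
                         params$band_width, self, as.integer(min_raw),
                         params$exact_limit)
  hits <- as_tibble(raw)
  if (self && nrow(hits) > 0L) {
    # canonicalise: query interval first in genome order; drop coincident pairs
    flip <- hits$s_start < hits$q_start
    tmp_qs <- hits$q_start; tmp_qe <- hits$q_end
    hits$q_start[flip] <- hits$s_start[flip]; hits$q_end[flip] <- hits$s_end[flip]
    hits$s_start[flip] <- tmp_qs[flip]; hits$s_end[flip] <- tmp_qe[flip]
    hits <- hits[!(hits$q_start == hits$s_start & hits$q_end == hits$s_end), ,
                 drop = FALSE]
    hits <- dplyr::distinct(hits, .data$q_start, .data$q_end, .data$s_start,
                            .data$s_end, .data$strand, .keep_all = TRUE)
  }
  db_len <- params$db_length %||% nchar(s)
  out <- tibble(
    query_id = qid, subject_id = sid,
    identity = ifelse(hits$cols > 0, hits$matches / hits$cols, 0),
    aln_length = as.integer(hits$cols),
    mismatches = as.integer(hits$cols - hits$matches -
                              pmax(0L, hits$cols - (hits$q_end - hits$q_start)) -
                              pmax(0L, hits$cols - (hits$s_end - hits$s_start))),
    gap_opens = NA_integer_,
    q_start = as.integer(hits$q_start), q_end = as.integer(hits$q_end),
    s_start = as.integer(hits$s_start), s_end = as.integer(hits$s_end),
    strand = hits$strand,
    evalue = karlin_evalue(hits$score, nchar(q), db_len),
    score = as.numeric(hits$score)
  )
  arrange(out, desc(.data$score), .data$s_start, .data$q_start)
}

#' Filter homology hits at explicit thresholds
#'
#' Retains exactly the hits with `evalue <= min_evalue`,
#' `aln_length >= min_length` and `identity >= min_identity`; every boundary
#' is inclusive and input order is preserved. The defaults are the
#' scaffolding/search thresholds used throughout the pipeline
#' (e-value 1e-10, 90 bp, 90%).
#'
#' @param hits Hit tibble.
#' @param min_evalue E-value ceiling (inclusive).
#' @param min_length Minimum alignment length in bp (inclusive).
#' @param min_identity Minimum fractional identity (inclusive).
#' @return The filtered hit tibble, original order preserved.
#' @export
filter_hits <- function(hits, min_evalue = 1e-10, min_length = 90L,
                        min_identity = 0.90) {
  keep <- hits$evalue <= min_evalue &
    hits$aln_length >= min_length &
    hits$identity >= min_identity
  hits[keep, , drop = FALSE]
}

#' Semi-global (glocal) pairwise alignment
#'
#' Optimal Needleman-Wunsch alignment with affine gaps in which end gaps on
#' the query side are free: a candidate gene copy that is 5'- or 3'-truncated
#' aligns with unaligned reference ends rather than paying terminal gap
#' penalties, which is how truncations are located.
#'
#' @param ref Reference DNA string (or single-row sequence tibble).
#' @param qry Query (candidate) DNA string.
#' @param params [align_params()] (only the scoring fields are used).
#' @return An object of class `pairwise_alignment`: a list with `score`,
#'   `ref_start`/`ref_end` (aligned reference extent, 0-based half-open),
#'   and gapped alignment strings `ref_aln`, `qry_aln`.
#' @export
global_align <- function(ref, qry, params = align_params()) {
  r <- toupper(get_residues(ref, "reference"))
  q <- toupper(get_residues(qry, "query"))
  check_dna(r, "reference"); check_dna(q, "query")
  if (nchar(r) == 0L || nchar(q) == 0L) abort("sequences must be non-empty")
  res <- cpp_nw_semiglobal(r, q, params$match, params$mismatch,
                           params$gap_open, params$gap_extend)
  structure(list(ref_id = get_seq_id(ref, "ref"),
                 qry_id = get_seq_id(qry, "qry"),
                 score = res$score,
                 ref_start = res$ref_start, ref_end = res$ref_end,
                 ref_length = nchar(r),
                 ref_aln = res$ref_aln, qry_aln = res$qry_aln),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s  score=%d  ref [%d,%d) of %d\n",
              x$ref_id, x$qry_id, x$score, x$ref_start, x$ref_end,
              x$ref_length))
  invisible(x)
}

#' Tidy a pairwise alignment into one row per column
#'
#' @param x A `pairwise_alignment`.
#' @param ... Unused.
#' @return A tibble with `column`, `ref_pos`, `qry_pos` (0-based, `NA` at
#'   gaps), `ref_char`, `qry_char`.
#' @method tidy pairwise_alignment
#' @export
tidy.pairwise_alignment <- function(x, ...) {
  rc <- strsplit(x$ref_aln, "", fixed = TRUE)[[1]]
  qc <- strsplit(x$qry_aln, "", fixed = TRUE)[[1]]
  ref_pos <- cumsum(rc != "-") - 1L + x$ref_start
  ref_pos[rc == "-"] <- NA_integer_
  qry_pos <- cumsum(qc != "-") - 1L
  qry_pos[qc == "-"] <- NA_integer_
  tibble(column = seq_along(rc), ref_pos = ref_pos, qry_pos = qry_pos,
         ref_char = rc, qry_char = qc)
}

#' @method glance pairwise_alignment
#' @export
glance.pairwise_alignment <- function(x, ...) {
  cols <- tidy(x)
  tibble(score = x$score,
         columns = nrow(cols),
         matches = sum(!is.na(cols$ref_pos) & !is.na(cols$qry_pos) &
                         cols$ref_char == cols$qry_char),
         identity = sum(!is.na(cols$ref_pos) & !is.na(cols$qry_pos) &
                          cols$ref_char == cols$qry_char) / nrow(cols),
         ref_start = x$ref_start, ref_end = x$ref_end,
         ref_length = x$ref_length)
}
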