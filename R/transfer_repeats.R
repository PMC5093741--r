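# Detection and quantification of plastid-derived mitogenome segments
# (MIPTs) and dispersed repeats, size-class summaries and merged-coverage
# statistics.

#' Detection configuration for MIPTs and repeats
#'
#' MIPTs decay over time, so their identity floor (0.70) is far looser than
#' the repeat floor (0.90); the MIPT length floor of 100 bp matches the
#' display convention of showing repeats and MIPTs > 100 bp, and
#' mitogenome-coordinate intervals separated by at most `mipt_merge_gap` are
#' merged into one insertion. Repeat size classes are half-open:
#' small [50, 100), intermediate [100, 1000), large [1000, Inf).
#'
#' @param mipt_min_len Minimum merged MIPT length (bp).
#' @param mipt_min_identity Minimum hit identity for a MIPT fragment.
#' @param mipt_merge_gap Maximum gap (bp) between merged MIPT fragments.
#' @param repeat_min_len Minimum repeat length (bp).
#' @param repeat_min_identity Minimum repeat identity.
#' @param size_bins Named vector of lower bin edges (small/intermediate/large).
#' @param align [align_params()] for the underlying searches.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(mipt_min_len = 100L, mipt_min_identity = 0.70,
                             mipt_merge_gap = 50L, repeat_min_len = 50L,
                             repeat_min_identity = 0.90,
                             size_bins = c(small = 50L, intermediate = 100L,
                                           large = 1000L),
                             align = align_params()) {
  stopifnot(size_bins[["small"]] == repeat_min_len)
  structure(list(mipt_min_len = as.integer(mipt_min_len),
                 mipt_min_identity = mipt_min_identity,
                 mipt_merge_gap = as.integer(mipt_merge_gap),
                 repeat_min_len = as.integer(repeat_min_len),
                 repeat_min_identity = repeat_min_identity,
                 size_bins = size_bins, align = align),
            class = "detection_config")
}

#' Find plastid-derived segments in a mitogenome
#'
#' The plastome is aligned locally against the mitogenome on both strands;
#' hits at or above `mipt_min_identity` are projected to mitogenome
#' coordinates, fragments separated by at most `mipt_merge_gap` bp are merged
#' into one insertion event, and merged intervals shorter than `mipt_min_len`
#' are discarded.
#'
#' @param mitogenome,plastome Sequence tibbles (single row) or DNA strings.
#' @param config [detection_config()].
#' @return A tibble sorted by mitogenome start: `mipt_id`, `start`, `end`,
#'   `length`, `mean_identity`, `n_fragments`, and a `source` list-column of
#'   plastome intervals (`start`, `end`, `strand`, `identity`).
#' @export
find_mipts <- function(mitogenome, plastome, config = detection_config()) {
  mseq <- toupper(get_residues(mitogenome, "mitogenome"))
  pseq <- toupper(get_residues(plastome, "plastome"))
  params <- config$align
  # a 100-bp fragment at the 0.70 identity floor scores 50; below that,
  # chance excursions in a genome-scale search space become numerous enough
  # to perturb interval merging
  params$min_raw_score <- params$min_raw_score %||% 50L
  hits <- local_align(pseq, mseq, params = params)
  hits <- hits[hits$identity >= config$mipt_min_identity, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty_mipts())
  merged <- merge_intervals(hits$s_start, hits$s_end, config$mipt_merge_gap)
  merged <- merged[merged$end - merged$start >= config$mipt_min_len, ,
                   drop = FALSE]
  if (nrow(merged) == 0L) return(empty_mipts())
  merged <- arrange(merged, .data$start)
  src <- lapply(seq_len(nrow(merged)), function(k) {
    within <- hits$s_start < merged$end[k] & hits$s_end > merged$start[k]
    h <- hits[within, , drop = FALSE]
    tibble(start = h$q_start, end = h$q_end, strand = h$strand,
           identity = h$identity, aln_length = h$aln_length)
  })
  tibble(mipt_id = sprintf("mipt%03d", seq_len(nrow(merged))),
         start = merged$start, end = merged$end,
         length = merged$end - merged$start,
         mean_identity = vapply(src, function(s)
           sum(s$identity * s$aln_length) / sum(s$aln_length), double(1)),
         n_fragments = vapply(src, nrow, integer(1)),
         source = src)
}

empty_mipts <- function() {
  tibble(mipt_id = character(), start = integer(), end = integer(),
         length = integer(), mean_identity = double(),
         n_fragments = integer(), source = list())
}

#' Coverage statistics for a set of genome segments
#'
#' `covered_bp` is the size of the union of the intervals; `percent` is
#' rounded half away from zero to one decimal; `min_len`/`max_len` are over
#' the segment lengths before merging.
#'
#' @param segments Tibble/data.frame with `start`, `end` (0-based half-open),
#'   or a two-column matrix.
#' @param genome_length Genome length (must be positive).
#' @return One-row tibble: `count`, `min_len`, `max_len`, `covered_bp`,
#'   `percent`.
#' @export
quantify_segments <- function(segments, genome_length) {
  if (genome_length <= 0) abort("genome_length must be positive")
  if (is.matrix(segments))
    segments <- tibble(start = segments[, 1], end = segments[, 2])
  n <- nrow(segments)
  if (n == 0L)
    return(tibble(count = 0L, min_len = NA_integer_, max_len = NA_integer_,
                  covered_bp = 0L, percent = 0))
  stopifnot(all(segments$start >= 0), all(segments$end <= genome_length))
  lens <- segments$end - segments$start
  covered <- interval_union_bp(segments$start, segments$end)
  tibble(count = n, min_len = as.integer(min(lens)),
         max_len = as.integer(max(lens)),
         covered_bp = as.integer(covered),
         percent = round_half_up(100 * covered / genome_length, 1L))
}

#' Plastid genes carried (nearly) full length by MIPTs
#'
#' A plastid gene is reported when at least `nearly_full_length` (default
#' 0.90) of its length falls inside the plastome source segments of a single
#' MIPT; its mitogenome copy is then extracted and classified with the
#' pseudogene classifier.
#'
#' @param mipts Output of [find_mipts()].
#' @param plastid_genes Tibble of plastid gene annotations: `gene`, `start`,
#'   `end` (plastome coordinates), `residues` (reference CDS), optional
#'   domain columns.
#' @param mitogenome,plastome The genome sequences.
#' @param config [detection_config()].
#' @param classifier [classifier_config()].
#' @return Tibble: `gene`, `mipt_id`, `containment`, `status`,
#'   `overall_fraction`.
#' @export
genes_in_mipts <- function(mipts, plastid_genes, mitogenome, plastome,
                           config = detection_config(),
                           classifier = classifier_config()) {
  mseq <- toupper(get_residues(mitogenome, "mitogenome"))
  out <- list()
  for (g in seq_len(nrow(plastid_genes))) {
    gene <- plastid_genes[g, ]
    glen <- gene$end - gene$start
    for (k in seq_len(nrow(mipts))) {
      src <- mipts$source[[k]]
      ov <- pmax(0L, pmin(src$end, gene$end) - pmax(src$start, gene$start))
      containment <- interval_union_bp(
        pmax(src$start, gene$start)[ov > 0],
        pmin(src$end, gene$end)[ov > 0]) / glen
      if (containment < classifier$nearly_full_length) next
      region <- substr(mseq, mipts$start[k] + 1L, mipts$end[k])
      params <- config$align
      params$min_raw_score <- 50L
      hits <- local_align(gene$residues, region, params = params)
      if (nrow(hits) == 0L) next
      cand <- extract_candidate(region, hits, nchar(gene$residues))
      domains <- NULL
      if (all(c("domain_start", "domain_end") %in% names(gene)))
        domains <- tibble(start = gene$domain_start, end = gene$domain_end)
      call <- classify_gene(cand, gene$residues, domains = domains,
                            config = classifier, gene = gene$gene,
                            params = config$align)
      out[[length(out) + 1L]] <- tibble(
        gene = gene$gene, mipt_id = mipts$mipt_id[k],
        containment = containment, status = call$status,
        overall_fraction = call$overall_fraction)
      break
    }
  }
  if (!length(out))
    return(tibble(gene = character(), mipt_id = character(),
                  containment = double(), status = character(),
                  overall_fraction = double()))
  bind_rows(out)
}

#' Find dispersed repeats by genome self-alignment
#'
#' The genome is aligned against itself on both strands. The trivial
#' full-length self-hit and coincident copies are excluded, symmetric
#' duplicates are canonicalised (first copy precedes the second in genome
#' order), and pairs shorter than `repeat_min_len` or below
#' `repeat_min_identity` are discarded.
#'
#' @param genome Sequence tibble (single row) or DNA string.
#' @param config [detection_config()].
#' @return Tibble: `repeat_id`, `a_start`, `a_end`, `b_start`, `b_end`,
#'   `length` (alignment length), `identity`, `orientation`
#'   (`direct`/`inverted`).
#' @export
find_repeats <- function(genome, config = detection_config()) {
  gseq <- toupper(get_residues(genome, "genome"))
  params <- config$align
  # a 50-bp copy at the 0.90 identity floor scores 75; leave headroom for gaps
  params$min_raw_score <- params$min_raw_score %||% 60L
  hits <- local_align(gseq, gseq, params = params, self = TRUE)
  hits <- hits[hits$aln_length >= config$repeat_min_len &
                 hits$identity >= config$repeat_min_identity, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty_repeats())
  hits <- arrange(hits, .data$q_start, .data$s_start)
  tibble(repeat_id = sprintf("rep%03d", seq_len(nrow(hits))),
         a_start = hits$q_start, a_end = hits$q_end,
         b_start = hits$s_start, b_end = hits$s_end,
         length = hits$aln_length, identity = hits$identity,
         orientation = ifelse(hits$strand == "+", "direct", "inverted"))
}

empty_repeats <- function() {
  tibble(repeat_id = character(), a_start = integer(), a_end = integer(),
         b_start = integer(), b_end = integer(), length = integer(),
         identity = double(), orientation = character())
}

#' Summarise repeats by size class and genome coverage
#'
#' Each repeat pair is assigned to the half-open size bin containing its
#' length; coverage is computed over the union of all copy intervals with
#' [quantify_segments()].
#'
#' @param pairs Output of [find_repeats()].
#' @param genome_length Genome length in bp.
#' @param config [detection_config()].
#' @return One-row tibble: `n_small`, `n_intermediate`, `n_large`, plus the
#'   [quantify_segments()] columns over all copies.
#' @export
summarize_repeats <- function(pairs, genome_length,
                              config = detection_config()) {
  bins <- config$size_bins
  n_small <- sum(pairs$length >= bins[["small"]] &
                   pairs$length < bins[["intermediate"]])
  n_int <- sum(pairs$length >= bins[["intermediate"]] &
                 pairs$length < bins[["large"]])
  n_large <- sum(pairs$length >= bins[["large"]])
  copies <- tibble(start = c(pairs$a_start, pairs$b_start),
                   end = c(pairs$a_end, pairs$b_end))
  stats <- quantify_segments(copies, genome_length)
  bind_cols(tibble(n_small = n_small, n_intermediate = n_int,
                   n_large = n_large), stats)
}
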