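# Loss-of-function detection for a candidate gene copy against a functional
# reference CDS, and classification of functional status by explicit
# disruption thresholds: a gene is called a pseudogene when mutations disrupt
# more than 20% of its conserved domain structure or more than 30% of the
# gene overall; a copy whose only defect is a 20-30% truncation is scored
# tentative ("present but possibly a pseudogene").

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Classifier configuration
#'
#' @param domain_threshold Pseudogene call when the disrupted fraction of the
#'   conserved-domain positions exceeds this (strict `>`). Default 0.20.
#' @param overall_threshold Pseudogene call when the disrupted fraction of
#'   the whole gene exceeds this (strict `>`). Default 0.30.
#' @param tentative_band Inclusive truncation band scored "tentative" when no
#'   pseudogene threshold is crossed.
#' @param nearly_full_length Containment fraction above which a plastid gene
#'   counts as carried (nearly) full-length by an insertion. Default 0.90.
#' @param homopolymer_min_run Minimum mononucleotide-run length for a
#'   frameshift to be eligible for the sequencing-artifact check.
#' @param artifact_support_fraction A frameshift inside a qualifying run is
#'   called an artifact when fewer than this fraction of covering reads carry
#'   the indel.
#' @param min_covering_reads Minimum covering reads for the artifact check to
#'   apply.
#' @param genetic_code Only `"standard"` is supported; RNA editing is not
#'   modelled.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(domain_threshold = 0.20,
                              overall_threshold = 0.30,
                              tentative_band = c(0.20, 0.30),
                              nearly_full_length = 0.90,
                              homopolymer_min_run = 4L,
                              artifact_support_fraction = 0.80,
                              min_covering_reads = 3L,
                              genetic_code = "standard") {
  stopifnot(domain_threshold > 0, domain_threshold < overall_threshold,
            overall_threshold < 1)
  genetic_code <- match.arg(genetic_code)
  structure(list(domain_threshold = domain_threshold,
                 overall_threshold = overall_threshold,
                 tentative_band = tentative_band,
                 nearly_full_length = nearly_full_length,
                 homopolymer_min_run = as.integer(homopolymer_min_run),
                 artifact_support_fraction = artifact_support_fraction,
                 min_covering_reads = as.integer(min_covering_reads),
                 genetic_code = genetic_code),
            class = "classifier_config")
}

validate_reference_cds <- function(residues, gene = "reference") {
  n <- nchar(residues)
  if (n %% 3L != 0L)
    abort(sprintf("%s: CDS length %d is not a multiple of 3", gene, n))
  if (substr(residues, 1L, 3L) != "ATG")
    abort(sprintf("%s: CDS must start with ATG", gene))
  if (!substr(residues, n - 2L, n) %in% STOP_CODONS)
    abort(sprintf("%s: CDS must end with a stop codon", gene))
  codons <- substring(residues, seq(1L, n - 3L, by = 3L), seq(3L, n, by = 3L))
  internal <- codons[-length(codons)]
  if (any(internal %in% STOP_CODONS))
    abort(sprintf("%s: CDS contains an internal in-frame stop codon", gene))
  invisible(residues)
}

empty_disruptions <- function() {
  tibble(kind = character(), ref_start = integer(), ref_end = integer(),
         indel_len = integer(), indel_type = character(),
         in_frame = logical(), in_homopolymer = logical(),
         homopolymer_len = integer())
}

#' Detect loss-of-function disruptions in a candidate gene copy
#'
#' The candidate is aligned semi-globally to the reference CDS (reference end
#' gaps free). Alignment gaps whose length is not a multiple of three become
#' frameshifts; in-frame deletions are recorded as `internal_deletion`;
#' unaligned reference ends become `truncation5`/`truncation3`. The candidate
#' is then translated codon-by-codon in the reading frame implied by the
#' reference (frame changes at indels tracked through the alignment), and
#' every stop codon strictly before the reference terminal stop is recorded
#' as `premature_stop` with an `in_frame` flag saying whether the stop is
#' reached in the original reference frame. Each frameshift is annotated with
#' the length of the mononucleotide run containing it, for the
#' pyrosequencing-artifact check.
#'
#' @param candidate Candidate DNA string (or single-row sequence tibble).
#' @param reference Reference CDS string: must start `ATG`, end with a stop,
#'   length a multiple of 3, no internal in-frame stop.
#' @param config [classifier_config()].
#' @param params [align_params()] used for the alignment.
#' @return A disruption tibble: `kind` (`frameshift`, `premature_stop`,
#'   `truncation5`, `truncation3`, `internal_deletion`), `ref_start`,
#'   `ref_end` (0-based half-open reference coordinates), `indel_len`,
#'   `indel_type`, `in_frame`, `in_homopolymer`, `homopolymer_len`.
#' @export
detect_disruptions <- function(candidate, reference,
                               config = classifier_config(),
                               params = align_params()) {
  cand <- toupper(get_residues(candidate, "candidate"))
  ref <- toupper(get_residues(reference, "reference"))
  validate_reference_cds(ref)
  L <- nchar(ref)
  if (cand == ref) return(empty_disruptions())
  aln <- global_align(ref, cand, params)
  cols <- tidy(aln)
  out <- list()

  # truncations: unaligned reference ends
  if (aln$ref_start > 0L)
    out[[length(out) + 1L]] <- tibble(
      kind = "truncation5", ref_start = 0L, ref_end = aln$ref_start,
      indel_len = NA_integer_, indel_type = NA_character_, in_frame = NA,
      in_homopolymer = FALSE, homopolymer_len = 0L)
  if (aln$ref_end < L)
    out[[length(out) + 1L]] <- tibble(
      kind = "truncation3", ref_start = aln$ref_end, ref_end = L,
      indel_len = NA_integer_, indel_type = NA_character_, in_frame = NA,
      in_homopolymer = FALSE, homopolymer_len = 0L)

  # indels: runs of gap columns
  gap_q <- is.na(cols$qry_pos)  # deletion relative to reference
  gap_r <- is.na(cols$ref_pos)  # insertion in candidate
  for (type in c("del", "ins")) {
    g <- if (type == "del") gap_q else gap_r
    if (!any(g)) next
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      len <- r$lengths[k]
      first_col <- starts[k]
      if (type == "del") {
        rs <- cols$ref_pos[first_col]
        re <- rs + len
        hp_pos <- rs
        hp_len <- homopolymer_run_at(ref, hp_pos)
      } else {
        # ref position where the insertion occurs = next aligned ref position
        after <- cols$ref_pos[seq(ends[k] + 1L, nrow(cols))]
        rs <- if (any(!is.na(after))) after[!is.na(after)][1] else L
        re <- rs
        ins_base_q <- cols$qry_pos[first_col]
        hp_len <- homopolymer_run_at(cand, ins_base_q)
      }
      if (len %% 3L != 0L) {
        out[[length(out) + 1L]] <- tibble(
          kind = "frameshift", ref_start = as.integer(rs),
          ref_end = as.integer(max(re, rs + 1L)),
          indel_len = as.integer(len), indel_type = type, in_frame = NA,
          in_homopolymer = hp_len >= config$homopolymer_min_run,
          homopolymer_len = as.integer(hp_len))
      } else if (type == "del") {
        out[[length(out) + 1L]] <- tibble(
          kind = "internal_deletion", ref_start = as.integer(rs),
          ref_end = as.integer(re),
          indel_len = as.integer(len), indel_type = type, in_frame = NA,
          in_homopolymer = FALSE, homopolymer_len = 0L)
      }
    }
  }

  # premature stops: translate the aligned candidate contiguously, mapping
  # each codon start to its reference position through the alignment
  aligned_q <- which(!is.na(cols$qry_pos))
  q_chars <- cols$qry_char[aligned_q]
  q_refpos <- vapply(seq_along(aligned_q), function(i) {
    rp <- cols$ref_pos[aligned_q[i]]
    if (!is.na(rp)) return(rp)
    # inserted base: use next aligned reference position
    later <- cols$ref_pos[seq(aligned_q[i], nrow(cols))]
    lat <- later[!is.na(later)]
    if (length(lat)) lat[1] else L
  }, integer(1))
  # first codon starts at the first candidate base whose reference position
  # is a codon boundary
  start_i <- which(q_refpos %% 3L == 0L)
  if (length(start_i)) {
    i0 <- start_i[1]
    nq <- length(q_chars)
    i <- i0
    while (i + 2L <= nq) {
      codon <- paste0(q_chars[i], q_chars[i + 1L], q_chars[i + 2L])
      rp <- q_refpos[i]
      if (codon %in% STOP_CODONS && rp < L - 3L) {
        out[[length(out) + 1L]] <- tibble(
          kind = "premature_stop", ref_start = as.integer(rp),
          ref_end = as.integer(rp + 3L),
          indel_len = NA_integer_, indel_type = NA_character_,
          in_frame = (rp %% 3L == 0L),
          in_homopolymer = FALSE, homopolymer_len = 0L)
      }
      i <- i + 3L
    }
  }

  if (!length(out)) return(empty_disruptions())
  bind_rows(out) |> arrange(.data$ref_start, .data$kind)
}

#' Disrupted-position fractions from a disruption list
#'
#' Disrupted positions are the union of (i) truncated reference positions,
#' (ii) positions from each frame-breaking indel to the next compensating
#' indel that restores the reading frame (or to the gene end), and (iii)
#' positions downstream of the first premature stop reached in frame.
#' `overall_fraction` divides by the reference length, `domain_fraction` by
#' the total domain length (0 when no domains are supplied), and
#' `truncated_fraction` counts only (i).
#'
#' @param disruptions Disruption tibble from [detect_disruptions()].
#' @param ref_length Reference CDS length in nucleotides.
#' @param domains Optional tibble/data.frame of domain segments with `start`,
#'   `end` (0-based half-open, within the reference).
#' @return A one-row tibble: `domain_fraction`, `overall_fraction`,
#'   `truncated_fraction`.
#' @export
disruption_fractions <- function(disruptions, ref_length, domains = NULL) {
  L <- as.integer(ref_length)
  if (!is.null(domains) && nrow(domains) > 0L) {
    stopifnot(all(domains$start >= 0L), all(domains$end <= L))
  }
  pos <- logical(L)
  trunc_pos <- logical(L)
  d <- disruptions
  # (i) truncations
  tr <- d[d$kind %in% c("truncation5", "truncation3"), , drop = FALSE]
  if (nrow(tr)) for (k in seq_len(nrow(tr))) {
    idx <- seq(tr$ref_start[k] + 1L, tr$ref_end[k])
    pos[idx] <- TRUE; trunc_pos[idx] <- TRUE
  }
  # (ii) frameshift intervals until frame restoration
  fs <- d[d$kind == "frameshift", , drop = FALSE]
  if (nrow(fs)) {
    fs <- fs[order(fs$ref_start), , drop = FALSE]
    shift <- ifelse(fs$indel_type == "ins", fs$indel_len, -fs$indel_len)
    offset <- 0L
    open_at <- NA_integer_
    for (k in seq_len(nrow(fs))) {
      prev <- offset
      offset <- (offset + shift[k]) %% 3L
      if (prev == 0L && offset != 0L) open_at <- fs$ref_start[k]
      if (prev != 0L && offset == 0L && !is.na(open_at)) {
        if (fs$ref_start[k] > open_at)
          pos[seq(open_at + 1L, fs$ref_start[k])] <- TRUE
        open_at <- NA_integer_
      }
    }
    if (!is.na(open_at) && open_at < L)
      pos[seq(open_at + 1L, L)] <- TRUE
  }
  # (iii) downstream of the first in-frame premature stop
  ps <- d[d$kind == "premature_stop", , drop = FALSE]
  if (nrow(ps)) {
    inf <- ps$in_frame
    if (all(is.na(inf))) {
      # derive frame parity at each stop from the frameshift walk
      inf <- vapply(ps$ref_start, function(p) {
        if (!nrow(fs)) return(TRUE)
        before <- fs[fs$ref_start <= p, , drop = FALSE]
        if (!nrow(before)) return(TRUE)
        sh <- ifelse(before$indel_type == "ins", before$indel_len,
                     -before$indel_len)
        sum(sh) %% 3L == 0L
      }, logical(1))
    }
    inframe <- ps[which(inf %in% TRUE), , drop = FALSE]
    if (nrow(inframe)) {
      first <- min(inframe$ref_end)
      if (first < L) pos[seq(first + 1L, L)] <- TRUE
    }
  }
  overall <- sum(pos) / L
  truncated <- sum(trunc_pos) / L
  domain <- 0
  if (!is.null(domains) && nrow(domains) > 0L) {
    dpos <- logical(L)
    for (k in seq_len(nrow(domains)))
      dpos[seq(domains$start[k] + 1L, domains$end[k])] <- TRUE
    domain <- sum(pos & dpos) / sum(dpos)
  }
  tibble(domain_fraction = domain, overall_fraction = overall,
         truncated_fraction = truncated)
}

#' Mononucleotide-repeat sequencing-artifact check for a frameshift
#'
#' Pyrosequencing mis-calls homopolymer lengths; a frameshift lying inside a
#' mononucleotide run of at least `homopolymer_min_run` bases is called an
#' artifact when enough reads cover the site (`>= min_covering_reads`) but
#' fewer than `artifact_support_fraction` of them carry the indel.
#' Frameshifts outside qualifying runs are always supported. An in-run
#' frameshift without read support is kept (supported) with a warning.
#'
#' @param disruption One-row disruption tibble (a frameshift).
#' @param read_support `NULL`, or a list/one-row tibble with
#'   `covering_reads` and `reads_with_indel`.
#' @param config [classifier_config()].
#' @return `"supported"` or `"artifact"`.
#' @export
homopolymer_artifact_check <- function(disruption, read_support = NULL,
                                       config = classifier_config()) {
  if (disruption$kind != "frameshift")
    abort("artifact check applies to frameshifts only")
  if (disruption$homopolymer_len < config$homopolymer_min_run)
    return("supported")
  if (is.null(read_support)) {
    warn(sprintf(
      "frameshift at %d lies in a %d-bp mononucleotide run but no read support was given; keeping it",
      disruption$ref_start, disruption$homopolymer_len))
    return("supported")
  }
  cov <- read_support$covering_reads
  with_indel <- read_support$reads_with_indel
  if (cov >= config$min_covering_reads &&
      with_indel / cov < config$artifact_support_fraction)
    return("artifact")
  "supported"
}

#' Classify a candidate gene copy as functional, tentative or pseudogene
#'
#' Runs [detect_disruptions()], drops frameshifts flagged as homopolymer
#' sequencing artifacts by [homopolymer_artifact_check()], computes the
#' disrupted fractions, and applies the thresholds: pseudogene when the
#' domain fraction exceeds `domain_threshold` or the overall fraction exceeds
#' `overall_threshold` (both strict); otherwise tentative when the truncated
#' fraction lies in the inclusive `tentative_band`; otherwise functional.
#'
#' @param candidate Candidate DNA string or single-row sequence tibble.
#' @param reference Reference CDS (string, single-row tibble, or a list with
#'   `residues` and optional `domains`).
#' @param domains Optional domain-segment tibble (`start`, `end`, 0-based
#'   half-open); overrides any domains carried by `reference`.
#' @param config [classifier_config()].
#' @param read_support Optional tibble mapping frameshifts to read evidence:
#'   columns `ref_start`, `covering_reads`, `reads_with_indel` (matched to
#'   frameshifts by reference position, +/- 2 bp).
#' @param gene Gene name for reporting.
#' @param params [align_params()].
#' @return An object of class `pseudogene_call`: a list with `gene`,
#'   `status`, the disruption tibble and the three fractions. `tidy()`
#'   returns the disruptions, `glance()` a one-row summary.
#' @export
classify_gene <- function(candidate, reference, domains = NULL,
                          config = classifier_config(), read_support = NULL,
                          gene = NULL, params = align_params()) {
  if (is.null(domains) && is.list(reference) && !is.data.frame(reference) &&
      !is.null(reference$domains))
    domains <- reference$domains
  if (is.null(domains) && is.data.frame(reference) &&
      all(c("domain_start", "domain_end") %in% names(reference)))
    domains <- tibble(start = reference$domain_start, end = reference$domain_end)
  gene <- gene %||% get_seq_id(reference, "gene")
  ref <- toupper(get_residues(reference, "reference"))
  d <- detect_disruptions(candidate, ref, config, params)
  dropped <- 0L
  if (nrow(d)) {
    keep <- vapply(seq_len(nrow(d)), function(k) {
      row <- d[k, , drop = FALSE]
      if (row$kind != "frameshift" || !row$in_homopolymer) return(TRUE)
      rs <- NULL
      if (!is.null(read_support) && nrow(read_support)) {
        m <- which(abs(read_support$ref_start - row$ref_start) <= 2L)
        if (length(m)) rs <- read_support[m[1], , drop = FALSE]
      }
      homopolymer_artifact_check(row, rs, config) == "supported"
    }, logical(1))
    dropped <- sum(!keep)
    d <- d[keep, , drop = FALSE]
  }
  fr <- disruption_fractions(d, nchar(ref), domains)
  status <- if (fr$domain_fraction > config$domain_threshold ||
                fr$overall_fraction > config$overall_threshold) {
    "pseudogene"
  } else if (fr$truncated_fraction >= config$tentative_band[1] &&
             fr$truncated_fraction <= config$tentative_band[2]) {
    "tentative"
  } else "functional"
  structure(list(gene = gene, status = status, disruptions = d,
                 domain_fraction = fr$domain_fraction,
                 overall_fraction = fr$overall_fraction,
                 truncated_fraction = fr$truncated_fraction,
                 artifacts_dropped = dropped),
            class = "pseudogene_call")
}

#' @export
print.pseudogene_call <- function(x, ...) {
  cat(sprintf("<pseudogene_call> %s: %s (overall %.2f, domain %.2f, truncated %.2f; %d disruption%s)\n",
              x$gene, x$status, x$overall_fraction, x$domain_fraction,
              x$truncated_fraction, nrow(x$disruptions),
              if (nrow(x$disruptions) == 1L) "" else "s"))
  invisible(x)
}

#' @method tidy pseudogene_call
#' @export
tidy.pseudogene_call <- function(x, ...) {
  d <- x$disruptions
  d$gene <- x$gene
  dplyr::relocate(d, "gene")
}

#' @method glance pseudogene_call
#' @export
glance.pseudogene_call <- function(x, ...) {
  tibble(gene = x$gene, status = x$status,
         n_disruptions = nrow(x$disruptions),
         domain_fraction = x$domain_fraction,
         overall_fraction = x$overall_fraction,
         truncated_fraction = x$truncated_fraction,
         artifacts_dropped = x$artifacts_dropped)
}
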