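# Read-pair mapping, link-graph scaffolding, repeat-region inference from
# linkage and depth, coverage profiling and the best-assembly selection
# criterion.

#' Map read pairs onto contigs
#'
#' Each mate is placed at its best filtered hit (e-value, length and identity
#' thresholds as in the scaffolding protocol); mates with no passing hit are
#' left unmapped. Ties are broken by higher score, then lower contig id, then
#' lower coordinate.
#'
#' @param pairs Tibble with `pair_id`, `read1`, `read2` (DNA strings).
#' @param contigs Sequence tibble (`id`, `residues`).
#' @param min_evalue,min_length,min_identity Hit filters (inclusive).
#' @param params [align_params()].
#' @return Tibble with one row per mate: `pair_id`, `mate` (1/2), `contig`,
#'   `start`, `end`, `strand`, `score`, `identity`, `mapped`.
#' @export
map_read_pairs <- function(pairs, contigs, min_evalue = 1e-10,
                           min_length = 90L, min_identity = 0.90,
                           params = align_params()) {
  params$band_width <- min(params$band_width, 16L)
  reads <- c(pairs$read1, pairs$read2)
  n <- nrow(pairs)
  meta <- tibble(pair_id = rep(pairs$pair_id, 2L),
                 mate = rep(c(1L, 2L), each = n))
  best <- NULL
  for (ci in order(contigs$id)) {
    cid <- contigs$id[ci]
    cseq <- toupper(contigs$residues[ci])
    m <- cpp_map_batch(toupper(reads), cseq, params$word_size, params$match,
                       params$mismatch, params$gap_open, params$gap_extend,
                       params$x_drop, params$band_width,
                       as.integer(params$word_size * params$match))
    if (nrow(m) == 0L) next
    m <- as_tibble(m)
    m$contig <- cid
    m$evalue <- karlin_evalue(m$score, nchar(reads[m$query]), nchar(cseq))
    m$identity <- m$matches / m$cols
    keep <- m$evalue <= min_evalue & m$cols >= min_length &
      m$identity >= min_identity
    m <- m[keep, , drop = FALSE]
    if (nrow(m) == 0L) next
    best <- if (is.null(best)) m else bind_rows(best, m)
  }
  placed <- tibble(pair_id = meta$pair_id, mate = meta$mate,
                   contig = NA_character_, start = NA_integer_,
                   end = NA_integer_, strand = NA_character_,
                   score = NA_real_, identity = NA_real_, mapped = FALSE)
  if (!is.null(best) && nrow(best)) {
    best <- best |>
      arrange(.data$query, desc(.data$score), .data$contig, .data$s_start) |>
      dplyr::distinct(.data$query, .keep_all = TRUE)
    placed$contig[best$query] <- best$contig
    placed$start[best$query] <- best$s_start
    placed$end[best$query] <- best$s_end
    placed$strand[best$query] <- best$strand
    placed$score[best$query] <- best$score
    placed$identity[best$query] <- best$identity
    placed$mapped[best$query] <- TRUE
  }
  placed
}

#' Build a contig link graph from read-pair mappings
#'
#' Every pair whose mates map to different contigs votes for an edge joining
#' the implied contig ends: a mate on the forward strand points off the right
#' end of its contig, a reverse-strand mate off the left end. Edges supported
#' by fewer than `min_support` pairs are dropped. The implied gap for an edge
#' is `insert_size` minus the two mate overhangs, taken as the median over
#' supporting pairs.
#'
#' @param mappings Output of [map_read_pairs()].
#' @param contigs Sequence tibble (`id`, `residues`), used for lengths and
#'   per-contig mean depth.
#' @param insert_size Library insert size (bp), used only for gap estimates.
#' @param min_support Minimum spanning pairs per edge.
#' @return A list of class `contig_graph`: `nodes` (contig, length,
#'   mean_depth) and `edges` (`end_a`, `end_b`, `support`, `median_gap`).
#' @export
build_link_graph <- function(mappings, contigs, insert_size = 800,
                             min_support = 2L) {
  lens <- setNames(nchar(contigs$residues), contigs$id)
  mapped <- mappings[mappings$mapped, , drop = FALSE]
  depth <- mapped |>
    group_by(contig = .data$contig) |>
    summarise(bases = sum(.data$end - .data$start), .groups = "drop")
  nodes <- tibble(contig = contigs$id, length = unname(lens)) |>
    left_join(depth, by = "contig") |>
    mutate(mean_depth = dplyr::coalesce(.data$bases, 0L) / .data$length) |>
    select("contig", "length", "mean_depth")
  wide <- mapped |>
    select("pair_id", "mate", "contig", "start", "end", "strand") |>
    tidyr::pivot_wider(names_from = "mate",
                       values_from = c("contig", "start", "end", "strand"))
  if (!all(c("contig_1", "contig_2") %in% names(wide)))
    return(new_contig_graph(nodes, empty_edges()))
  span <- wide[!is.na(wide$contig_1) & !is.na(wide$contig_2) &
                 wide$contig_1 != wide$contig_2, , drop = FALSE]
  if (nrow(span) == 0L) return(new_contig_graph(nodes, empty_edges()))
  end_of <- function(contig, strand) {
    ifelse(strand == "+", paste0(contig, ":R"), paste0(contig, ":L"))
  }
  overhang <- function(contig, start, end, strand) {
    ifelse(strand == "+", lens[contig] - start, end)
  }
  e1 <- end_of(span$contig_1, span$strand_1)
  e2 <- end_of(span$contig_2, span$strand_2)
  gap <- insert_size -
    overhang(span$contig_1, span$start_1, span$end_1, span$strand_1) -
    overhang(span$contig_2, span$start_2, span$end_2, span$strand_2)
  key_a <- pmin(e1, e2); key_b <- pmax(e1, e2)
  edges <- tibble(end_a = key_a, end_b = key_b, gap = gap) |>
    group_by(.data$end_a, .data$end_b) |>
    summarise(support = dplyr::n(), median_gap = median(.data$gap),
              .groups = "drop") |>
    filter(.data$support >= min_support) |>
    arrange(.data$end_a, .data$end_b)
  new_contig_graph(nodes, edges)
}

empty_edges <- function() {
  tibble(end_a = character(), end_b = character(), support = integer(),
         median_gap = double())
}

new_contig_graph <- function(nodes, edges) {
  structure(list(nodes = arrange(nodes, .data$contig), edges = edges),
            class = "contig_graph")
}

#' @export
print.contig_graph <- function(x, ...) {
  cat(sprintf("<contig_graph> %d contigs, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

end_contig <- function(end) sub(":[LR]$", "", end)

#' Infer scaffold joins and repeat contigs from a link graph
#'
#' Contig ends with exactly one passing edge are joined. A contig is flagged
#' as a repeat when one of its ends has edges to two or more distinct
#' partners, or when its mean depth is at least `depth_flag` times the median
#' contig depth (a collapsed multi-copy region carries proportionally more
#' reads). Flagged contigs break scaffold paths; the output paths are maximal
#' simple chains in deterministic order.
#'
#' @param graph A `contig_graph`.
#' @param depth_flag Depth multiple of the median that flags a repeat.
#' @return A list: `scaffolds` (tibble `scaffold`, `position`, `contig`,
#'   `orientation`, `gap_after`) and `repeat_flags` (tibble `contig`,
#'   `by_linkage`, `by_depth`, `flagged`).
#' @export
infer_joins <- function(graph, depth_flag = 1.5) {
  nodes <- graph$nodes
  edges <- graph$edges
  end_degree <- table(c(edges$end_a, edges$end_b))
  partner_count <- c(tapply(end_contig(edges$end_b), edges$end_a,
                            function(x) length(unique(x))),
                     tapply(end_contig(edges$end_a), edges$end_b,
                            function(x) length(unique(x))))
  multi_ends <- names(partner_count)[partner_count >= 2]
  by_linkage <- nodes$contig %in% unique(end_contig(multi_ends))
  med <- median(nodes$mean_depth)
  by_depth <- med > 0 & nodes$mean_depth >= depth_flag * med
  flags <- tibble(contig = nodes$contig, by_linkage = by_linkage,
                  by_depth = by_depth,
                  flagged = by_linkage | by_depth)
  flagged <- flags$contig[flags$flagged]
  # usable joins: both ends unique and neither contig flagged
  usable <- edges[
    edges$end_a %in% names(end_degree)[end_degree == 1] &
      edges$end_b %in% names(end_degree)[end_degree == 1] &
      !(end_contig(edges$end_a) %in% flagged) &
      !(end_contig(edges$end_b) %in% flagged), , drop = FALSE]
  # build chains
  link <- setNames(as.list(usable$end_b), usable$end_a)
  link <- c(link, setNames(as.list(usable$end_a), usable$end_b))
  gaps <- setNames(as.list(usable$median_gap),
                   paste(usable$end_a, usable$end_b))
  gap_for <- function(a, b) {
    g <- gaps[[paste(min(a, b), max(a, b))]]
    if (is.null(g)) NA_real_ else g
  }
  visited <- character()
  scaffolds <- list()
  other_end <- function(end) {
    c0 <- end_contig(end)
    paste0(c0, if (endsWith(end, ":L")) ":R" else ":L")
  }
  ordered <- sort(nodes$contig)
  has_free_end <- vapply(ordered, function(ctg) {
    ends <- paste0(ctg, c(":L", ":R"))
    any(!ends %in% names(link))
  }, logical(1))
  # chains are started from free ends; anything left after that is a cycle
  for (ctg in c(ordered[has_free_end], ordered[!has_free_end])) {
    if (ctg %in% visited) next
    if (ctg %in% flagged) { visited <- c(visited, ctg); next }
    ends <- paste0(ctg, c(":L", ":R"))
    free <- ends[!ends %in% names(link)]
    start_end <- if (length(free)) free[1] else ends[1]
    chain <- tibble(contig = character(), orientation = character(),
                    gap_after = double())
    cur_entry <- start_end
    repeat {
      c0 <- end_contig(cur_entry)
      if (c0 %in% visited) break
      visited <- c(visited, c0)
      orient <- if (endsWith(cur_entry, ":L")) "+" else "-"
      exit_end <- other_end(cur_entry)
      nxt <- link[[exit_end]]
      chain <- bind_rows(chain, tibble(
        contig = c0, orientation = orient,
        gap_after = if (is.null(nxt)) NA_real_ else gap_for(exit_end, nxt)))
      if (is.null(nxt)) break
      cur_entry <- nxt
    }
    scaffolds[[length(scaffolds) + 1L]] <- chain
  }
  sc <- imap(scaffolds, function(ch, i)
    mutate(ch, scaffold = sprintf("scaffold%02d", i),
           position = seq_len(nrow(ch)))) |>
    bind_rows() |>
    select("scaffold", "position", "contig", "orientation", "gap_after")
  list(scaffolds = sc, repeat_flags = flags)
}

#' Per-position coverage from read placements
#'
#' @param placements Tibble with `start`, `end` (0-based half-open genome
#'   coordinates; `end` may exceed the genome length for placements wrapping
#'   the origin of a circular genome).
#' @param genome Sequence tibble (single row) or DNA string.
#' @param circular Whether placements may wrap the origin.
#' @return A coverage track tibble (`seq_id`, `pos`, `depth`).
#' @export
coverage_profile <- function(placements, genome, circular = TRUE) {
  gseq <- get_residues(genome, "genome")
  L <- nchar(gseq)
  st <- placements$start; en <- placements$end
  stopifnot(all(st >= 0), all(st < L), all(en > st))
  if (any(en > L) && !circular) abort("placement beyond a linear genome end")
  wrap <- en > L
  st2 <- c(st[!wrap], st[wrap], rep(0L, sum(wrap)))
  en2 <- c(en[!wrap], rep(L, sum(wrap)), en[wrap] - L)
  keep <- en2 > st2
  cov <- IRanges::coverage(IRanges::IRanges(start = st2[keep] + 1L,
                                            end = en2[keep]), width = L)
  new_coverage_track(get_seq_id(genome, "genome"), as.integer(cov))
}

#' Depth ratio of a region over a background
#'
#' Mean depth over the region divided by mean depth over the background
#' intervals (default: the complement of the region). A collapsed two-copy
#' repeat shows a ratio near 2.
#'
#' @param track Coverage track tibble.
#' @param region Length-2 vector `c(start, end)`, 0-based half-open.
#' @param background Optional tibble of intervals (`start`, `end`); `NULL`
#'   means everything outside `region`.
#' @return A single number.
#' @export
depth_ratio <- function(track, region, background = NULL) {
  L <- nrow(track)
  stopifnot(region[1] >= 0, region[2] <= L, region[2] > region[1])
  in_region <- track$pos >= region[1] & track$pos < region[2]
  if (is.null(background)) {
    in_bg <- !in_region
  } else {
    in_bg <- rep(FALSE, L)
    for (k in seq_len(nrow(background)))
      in_bg <- in_bg | (track$pos >= background$start[k] &
                          track$pos < background$end[k])
  }
  if (!any(in_bg)) abort("empty background")
  bg <- mean(track$depth[in_bg])
  if (bg == 0) abort("zero background depth")
  mean(track$depth[in_region]) / bg
}

#' Select the best assembly
#'
#' Lexicographic criterion: maximal organellar length first, ties broken by
#' the fewest contigs, remaining ties by input order.
#'
#' @param stats Tibble with `assembly_id`, `organellar_bp`, `n_contigs`.
#' @return The chosen `assembly_id`.
#' @export
select_best_assembly <- function(stats) {
  if (is.null(stats) || nrow(stats) == 0L) abort("no assemblies to choose from")
  ord <- order(-stats$organellar_bp, stats$n_contigs)
  stats$assembly_id[ord[1]]
}
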