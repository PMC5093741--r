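# Gene and intron presence scoring across taxa and construction of the
# content matrix: present (+), lost (-), pseudogene (psi), intron missing
# because its host gene is lost (x), tentatively present (+*, truncated by
# 20-30%), and pseudogene with retained intron remnant (psi-r).

CALL_LEVELS <- c("present", "lost", "pseudogene", "intron_host_lost",
                 "tentative", "remnant")

CALL_GLYPHS <- c(present = "+", lost = "-", pseudogene = "ψ",
                 intron_host_lost = "x", tentative = "+*",
                 remnant = "ψr")

call_to_glyph <- function(call) unname(CALL_GLYPHS[call])

glyph_to_call <- function(glyph) {
  m <- setNames(names(CALL_GLYPHS), CALL_GLYPHS)
  out <- unname(m[glyph])
  if (anyNA(out)) abort(sprintf("unknown content glyph: %s",
                                glyph[is.na(out)][1]))
  out
}

#' Content-scoring configuration
#'
#' Hit-filter thresholds follow the standard search settings (e-value 1e-10,
#' 90 bp, 90% identity). A gene whose filtered hits cover less than
#' `detection_min_fraction` of the reference is scored lost rather than
#' pseudogenized; references shorter than `short_gene_warn` bp trigger a
#' caution (non-detection of very short genes may be an assembly artifact).
#' Intron presence is anchored on exact exon-flank matches of
#' `intron_anchor_len` bp; a cis intron counts as detected when the sequence
#' between its anchors is at least `intron_min_fraction` of the reference
#' intron length.
#'
#' @param min_evalue,min_hit_length,min_identity Hit filters (inclusive).
#' @param detection_min_fraction Reference coverage floor for detectability.
#' @param intron_anchor_len Exact exon-flank anchor length (bp).
#' @param intron_min_fraction Minimum intervening-length fraction for a
#'   detected intron.
#' @param short_gene_warn Reference length below which a "lost" call warns.
#' @param classifier [classifier_config()].
#' @param align [align_params()].
#' @return A list of class `content_config`.
#' @export
content_config <- function(min_evalue = 1e-10, min_hit_length = 90L,
                           min_identity = 0.90,
                           detection_min_fraction = 0.30,
                           intron_anchor_len = 20L,
                           intron_min_fraction = 0.30,
                           short_gene_warn = 300L,
                           classifier = classifier_config(),
                           align = align_params()) {
  structure(list(min_evalue = min_evalue,
                 min_hit_length = as.integer(min_hit_length),
                 min_identity = min_identity,
                 detection_min_fraction = detection_min_fraction,
                 intron_anchor_len = as.integer(intron_anchor_len),
                 intron_min_fraction = intron_min_fraction,
                 short_gene_warn = as.integer(short_gene_warn),
                 classifier = classifier, align = align),
            class = "content_config")
}

#' Score presence of one gene in one genome
#'
#' The reference CDS is searched against the genome; if no filtered hit set
#' covers at least `detection_min_fraction` of the reference the gene is
#' scored `lost`. Otherwise the candidate locus is extracted (reverse
#' complemented for minus-strand loci) and classified with [classify_gene()]:
#' functional copies are `present`, 20-30% truncated copies `tentative`,
#' threshold-crossing copies `pseudogene`.
#'
#' @param genome Genome sequence (single-row tibble or string).
#' @param ref_gene Reference gene: a single-row tibble from a gene set
#'   (columns `gene`, `residues`, optionally `domain_start`/`domain_end`) or
#'   a list with `residues` (+ optional `domains`).
#' @param config [content_config()].
#' @return One-row tibble: `element`, `type = "gene"`, `call`, `glyph`,
#'   `coverage`, plus the classifier fractions (NA when lost).
#' @export
score_gene <- function(genome, ref_gene, config = content_config()) {
  ref <- toupper(get_residues(ref_gene, "reference gene"))
  gname <- if (is.data.frame(ref_gene) && "gene" %in% names(ref_gene)) {
    ref_gene$gene
  } else if (is.data.frame(ref_gene) && "name" %in% names(ref_gene)) {
    ref_gene$name
  } else get_seq_id(ref_gene, "gene")
  gseq <- toupper(get_residues(genome, "genome"))
  L <- nchar(ref)
  hits <- local_align(ref, gseq, params = config$align)
  hits <- filter_hits(hits, config$min_evalue, config$min_hit_length,
                      config$min_identity)
  cov <- if (nrow(hits)) interval_union_bp(hits$q_start, hits$q_end) / L else 0
  if (cov < config$detection_min_fraction) {
    if (L < config$short_gene_warn)
      warn(sprintf(
        "%s: reference is only %d bp; non-detection of very short genes may be an artifact of an incomplete assembly",
        gname, L))
    return(tibble(element = gname, type = "gene", call = "lost",
                  glyph = call_to_glyph("lost"), coverage = cov,
                  status = NA_character_, overall_fraction = NA_real_,
                  domain_fraction = NA_real_, truncated_fraction = NA_real_))
  }
  cand <- extract_candidate(gseq, hits, L)
  domains <- NULL
  if (is.data.frame(ref_gene) &&
      all(c("domain_start", "domain_end") %in% names(ref_gene)))
    domains <- tibble(start = ref_gene$domain_start, end = ref_gene$domain_end)
  if (is.list(ref_gene) && !is.data.frame(ref_gene) &&
      !is.null(ref_gene$domains))
    domains <- ref_gene$domains
  cls <- classify_gene(cand, ref, domains = domains,
                       config = config$classifier, gene = gname,
                       params = config$align)
  code <- switch(cls$status, functional = "present",
                 tentative = "tentative", pseudogene = "pseudogene")
  tibble(element = gname, type = "gene", call = code,
         glyph = call_to_glyph(code), coverage = cov,
         status = cls$status,
         overall_fraction = cls$overall_fraction,
         domain_fraction = cls$domain_fraction,
         truncated_fraction = cls$truncated_fraction)
}

# Extract the candidate locus from the hits around the best one: the subject
# intervals of same-strand hits near the best locus are merged and
# concatenated in genome order, which splices out long intervening sequence
# (an intron, say) while leaving small indels inside hits intact. A
# minus-strand locus is reverse complemented so the candidate reads in the
# reference orientation.
extract_candidate <- function(genome, hits, ref_length) {
  best <- hits[1, ]
  same <- hits[hits$strand == best$strand &
                 hits$s_start < best$s_end + ref_length &
                 hits$s_end > best$s_start - ref_length, , drop = FALSE]
  pieces <- merge_intervals(same$s_start, same$s_end, max_gap = 0L)
  cand <- paste(substring(genome, pieces$start + 1L, pieces$end),
                collapse = "")
  if (best$strand == "-") cand <- revcomp(cand)
  cand
}

#' Score presence of one intron in one genome
#'
#' A missing host gene forces the call `intron_host_lost` ("x"). For a
#' cis-spliced intron, presence is anchored on exact matches of the flanking
#' exon ends; the intron is detected when both anchors are found in order on
#' one strand with at least `intron_min_fraction` of the reference intron
#' length between them. Trans-spliced introns (whose exons are transcribed
#' from separate loci) are detected by direct homology search of the intron
#' sequence. A detected intron in a pseudogenized host is scored `remnant`.
#'
#' @param gene_call Host-gene call: a one-row tibble from [score_gene()] or a
#'   call code string.
#' @param genome Genome sequence.
#' @param intron_ref List or one-row tibble with `name`, `splicing`
#'   (`"cis"`/`"trans"`), `residues` (reference intron sequence), and for cis
#'   introns `left_flank`, `right_flank` (upstream exon 3' end and downstream
#'   exon 5' start).
#' @param config [content_config()].
#' @return One-row tibble: `element`, `type = "intron"`, `call`, `glyph`.
#' @export
score_intron <- function(gene_call, genome, intron_ref,
                         config = content_config()) {
  host_call <- if (is.character(gene_call)) gene_call else gene_call$call
  iname <- if (is.data.frame(intron_ref)) intron_ref$name else intron_ref$name
  row <- function(code) tibble(element = iname, type = "intron", call = code,
                               glyph = call_to_glyph(code))
  if (host_call == "lost") return(row("intron_host_lost"))
  gseq <- toupper(get_residues(genome, "genome"))
  splicing <- if (is.data.frame(intron_ref)) intron_ref$splicing else
    intron_ref$splicing
  detected <- if (identical(splicing, "trans")) {
    iseq <- toupper(if (is.data.frame(intron_ref)) intron_ref$residues else
      intron_ref$residues)
    hits <- local_align(iseq, gseq, params = config$align)
    hits <- filter_hits(hits, config$min_evalue,
                        min(config$min_hit_length, nchar(iseq)),
                        config$min_identity)
    nrow(hits) > 0 &&
      interval_union_bp(hits$q_start, hits$q_end) / nchar(iseq) >=
        config$intron_min_fraction
  } else {
    detect_cis_intron(gseq, intron_ref, config)
  }
  if (!detected) return(row("lost"))
  if (host_call == "pseudogene") return(row("remnant"))
  row("present")
}

detect_cis_intron <- function(gseq, intron_ref, config) {
  lf <- toupper(if (is.data.frame(intron_ref)) intron_ref$left_flank else
    intron_ref$left_flank)
  rf <- toupper(if (is.data.frame(intron_ref)) intron_ref$right_flank else
    intron_ref$right_flank)
  iseq <- toupper(if (is.data.frame(intron_ref)) intron_ref$residues else
    intron_ref$residues)
  al <- config$intron_anchor_len
  lf <- substr(lf, nchar(lf) - al + 1L, nchar(lf))
  rf <- substr(rf, 1L, al)
  min_len <- config$intron_min_fraction * nchar(iseq)
  for (target in c(gseq, revcomp(gseq))) {
    subj <- Biostrings::DNAString(target)
    lpos <- Biostrings::end(Biostrings::matchPattern(lf, subj))       # anchor 3' ends
    rpos <- Biostrings::start(Biostrings::matchPattern(rf, subj))     # anchor 5' starts
    if (length(lpos) && length(rpos)) {
      for (l in lpos) {
        gapn <- rpos[rpos > l] - l - 1L
        if (any(gapn >= min_len)) return(TRUE)
      }
    }
  }
  FALSE
}

#' Build a gene/intron content matrix across taxa
#'
#' Rows follow the input taxon order, columns the registry order (genes then
#' introns); every cell is computed with [score_gene()]/[score_intron()]. The
#' invariant that a lost gene forces `intron_host_lost` for all of its
#' introns is enforced by construction and asserted.
#'
#' @param taxa A tibble with columns `taxon` and `residues` (one genome per
#'   row), or a named list of genome strings.
#' @param registry An element registry (see [element_registry()]), whose gene
#'   table must carry reference `residues` (and intron table the intron
#'   references) for scoring.
#' @param config [content_config()].
#' @return A `content_matrix`: a tibble with columns `taxon`, `element`,
#'   `type`, `call`, `glyph` and the registry stored as an attribute.
#' @export
build_matrix <- function(taxa, registry, config = content_config()) {
  if (!is.data.frame(taxa))
    taxa <- tibble(taxon = names(taxa), residues = unname(unlist(taxa)))
  if (anyDuplicated(taxa$taxon))
    abort("duplicate taxon ids")
  if (nrow(registry$genes) == 0L) abort("registry has no genes")
  cells <- vector("list", nrow(taxa))
  for (t in seq_len(nrow(taxa))) {
    genome <- taxa$residues[t]
    gcalls <- lapply(seq_len(nrow(registry$genes)), function(g)
      score_gene(genome, registry$genes[g, ], config))
    gtab <- bind_rows(gcalls)
    icalls <- lapply(seq_len(nrow(registry$introns %||% tibble())), function(i) {
      iref <- registry$introns[i, ]
      host <- gtab[gtab$element == iref$host, , drop = FALSE]
      hostcall <- if (nrow(host)) host$call[1] else "lost"
      score_intron(hostcall, genome, iref, config)
    })
    cell <- bind_rows(gtab[, c("element", "type", "call", "glyph")],
                      if (length(icalls)) bind_rows(icalls))
    cell$taxon <- taxa$taxon[t]
    cells[[t]] <- cell
  }
  out <- bind_rows(cells) |>
    dplyr::relocate("taxon")
  new_content_matrix(out, registry)
}

new_content_matrix <- function(cells, registry = NULL) {
  elements <- unique(cells$element)
  out <- as_tibble(cells[, c("taxon", "element", "type", "call", "glyph")])
  attr(out, "registry") <- registry
  attr(out, "element_order") <- elements
  class(out) <- c("content_matrix", class(out))
  assert_matrix_invariant(out, registry)
  out
}

assert_matrix_invariant <- function(m, registry) {
  if (is.null(registry) || is.null(registry$introns) ||
      nrow(registry$introns) == 0L) return(invisible(TRUE))
  for (i in seq_len(nrow(registry$introns))) {
    host <- registry$introns$host[i]
    iname <- registry$introns$name[i]
    hc <- m$call[m$type == "gene" & m$element == host]
    ic <- m$call[m$type == "intron" & m$element == iname]
    ht <- m$taxon[m$type == "gene" & m$element == host]
    it <- m$taxon[m$type == "intron" & m$element == iname]
    lost_taxa <- ht[hc == "lost"]
    bad <- it %in% lost_taxa & ic != "intron_host_lost"
    if (any(bad))
      abort(sprintf("matrix invariant violated: host %s lost but intron %s is not 'x'",
                    host, iname))
  }
  invisible(TRUE)
}

#' Shared-element counts from a content matrix
#'
#' An element is shared when every taxon's cell is `present` or `tentative`.
#' Core genes are those with registry category `"core"`; intron counts are
#' split by cis/trans splicing arrangement.
#'
#' @param matrix A `content_matrix`.
#' @param registry The element registry used to build it (defaults to the one
#'   stored on the matrix).
#' @return A one-row tibble: `shared_genes`, `shared_core_genes`,
#'   `cis_introns_shared`, `trans_introns_shared`.
#' @export
shared_counts <- function(matrix, registry = NULL) {
  registry <- registry %||% attr(matrix, "registry")
  if (nrow(matrix) == 0L)
    return(tibble(shared_genes = 0L, shared_core_genes = 0L,
                  cis_introns_shared = 0L, trans_introns_shared = 0L))
  shared <- matrix |>
    group_by(.data$element, .data$type) |>
    summarise(shared = all(.data$call %in% c("present", "tentative")),
              .groups = "drop")
  genes <- shared[shared$type == "gene" & shared$shared, "element",
                  drop = TRUE]
  introns <- shared[shared$type == "intron" & shared$shared, "element",
                    drop = TRUE]
  core <- if (!is.null(registry))
    registry$genes$name[registry$genes$category == "core"] else character()
  cis <- if (!is.null(registry) && !is.null(registry$introns))
    registry$introns$name[registry$introns$splicing == "cis"] else character()
  trans <- if (!is.null(registry) && !is.null(registry$introns))
    registry$introns$name[registry$introns$splicing == "trans"] else character()
  tibble(shared_genes = length(genes),
         shared_core_genes = sum(genes %in% core),
         cis_introns_shared = sum(introns %in% cis),
         trans_introns_shared = sum(introns %in% trans))
}

#' Construct an element registry
#'
#' The registry fixes the element ordering of a content matrix: an ordered
#' gene table (name, category, complex, optional reference sequence/domains)
#' and an ordered intron table (name, host gene, ordinal, cis/trans splicing
#' arrangement, optional reference sequences).
#'
#' @param genes Tibble with at least `name` and `category`
#'   (`core`/`ribosomal`/`sdh`/`other`).
#' @param introns Tibble with at least `name`, `host`, `ordinal`, `splicing`.
#' @return A list of class `element_registry`.
#' @export
element_registry <- function(genes, introns = NULL) {
  genes <- as_tibble(genes)
  introns <- if (is.null(introns)) {
    tibble(name = character(), host = character(), ordinal = integer(),
           splicing = character())
  } else as_tibble(introns)
  if (nrow(introns) && !all(introns$host %in% genes$name))
    abort("intron hosts must exist in the gene list")
  structure(list(genes = genes, introns = introns),
            class = "element_registry")
}
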