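# Worked-example fixtures: the conserved Orobanchaceae gene/intron sets, the
# published content-matrix cells that the comparative results enumerate, a
# synthetic ndh gene set carrying the reported plastome disruptions, and the
# Castilleja paramensis annotation summary. Fixtures encode printed lists
# only; the ndh sequences are synthetic stand-ins generated deterministically
# with the planted mutations the figure describes.

OROBANCHACEAE_TAXA <- c("Cpa", "Bpe", "Ocr", "Ogr", "Pra", "Sam", "Lph")

# 29 protein-coding genes shared by all seven Orobanchaceae mitogenomes
SHARED_GENES_29 <- c(
  "atp1", "atp4", "atp6", "atp8",
  "ccmB", "ccmC", "ccmFc", "ccmFn",
  "cob", "cox1", "cox2", "cox3",
  "matR", "mttB",
  "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6", "nad7", "nad9",
  "rpl10", "rpl16", "rps3", "rps4", "rps12", "rps14")

# the 24 core genes nearly universally present in angiosperm mitogenomes:
# the 23 shared ones plus atp9 (the fifth ATP synthase subunit, absent from
# one draft assembly in the panel)
CORE_GENES_24 <- c(
  "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6", "nad7", "nad9",
  "cob", "cox1", "cox2", "cox3",
  "atp1", "atp4", "atp6", "atp8", "atp9",
  "ccmB", "ccmC", "ccmFc", "ccmFn",
  "matR", "mttB")

CIS_INTRONS_14 <- c(
  "ccmFc-i1", "nad1-i2", "nad2-i1", "nad2-i3", "nad2-i4",
  "nad4-i1", "nad4-i2", "nad4-i3", "nad5-i1", "nad5-i4",
  "nad7-i1", "nad7-i2", "nad7-i4", "rps3-i1")

TRANS_INTRONS_6 <- c(
  "nad1-i1", "nad1-i3", "nad1-i4", "nad2-i2", "nad5-i2", "nad5-i3")

gene_category <- function(g) {
  dplyr::case_when(
    g %in% CORE_GENES_24 ~ "core",
    grepl("^rp[ls]", g) ~ "ribosomal",
    grepl("^sdh", g) ~ "sdh",
    TRUE ~ "other")
}

gene_complex <- function(g) {
  dplyr::case_when(
    grepl("^nad", g) ~ "complex I (NADH dehydrogenase)",
    g == "cob" ~ "complex III (cytochrome bc1)",
    grepl("^cox", g) ~ "complex IV (cytochrome c oxidase)",
    grepl("^atp", g) ~ "ATP synthase",
    grepl("^ccm", g) ~ "cytochrome c maturation",
    g == "matR" ~ "intron maturase",
    g == "mttB" ~ "protein translocase",
    grepl("^rp[ls]", g) ~ "ribosomal protein",
    grepl("^sdh", g) ~ "complex II (succinate dehydrogenase)",
    TRUE ~ "other")
}

fig2_gene_order <- function() {
  c(SHARED_GENES_29, "atp9",
    "rpl2", "rps1", "rps7", "rps10", "rps13", "sdh3", "sdh4")
}

fig2_intron_order <- function() {
  tibble(
    name = c(CIS_INTRONS_14, TRANS_INTRONS_6,
             "cox1-i1", "cox2-i1", "cox2-i2", "nad7-i3", "rpl2-i1",
             "rps10-i1"),
    splicing = c(rep("cis", length(CIS_INTRONS_14)),
                 rep("trans", length(TRANS_INTRONS_6)),
                 "cis", "cis", "cis", "cis", "cis", "cis")
  ) |>
    mutate(host = sub("-i[0-9]+$", "", .data$name),
           ordinal = as.integer(sub("^.*-i", "", .data$name)))
}

build_fig2_registry <- function() {
  genes <- tibble(name = fig2_gene_order()) |>
    mutate(category = gene_category(.data$name),
           complex = gene_complex(.data$name))
  element_registry(genes, fig2_intron_order())
}

# Deviations from "+" that the comparative results spell out, per taxon.
fig2_cell_overrides <- function() {
  tribble(
    ~taxon, ~element, ~call,
    # atp9 not detected in the nonparasite draft assembly
    "Lph", "atp9", "lost",
    # heavily truncated pseudogenes
    "Ocr", "rps1", "pseudogene",
    "Pra", "rps1", "pseudogene",
    "Ogr", "rps10", "pseudogene",
    "Ogr", "rps13", "pseudogene",
    "Pra", "rpl2", "pseudogene",
    "Sam", "rps7", "pseudogene",
    # frameshift pseudogenes not attributable to homopolymer errors
    "Ocr", "rps10", "pseudogene",
    "Ocr", "sdh4", "pseudogene",
    "Ogr", "sdh4", "pseudogene",
    "Sam", "sdh3", "pseudogene",
    # tentatively present, truncated by 20-30%
    "Ogr", "rps7", "tentative",
    "Ocr", "rps13", "tentative",
    "Pra", "rps13", "tentative",
    "Cpa", "sdh3", "tentative",
    "Lph", "sdh3", "tentative",
    # introns lost before the radiation of the family
    "Cpa", "cox2-i1", "lost", "Bpe", "cox2-i1", "lost",
    "Ocr", "cox2-i1", "lost", "Ogr", "cox2-i1", "lost",
    "Pra", "cox2-i1", "lost", "Sam", "cox2-i1", "lost",
    "Lph", "cox2-i1", "lost",
    "Cpa", "nad7-i3", "lost", "Bpe", "nad7-i3", "lost",
    "Ocr", "nad7-i3", "lost", "Ogr", "nad7-i3", "lost",
    "Pra", "nad7-i3", "lost", "Sam", "nad7-i3", "lost",
    "Lph", "nad7-i3", "lost",
    "Cpa", "rpl2-i1", "lost", "Bpe", "rpl2-i1", "lost",
    "Ocr", "rpl2-i1", "lost", "Ogr", "rpl2-i1", "lost",
    "Pra", "rpl2-i1", "lost", "Sam", "rpl2-i1", "lost",
    "Lph", "rpl2-i1", "lost",
    # uniquely lost intron
    "Bpe", "cox2-i2", "lost",
    # intron remnants retained in rps10 pseudogenes
    "Ocr", "rps10-i1", "remnant",
    "Ogr", "rps10-i1", "remnant")
}

build_orobanchaceae_matrix <- function() {
  registry <- build_fig2_registry()
  elements <- bind_rows(
    tibble(element = registry$genes$name, type = "gene"),
    tibble(element = registry$introns$name, type = "intron"))
  cells <- tidyr::expand_grid(taxon = OROBANCHACEAE_TAXA, elements) |>
    mutate(call = "present")
  ov <- fig2_cell_overrides()
  for (k in seq_len(nrow(ov))) {
    idx <- cells$taxon == ov$taxon[k] & cells$element == ov$element[k]
    cells$call[idx] <- ov$call[k]
  }
  cells$glyph <- call_to_glyph(cells$call)
  new_content_matrix(cells, registry)
}

# Synthetic 11-gene ndh set: frameshifting indels planted in ndhD and ndhF,
# premature stop codons in ndhH and ndhJ, every other gene intact. Lengths
# are typical plastid ndh CDS lengths; sequences are generated
# deterministically.
NDH_LENGTHS <- c(ndhA = 1089L, ndhB = 1533L, ndhC = 363L, ndhD = 1503L,
                 ndhE = 306L, ndhF = 2211L, ndhG = 531L, ndhH = 1182L,
                 ndhI = 543L, ndhJ = 480L, ndhK = 678L)

build_ndh_plastome <- function() {
  refs <- withr::with_seed(480721L, {
    lapply(names(NDH_LENGTHS), function(g)
      random_cds(NDH_LENGTHS[[g]]))
  })
  names(refs) <- names(NDH_LENGTHS)
  genes <- tibble(gene = names(NDH_LENGTHS),
                  residues = unlist(refs, use.names = FALSE),
                  length = unname(NDH_LENGTHS))
  candidates <- genes$residues
  names(candidates) <- genes$gene
  # frameshifting indels: single-base deletions at ~40% of the CDS, so the
  # out-of-frame tail disrupts ~60% of the gene
  for (g in c("ndhD", "ndhF")) {
    s <- candidates[[g]]
    at <- 3L * floor(0.4 * nchar(s) / 3L) + 2L  # inside a codon
    candidates[[g]] <- paste0(substr(s, 1L, at - 1L),
                              substr(s, at + 1L, nchar(s)))
  }
  # premature stop codons substituted in frame at ~40% of the CDS
  for (g in c("ndhH", "ndhJ")) {
    s <- candidates[[g]]
    cod <- floor(0.4 * nchar(s) / 3L)
    at <- 3L * cod + 1L
    candidates[[g]] <- paste0(substr(s, 1L, at - 1L), "TAA",
                              substr(s, at + 3L, nchar(s)))
  }
  truth <- tibble(gene = genes$gene,
                  status = ifelse(genes$gene %in%
                                    c("ndhD", "ndhF", "ndhH", "ndhJ"),
                                  "pseudogene", "functional"),
                  planted = dplyr::case_when(
                    genes$gene %in% c("ndhD", "ndhF") ~ "frameshift",
                    genes$gene %in% c("ndhH", "ndhJ") ~ "premature_stop",
                    TRUE ~ "none"))
  list(genes = genes,
       candidates = tibble(gene = names(candidates),
                           residues = unname(candidates)),
       truth = truth)
}

build_cpa_summary <- function() {
  list(
    genes = tibble(category = c("protein_coding", "rRNA", "tRNA"),
                   n = c(34L, 3L, 30L)),
    introns = tibble(splicing = c("cis", "trans"), n = c(17L, 6L)),
    genome_length = 495499L,
    plastome_length = 152926L,
    mipt_count = 43L, mipt_bp = 82133L,
    repeat_bp = 13525L,
    repeat_counts = c(large = 1L, intermediate = 15L, small = 32L))
}

#' Packaged worked-example fixtures
#'
#' Returns the encoded comparative-genomics fixtures used in worked examples
#' and tests:
#' \describe{
#'   \item{`conserved_genes`}{The 29 protein-coding genes shared by all seven
#'     Orobanchaceae mitogenomes.}
#'   \item{`core_genes`}{The 24 core genes nearly universally present in
#'     angiosperm mitogenomes.}
#'   \item{`fig2_registry`}{An [element_registry()] of the content-matrix
#'     elements, with gene categories and the six trans-arranged introns.}
#'   \item{`orobanchaceae_matrix`}{The seven-taxon content matrix with the
#'     published deviations from presence encoded cell by cell.}
#'   \item{`ndh_plastome`}{A synthetic 11-gene ndh set in which ndhD and ndhF
#'     carry frameshifting indels and ndhH and ndhJ premature stop codons
#'     (others intact), with disruptions placed to exceed the classifier
#'     thresholds.}
#'   \item{`cpa_annotation_summary`}{Category counts of the annotated
#'     Castilleja paramensis mitogenome (34 protein-coding + 3 rRNA + 30 tRNA
#'     genes; 17 cis- and 6 trans-spliced introns) and headline genome
#'     statistics.}
#' }
#'
#' @param name Fixture name.
#' @return The fixture object (a character vector, registry, matrix or list).
#' @export
paper_fixture <- function(name = c("conserved_genes", "core_genes",
                                   "fig2_registry", "orobanchaceae_matrix",
                                   "ndh_plastome",
                                   "cpa_annotation_summary")) {
  name <- tryCatch(match.arg(name),
                   error = function(e) abort(sprintf(
                     "unknown fixture name: %s", name[1])))
  switch(name,
         conserved_genes = SHARED_GENES_29,
         core_genes = CORE_GENES_24,
         fig2_registry = build_fig2_registry(),
         orobanchaceae_matrix = build_orobanchaceae_matrix(),
         ndh_plastome = build_ndh_plastome(),
         cpa_annotation_summary = build_cpa_summary())
}

#' Summarise an annotation into gene and intron totals
#'
#' Accepts either a category-count summary (as returned by
#' `paper_fixture("cpa_annotation_summary")`) or a feature tibble from
#' [read_features()], and reports total genes by category and intron counts.
#'
#' @param x Annotation summary list or feature tibble.
#' @return One-row tibble with `total_genes`, per-category counts,
#'   `total_introns`, `cis_introns`, `trans_introns`.
#' @export
summarize_annotation <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$genes)) {
    g <- x$genes
    i <- x$introns %||% tibble(splicing = character(), n = integer())
    counts <- setNames(as.list(g$n), g$category)
    return(as_tibble(c(list(total_genes = sum(g$n)), counts,
                       list(total_introns = sum(i$n),
                            cis_introns = sum(i$n[i$splicing == "cis"]),
                            trans_introns = sum(i$n[i$splicing == "trans"])))))
  }
  if (is.data.frame(x)) {
    genes <- x[x$kind %in% c("gene", "CDS", "tRNA", "rRNA"), , drop = FALSE]
    gu <- dplyr::distinct(genes, .data$feature_id, .data$kind)
    introns <- x[x$kind == "intron", , drop = FALSE]
    return(tibble(total_genes = length(unique(gu$feature_id)),
                  total_introns = length(unique(introns$feature_id)),
                  cis_introns = NA_integer_, trans_introns = NA_integer_))
  }
  abort("cannot summarise this annotation object")
}
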