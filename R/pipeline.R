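# End-to-end orchestration from a single configuration, plus text rendering
# of content matrices. The pipeline runs its enabled stages in dependency
# order (simulate -> insertions/repeats -> classify -> coverage), writes
# standard-format artifacts, and returns a report whose numbers are exactly
# the module outputs.

#' Pipeline configuration
#'
#' @param stages Character vector of stages to run, from `"simulate"`,
#'   `"mipts"`, `"repeats"`, `"classify"`, `"coverage"`.
#' @param outdir Output directory (`NULL` for no files).
#' @param generator [generator_config()] for the simulate stage (also the
#'   seed source).
#' @param detection [detection_config()].
#' @param classifier [classifier_config()].
#' @param mitogenome_path,plastome_path Optional FASTA inputs used when the
#'   simulate stage is disabled.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("simulate", "mipts", "repeats",
                                       "classify"),
                            outdir = NULL,
                            generator = generator_config(),
                            detection = detection_config(),
                            classifier = classifier_config(),
                            mitogenome_path = NULL, plastome_path = NULL) {
  known <- c("simulate", "mipts", "repeats", "classify", "coverage")
  bad <- setdiff(stages, known)
  if (length(bad)) abort(sprintf("unknown stage: %s", bad[1]))
  structure(list(stages = stages, outdir = outdir, generator = generator,
                 detection = detection, classifier = classifier,
                 mitogenome_path = mitogenome_path,
                 plastome_path = plastome_path),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order and returns a report of
#' per-stage summaries; every number in the report equals the corresponding
#' module output. With an `outdir`, stage artifacts are written as FASTA,
#' GFF3, TSV and bedGraph.
#'
#' @param config [pipeline_config()].
#' @return A list of class `orgdecay_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stages <- config$stages
  report <- list(seed = config$generator$seed, stages = stages)
  sim <- NULL
  mito <- NULL; plast <- NULL
  if (length(stages) == 0L) {
    return(structure(report, class = "orgdecay_report"))
  }
  needs_genomes <- any(c("mipts", "repeats", "classify", "coverage") %in%
                         stages)
  if ("simulate" %in% stages) {
    sim <- make_organelle_pair(config$generator)
    mito <- sim$mitogenome; plast <- sim$plastome
    report$simulate <- list(
      mito_length = sim$mitogenome$length,
      plast_length = sim$plastome$length,
      planted_repeats = nrow(sim$truth$repeats),
      planted_mipts = nrow(sim$truth$mipts))
  } else if (needs_genomes) {
    if (is.null(config$mitogenome_path))
      abort("configuration error: mitogenome input required for the enabled stages",
            class = "orgdecay_config_error")
    mito <- read_sequences(config$mitogenome_path)[1, ]
    if (!is.null(config$plastome_path))
      plast <- read_sequences(config$plastome_path)[1, ]
  }
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)
  if (!is.null(outdir) && !is.null(sim)) {
    write_sequences(sim$mitogenome, file.path(outdir, "mitogenome.fasta"))
    write_sequences(sim$plastome, file.path(outdir, "plastome.fasta"))
    write_features(sim$features[sim$features$seq_id == "mito", ],
                   file.path(outdir, "mitogenome.gff3"))
  }
  if ("mipts" %in% stages) {
    if (is.null(plast))
      abort("configuration error: plastome required for the mipts stage",
            class = "orgdecay_config_error")
    mipts <- find_mipts(mito, plast, config$detection)
    stats <- quantify_segments(mipts[, c("start", "end")], mito$length)
    report$mipts <- list(count = nrow(mipts), stats = stats)
    if (!is.null(outdir)) {
      readr::write_tsv(mipts[, setdiff(names(mipts), "source")],
                       file.path(outdir, "mipts.tsv"), progress = FALSE)
    }
    report$mipts_table <- mipts
  }
  if ("repeats" %in% stages) {
    reps <- find_repeats(mito, config$detection)
    report$repeats <- summarize_repeats(reps, mito$length, config$detection)
    report$repeats_table <- reps
    if (!is.null(outdir))
      readr::write_tsv(reps, file.path(outdir, "repeats.tsv"),
                       progress = FALSE)
  }
  if ("classify" %in% stages) {
    if (is.null(sim))
      abort("configuration error: the classify stage needs simulated truth references",
            class = "orgdecay_config_error")
    calls <- lapply(seq_len(nrow(sim$mito_genes)), function(g) {
      tr <- sim$truth$pseudogenes[g, ]
      cand <- substr(mito$residues, tr$start + 1L, tr$end)
      if (tr$strand == "-") cand <- revcomp(cand)
      glance(classify_gene(cand, sim$mito_genes[g, ],
                           config = config$classifier,
                           gene = sim$mito_genes$gene[g]))
    }) |> bind_rows()
    report$classify <- list(
      n_genes = nrow(calls),
      tally = table(calls$status))
    report$classify_table <- calls
    if (!is.null(outdir))
      readr::write_tsv(calls, file.path(outdir, "gene_calls.tsv"),
                       progress = FALSE)
  }
  if ("coverage" %in% stages) {
    reads <- simulate_reads(mito, config$generator)
    track <- coverage_profile(reads, mito, circular = TRUE)
    report$coverage <- list(mean_depth = mean(track$depth),
                            requested_depth = config$generator$depth)
    if (!is.null(outdir))
      write_coverage(track, file.path(outdir, "coverage.bedgraph"))
  }
  structure(report, class = "orgdecay_report")
}

#' @export
print.orgdecay_report <- function(x, ...) {
  cat("<orgdecay_report>\n")
  cat("  stages:", paste(x$stages, collapse = ", "), "\n")
  if (!is.null(x$mipts))
    cat(sprintf("  insertions: %d covering %s bp (%.1f%%)\n",
                x$mipts$count, format(x$mipts$stats$covered_bp, big.mark = ","),
                x$mipts$stats$percent))
  if (!is.null(x$repeats))
    cat(sprintf("  repeats: %d small / %d intermediate / %d large, %.1f%% of the genome\n",
                x$repeats$n_small, x$repeats$n_intermediate,
                x$repeats$n_large, x$repeats$percent))
  if (!is.null(x$classify))
    cat("  gene calls:", paste(sprintf("%s=%d", names(x$classify$tally),
                                       x$classify$tally), collapse = ", "),
        "\n")
  invisible(x)
}

#' @method glance orgdecay_report
#' @export
glance.orgdecay_report <- function(x, ...) {
  tibble(
    seed = x$seed,
    mipt_count = if (!is.null(x$mipts)) x$mipts$count else NA_integer_,
    mipt_percent = if (!is.null(x$mipts)) x$mipts$stats$percent else NA_real_,
    repeat_pairs = if (!is.null(x$repeats))
      x$repeats$n_small + x$repeats$n_intermediate + x$repeats$n_large
    else NA_integer_,
    repeat_percent = if (!is.null(x$repeats)) x$repeats$percent else NA_real_,
    pseudogenes = if (!is.null(x$classify))
      sum(x$classify_table$status == "pseudogene") else NA_integer_)
}

#' Render a content matrix as TSV text
#'
#' Header row of element names, one row per taxon, glyph cells (`+`, `-`,
#' `ψ`, `x`, `+*`, `ψr`), UTF-8.
#'
#' @param matrix A `content_matrix`.
#' @return A single TSV string.
#' @export
render_matrix <- function(matrix) {
  elements <- attr(matrix, "element_order") %||% unique(matrix$element)
  taxa <- unique(matrix$taxon)
  wide <- matrix |>
    select("taxon", "element", "glyph") |>
    tidyr::pivot_wider(names_from = "element", values_from = "glyph")
  wide <- wide[match(taxa, wide$taxon), c("taxon", elements)]
  lines <- c(paste(c("taxon", elements), collapse = "\t"),
             vapply(seq_len(nrow(wide)), function(i)
               paste(unlist(wide[i, ]), collapse = "\t"), character(1)))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse a content matrix from TSV text
#'
#' Inverse of [render_matrix()] (up to the registry attribute, which cannot
#' be reconstructed from glyphs alone).
#'
#' @param text TSV string.
#' @param registry Optional [element_registry()] giving element types.
#' @return A `content_matrix`.
#' @export
parse_matrix <- function(text, registry = NULL) {
  lines <- strsplit(sub("\n$", "", text), "\n", fixed = TRUE)[[1]]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  elements <- header[-1]
  rows <- lapply(lines[-1], function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  cells <- bind_rows(lapply(rows, function(r)
    tibble(taxon = r[1], element = elements, glyph = r[-1])))
  cells$call <- glyph_to_call(cells$glyph)
  type <- if (!is.null(registry)) {
    ifelse(cells$element %in% registry$introns$name, "intron", "gene")
  } else ifelse(grepl("-i[0-9]+$", cells$element), "intron", "gene")
  cells$type <- type
  new_content_matrix(cells[, c("taxon", "element", "type", "call", "glyph")],
                     registry)
}
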