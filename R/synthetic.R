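# Deterministic synthetic organelle genomes with planted degradation
# features and a full ground-truth manifest: plastid-derived insertions
# (with optional secondary pseudogenization), dispersed repeats in three
# size classes, native gene copies carrying frameshifts / premature stops /
# truncations, and paired reads with optional pyrosequencing-style
# homopolymer errors. Everything is reproducible from a single seed.

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# 61 sense codons
sense_codons <- function() {
  all <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES,
                         paste0))
  setdiff(all, STOP_CODONS)
}

random_cds <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  ncod <- len / 3L
  body <- sample(sense_codons(), ncod - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1L))
}

#' Generator configuration
#'
#' Defaults emulate the study conditions of the motivating system: a
#' 495,499-bp circular mitogenome and a 152,926-bp plastome; one large
#' (8.7 kb), 15 intermediate (100-447 bp) and 32 small (50-100 bp) repeat
#' pairs; 43 plastid-derived insertions ranging from ~116 bp to several kb,
#' together carrying 55 (nearly) full-length plastid genes of which half are
#' secondarily pseudogenized; and 100-bp read pairs from an 800-bp library
#' at 50x depth. Identity decay of insertions is modelled as i.i.d.
#' substitutions outside gene bodies (so planted gene statuses stay
#' analytically known) and outside a short anchor collar at each insertion
#' end (so planted boundaries are recovered exactly).
#'
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param mito_length,plast_length Genome lengths (bp).
#' @param n_mito_genes,n_plast_genes Gene counts.
#' @param gene_length_range CDS length range (rounded to codons).
#' @param domain_fraction Fraction of each gene covered by its conserved
#'   domain segment.
#' @param n_large_repeats,large_repeat_len,n_intermediate_repeats,
#'   intermediate_repeat_range,n_small_repeats,small_repeat_range Planted
#'   repeat counts and length ranges per size class.
#' @param inverted_fraction Fraction of repeat pairs planted inverted.
#' @param n_mipts Number of plastid-derived insertions.
#' @param mipt_genes_total Plastid genes carried full length by insertions.
#' @param mipt_gene_pad Padding (bp) around gene clusters in source windows.
#' @param mipt_intergenic_range Length range of gene-free insertions.
#' @param mipt_identity Target identity of insertions (1 = no decay).
#' @param mipt_collar Unmutated anchor length at each insertion end (bp).
#' @param n_collar Length of the run of `N` placed on each side of every
#'   planted feature. `N` is scored as a mismatch and forms no seeds, so
#'   local alignments provably terminate at planted boundaries (in real
#'   draft assemblies, scaffold-gap characters play the same role).
#' @param secondary_pseudogene_fraction Fraction of carried genes whose
#'   mitochondrial copy receives a frame-breaking deletion.
#' @param planted_pseudogenes Tibble (`kind`, `fraction`) of disruptions
#'   planted in the first native mitochondrial gene copies; `NULL` for the
#'   default panel, a 0-row tibble for none.
#' @param min_spacing Minimum background spacing between planted features.
#' @param guard_len The generator rejection-samples until plastome and
#'   mitogenome share no exact substring of this length outside planted
#'   insertions.
#' @param read_length,insert_mean,insert_sd,depth Read-simulation geometry.
#' @param error_model `"none"`, `"uniform_substitution"` or
#'   `"homopolymer_indel"`.
#' @param error_rate Per-base substitution rate (uniform model).
#' @param homopolymer_indel_rate Per-run 1-bp indel rate (homopolymer model).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             mito_length = 495499L, plast_length = 152926L,
                             n_mito_genes = 36L, n_plast_genes = 70L,
                             gene_length_range = c(300L, 1500L),
                             domain_fraction = 0.4,
                             n_large_repeats = 1L, large_repeat_len = 8700L,
                             n_intermediate_repeats = 15L,
                             intermediate_repeat_range = c(100L, 447L),
                             n_small_repeats = 32L,
                             small_repeat_range = c(50L, 99L),
                             inverted_fraction = 0.25,
                             n_mipts = 43L, mipt_genes_total = 55L,
                             mipt_gene_pad = 20L,
                             mipt_intergenic_range = c(116L, 1000L),
                             mipt_identity = 0.98, mipt_collar = 8L, n_collar = 6L,
                             secondary_pseudogene_fraction = 0.5,
                             planted_pseudogenes = NULL,
                             min_spacing = 200L, guard_len = 18L,
                             read_length = 100L, insert_mean = 800,
                             insert_sd = 80, depth = 50,
                             error_model = c("none", "uniform_substitution",
                                             "homopolymer_indel"),
                             error_rate = 0.005,
                             homopolymer_indel_rate = 0.2) {
  error_model <- match.arg(error_model)
  if (is.null(planted_pseudogenes)) {
    planted_pseudogenes <- tibble(
      kind = c("frameshift", "premature_stop", "truncation3",
               "frameshift_compensated", "truncation3", "frameshift"),
      fraction = c(0.50, 0.50, 0.40, 0.10, 0.25, 0.05))
  }
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a reference gene set
#'
#' Each gene is a valid CDS (starts ATG, ends with a stop, no internal
#' in-frame stop) with one conserved-domain segment of the configured
#' fraction placed uniformly at random.
#'
#' @param n Number of genes.
#' @param config [generator_config()] (gene length range, domain fraction;
#'   the seed is used only when `use_seed = TRUE`).
#' @param prefix Gene-name prefix.
#' @param use_seed Whether to seed the RNG from `config$seed` (set `FALSE`
#'   when calling inside an already-seeded generator).
#' @return Tibble: `gene`, `residues`, `length`, `domain_start`,
#'   `domain_end`.
#' @export
make_reference_geneset <- function(n = NULL, config = generator_config(),
                                   prefix = "g", use_seed = TRUE) {
  n <- n %||% config$n_mito_genes
  lo <- config$gene_length_range[1]; hi <- config$gene_length_range[2]
  if (hi < 9L || hi < lo) abort("infeasible gene length range")
  gen <- function() {
    lens <- 3L * pmax(3L, round(runif(n, lo, hi) / 3L))
    res <- vapply(lens, random_cds, character(1))
    dlen <- pmax(3L, round(config$domain_fraction * lens))
    dstart <- vapply(lens - dlen, function(m) sample.int(m + 1L, 1L) - 1L,
                     integer(1))
    tibble(gene = sprintf("%s%02d", prefix, seq_len(n)),
           residues = res, length = lens,
           domain_start = dstart, domain_end = dstart + dlen)
  }
  if (use_seed) withr::with_seed(config$seed, gen()) else gen()
}

# --- disruption planting -----------------------------------------------------

# Positions where a 1-bp edit does not sit in a mononucleotide run >= 3
# (keeps alignment gap placement, and hence the planted fraction, sharp).
pick_clean_position <- function(residues, target) {
  L <- nchar(residues)
  for (off in c(0L, cumsum(rep(c(1L, -1L), 30L) * rep(1:30, each = 2L)))) {
    p <- target + off
    if (p < 4L || p > L - 4L) next
    if (homopolymer_run_at(residues, p) < 3L &&
        homopolymer_run_at(residues, p - 1L) < 3L &&
        homopolymer_run_at(residues, p + 1L) < 3L) return(p)
  }
  target
}

#' Plant a disruption of known extent into a reference CDS
#'
#' Creates a candidate gene copy carrying a single loss-of-function event
#' whose disrupted fraction is analytically known, for classifier recovery
#' testing.
#'
#' @param reference Reference CDS string.
#' @param kind One of `"premature_stop"`, `"frameshift"` (uncompensated
#'   1-bp deletion), `"frameshift_compensated"` (deletion plus a downstream
#'   compensating insertion), `"truncation5"`, `"truncation3"`.
#' @param fraction Target disrupted fraction of the gene.
#' @return List: `residues` (the disrupted copy) and `expected` (one-row
#'   tibble with the planted `overall_fraction`, `truncated_fraction` and the
#'   threshold-implied `status`).
#' @export
make_disrupted_copy <- function(reference, kind, fraction) {
  L <- nchar(reference)
  ncod <- L / 3L
  cfg <- classifier_config()
  expected_status <- function(overall, truncated) {
    if (overall > cfg$overall_threshold) "pseudogene"
    else if (truncated >= cfg$tentative_band[1] &&
             truncated <= cfg$tentative_band[2]) "tentative"
    else "functional"
  }
  if (kind == "premature_stop") {
    k <- max(1L, min(ncod - 2L, round((L * (1 - fraction) - 3L) / 3L)))
    at <- 3L * k + 1L
    res <- paste0(substr(reference, 1L, at - 1L), "TAA",
                  substr(reference, at + 3L, L))
    overall <- (L - 3L * (k + 1L)) / L
    exp <- tibble(kind = kind, overall_fraction = overall,
                  truncated_fraction = 0,
                  disrupted_start = 3L * (k + 1L), disrupted_end = L,
                  status = expected_status(overall, 0))
  } else if (kind == "frameshift") {
    p <- pick_clean_position(reference, round(L * (1 - fraction)))
    res <- paste0(substr(reference, 1L, p), substr(reference, p + 2L, L))
    overall <- (L - p) / L
    exp <- tibble(kind = kind, overall_fraction = overall,
                  truncated_fraction = 0,
                  disrupted_start = p, disrupted_end = L,
                  status = expected_status(overall, 0))
  } else if (kind == "frameshift_compensated") {
    p <- pick_clean_position(reference, round(L * 0.3))
    q <- pick_clean_position(reference, p + round(L * fraction))
    if (q <= p + 3L) q <- p + round(L * fraction)
    res <- paste0(substr(reference, 1L, p), substr(reference, p + 2L, q),
                  sample(DNA_BASES, 1L), substr(reference, q + 1L, L))
    overall <- (q - p) / L
    exp <- tibble(kind = kind, overall_fraction = overall,
                  truncated_fraction = 0,
                  disrupted_start = p, disrupted_end = q,
                  status = expected_status(overall, 0))
  } else if (kind == "truncation5") {
    t <- round(L * fraction)
    res <- substr(reference, t + 1L, L)
    exp <- tibble(kind = kind, overall_fraction = t / L,
                  truncated_fraction = t / L,
                  disrupted_start = 0L, disrupted_end = t,
                  status = expected_status(t / L, t / L))
  } else if (kind == "truncation3") {
    t <- round(L * fraction)
    res <- substr(reference, 1L, L - t)
    exp <- tibble(kind = kind, overall_fraction = t / L,
                  truncated_fraction = t / L,
                  disrupted_start = L - t, disrupted_end = L,
                  status = expected_status(t / L, t / L))
  } else abort(sprintf("unknown disruption kind: %s", kind))
  list(residues = res, expected = exp)
}

# --- layout helpers ----------------------------------------------------------

# Place n feature widths into [0, L) with at least `spacing` background
# between them (and at both genome ends); returns start positions in the
# given order, randomly interleaved along the genome.
place_features <- function(widths, L, spacing) {
  n <- length(widths)
  if (n == 0L) return(integer())
  extra <- L - sum(widths) - (n + 1L) * spacing
  if (extra < 0L)
    abort(sprintf("genome of %d bp is too small for %d planted features (%d bp + spacing)",
                  L, n, sum(widths)))
  ord <- sample.int(n)
  parts <- as.integer(stats::rmultinom(1L, extra, rep(1, n + 1L)))
  starts_ord <- integer(n)
  cur <- spacing + parts[1L]
  for (k in seq_len(n)) {
    starts_ord[k] <- cur
    cur <- cur + widths[ord[k]] + spacing + parts[k + 1L]
  }
  starts <- integer(n)
  starts[ord] <- starts_ord
  starts
}

substitute_at <- function(chars, pos) {
  # pos: 1-based indices; substitute to a different base
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  chars
}

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

#' Generate a mitogenome/plastome pair with planted features
#'
#' The plastome carries intact gene copies; the mitogenome receives native
#' gene copies (some with planted disruptions), plastid-derived insertions
#' copied from the plastome (with configured identity decay and optional
#' secondary pseudogenization of carried genes), and dispersed repeat pairs
#' at the configured counts per size class. Planted features are separated
#' by background spacing, their boundaries are anchored (flanking bases are
#' forced to mismatch the partner's continuation so detected intervals are
#' exact), and the two genomes are rejection-sampled to share no exact
#' substring of `guard_len` outside the insertions. The truth manifest
#' records every planted feature.
#'
#' @param config [generator_config()].
#' @return A list of class `organelle_sim`: `mitogenome` and `plastome`
#'   (single-row sequence tibbles), `mito_genes` / `plast_genes` (reference
#'   gene sets; plastid genes carry plastome coordinates), `features`
#'   (annotation tibble for both genomes) and `truth` (the manifest).
#' @export
make_organelle_pair <- function(config = generator_config()) {
  withr::with_seed(config$seed, build_organelle_pair(config))
}

build_organelle_pair <- function(config) {
  plast_genes <- make_reference_geneset(config$n_plast_genes, config,
                                        prefix = "ptg", use_seed = FALSE)
  mito_genes <- make_reference_geneset(config$n_mito_genes, config,
                                       prefix = "mtg", use_seed = FALSE)
  # geneset-level guard: native mitochondrial genes must share no
  # guard_len-mer with any plastid gene, so the only cross-genome homology
  # is the planted insertions
  gl <- config$guard_len
  plast_kmers <- unlist(lapply(plast_genes$residues, function(s) {
    n <- nchar(s) - gl + 1L
    substring(s, seq_len(n), seq_len(n) + gl - 1L)
  }))
  for (g in seq_len(config$n_mito_genes)) {
    for (try in 1:50) {
      s <- mito_genes$residues[g]
      n <- nchar(s) - gl + 1L
      if (!any(substring(s, seq_len(n), seq_len(n) + gl - 1L) %in%
               plast_kmers)) break
      mito_genes$residues[g] <- random_cds(mito_genes$length[g])
    }
  }

  ## ---- plastome: genes in order with random spacers, windows in the tail
  pl <- strsplit(random_dna(config$plast_length), "", fixed = TRUE)[[1]]
  cur <- 0L
  pstart <- integer(config$n_plast_genes)
  for (g in seq_len(config$n_plast_genes)) {
    cur <- cur + sample(150:300, 1L)
    pstart[g] <- cur
    cur <- cur + plast_genes$length[g]
  }
  if (cur + config$min_spacing > config$plast_length)
    abort("plastome too small for the configured gene set")
  plast_genes$start <- pstart
  plast_genes$end <- pstart + plast_genes$length
  for (g in seq_len(config$n_plast_genes)) {
    pl[(pstart[g] + 1L):(pstart[g] + plast_genes$length[g])] <-
      strsplit(plast_genes$residues[g], "", fixed = TRUE)[[1]]
  }

  ## ---- MIPT source windows
  n_carried <- min(config$mipt_genes_total, config$n_plast_genes)
  sizes <- integer()
  left <- n_carried
  while (left > 0L) {
    s <- min(left, sample(1:4, 1L))
    sizes <- c(sizes, s)
    left <- left - s
  }
  if (length(sizes) > config$n_mipts)
    abort("more gene clusters than insertions; increase n_mipts")
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  pad <- config$mipt_gene_pad
  src <- tibble(
    src_start = plast_genes$start[starts] - pad,
    src_end = plast_genes$end[ends] + pad,
    first_gene = starts, last_gene = ends)
  n_intergenic <- config$n_mipts - length(sizes)
  if (n_intergenic > 0L) {
    tail0 <- cur + config$min_spacing
    tail_len <- config$plast_length - tail0
    iw <- sample(config$mipt_intergenic_range[1]:config$mipt_intergenic_range[2],
                 n_intergenic, replace = TRUE)
    istarts <- place_features(iw, tail_len, config$min_spacing) + tail0
    src <- bind_rows(src, tibble(src_start = istarts, src_end = istarts + iw,
                                 first_gene = NA_integer_,
                                 last_gene = NA_integer_))
  }
  src <- arrange(src, .data$src_start)

  ## ---- secondary pseudogenization of carried genes
  carried <- which(!is.na(src$first_gene))
  carried_genes <- unlist(lapply(carried, function(k)
    seq(src$first_gene[k], src$last_gene[k])))
  n_disrupt <- ceiling(config$secondary_pseudogene_fraction *
                         length(carried_genes))
  disrupted_genes <- sort(sample(carried_genes, n_disrupt))

  ## ---- build MIPT copy sequences
  mipt_strand <- sample(c("+", "-"), nrow(src), replace = TRUE,
                        prob = c(0.7, 0.3))
  copies <- vector("list", nrow(src))
  mipt_gene_rows <- list()
  for (k in seq_len(nrow(src))) {
    seg <- pl[(src$src_start[k] + 1L):src$src_end[k]]
    seg_genes <- if (!is.na(src$first_gene[k]))
      seq(src$first_gene[k], src$last_gene[k]) else integer()
    # identity decay outside gene bodies and end collars
    if (config$mipt_identity < 1) {
      protected <- logical(length(seg))
      cl <- config$mipt_collar
      protected[seq_len(min(cl, length(seg)))] <- TRUE
      protected[seq(max(1L, length(seg) - cl + 1L), length(seg))] <- TRUE
      for (g in seg_genes) {
        a <- plast_genes$start[g] - src$src_start[k]
        protected[(a + 1L):(a + plast_genes$length[g])] <- TRUE
      }
      eligible <- which(!protected)
      nsub <- stats::rbinom(1L, length(eligible), 1 - config$mipt_identity)
      if (nsub > 0L)
        seg <- substitute_at(seg, sample(eligible, nsub))
    }
    # secondary pseudogenization: 1-bp deletion at ~40% of each chosen gene
    dels <- integer()
    for (g in rev(seg_genes)) {
      if (!g %in% disrupted_genes) next
      a <- plast_genes$start[g] - src$src_start[k]  # gene offset in segment
      p <- pick_clean_position(plast_genes$residues[g],
                               round(0.4 * plast_genes$length[g]))
      seg <- seg[-(a + p + 1L)]
      dels <- c(dels, g)
    }
    copies[[k]] <- if (mipt_strand[k] == "-")
      strsplit(revcomp(paste(seg, collapse = "")), "", fixed = TRUE)[[1]]
    else seg
    if (length(seg_genes))
      mipt_gene_rows[[length(mipt_gene_rows) + 1L]] <- tibble(
        gene_idx = seg_genes, mipt_idx = k,
        disrupted = seg_genes %in% disrupted_genes)
  }

  ## ---- native mitochondrial gene copies (some disrupted)
  plant <- config$planted_pseudogenes
  n_plant <- min(nrow(plant), config$n_mito_genes)
  native <- vector("list", config$n_mito_genes)
  pg_rows <- list()
  cls_cfg <- classifier_config()
  for (g in seq_len(config$n_mito_genes)) {
    if (g <= n_plant) {
      pc <- make_disrupted_copy(mito_genes$residues[g], plant$kind[g],
                                plant$fraction[g])
      native[[g]] <- pc$residues
      ex <- pc$expected
      dlen <- mito_genes$domain_end[g] - mito_genes$domain_start[g]
      dov <- max(0L, min(ex$disrupted_end, mito_genes$domain_end[g]) -
                   max(ex$disrupted_start, mito_genes$domain_start[g]))
      ex$domain_fraction <- dov / dlen
      ex$status <- if (ex$domain_fraction > cls_cfg$domain_threshold ||
                       ex$overall_fraction > cls_cfg$overall_threshold) {
        "pseudogene"
      } else if (ex$truncated_fraction >= cls_cfg$tentative_band[1] &&
                 ex$truncated_fraction <= cls_cfg$tentative_band[2]) {
        "tentative"
      } else "functional"
      pg_rows[[g]] <- mutate(ex, gene = mito_genes$gene[g])
    } else {
      native[[g]] <- mito_genes$residues[g]
      pg_rows[[g]] <- tibble(kind = "none", overall_fraction = 0,
                             truncated_fraction = 0,
                             disrupted_start = NA_integer_,
                             disrupted_end = NA_integer_,
                             domain_fraction = 0, status = "functional",
                             gene = mito_genes$gene[g])
    }
  }
  gene_strand <- sample(c("+", "-"), config$n_mito_genes, replace = TRUE)

  ## ---- repeat unit sequences
  rep_lens <- c(rep(config$large_repeat_len, config$n_large_repeats),
                if (config$n_intermediate_repeats > 0L)
                  sample(config$intermediate_repeat_range[1]:
                           config$intermediate_repeat_range[2],
                         config$n_intermediate_repeats, replace = TRUE),
                if (config$n_small_repeats > 0L)
                  sample(config$small_repeat_range[1]:
                           config$small_repeat_range[2],
                         config$n_small_repeats, replace = TRUE))
  n_rep <- length(rep_lens)
  rep_units <- vapply(rep_lens, random_dna, character(1))
  rep_inverted <- runif(n_rep) < config$inverted_fraction

  ## ---- assemble the mitogenome
  native_seqs <- unlist(native)
  copy_seqs <- vapply(copies, paste, character(1), collapse = "")
  oriented_native <- vapply(seq_len(config$n_mito_genes), function(g)
    if (gene_strand[g] == "-") revcomp(native_seqs[g]) else native_seqs[g],
    character(1))
  rep_b <- vapply(seq_len(n_rep), function(k)
    if (rep_inverted[k]) revcomp(rep_units[k]) else rep_units[k],
    character(1))
  pieces <- c(oriented_native, copy_seqs, rep_units, rep_b)
  kind <- c(rep("gene", config$n_mito_genes),
            rep("mipt", length(copy_seqs)),
            rep("repeat_a", n_rep), rep("repeat_b", n_rep))
  widths <- nchar(pieces)
  mt <- strsplit(random_dna(config$mito_length), "", fixed = TRUE)[[1]]
  starts <- place_features(widths, config$mito_length, config$min_spacing)
  for (k in seq_along(pieces)) {
    mt[(starts[k] + 1L):(starts[k] + widths[k])] <-
      strsplit(pieces[k], "", fixed = TRUE)[[1]]
  }

  idx_gene <- seq_len(config$n_mito_genes)
  idx_mipt <- config$n_mito_genes + seq_along(copy_seqs)
  idx_ra <- config$n_mito_genes + length(copy_seqs) + seq_len(n_rep)
  idx_rb <- config$n_mito_genes + length(copy_seqs) + n_rep + seq_len(n_rep)

  ## ---- boundary anchoring: a run of N on each side of every planted
  ## feature; N matches nothing, so extensions stop exactly at the boundary
  cl <- config$mipt_collar
  nc <- config$n_collar
  if (nc > 0L) {
    for (k in seq_along(pieces)) {
      s0 <- starts[k]; e0 <- s0 + widths[k]
      left <- max(1L, s0 - nc + 1L):s0
      right <- (e0 + 1L):min(config$mito_length, e0 + nc)
      mt[left] <- "N"; mt[right] <- "N"
    }
  }

  ## ---- cross-genome guard: no shared guard_len-mer outside insertions
  in_mipt_mt <- logical(config$mito_length)
  for (k in seq_along(idx_mipt)) {
    s <- starts[idx_mipt[k]]
    in_mipt_mt[(s + 1L):(s + widths[idx_mipt[k]])] <- TRUE
  }
  in_src_pl <- logical(config$plast_length)
  for (k in seq_len(nrow(src)))
    in_src_pl[(src$src_start[k] + 1L):src$src_end[k]] <- TRUE
  for (iter in 1:25) {
    viol <- shared_kmer_positions(mt, pl, gl, in_mipt_mt, in_src_pl)
    if (nrow(viol) == 0L) break
    # resample the mitogenome side when it is background; otherwise the
    # plastome side (features are dilated by the collar so boundary anchors
    # are never touched)
    fixed_any <- FALSE
    feature_mt <- logical(config$mito_length)
    for (k in seq_along(pieces)) {
      a <- max(1L, starts[k] + 1L - cl)
      b <- min(config$mito_length, starts[k] + widths[k] + cl)
      feature_mt[a:b] <- TRUE
    }
    feature_pl <- in_src_pl
    for (g in seq_len(config$n_plast_genes))
      feature_pl[(plast_genes$start[g] + 1L):plast_genes$end[g]] <- TRUE
    for (v in seq_len(nrow(viol))) {
      mpos <- viol$m_pos[v]; ppos <- viol$p_pos[v]
      mrange <- (mpos + 1L):(mpos + gl)
      prange <- (ppos + 1L):(ppos + gl)
      if (!any(feature_mt[mrange])) {
        mt[mrange] <- sample(DNA_BASES, gl, replace = TRUE)
        fixed_any <- TRUE
      } else if (!any(feature_pl[prange])) {
        pl[prange] <- sample(DNA_BASES, gl, replace = TRUE)
        fixed_any <- TRUE
      }
    }
    if (!fixed_any)
      abort("could not satisfy the shared-substring guard; change the seed")
  }

  mito <- paste(mt, collapse = "")
  plast <- paste(pl, collapse = "")

  ## ---- features + manifest
  feat <- list()
  feat[[1]] <- tibble(
    feature_id = mito_genes$gene, seq_id = "mito", kind = "gene",
    name = mito_genes$gene, strand = gene_strand,
    start = starts[idx_gene], end = starts[idx_gene] + widths[idx_gene],
    segment = 1L)
  feat[[2]] <- tibble(
    feature_id = sprintf("mipt%03d", seq_along(idx_mipt)), seq_id = "mito",
    kind = "mipt", name = sprintf("mipt%03d", seq_along(idx_mipt)),
    strand = mipt_strand,
    start = starts[idx_mipt], end = starts[idx_mipt] + widths[idx_mipt],
    segment = 1L)
  feat[[3]] <- tibble(
    feature_id = rep(sprintf("rep%03d", seq_len(n_rep)), 2L),
    seq_id = "mito", kind = "repeat_region",
    name = rep(sprintf("rep%03d", seq_len(n_rep)), 2L),
    strand = c(rep("+", n_rep), ifelse(rep_inverted, "-", "+")),
    start = c(starts[idx_ra], starts[idx_rb]),
    end = c(starts[idx_ra] + widths[idx_ra], starts[idx_rb] + widths[idx_rb]),
    segment = rep(c(1L, 2L), each = n_rep))
  feat[[4]] <- tibble(
    feature_id = plast_genes$gene, seq_id = "plast", kind = "gene",
    name = plast_genes$gene, strand = "+",
    start = plast_genes$start, end = plast_genes$end, segment = 1L)
  features <- bind_rows(feat)

  mipt_genes <- if (length(mipt_gene_rows)) {
    bind_rows(mipt_gene_rows) |>
      mutate(gene = plast_genes$gene[.data$gene_idx],
             mipt_id = sprintf("mipt%03d", .data$mipt_idx),
             expected_status = ifelse(.data$disrupted, "pseudogene",
                                      "functional")) |>
      select("gene", "mipt_id", "disrupted", "expected_status")
  } else tibble(gene = character(), mipt_id = character(),
                disrupted = logical(), expected_status = character())

  truth <- list(
    mito_length = config$mito_length,
    plast_length = config$plast_length,
    repeats = {
      # canonical order: copy a precedes copy b in the genome
      sa <- starts[idx_ra]; sb <- starts[idx_rb]
      ea <- sa + widths[idx_ra]; eb <- sb + widths[idx_rb]
      flip <- sb < sa
      tibble(
        repeat_id = sprintf("rep%03d", seq_len(n_rep)),
        a_start = ifelse(flip, sb, sa), a_end = ifelse(flip, eb, ea),
        b_start = ifelse(flip, sa, sb), b_end = ifelse(flip, ea, eb),
        length = rep_lens,
        orientation = ifelse(rep_inverted, "inverted", "direct"))
    },
    mipts = tibble(
      mipt_id = sprintf("mipt%03d", seq_along(idx_mipt)),
      start = starts[idx_mipt], end = starts[idx_mipt] + widths[idx_mipt],
      length = widths[idx_mipt],
      src_start = src$src_start, src_end = src$src_end,
      strand = mipt_strand,
      n_genes = ifelse(is.na(src$first_gene), 0L,
                       src$last_gene - src$first_gene + 1L)),
    mipt_genes = mipt_genes,
    pseudogenes = bind_rows(pg_rows) |>
      mutate(strand = gene_strand,
             start = starts[idx_gene],
             end = starts[idx_gene] + widths[idx_gene]) |>
      select("gene", "kind", "overall_fraction", "truncated_fraction",
             "domain_fraction", "status", "strand", "start", "end"))

  structure(list(
    mitogenome = tibble(id = "mito", residues = mito,
                        length = nchar(mito), topology = "circular",
                        compartment = "mitochondrial"),
    plastome = tibble(id = "plast", residues = plast,
                      length = nchar(plast), topology = "circular",
                      compartment = "plastid"),
    mito_genes = mito_genes, plast_genes = plast_genes,
    features = features, truth = truth, config = config),
    class = "organelle_sim")
}

# Shared exact k-mers between two genomes, excluding k-mers lying entirely
# inside masked (expected-homology) regions.
shared_kmer_positions <- function(mt, pl, k, mask_mt, mask_pl) {
  mseq <- paste(mt, collapse = ""); pseq <- paste(pl, collapse = "")
  nm <- nchar(mseq) - k + 1L; np <- nchar(pseq) - k + 1L
  unmasked_starts <- function(mask, n) {
    cs <- c(0L, cumsum(mask))
    which((cs[seq_len(n) + k] - cs[seq_len(n)]) < k)
  }
  keep_m <- unmasked_starts(mask_mt, nm)
  keep_p <- unmasked_starts(mask_pl, np)
  mk <- substring(mseq, keep_m, keep_m + k - 1L)
  pk <- substring(pseq, keep_p, keep_p + k - 1L)
  common <- intersect(mk, pk)
  if (!length(common)) return(tibble(m_pos = integer(), p_pos = integer()))
  dm <- tibble(kmer = mk, m_pos = keep_m - 1L)[mk %in% common, ]
  dp <- tibble(kmer = pk, p_pos = keep_p - 1L)[pk %in% common, ]
  inner_join(dm, dp, by = "kmer", relationship = "many-to-many")[
    , c("m_pos", "p_pos")]
}

#' Simulate paired reads from a genome
#'
#' Fragment starts are uniform over the (circularised) genome; the pair
#' count is `depth * genome_length / (2 * read_length)`. The
#' `homopolymer_indel` error model inserts or deletes one base only inside
#' mononucleotide runs of four or more, at the configured per-run rate,
#' mimicking pyrosequencing; `uniform_substitution` applies i.i.d.
#' substitutions.
#'
#' @param genome Sequence tibble (single row) or DNA string.
#' @param config [generator_config()] (read geometry, error model, seed).
#' @return Tibble with one row per mate: `pair_id`, `mate`, `seq`, and the
#'   true placement `start`, `end` (0-based half-open; `end` may exceed the
#'   genome length for origin-wrapping placements), `strand`.
#' @export
simulate_reads <- function(genome, config = generator_config()) {
  gseq <- toupper(get_residues(genome, "genome"))
  L <- nchar(gseq)
  rl <- config$read_length
  if (rl >= L) abort("read length must be shorter than the genome")
  withr::with_seed(derive_seed(config$seed, 7919L), {
    n_pairs <- round(config$depth * L / (2 * rl))
    ins <- pmax(2L * rl, round(rnorm(n_pairs, config$insert_mean,
                                     config$insert_sd)))
    fs <- sample.int(L, n_pairs, replace = TRUE) - 1L
    doubled <- paste0(gseq, gseq)
    r1 <- substring(doubled, fs + 1L, fs + rl)
    r2_start <- fs + ins - rl
    r2 <- revcomp(substring(doubled, r2_start + 1L, r2_start + rl))
    reads <- tibble(
      pair_id = rep(sprintf("p%06d", seq_len(n_pairs)), 2L),
      mate = rep(c(1L, 2L), each = n_pairs),
      seq = c(r1, r2),
      start = c(fs, r2_start),
      end = c(fs + rl, r2_start + rl),
      strand = rep(c("+", "-"), each = n_pairs))
    # normalise wrapped starts into [0, L)
    over <- reads$start >= L
    reads$start[over] <- reads$start[over] - L
    reads$end[over] <- reads$end[over] - L
    if (config$error_model == "uniform_substitution") {
      reads$seq <- vapply(reads$seq, function(s) {
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        nmut <- stats::rbinom(1L, length(ch), config$error_rate)
        if (nmut > 0L) ch <- substitute_at(ch, sample(length(ch), nmut))
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    } else if (config$error_model == "homopolymer_indel") {
      reads$seq <- vapply(reads$seq, function(s) {
        runs <- gregexpr("A{4,}|C{4,}|G{4,}|T{4,}", s)[[1]]
        if (runs[1] == -1L) return(s)
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        lens <- attr(runs, "match.length")
        # process right-to-left so positions stay valid
        for (k in rev(seq_along(runs))) {
          if (runif(1) >= config$homopolymer_indel_rate) next
          at <- runs[k]
          if (runif(1) < 0.5) {
            ch <- append(ch, ch[at], after = at)    # one extra base
          } else {
            ch <- ch[-at]                           # one base short
          }
        }
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    reads
  })
}

#' Reshape simulated reads into mate-pair rows
#'
#' @param reads Output of [simulate_reads()].
#' @return Tibble `pair_id`, `read1`, `read2` suitable for
#'   [map_read_pairs()].
#' @export
pair_table <- function(reads) {
  r1 <- reads[reads$mate == 1L, c("pair_id", "seq")]
  r2 <- reads[reads$mate == 2L, c("pair_id", "seq")]
  tibble(pair_id = r1$pair_id, read1 = r1$seq,
         read2 = r2$seq[match(r1$pair_id, r2$pair_id)])
}

#' @export
print.organelle_sim <- function(x, ...) {
  cat(sprintf(
    "<organelle_sim> mitogenome %s bp, plastome %s bp; %d repeats, %d insertions, %d native genes (seed %d)\n",
    format(x$mitogenome$length, big.mark = ","),
    format(x$plastome$length, big.mark = ","),
    nrow(x$truth$repeats), nrow(x$truth$mipts), nrow(x$mito_genes),
    x$config$seed))
  invisible(x)
}
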