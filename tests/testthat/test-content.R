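# Gene/intron presence scoring and the content matrix.

# A small panel: three genes with references, one of them intron-bearing.
make_panel <- function(seed = 2001) {
  withr::with_seed(seed, {
    genes <- tibble::tibble(
      gene = c("gA", "gB", "gC"),
      residues = vapply(c(600L, 750L, 660L), orgdecay:::random_cds,
                        character(1)),
      category = c("core", "core", "ribosomal"))
    intron <- rand_dna(301)  # length not a multiple of 3: splicing matters
    bg <- function(n) rand_dna(n)
    list(genes = genes, intron = intron, bg = bg)
  })
}

embed <- function(parts) paste(parts, collapse = "")

test_that("gene scoring distinguishes present, lost, pseudogene and tentative", {
  p <- make_panel()
  g <- p$genes
  withr::with_seed(2002, {
    genome_present <- embed(c(rand_dna(400), g$residues[1], rand_dna(400)))
    genome_lost <- embed(c(rand_dna(400), rand_dna(400)))
    ps <- make_disrupted_copy(g$residues[1], "frameshift", 0.40)
    genome_pseudo <- embed(c(rand_dna(400), ps$residues, rand_dna(400)))
    tn <- make_disrupted_copy(g$residues[1], "truncation3", 0.25)
    genome_tent <- embed(c(rand_dna(400), tn$residues, rand_dna(400)))
  })
  ref <- g[1, ]
  expect_equal(score_gene(genome_present, ref)$call, "present")
  expect_equal(score_gene(genome_lost, ref)$call, "lost")
  expect_equal(score_gene(genome_pseudo, ref)$call, "pseudogene")
  expect_equal(score_gene(genome_tent, ref)$call, "tentative")
  # minus-strand locus scores the same
  expect_equal(score_gene(revcomp(genome_present), ref)$call, "present")
})

test_that("a warning accompanies non-detection of a very short gene", {
  withr::with_seed(2003, {
    tiny <- orgdecay:::random_cds(225L)
    genome <- rand_dna(2000)
  })
  expect_warning(out <- score_gene(genome, list(id = "atp9", residues = tiny)),
                 "short")
  expect_equal(out$call, "lost")
})

test_that("intron scoring follows the host call and exon anchors", {
  p <- make_panel()
  gB <- p$genes$residues[2]
  exon1 <- substr(gB, 1, 375); exon2 <- substr(gB, 376, nchar(gB))
  iref <- list(name = "gB-i1", host = "gB", splicing = "cis",
               residues = p$intron, left_flank = exon1, right_flank = exon2)
  withr::with_seed(2004, {
    genome_with <- embed(c(rand_dna(300), exon1, p$intron, exon2,
                           rand_dna(300)))
    genome_without <- embed(c(rand_dna(300), gB, rand_dna(300)))
  })
  # host lost forces "x" without touching the genome
  expect_equal(score_intron("lost", genome_with, iref)$call,
               "intron_host_lost")
  expect_equal(score_intron("present", genome_with, iref)$call, "present")
  expect_equal(score_intron("present", genome_without, iref)$call, "lost")
  # a pseudogenized host with retained intron sequence scores remnant
  expect_equal(score_intron("pseudogene", genome_with, iref)$call, "remnant")
  # minus-strand locus
  expect_equal(score_intron("present", revcomp(genome_with), iref)$call,
               "present")
})

test_that("an intron-bearing host still classifies as present", {
  p <- make_panel()
  gB <- p$genes$residues[2]
  exon1 <- substr(gB, 1, 375); exon2 <- substr(gB, 376, nchar(gB))
  withr::with_seed(2005, {
    genome <- embed(c(rand_dna(300), exon1, p$intron, exon2, rand_dna(300)))
  })
  out <- score_gene(genome, p$genes[2, ])
  expect_equal(out$call, "present")
})

test_that("the content matrix respects taxon order and the lost-host rule", {
  p <- make_panel()
  g <- p$genes
  gB <- g$residues[2]
  exon1 <- substr(gB, 1, 375); exon2 <- substr(gB, 376, nchar(gB))
  registry <- element_registry(
    g[, c("gene", "residues", "category")] |>
      dplyr::rename(name = "gene"),
    tibble::tibble(name = "gB-i1", host = "gB", ordinal = 1L,
                   splicing = "cis", residues = p$intron,
                   left_flank = exon1, right_flank = exon2))
  withr::with_seed(2006, {
    t1 <- embed(c(rand_dna(200), g$residues[1], rand_dna(150),
                  exon1, p$intron, exon2, rand_dna(150), g$residues[3],
                  rand_dna(200)))
    # taxon 2 lost gB entirely and pseudogenized gC
    psC <- make_disrupted_copy(g$residues[3], "premature_stop", 0.5)
    t2 <- embed(c(rand_dna(200), g$residues[1], rand_dna(150), psC$residues,
                  rand_dna(200)))
  })
  taxa <- tibble::tibble(taxon = c("tax1", "tax2"), residues = c(t1, t2))
  m <- build_matrix(taxa, registry)
  expect_s3_class(m, "content_matrix")
  expect_equal(unique(m$taxon), c("tax1", "tax2"))
  cell <- function(tx, el) m$call[m$taxon == tx & m$element == el]
  expect_equal(cell("tax1", "gA"), "present")
  expect_equal(cell("tax1", "gB-i1"), "present")
  expect_equal(cell("tax2", "gB"), "lost")
  expect_equal(cell("tax2", "gB-i1"), "intron_host_lost")
  expect_equal(cell("tax2", "gC"), "pseudogene")

  # permuting taxon input order permutes rows only
  m2 <- build_matrix(taxa[2:1, ], registry)
  expect_equal(unique(m2$taxon), c("tax2", "tax1"))
  for (el in unique(m$element)) {
    expect_equal(m2$call[m2$taxon == "tax1" & m2$element == el],
                 cell("tax1", el))
  }
  # shared counts are invariant under taxon order
  expect_equal(shared_counts(m, registry), shared_counts(m2, registry))
  sc <- shared_counts(m, registry)
  expect_equal(sc$shared_genes, 1L)       # only gA intact in both
  expect_equal(sc$shared_core_genes, 1L)
  expect_equal(sc$cis_introns_shared, 0L)

  expect_error(build_matrix(taxa[c(1, 1), ], registry), "duplicate")
})

test_that("the published matrix fixture reproduces the conserved-set counts", {
  m <- paper_fixture("orobanchaceae_matrix")
  sc <- shared_counts(m)
  expect_equal(sc$shared_genes, 29L)
  expect_equal(sc$shared_core_genes, 23L)
  expect_equal(sc$trans_introns_shared, 6L)
  # all seven taxa retain 15 cis-spliced introns (the 14 conserved
  # cis-arranged introns plus the mobile cox1 intron)
  expect_equal(sc$cis_introns_shared, 15L)
  # empty matrix gives zeros
  empty <- m[0, ]
  expect_equal(shared_counts(empty)$shared_genes, 0L)
})

test_that("fixture gene sets match the published enumerations", {
  conserved <- paper_fixture("conserved_genes")
  expect_length(conserved, 29L)
  core <- paper_fixture("core_genes")
  expect_length(core, 24L)
  # the 23 conserved core genes named in the text are all core
  named23 <- c("nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
               "nad7", "nad9", "cob", "cox1", "cox2", "cox3",
               "atp1", "atp4", "atp6", "atp8",
               "ccmB", "ccmC", "ccmFc", "ccmFn", "matR", "mttB")
  expect_true(all(named23 %in% core))
  expect_true(all(named23 %in% conserved))
  expect_equal(setdiff(core, conserved), "atp9")
  reg <- paper_fixture("fig2_registry")
  expect_setequal(reg$introns$name[reg$introns$splicing == "trans"],
                  c("nad1-i1", "nad1-i3", "nad1-i4", "nad2-i2",
                    "nad5-i2", "nad5-i3"))
  expect_error(paper_fixture("nope"), "unknown fixture")
})

test_that("intron hosts must exist in the registry gene list", {
  expect_error(element_registry(
    tibble::tibble(name = "gA", category = "core"),
    tibble::tibble(name = "gZ-i1", host = "gZ", ordinal = 1L,
                   splicing = "cis")), "hosts")
})
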