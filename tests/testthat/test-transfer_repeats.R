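# MIPT and dispersed-repeat detection and quantification.

test_that("segment quantification reproduces the printed coverage arithmetic", {
  expect_equal(quantify_segments(tibble::tibble(start = 0L, end = 82133L),
                                 495499L)$percent, 16.6)
  expect_equal(quantify_segments(tibble::tibble(start = 0L, end = 13525L),
                                 495499L)$percent, 2.7)
  q <- quantify_segments(tibble::tibble(start = c(0L, 50L),
                                        end = c(100L, 150L)), 1000L)
  expect_equal(q$covered_bp, 150L)
  expect_equal(q$count, 2L)
  expect_error(quantify_segments(tibble::tibble(start = 0L, end = 1L), 0),
               "positive")
})

test_that("segment quantification is order-invariant and merge-idempotent", {
  withr::with_seed(3001, {
    segs <- tibble::tibble(start = sample.int(5000, 20) - 1L)
    segs$end <- segs$start + sample(50:500, 20, TRUE)
  })
  q1 <- quantify_segments(segs, 6000L)
  q2 <- quantify_segments(segs[sample.int(20), ], 6000L)
  expect_equal(q1$covered_bp, q2$covered_bp)
  expect_equal(q1$percent, q2$percent)
  merged <- orgdecay:::merge_intervals(segs$start, segs$end)
  q3 <- quantify_segments(merged, 6000L)
  expect_equal(q3$covered_bp, q1$covered_bp)
})

test_that("percent rounding is half away from zero to one decimal", {
  expect_equal(orgdecay:::round_half_up(2.7296 * 10, 0) / 10, 2.7)
  expect_equal(orgdecay:::round_half_up(16.5759, 1), 16.6)
  expect_equal(orgdecay:::round_half_up(2.25, 1), 2.3)
  expect_equal(orgdecay:::round_half_up(-2.25, 1), -2.3)
})

test_that("unrelated genomes yield no insertions; planted segments are exact", {
  withr::with_seed(3002, {
    mito <- rand_dna(10000)
    plast <- rand_dna(5000)
  })
  expect_equal(nrow(find_mipts(mito, plast)), 0L)

  # one 500-bp plastid segment copied into the mitogenome
  seg <- substr(plast, 1001, 1500)
  mito2 <- paste0(substr(mito, 1, 4000), "NNNNNN", seg, "NNNNNN",
                  substr(mito, 4001, 10000))
  m <- find_mipts(mito2, plast)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(4006L, 4506L))
  expect_equal(m$mean_identity, 1)
  expect_equal(m$source[[1]]$start, 1000L)
  expect_equal(m$source[[1]]$end, 1500L)

  # two planted segments 30 bp apart merge into one insertion
  segB <- substr(plast, 2001, 2300)
  mito3 <- paste0(substr(mito, 1, 4000), seg, substr(mito, 4001, 4030),
                  segB, substr(mito, 4031, 10000))
  m3 <- find_mipts(mito3, plast)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$length, 500L + 30L + 300L)
  expect_equal(m3$n_fragments, 2L)
})

test_that("genes carried by insertions are classified; partial genes are excluded", {
  withr::with_seed(3003, {
    gene1 <- orgdecay:::random_cds(600)
    gene2 <- orgdecay:::random_cds(600)
    gene3 <- orgdecay:::random_cds(600)
    plast <- paste0(rand_dna(500), gene1, rand_dna(200), gene2,
                    rand_dna(200), gene3, rand_dna(500))
    genes <- tibble::tibble(
      gene = c("p1", "p2", "p3"),
      start = c(500L, 1300L, 2100L),
      end = c(1100L, 1900L, 2700L),
      residues = c(gene1, gene2, gene3))
    # insertion carrying all of gene1, a disrupted copy of gene2, and only
    # half of gene3
    ps <- make_disrupted_copy(gene2, "frameshift", 0.40)
    insertion <- paste0(substr(plast, 451, 1150), rand_dna(60), ps$residues,
                        rand_dna(60), substr(plast, 2101, 2400))
    mito <- paste0(rand_dna(2000), "NNNNNN", insertion, "NNNNNN",
                   rand_dna(2000))
  })
  mipts <- find_mipts(mito, plast)
  out <- genes_in_mipts(mipts, genes, mito, plast)
  expect_true("p1" %in% out$gene)
  expect_equal(out$status[out$gene == "p1"], "functional")
  expect_equal(out$containment[out$gene == "p1"], 1)
  expect_equal(out$status[out$gene == "p2"], "pseudogene")
  expect_false("p3" %in% out$gene)  # only half contained, below 0.90
})

test_that("repeat detection finds planted pairs and never the self-match", {
  withr::with_seed(3004, g <- rand_dna(10000))
  expect_equal(nrow(find_repeats(g)), 0L)

  withr::with_seed(3005, unit <- rand_dna(200))
  g2 <- paste0(substr(g, 1, 3000), "NNNNNN", unit, "NNNNNN",
               substr(g, 3001, 7000), "NNNNNN", unit, "NNNNNN",
               substr(g, 7001, 10000))
  r <- find_repeats(g2)
  expect_equal(nrow(r), 1L)
  expect_equal(r$orientation, "direct")
  expect_equal(c(r$a_start, r$a_end), c(3006L, 3206L))
  expect_equal(c(r$b_start, r$b_end), c(7218L, 7418L))
  expect_true(all(r$a_start != r$b_start))

  # inverted copy
  g3 <- paste0(substr(g, 1, 3000), "NNNNNN", unit, "NNNNNN",
               substr(g, 3001, 7000), "NNNNNN", revcomp(unit), "NNNNNN",
               substr(g, 7001, 10000))
  r3 <- find_repeats(g3)
  expect_equal(nrow(r3), 1L)
  expect_equal(r3$orientation, "inverted")
})

test_that("reversing the genome preserves orientations and mirrors coordinates", {
  withr::with_seed(3006, {
    g <- rand_dna(8000)
    unit <- rand_dna(150)
  })
  g2 <- paste0(substr(g, 1, 2000), "NNNNNN", unit, "NNNNNN",
               substr(g, 2001, 5000), "NNNNNN", revcomp(unit), "NNNNNN",
               substr(g, 5001, 8000))
  r_f <- find_repeats(g2)
  r_r <- find_repeats(revcomp(g2))
  expect_equal(nrow(r_f), 1L)
  expect_equal(nrow(r_r), 1L)
  expect_equal(r_r$orientation, r_f$orientation)
  L <- nchar(g2)
  expect_equal(r_r$a_start, L - r_f$b_end)
  expect_equal(r_r$b_end, L - r_f$a_start)
})

test_that("repeat size classes use half-open bins", {
  pairs <- tibble::tibble(
    repeat_id = c("r1", "r2", "r3", "r4", "r5"),
    a_start = c(0L, 10000L, 20000L, 30000L, 40000L),
    a_end = c(8700L, 10120L, 20060L, 30099L, 40100L),
    b_start = c(100000L, 110000L, 120000L, 130000L, 140000L),
    b_end = c(108700L, 110120L, 120060L, 130099L, 140100L),
    length = c(8700L, 120L, 60L, 99L, 100L),
    identity = 1, orientation = "direct")
  s <- summarize_repeats(pairs, 495499L)
  expect_equal(s$n_large, 1L)
  expect_equal(s$n_intermediate, 2L)  # 120 and the boundary 100
  expect_equal(s$n_small, 2L)         # 60 and the boundary 99
  expect_equal(s$covered_bp, 2L * sum(pairs$length))
})

test_that("detection recovers the truth manifest on a noise-free genome pair", {
  cfg <- generator_config(seed = 3007, mito_length = 80000,
                          plast_length = 25000, n_mito_genes = 6,
                          n_plast_genes = 14, n_large_repeats = 1,
                          large_repeat_len = 3000, n_intermediate_repeats = 5,
                          n_small_repeats = 8, n_mipts = 10,
                          mipt_genes_total = 8, mipt_identity = 1.0)
  sim <- make_organelle_pair(cfg)
  mipts <- find_mipts(sim$mitogenome, sim$plastome)
  tm <- sim$truth$mipts[order(sim$truth$mipts$start), ]
  expect_equal(nrow(mipts), nrow(tm))
  expect_equal(mipts$start, tm$start)
  expect_equal(mipts$end, tm$end)
  # coverage over detected equals coverage over planted
  expect_equal(
    quantify_segments(mipts[, c("start", "end")], cfg$mito_length),
    quantify_segments(tm[, c("start", "end")], cfg$mito_length))

  reps <- find_repeats(sim$mitogenome)
  tr <- sim$truth$repeats[order(sim$truth$repeats$a_start), ]
  expect_equal(nrow(reps), nrow(tr))
  expect_equal(reps$a_start, tr$a_start)
  expect_equal(reps$a_end, tr$a_end)
  expect_equal(reps$b_start, tr$b_start)
  expect_equal(reps$b_end, tr$b_end)
  expect_equal(reps$orientation, tr$orientation)
  s <- summarize_repeats(reps, cfg$mito_length)
  expect_equal(s$n_large, cfg$n_large_repeats)
  expect_equal(s$n_intermediate, cfg$n_intermediate_repeats)
  expect_equal(s$n_small, cfg$n_small_repeats)

  # carried-gene inventory matches the planted one
  gm <- genes_in_mipts(mipts, sim$plast_genes, sim$mitogenome, sim$plastome)
  truth_g <- sim$truth$mipt_genes
  expect_setequal(gm$gene, truth_g$gene)
  got <- setNames(gm$status, gm$gene)
  expect_equal(unname(got[truth_g$gene]), truth_g$expected_status)
})
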