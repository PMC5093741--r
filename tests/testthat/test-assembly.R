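# Read-pair mapping, link-graph scaffolding, coverage and assembly choice.

test_that("mates map at exact loci and fail below the identity threshold", {
  withr::with_seed(4001, {
    c1 <- rand_dna(5000); c2 <- rand_dna(5000)
    read_ok <- substr(c1, 1001, 1100)
    # a read with 15 substitutions: 85% identity, below the 90% threshold
    rv <- strsplit(read_ok, "")[[1]]
    pos <- sample(100, 15)
    for (p in pos) rv[p] <- setdiff(c("A", "C", "G", "T"), rv[p])[1]
    read_bad <- paste(rv, collapse = "")
  })
  contigs <- tibble::tibble(id = c("ctgA", "ctgB"), residues = c(c1, c2))
  pairs <- tibble::tibble(pair_id = "p1", read1 = read_ok, read2 = read_bad)
  m <- map_read_pairs(pairs, contigs)
  m1 <- m[m$mate == 1, ]; m2 <- m[m$mate == 2, ]
  expect_true(m1$mapped)
  expect_equal(m1$contig, "ctgA")
  expect_equal(c(m1$start, m1$end), c(1000L, 1100L))
  expect_false(m2$mapped)
})

test_that("ties break to the lexicographically first contig", {
  withr::with_seed(4002, {
    locus <- rand_dna(300)
    cA <- paste0(rand_dna(500), locus, rand_dna(500))
    cB <- paste0(rand_dna(700), locus, rand_dna(300))
  })
  contigs <- tibble::tibble(id = c("ctgB", "ctgA"), residues = c(cB, cA))
  pairs <- tibble::tibble(pair_id = "p1",
                          read1 = substr(locus, 51, 150),
                          read2 = substr(locus, 151, 250))
  m <- map_read_pairs(pairs, contigs)
  expect_true(all(m$contig == "ctgA"))
})

test_that("the link graph counts spanning pairs and applies min_support", {
  withr::with_seed(4003, {
    cA <- rand_dna(3000); cB <- rand_dna(3000)
  })
  contigs <- tibble::tibble(id = c("ctgA", "ctgB"), residues = c(cA, cB))
  # internal pair only -> no edges
  internal <- tibble::tibble(pair_id = "i1",
                             read1 = substr(cA, 101, 200),
                             read2 = revcomp(substr(cA, 701, 800)))
  g0 <- build_link_graph(map_read_pairs(internal, contigs), contigs)
  expect_equal(nrow(g0$edges), 0L)

  # ten synthetic pairs spanning the end of A to the start of B
  spanning <- tibble::tibble(
    pair_id = sprintf("s%02d", 1:10),
    read1 = vapply(seq(2500, 2770, by = 30), function(s)
      substr(cA, s, s + 99), character(1)),
    read2 = vapply(seq(150, 420, by = 30), function(s)
      revcomp(substr(cB, s, s + 99)), character(1)))
  maps <- map_read_pairs(spanning, contigs)
  g1 <- build_link_graph(maps, contigs, insert_size = 800, min_support = 2L)
  expect_equal(nrow(g1$edges), 1L)
  expect_equal(g1$edges$support, 10L)
  expect_setequal(c(g1$edges$end_a, g1$edges$end_b), c("ctgA:R", "ctgB:L"))
  # conservation: edge support equals the number of cross-contig pairs
  wide <- tidyr::pivot_wider(maps[maps$mapped, c("pair_id", "mate", "contig")],
                             names_from = "mate", values_from = "contig")
  expect_equal(sum(g1$edges$support),
               sum(wide$`1` != wide$`2`, na.rm = TRUE))

  # a single spanning pair is below the support threshold
  g2 <- build_link_graph(maps[maps$pair_id == "s01", ], contigs,
                         min_support = 2L)
  expect_equal(nrow(g2$edges), 0L)
})

test_that("unique edges chain contigs and ambiguous ends flag repeats", {
  nodes <- tibble::tibble(contig = c("ctgA", "ctgB", "ctgC"),
                          length = c(1000L, 1000L, 1000L),
                          mean_depth = c(30, 30, 30))
  edges <- tibble::tibble(end_a = c("ctgA:R", "ctgB:R"),
                          end_b = c("ctgB:L", "ctgC:L"),
                          support = c(5L, 4L), median_gap = c(10, -5))
  g <- orgdecay:::new_contig_graph(nodes, edges)
  j <- infer_joins(g)
  expect_equal(j$scaffolds$contig, c("ctgA", "ctgB", "ctgC"))
  expect_equal(unique(j$scaffolds$scaffold), "scaffold01")
  expect_equal(j$scaffolds$orientation, c("+", "+", "+"))
  expect_false(any(j$repeat_flags$flagged))

  # one end linking two distinct partners flags the contig and breaks paths
  edges2 <- dplyr::bind_rows(edges, tibble::tibble(
    end_a = "ctgB:R", end_b = "ctgA:L", support = 3L, median_gap = 0))
  j2 <- infer_joins(orgdecay:::new_contig_graph(nodes, edges2))
  expect_true(j2$repeat_flags$flagged[j2$repeat_flags$contig == "ctgB"])
  expect_false("ctgB" %in% j2$scaffolds$contig)

  # depth flag: 2x the median marks a collapsed repeat
  nodes3 <- nodes; nodes3$mean_depth <- c(30, 62, 31)
  j3 <- infer_joins(orgdecay:::new_contig_graph(nodes3, edges))
  f3 <- j3$repeat_flags
  expect_true(f3$by_depth[f3$contig == "ctgB"])
  expect_true(f3$flagged[f3$contig == "ctgB"])
})

test_that("join inference is invariant under contig input order", {
  withr::with_seed(4004, g <- rand_dna(30000))
  cuts <- c(0, 9000, 16000, 23000, 30000)
  contigs <- tibble::tibble(id = sprintf("ctg%d", 1:4),
                            residues = substring(g, cuts[-5] + 1, cuts[-1]))
  cfg <- generator_config(seed = 4005, depth = 15)
  reads <- simulate_reads(tibble::tibble(id = "g", residues = g), cfg)
  pr <- pair_table(reads)
  j1 <- infer_joins(build_link_graph(map_read_pairs(pr, contigs), contigs))
  j2 <- infer_joins(build_link_graph(map_read_pairs(pr, contigs[c(3, 1, 4, 2), ]),
                                     contigs[c(3, 1, 4, 2), ]))
  expect_equal(j1$scaffolds, j2$scaffolds)
  # every true adjacency is recovered, and no join contradicts the layout
  path <- j1$scaffolds$contig
  adj <- paste(path[-length(path)], path[-1])
  true_adj <- c("ctg1 ctg2", "ctg2 ctg3", "ctg3 ctg4",
                "ctg4 ctg1")  # circular genome wraps
  expect_true(all(adj %in% c(true_adj,
                             sapply(strsplit(true_adj, " "), function(x)
                               paste(rev(x), collapse = " ")))))
})

test_that("coverage profiles count covering reads and conserve aligned bases", {
  withr::with_seed(4006, g <- rand_dna(1000))
  pl <- tibble::tibble(start = 0L, end = 100L)
  tr <- coverage_profile(pl, g, circular = FALSE)
  expect_equal(sum(tr$depth), 100L)
  expect_equal(unique(tr$depth[tr$pos < 100]), 1L)
  expect_equal(unique(tr$depth[tr$pos >= 100]), 0L)

  # wrapped placement on a circular genome
  tr2 <- coverage_profile(tibble::tibble(start = 950L, end = 1050L), g,
                          circular = TRUE)
  expect_equal(sum(tr2$depth), 100L)
  expect_equal(tr2$depth[tr2$pos == 0], 1L)
  expect_error(coverage_profile(tibble::tibble(start = 950L, end = 1050L), g,
                                circular = FALSE), "linear")
})

test_that("simulated uniform coverage is close to the requested depth", {
  withr::with_seed(4007, g <- rand_dna(20000))
  cfg <- generator_config(seed = 4008, depth = 50)
  reads <- simulate_reads(tibble::tibble(id = "g", residues = g), cfg)
  tr <- coverage_profile(reads, g, circular = TRUE)
  expect_lt(abs(mean(tr$depth) - 50) / 50, 0.05)
  expect_equal(sum(tr$depth), sum(reads$end - reads$start))
})

test_that("depth ratios behave like region means", {
  depth <- c(rep(30L, 500), rep(60L, 200), rep(30L, 300))
  track <- orgdecay:::new_coverage_track("g", depth)
  expect_equal(depth_ratio(track, c(500, 700)), 2)
  expect_equal(depth_ratio(track, c(0, 500),
                           background = tibble::tibble(start = 0L, end = 500L)),
               1)
  # scale invariance
  track2 <- orgdecay:::new_coverage_track("g", depth * 2L)
  expect_equal(depth_ratio(track2, c(500, 700)), 2)
  zero <- orgdecay:::new_coverage_track("g", c(rep(0L, 500), rep(10L, 500)))
  expect_error(depth_ratio(zero, c(500, 1000)), "zero background")
})

test_that("assembly choice maximises length first, then fewest contigs", {
  stats <- tibble::tibble(assembly_id = c("k61", "k71"),
                          organellar_bp = c(500000L, 480000L),
                          n_contigs = c(10L, 2L))
  expect_equal(select_best_assembly(stats), "k61")
  stats2 <- tibble::tibble(assembly_id = c("a", "b"),
                           organellar_bp = c(100L, 100L),
                           n_contigs = c(5L, 2L))
  expect_equal(select_best_assembly(stats2), "b")
  expect_equal(select_best_assembly(stats2[1, ]), "a")
  expect_error(select_best_assembly(stats2[0, ]), "no assemblies")
})
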