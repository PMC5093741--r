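# Disruption detection, disrupted-fraction arithmetic, and status calls.

ref_gene <- function(ncod, seed) {
  withr::with_seed(seed, orgdecay:::random_cds(3L * ncod))
}

test_that("an identical candidate is functional with no disruptions", {
  ref <- ref_gene(100, 1001)
  expect_equal(nrow(detect_disruptions(ref, ref)), 0L)
  call <- classify_gene(ref, ref, gene = "g")
  expect_equal(call$status, "functional")
  expect_equal(call$overall_fraction, 0)
})

test_that("an in-frame stop substituted at codon 50 of 100 is a premature stop", {
  ref <- ref_gene(100, 1002)
  cand <- paste0(substr(ref, 1, 147), "TAA", substr(ref, 151, 300))
  d <- detect_disruptions(cand, ref)
  ps <- d[d$kind == "premature_stop", ]
  expect_equal(nrow(ps), 1L)
  expect_equal(c(ps$ref_start, ps$ref_end), c(147L, 150L))
  expect_true(ps$in_frame)
  fr <- disruption_fractions(d, 300L,
                             domains = tibble::tibble(start = 0L, end = 120L))
  expect_equal(fr$overall_fraction, 0.50)
  expect_equal(fr$domain_fraction, 0)
  expect_equal(fr$truncated_fraction, 0)
})

test_that("a single-base deletion is a frameshift with indel length 1", {
  ref <- ref_gene(100, 1003)
  # delete one base inside codon 10 (1-based codon, nt 28-30)
  cand <- paste0(substr(ref, 1, 28), substr(ref, 30, 300))
  d <- detect_disruptions(cand, ref)
  fs <- d[d$kind == "frameshift", ]
  expect_equal(nrow(fs), 1L)
  expect_equal(fs$indel_len, 1L)
  expect_equal(fs$indel_type, "del")
  expect_lt(abs(fs$ref_start - 28L), 3L)  # gap placement within its context
})

test_that("a candidate missing its last 30 of 100 codons is 3'-truncated", {
  ref <- ref_gene(100, 1004)
  cand <- substr(ref, 1, 210)
  d <- detect_disruptions(cand, ref)
  tr <- d[d$kind == "truncation3", ]
  expect_equal(nrow(tr), 1L)
  expect_equal(c(tr$ref_start, tr$ref_end), c(210L, 300L))
  fr <- disruption_fractions(d, 300L)
  expect_equal(fr$overall_fraction, 0.30)
  expect_equal(fr$truncated_fraction, 0.30)
})

test_that("compensating frameshifts bound the disrupted interval", {
  d <- tibble::tibble(
    kind = c("frameshift", "frameshift"),
    ref_start = c(27L, 57L), ref_end = c(28L, 57L),
    indel_len = c(1L, 1L), indel_type = c("del", "ins"),
    in_frame = NA, in_homopolymer = FALSE, homopolymer_len = 0L)
  fr <- disruption_fractions(d, 300L)
  expect_equal(fr$overall_fraction, 0.10)

  # and end-to-end through the aligner
  ref <- ref_gene(100, 1005)
  cand <- paste0(substr(ref, 1, 27), substr(ref, 29, 57), "G",
                 substr(ref, 58, 300))
  # the deletion may fall near a short mononucleotide run, in which case the
  # classifier warns about missing read support; the call itself is the point
  call <- suppressWarnings(classify_gene(cand, ref, gene = "g"))
  expect_equal(call$status, "functional")
  expect_lt(abs(call$overall_fraction - 0.10), 0.02)
})

test_that("no disruptions give zero fractions", {
  fr <- disruption_fractions(orgdecay:::empty_disruptions(), 300L)
  expect_equal(unlist(fr), c(domain_fraction = 0, overall_fraction = 0,
                             truncated_fraction = 0))
})

test_that("status thresholds are strict for pseudogenes, inclusive for tentative", {
  ref <- ref_gene(100, 1006)
  # overall 0.50 -> pseudogene
  c1 <- make_disrupted_copy(ref, "premature_stop", 0.50)
  expect_equal(classify_gene(c1$residues, ref, gene = "g")$status, "pseudogene")
  # sole truncation at 0.25 -> tentative
  c2 <- make_disrupted_copy(ref, "truncation3", 0.25)
  expect_equal(classify_gene(c2$residues, ref, gene = "g")$status, "tentative")
  # late stop: overall 0.05, no domains -> functional
  c3 <- make_disrupted_copy(ref, "premature_stop", 0.05)
  expect_equal(classify_gene(c3$residues, ref, gene = "g")$status, "functional")
  # small overall disruption concentrated in the conserved domain -> pseudogene
  c4 <- make_disrupted_copy(ref, "premature_stop", 0.15)
  dom <- tibble::tibble(start = 240L, end = 300L)
  call4 <- classify_gene(c4$residues, ref, domains = dom, gene = "g")
  expect_equal(call4$status, "pseudogene")
  expect_lt(call4$overall_fraction, 0.31)
  expect_gt(call4$domain_fraction, 0.20)
  # same disruption without domain annotation stays below both thresholds
  call4b <- classify_gene(c4$residues, ref, gene = "g")
  expect_equal(call4b$status, "functional")
})

test_that("homopolymer artifact rule follows run length and read support", {
  cfg <- classifier_config()
  fs <- function(hp_len) tibble::tibble(
    kind = "frameshift", ref_start = 10L, ref_end = 11L, indel_len = 1L,
    indel_type = "del", in_frame = NA,
    in_homopolymer = hp_len >= cfg$homopolymer_min_run,
    homopolymer_len = hp_len)
  sup <- function(cov, with) list(covering_reads = cov, reads_with_indel = with)
  # in a 6-bp run, 1 of 10 covering reads carry the indel: artifact
  expect_equal(homopolymer_artifact_check(fs(6L), sup(10L, 1L), cfg),
               "artifact")
  # run of 3 is below the threshold: supported regardless of reads
  expect_equal(homopolymer_artifact_check(fs(3L), sup(10L, 1L), cfg),
               "supported")
  # 9 of 10 reads carry the indel: supported (0.9 >= 0.8)
  expect_equal(homopolymer_artifact_check(fs(5L), sup(10L, 9L), cfg),
               "supported")
  # too few covering reads: the check does not apply
  expect_equal(homopolymer_artifact_check(fs(6L), sup(2L, 0L), cfg),
               "supported")
  # missing support for an in-run frameshift: supported, with a warning
  expect_warning(
    out <- homopolymer_artifact_check(fs(6L), NULL, cfg),
    "read support")
  expect_equal(out, "supported")
})

test_that("artifact frameshifts are dropped before classification", {
  withr::with_seed(1007, core <- orgdecay:::random_cds(540))
  # insert two in-frame AAA codons mid-gene: a 6-bp homopolymer hotspot
  ref <- paste0(substr(core, 1, 270), "AAAAAA", substr(core, 271, 540))
  orgdecay:::validate_reference_cds(ref)
  run_at <- as.integer(regexpr("A{6,}", ref))
  # delete one A from the run: frameshift inside the homopolymer
  cand <- paste0(substr(ref, 1, run_at), substr(ref, run_at + 2, nchar(ref)))
  det <- detect_disruptions(cand, ref)
  fs_row <- det[det$kind == "frameshift", ]
  expect_true(fs_row$in_homopolymer[1])
  sup <- tibble::tibble(ref_start = fs_row$ref_start[1],
                        covering_reads = 10L, reads_with_indel = 1L)
  call <- suppressWarnings(
    classify_gene(cand, ref, read_support = sup, gene = "g"))
  expect_equal(call$artifacts_dropped, 1L)
  expect_equal(call$status, "functional")
  # without read support the frameshift stands (with a warning) and the
  # downstream frame disruption makes the call a pseudogene
  expect_warning(call2 <- classify_gene(cand, ref, gene = "g"),
                 "read support")
  expect_equal(call2$status, "pseudogene")
})

test_that("adding disruptions never moves a call toward functional", {
  severity <- c(functional = 1L, tentative = 2L, pseudogene = 3L)
  base <- tibble::tibble(
    kind = "premature_stop", ref_start = 150L, ref_end = 153L,
    indel_len = NA_integer_, indel_type = NA_character_, in_frame = TRUE,
    in_homopolymer = FALSE, homopolymer_len = 0L)
  extras <- list(
    tibble::tibble(kind = "truncation3", ref_start = 270L, ref_end = 300L,
                   indel_len = NA_integer_, indel_type = NA_character_,
                   in_frame = NA, in_homopolymer = FALSE,
                   homopolymer_len = 0L),
    tibble::tibble(kind = "frameshift", ref_start = 60L, ref_end = 61L,
                   indel_len = 1L, indel_type = "del", in_frame = NA,
                   in_homopolymer = FALSE, homopolymer_len = 0L),
    tibble::tibble(kind = "premature_stop", ref_start = 30L, ref_end = 33L,
                   indel_len = NA_integer_, indel_type = NA_character_,
                   in_frame = TRUE, in_homopolymer = FALSE,
                   homopolymer_len = 0L))
  status_of <- function(d) {
    fr <- disruption_fractions(d, 300L)
    if (fr$overall_fraction > 0.30) "pseudogene"
    else if (fr$truncated_fraction >= 0.20 && fr$truncated_fraction <= 0.30)
      "tentative"
    else "functional"
  }
  d <- base
  prev_status <- severity[[status_of(d)]]
  prev_overall <- disruption_fractions(d, 300L)$overall_fraction
  for (e in extras) {
    d <- dplyr::bind_rows(d, e)
    fr <- disruption_fractions(d, 300L)
    # the disrupted set only grows
    expect_gte(fr$overall_fraction, prev_overall)
    # once a pseudogene, always a pseudogene
    cur_status <- severity[[status_of(d)]]
    if (prev_status == 3L) expect_equal(cur_status, 3L)
    prev_status <- cur_status
    prev_overall <- fr$overall_fraction
  }
})

test_that("planted disruptions are recovered when clear of the thresholds", {
  kinds <- c("premature_stop", "frameshift", "truncation3", "truncation5",
             "frameshift_compensated")
  fractions <- c(0.05, 0.10, 0.15, 0.25, 0.35, 0.45, 0.55)
  withr::with_seed(1010, {
    for (k in kinds) {
      for (f in fractions) {
        ref <- orgdecay:::random_cds(3L * sample(120:250, 1))
        pc <- make_disrupted_copy(ref, k, f)
        # only assert when the planted fractions are clear of both thresholds
        clear <- abs(pc$expected$overall_fraction - 0.30) >= 0.02 &&
          abs(pc$expected$truncated_fraction - 0.20) >= 0.02 &&
          abs(pc$expected$truncated_fraction - 0.30) >= 0.02
        if (!clear) next
        call <- classify_gene(pc$residues, ref, gene = k)
        expect_equal(call$status, pc$expected$status,
                     info = sprintf("%s at %.2f", k, f))
        expect_lt(abs(call$overall_fraction - pc$expected$overall_fraction),
                  0.02)
      }
    }
  })
})

test_that("fractions stay within bounds and overall dominates truncation", {
  withr::with_seed(1011, {
    for (i in 1:25) {
      n <- sample(1:4, 1)
      kinds <- sample(c("premature_stop", "frameshift", "truncation3",
                        "truncation5"), n, replace = TRUE)
      L <- 300L
      d <- dplyr::bind_rows(lapply(kinds, function(k) {
        if (k == "truncation3") {
          s <- sample(200:290, 1)
          tibble::tibble(kind = k, ref_start = s, ref_end = L)
        } else if (k == "truncation5") {
          e <- sample(10:100, 1)
          tibble::tibble(kind = k, ref_start = 0L, ref_end = e)
        } else if (k == "premature_stop") {
          s <- 3L * sample(10:90, 1)
          tibble::tibble(kind = k, ref_start = s, ref_end = s + 3L)
        } else {
          s <- sample(30:250, 1)
          tibble::tibble(kind = k, ref_start = s, ref_end = s + 1L)
        }
      }))
      d$indel_len <- ifelse(d$kind == "frameshift", 1L, NA_integer_)
      d$indel_type <- ifelse(d$kind == "frameshift", "del", NA_character_)
      d$in_frame <- ifelse(d$kind == "premature_stop", TRUE, NA)
      d$in_homopolymer <- FALSE; d$homopolymer_len <- 0L
      dom <- tibble::tibble(start = 60L, end = 180L)
      fr <- disruption_fractions(d, L, dom)
      expect_true(all(unlist(fr) >= 0 & unlist(fr) <= 1))
      expect_gte(fr$overall_fraction, fr$truncated_fraction)
    }
  })
})
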