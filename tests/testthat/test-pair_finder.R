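# Elements used here are plain data.frames; alignment fixtures stay small
# (<= a few kb) so the whole file runs in seconds.

mk_elements <- function(start, end, strand = "+", chrom = "chr1",
                        name = "HERVH-int") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             name = name, join_id = seq_along(start),
             length = end - start + 1L, stringsAsFactors = FALSE)
}

test_that("length filter boundary is inclusive at the minimum", {
  el <- mk_elements(c(1L, 1L, 1L), c(4000L, 3999L, 5000L))
  kept <- filter_elements_by_length(el, 4000)
  expect_equal(kept$end, c(4000L, 5000L))
  set.seed(5)
  el2 <- mk_elements(rep(1L, 50), sample(3000:6000, 50))
  expect_equal(filter_elements_by_length(el2, 4000)$end,
               el2$end[el2$end - el2$start + 1L >= 4000])
})

test_that("candidate enumeration honours chrom, strand and separation", {
  a <- mk_elements(c(1000L, 57001L), c(7000L, 63000L))
  expect_equal(nrow(enumerate_candidate_pairs(a)), 1L)
  expect_equal(enumerate_candidate_pairs(a)$separation, 50000L)
  b <- mk_elements(c(1000L, 57001L), c(7000L, 63000L), strand = c("+", "-"))
  expect_equal(nrow(enumerate_candidate_pairs(b)), 0L)
  # overlapping elements are never paired
  ov <- mk_elements(c(1000L, 5000L), c(7000L, 12000L))
  expect_equal(nrow(enumerate_candidate_pairs(ov, min_sep = 0)), 0L)
  # bounds inclusive on both sides
  at_min <- mk_elements(c(1L, 10002L), c(1L, 10002L))
  expect_equal(nrow(enumerate_candidate_pairs(at_min)), 1L)
})

test_that("candidate enumeration equals O(n^2) brute force on random sets", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 10
    el <- data.frame(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample.int(3000000, n),
      strand = sample(c("+", "-"), n, replace = TRUE),
      name = "HERVH-int", join_id = seq_len(n), stringsAsFactors = FALSE)
    el$end <- el$start + sample(4000:8000, n, replace = TRUE)
    got <- enumerate_candidate_pairs(el, 10000, 1000000)
    exp <- pairs_oracle(el, 10000, 1000000)
    if (is.null(exp)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got[, c("chrom", "a_start", "b_start")], exp,
                   ignore_attr = TRUE)
    }
  }
})

test_that("local_align handles the identity case and rejects empty input", {
  aln <- local_align("ACGT", "ACGT")
  expect_equal(aln$identity, 1)
  expect_equal(aln$aln_length, 4L)
  expect_equal(aln$score, 4)
  expect_error(local_align("", "ACGT"), "empty")
})

test_that("local_align matches the quadratic DP oracle on short strings", {
  expect_equal(local_align("ACGTACGT", "ACGAACGT")$score,
               sw_full_oracle("ACGTACGT", "ACGAACGT")$score)
  set.seed(11)
  for (k in 1:10) {
    a <- random_seq(sample(30:120, 1))
    b <- random_seq(sample(30:120, 1))
    imp <- local_align(a, b)
    expect_equal(imp$score, sw_score_oracle(a, b))
    expect_equal(score_gapped_oracle(imp$aligned_a, imp$aligned_b),
                 imp$score)
  }
})

test_that("planted divergence is recovered as alignment identity", {
  pr <- fixture_pair(seed = 19, len = 4000, divergence = 0.05)
  aln <- local_align(pr$seq_a, pr$seq_b)
  expect_lt(abs(aln$identity - 0.95), 0.005)
})

test_that("identity counts all columns unless gap-excluded mode is chosen", {
  aln98 <- alignment_from_strings(
    paste(rep("A", 100), collapse = ""),
    paste(c(rep("A", 98), "C", "C"), collapse = ""))
  expect_equal(aln98$identity, 0.98)
  # 2 mismatches and 3 one-base gaps over 100 columns -> 95/100
  a <- c(rep("A", 50), "-", rep("A", 30), "-", "-", rep("A", 17))
  b <- c(rep("A", 20), "C", "C", rep("A", 28), "G", rep("A", 30), "T", "T",
         rep("A", 17))
  aln <- alignment_from_strings(paste(a, collapse = ""),
                                paste(b, collapse = ""))
  expect_equal(aln$aln_length, 100L)
  expect_equal(aln$identity, 0.95)
  expect_equal(alignment_identity(aln, gap_excluded = TRUE), 95 / 97)
  # 94 identical of 100 passes the inclusive threshold
  aln94 <- alignment_from_strings(
    paste(rep("A", 100), collapse = ""),
    paste(c(rep("C", 6), rep("A", 94)), collapse = ""))
  expect_equal(aln94$identity, 0.94)
  expect_gte(aln94$identity, 0.94)
})

test_that("identity and length are symmetric in the two sequences", {
  pr <- fixture_pair(seed = 3, len = 1500, divergence = 0.04)
  f <- local_align(pr$seq_a, pr$seq_b)
  r <- local_align(pr$seq_b, pr$seq_a)
  expect_equal(f$identity, r$identity)
  expect_equal(f$aln_length, r$aln_length)
  expect_equal(f$score, r$score)
})

test_that("pair filters apply inclusive thresholds and drop LTR-only hits", {
  pairs <- data.frame(identity = c(0.95, 0.95, 0.94, 0.939),
                      aln_length = c(2500L, 450L, 2000L, 2500L))
  kept <- filter_pairs(pairs)
  expect_equal(kept$aln_length, c(2500L, 2000L))
  # monotonicity: raising either threshold never grows the set
  set.seed(13)
  rnd <- data.frame(identity = runif(200, 0.85, 1),
                    aln_length = sample(500:4000, 200, replace = TRUE))
  base <- nrow(filter_pairs(rnd, 0.94, 2000))
  for (mi in c(0.95, 0.97)) {
    expect_lte(nrow(filter_pairs(rnd, mi, 2000)), base)
  }
  for (ml in c(2500, 3500)) {
    expect_lte(nrow(filter_pairs(rnd, 0.94, ml)), base)
  }
})

test_that("LCR exclusion drops only pairs touching qualifying segdups", {
  pairs <- data.frame(
    chrom = "chr1",
    a_start = c(100000L, 500000L), a_end = c(105000L, 505000L),
    b_start = c(200000L, 700000L), b_end = c(205000L, 705000L),
    stringsAsFactors = FALSE)
  segdup <- function(s, e, os, oe, strand = "+", frac = 0.97,
                     chrom = "chr1", other = "chr1") {
    data.frame(chrom = chrom, start = s, end = e, other_chrom = other,
               other_start = os, other_end = oe, other_strand = strand,
               frac_match = frac, stringsAsFactors = FALSE)
  }
  # direct, high-identity, same-chrom, 5kb-10Mb apart, overlapping pair 1
  expect_equal(nrow(exclude_lcr_overlapping_pairs(
    pairs, segdup(104000, 110000, 300000, 306000))), 1L)
  # inverted orientation -> kept
  expect_equal(nrow(exclude_lcr_overlapping_pairs(
    pairs, segdup(104000, 110000, 300000, 306000, strand = "-"))), 2L)
  # identity at exactly the bound (not greater) -> kept
  expect_equal(nrow(exclude_lcr_overlapping_pairs(
    pairs, segdup(104000, 110000, 300000, 306000, frac = 0.94))), 2L)
  # copies too close together -> kept
  expect_equal(nrow(exclude_lcr_overlapping_pairs(
    pairs, segdup(104000, 110000, 112000, 118000))), 2L)
  # overlap with the distal copy counts too
  expect_equal(nrow(exclude_lcr_overlapping_pairs(
    pairs, segdup(900000, 910000, 704000, 710000))), 1L)
})

test_that("LCR exclusion equals a brute-force interval filter on fixtures", {
  set.seed(41)
  for (rep in 1:5) {
    pairs <- data.frame(chrom = "chr1",
                        a_start = sample.int(900000, 8),
                        stringsAsFactors = FALSE)
    pairs$a_end <- pairs$a_start + 5000L
    pairs$b_start <- pairs$a_end + sample(20000:50000, 8, replace = TRUE)
    pairs$b_end <- pairs$b_start + 5000L
    sd <- data.frame(chrom = "chr1",
                     start = sample.int(900000, 6),
                     other_chrom = "chr1",
                     other_strand = sample(c("+", "-"), 6, replace = TRUE),
                     frac_match = runif(6, 0.9, 1),
                     stringsAsFactors = FALSE)
    sd$end <- sd$start + 8000L
    sd$other_start <- sd$end + sample(3000:30000, 6, replace = TRUE)
    sd$other_end <- sd$other_start + 8000L
    got <- exclude_lcr_overlapping_pairs(pairs, sd)
    qual <- sd[sd$other_strand == "+" & sd$frac_match > 0.94 &
                 (sd$other_start - sd$end - 1L) >= 5000 &
                 (sd$other_start - sd$end - 1L) <= 10000000, ]
    drop <- vapply(seq_len(nrow(pairs)), function(k) {
      any(vapply(seq_len(nrow(qual)), function(q) {
        any(c(
          pairs$a_start[k] <= qual$end[q] & qual$start[q] <= pairs$a_end[k],
          pairs$a_start[k] <= qual$other_end[q] &
            qual$other_start[q] <= pairs$a_end[k],
          pairs$b_start[k] <= qual$end[q] & qual$start[q] <= pairs$b_end[k],
          pairs$b_start[k] <= qual$other_end[q] &
            qual$other_start[q] <= pairs$b_end[k]))
      }, logical(1)))
    }, logical(1))
    expect_equal(got$a_start, pairs$a_start[!drop])
  }
})

test_that("pair table TSV round-trips through write/read", {
  g <- make_genome(simulation_config(
    seed = 77, internal_length = 3500,
    pairs = data.frame(divergence = 0.02, separation = 30000,
                       strand = "+")))
  pairs <- find_herv_pairs(join_fragments(g$rmsk), g$genome)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairs_tsv(pairs, path, params = list(min_identity = 0.94))
  back <- read_pairs_tsv(path)
  expect_equal(back$a_start, pairs$a_start)
  expect_equal(back$identity, pairs$identity, tolerance = 1e-12)
  expect_equal(back$pair_id, pairs$pair_id)
})
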