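test_that("UCSC rmsk dialect parses with 0-based to 1-based conversion", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "#genoName\tgenoStart\tgenoEnd\tstrand\trepName\trepClass\trepFamily\tid",
    "chr1\t100\t600\t+\tHERVH-int\tLTR\tERV1\t7",
    "chr1\t800\t1200\t+\tLTR7\tLTR\tERV1\t7",
    "chr2\t0\t450\t-\tLTR7\tLTR\tERV1\t9"), path)
  ann <- read_rmsk_table(path)
  expect_equal(nrow(ann), 3L)
  expect_equal(ann$start, c(101L, 801L, 1L))
  expect_equal(ann$end, c(600L, 1200L, 450L))
  expect_equal(ann$strand, c("+", "+", "-"))
  expect_equal(ann$join_id, c(7L, 7L, 9L))
  expect_equal(ann$rep_family, rep("ERV1", 3))
})

test_that("header-only table gives an empty annotation set", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(
    "#genoName\tgenoStart\tgenoEnd\tstrand\trepName\trepClass\trepFamily\tid",
    path)
  expect_equal(nrow(read_rmsk_table(path)), 0L)
})

test_that("RepeatMasker .out dialect is auto-detected", {
  path <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW  perc perc perc  query     position in query    matching repeat       position in repeat",
    "score  div. del. ins.  sequence  begin end   (left)   repeat  class/family  begin end (left) ID",
    "",
    " 1200  5.0  0.1  0.2   chr1      101   600  (5000)  +  HERVH-int LTR/ERV1  1  500 (0) 7",
    "  900  6.1  0.0  0.0   chr1      801  1200  (4400)  C  LTR7      LTR/ERV1  1  400 (0) 7"), path)
  ann <- read_rmsk_table(path)
  expect_equal(nrow(ann), 2L)
  expect_equal(ann$start, c(101L, 801L))
  expect_equal(ann$strand, c("+", "-"))
  expect_equal(ann$rep_class, c("LTR", "LTR"))
  expect_equal(ann$rep_family, c("ERV1", "ERV1"))
  expect_equal(ann$join_id, c(7L, 7L))
})

test_that("parse errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "#genoName\tgenoStart\tgenoEnd\tstrand\trepName\trepClass\trepFamily\tid",
    "chr1\t100\t600\t+\tHERVH-int\tLTR\tERV1\t7",
    "chr1\t900\t700\t+\tLTR7\tLTR\tERV1\t7"), path)
  expect_error(read_rmsk_table(path), "line 3")
  expect_error(read_rmsk_table(tempfile()), "not found")
  bad <- withr::local_tempfile()
  writeLines(c("just some text", "no dialect here"), bad)
  expect_error(read_rmsk_table(bad), "unknown")
})

test_that("rmsk write/read round-trips field-for-field", {
  set.seed(31)
  g <- make_genome(simulation_config(seed = 31, internal_length = 600,
                                     margin = 500,
                                     pairs = data.frame(
                                       divergence = c(0.02, 0.05),
                                       separation = c(2000, 3000),
                                       strand = c("+", "-"))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rmsk_table(g$rmsk, path)
  back <- read_rmsk_table(path)
  expect_equal(back, g$rmsk, ignore_attr = TRUE)
})

test_that("join_fragments merges within the gap and splits beyond it", {
  ann <- data.frame(
    chrom = "chr1", start = c(101L, 2501L), end = c(2000L, 6000L),
    strand = "+", rep_name = c("LTR7", "HERVH-int"), rep_class = "LTR",
    rep_family = "ERV1", join_id = 7L, stringsAsFactors = FALSE)
  one <- join_fragments(ann, max_join_gap = 5000)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(101L, 6000L))
  expect_equal(one$name, "HERVH-int")  # longest fragment names the element
  expect_equal(one$n_fragments, 2L)
  two <- join_fragments(ann, max_join_gap = 100)
  expect_equal(nrow(two), 2L)
  expect_equal(two$start, c(101L, 2501L))
  expect_equal(nrow(join_fragments(ann[0, ])), 0L)
})

test_that("join_fragments splits join ids spanning both strands", {
  ann <- data.frame(
    chrom = "chr1", start = c(101L, 1001L), end = c(900L, 1900L),
    strand = c("+", "-"), rep_name = "LTR7", rep_class = "LTR",
    rep_family = "ERV1", join_id = 3L, stringsAsFactors = FALSE)
  el <- join_fragments(ann, max_join_gap = 5000)
  expect_equal(nrow(el), 2L)
  expect_setequal(el$strand, c("+", "-"))
})

test_that("join_fragments spans match a brute-force union-by-id oracle", {
  set.seed(101)
  for (rep in 1:5) {
    n <- 40
    ann <- data.frame(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample.int(50000, n),
      strand = sample(c("+", "-"), n, replace = TRUE),
      rep_name = sample(c("LTR7", "HERVH-int"), n, replace = TRUE),
      rep_class = "LTR", rep_family = "ERV1",
      join_id = sample.int(6, n, replace = TRUE),
      stringsAsFactors = FALSE)
    ann$end <- ann$start + sample.int(800, n)
    gap <- 1000L
    el <- join_fragments(ann, max_join_gap = gap)
    # oracle: per (chrom, strand, id), sort fragments and accumulate runs
    expected <- list()
    for (key in unique(paste(ann$chrom, ann$strand, ann$join_id))) {
      parts <- strsplit(key, " ")[[1]]
      fr <- ann[ann$chrom == parts[1] & ann$strand == parts[2] &
                  ann$join_id == as.integer(parts[3]), ]
      fr <- fr[order(fr$start, fr$end), ]
      cur_s <- fr$start[1]; cur_e <- fr$end[1]
      for (k in seq_len(nrow(fr))[-1]) {
        if (fr$start[k] - cur_e - 1L > gap) {
          expected[[length(expected) + 1L]] <- c(parts[1], cur_s, cur_e)
          cur_s <- fr$start[k]; cur_e <- fr$end[k]
        } else {
          cur_e <- max(cur_e, fr$end[k])
        }
      }
      expected[[length(expected) + 1L]] <- c(parts[1], cur_s, cur_e)
    }
    exp_df <- unique(do.call(rbind, expected))
    got <- unique(cbind(el$chrom, el$start, el$end))
    expect_setequal(apply(got, 1, paste, collapse = ":"),
                    apply(exp_df, 1, paste, collapse = ":"))
  }
})

test_that("FASTA, BED and segdup parsing behave and round-trip", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">contigA extra words", "ACGTacgt", "ACGT",
               ">contigB", "GGGGCCCC"), fa)
  g <- read_genome_fasta(fa)
  expect_equal(names(g), c("contigA", "contigB"))
  expect_equal(unname(genome_lengths(g)), c(12L, 8L))
  expect_equal(as.character(g[["contigA"]]), "ACGTACGTACGT")

  bed <- withr::local_tempfile(fileext = ".bed")
  iv <- data.frame(chrom = c("contigA", "contigA", "contigB"),
                   start = c(1L, 5L, 3L), end = c(4L, 12L, 8L),
                   name = c("x", "y", "z"), stringsAsFactors = FALSE)
  write_bed(iv, bed)
  back <- read_bed(bed)
  expect_equal(back$start, iv$start)
  expect_equal(back$end, iv$end)
  expect_equal(back$name, iv$name)

  sd <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "#chrom\tchromStart\tchromEnd\totherChrom\totherStart\totherEnd\tstrand\tfracMatch",
    "chr1\t1000\t2000\tchr1\t50000\t51000\t+\t0.95"), sd)
  dup <- read_segdup_table(sd)
  expect_equal(dup$frac_match, 0.95)
  expect_equal(dup$start, 1001L)
  expect_equal(dup$other_start, 50001L)
})
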