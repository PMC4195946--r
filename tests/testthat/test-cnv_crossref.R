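test_that("uncertainty intervals bracket the altered probe run", {
  res <- uncertainty_intervals_from_probes(
    c(100, 200, 300, 400, 500), c("N", "N", "A", "A", "N"))
  expect_equal(res$proximal, c(200, 300))
  expect_equal(res$distal, c(400, 500))
  # degenerate single altered probe shares its position as inner bound
  one <- uncertainty_intervals_from_probes(
    c(100, 200, 300), c("N", "A", "N"))
  expect_equal(one$proximal, c(100, 200))
  expect_equal(one$distal, c(200, 300))
  expect_error(uncertainty_intervals_from_probes(
    c(100, 200), c("N", "N")), "no altered")
  expect_error(uncertainty_intervals_from_probes(
    c(100, 200, 300), c("A", "A", "N")), "edge")
  expect_error(uncertainty_intervals_from_probes(
    c(100, 200, 300, 400), c("N", "A", "N", "A")), "contiguous")
})

test_that("simulated probe grids always bracket the planted breakpoints", {
  set.seed(67)
  for (rep in 1:20) {
    cnv <- sort(sample.int(100000, 2))
    if (diff(cnv) < 1000) next
    spacing <- sample(c(50, 200, 1000), 1)
    grid <- make_probe_grid(cnv, spacing,
                            extent = c(cnv[1] - 3 * spacing,
                                       cnv[2] + 3 * spacing))
    iv <- uncertainty_intervals_from_probes(grid$positions, grid$states)
    expect_true(iv$proximal[1] < cnv[1] && cnv[1] <= iv$proximal[2])
    expect_true(iv$distal[1] <= cnv[2] && cnv[2] < iv$distal[2])
    expect_lte(iv$proximal[2] - iv$proximal[1], spacing + 1)
    expect_lte(iv$distal[2] - iv$distal[1], spacing + 1)
  }
})

mk_cnv <- function(start_max, start_min, stop_min, stop_max,
                   chrom = "chr1") {
  data.frame(sample_id = "s1", chrom = chrom, cnv_type = "deletion",
             start_max = start_max, start_min = start_min,
             stop_min = stop_min, stop_max = stop_max,
             stringsAsFactors = FALSE)
}

test_that("CNVs are flagged only with a HERV in each uncertainty interval", {
  elements <- data.frame(chrom = "chr1",
                         start = c(9000L, 60000L), end = c(15000L, 66000L),
                         strand = "+", name = "HERVH-int",
                         join_id = 1:2, stringsAsFactors = FALSE)
  both <- match_cnvs_to_pairs(mk_cnv(8000L, 16000L, 59000L, 67000L),
                              elements)
  expect_true(both$herv_mediated)
  only_prox <- match_cnvs_to_pairs(mk_cnv(8000L, 16000L, 30000L, 35000L),
                                   elements)
  expect_false(only_prox$herv_mediated)
  # strict mode requires the two elements to be an emitted pair
  pairs <- data.frame(chrom = "chr1", a_start = 9000L, a_end = 15000L,
                      b_start = 60000L, b_end = 66000L, pair_id = "pX",
                      stringsAsFactors = FALSE)
  strict <- match_cnvs_to_pairs(mk_cnv(8000L, 16000L, 59000L, 67000L),
                                elements, pairs)
  expect_true(strict$herv_mediated)
  expect_equal(strict$pair_id, "pX")
  other_pair <- data.frame(chrom = "chr1", a_start = 200000L,
                           a_end = 206000L, b_start = 300000L,
                           b_end = 306000L, pair_id = "pY",
                           stringsAsFactors = FALSE)
  miss <- match_cnvs_to_pairs(mk_cnv(8000L, 16000L, 59000L, 67000L),
                              elements, other_pair)
  expect_false(miss$herv_mediated)
})

test_that("flagging is monotone under interval enlargement", {
  set.seed(29)
  elements <- data.frame(chrom = "chr1",
                         start = sample.int(500000, 20),
                         strand = "+", name = "h", join_id = 1:20,
                         stringsAsFactors = FALSE)
  elements$end <- elements$start + 5000L
  for (rep in 1:20) {
    b <- sort(sample.int(500000, 4))
    cnv <- mk_cnv(b[1], b[2], b[3], b[4])
    base <- match_cnvs_to_pairs(cnv, elements)$herv_mediated
    grown <- mk_cnv(max(b[1] - 20000L, 1L), b[2], b[3], b[4] + 20000L)
    if (base) {
      expect_true(match_cnvs_to_pairs(grown, elements)$herv_mediated)
    }
  }
})

test_that("planted CNVs between planted HERVs are recovered end-to-end", {
  g <- make_genome(simulation_config(
    seed = 97, internal_length = 3500,
    pairs = data.frame(divergence = c(0.02, 0.05), separation = c(30000, 40000),
                       strand = "+")))
  el <- join_fragments(g$rmsk)
  pairs <- find_herv_pairs(el, g$genome)
  tp <- g$truth$pairs
  cnvs <- do.call(rbind, lapply(seq_len(nrow(tp)), function(i) {
    # true breakpoints inside each element; probes every 500 bp
    bp <- c(tp$a_start[i] + 2000L, tp$b_start[i] + 2000L)
    grid <- make_probe_grid(bp, 500, c(bp[1] - 5000L, bp[2] + 5000L))
    iv <- uncertainty_intervals_from_probes(grid$positions, grid$states)
    data.frame(sample_id = sprintf("s%d", i), chrom = tp$chrom[i],
               cnv_type = "deletion",
               start_max = iv$proximal[1], start_min = iv$proximal[2],
               stop_min = iv$distal[1], stop_max = iv$distal[2],
               stringsAsFactors = FALSE)
  }))
  # a decoy CNV away from any element
  cnvs <- rbind(cnvs, mk_cnv(5000L, 5500L, 8000L, 8500L,
                             chrom = tp$chrom[1]))
  res <- match_cnvs_to_pairs(cnvs, filter_elements_by_length(el), pairs)
  expect_equal(res$herv_mediated, c(TRUE, TRUE, FALSE))
  expect_equal(res$pair_id[1:2], pairs$pair_id[match(cnvs$chrom[1:2],
                                                     pairs$chrom)])
})

test_that("CNV table validation and IO work", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tchrom\tcnv_type\tstart_max\tstart_min\tstop_min\tstop_max",
               "s1\tchr1\tdeletion\t100\t200\t5000\t5100"), path)
  cnvs <- read_cnv_table(path)
  expect_equal(cnvs$stop_min, 5000L)
  bad <- mk_cnv(200L, 100L, 5000L, 5100L)
  expect_error(match_cnvs_to_pairs(bad, data.frame()), "disordered")
})

test_that("probe placement yields five probes per side, clear of elements", {
  pairs <- data.frame(chrom = "chr1", a_start = 50000L, a_end = 56000L,
                      b_start = 150000L, b_end = 156000L, pair_id = "p1",
                      stringsAsFactors = FALSE)
  probes <- place_flanking_probes(pairs, c(chr1 = 300000L))
  expect_equal(nrow(probes), 20L)  # 5 x 2 sides x 2 elements
  expect_true(all(probes$placeable))
  for (k in seq_len(nrow(probes))) {
    es <- if (probes$element[k] == "a") 50000L else 150000L
    ee <- if (probes$element[k] == "a") 56000L else 156000L
    expect_false(probes$start[k] <= ee && es <= probes$end[k])
  }
  # element at the contig edge: that side is unplaceable, not an error
  edge <- data.frame(chrom = "chr1", a_start = 1L, a_end = 6000L,
                     b_start = 100000L, b_end = 106000L, pair_id = "p2",
                     stringsAsFactors = FALSE)
  pe <- place_flanking_probes(edge, c(chr1 = 120000L))
  left_a <- pe[pe$element == "a" & pe$side == "left", ]
  expect_equal(nrow(left_a), 1L)
  expect_false(left_a$placeable)
  # a repeat mask forces probes off masked positions
  mask <- data.frame(chrom = "chr1", start = 56001L, end = 57000L,
                     stringsAsFactors = FALSE)
  pm <- place_flanking_probes(pairs, c(chr1 = 300000L), repeat_mask = mask)
  right_a <- pm[pm$element == "a" & pm$side == "right" & pm$placeable, ]
  expect_true(all(right_a$start > 57000L))
})
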