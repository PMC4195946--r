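# Condensation of predicted pairs into susceptibility regions and
# chromosome/genome coverage statistics.

#' Genomic span of a pair
#'
#' The segment deletable/duplicable by a recombination event between the
#' two elements: from the proximal element's start to the distal element's
#' end.
#'
#' @param pairs Pair data.frame (rows with `chrom`, `a_start`, `b_end`).
#' @return data.frame with `chrom`, `start`, `end`, `pair_id`.
#' @export
pair_span <- function(pairs) {
  data.frame(chrom = pairs$chrom, start = pairs$a_start, end = pairs$b_end,
             pair_id = pairs$pair_id %||%
               sprintf("%s:%d-%d|%d-%d", pairs$chrom, pairs$a_start,
                       pairs$a_end, pairs$b_start, pairs$b_end),
             stringsAsFactors = FALSE)
}

#' Condense pair spans into susceptibility regions
#'
#' Spans overlapping by at least one base on one chromosome are merged
#' (transitively) into maximal regions; merely bookended spans are not
#' merged. Every pair is assigned to exactly one region.
#'
#' @param pairs Pair data.frame.
#' @return data.frame of regions (`chrom`, `start`, `end`, `n_pairs`,
#'   `name`) with a `contributing_pairs` list-column of pair ids, sorted by
#'   (`chrom`, `start`).
#' @export
condense_regions <- function(pairs) {
  spans <- pair_span(pairs)
  if (nrow(spans) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_pairs = integer(),
                      name = character(),
                      contributing_pairs = I(list()),
                      stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::GRanges(spans$chrom,
                               IRanges::IRanges(spans$start, spans$end))
  # min.gapwidth = 0L: merge only true overlaps, not bookended spans
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  ov <- GenomicRanges::findOverlaps(gr, red)
  by_region <- split(spans$pair_id[S4Vectors::queryHits(ov)],
                     S4Vectors::subjectHits(ov))
  regions <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red),
    end = GenomicRanges::end(red),
    stringsAsFactors = FALSE
  )
  regions$n_pairs <- lengths(by_region)[as.character(seq_len(nrow(regions)))]
  regions$contributing_pairs <-
    I(unname(by_region[as.character(seq_len(nrow(regions)))]))
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  regions$name <- sprintf("region_%03d", seq_len(nrow(regions)))
  rownames(regions) <- NULL
  regions
}

#' Coverage of susceptibility regions per chromosome and genome-wide
#'
#' @param regions Region data.frame from [condense_regions()].
#' @param chrom_lengths Named vector of chromosome lengths (e.g.
#'   [genome_lengths()]); every region chromosome must be present.
#' @return A list with `per_chrom` (data.frame: `chrom`, `chrom_length`,
#'   `covered`, `fraction`, `percent`) and scalars `genome_covered_bases`,
#'   `genome_covered_mb`, `genome_fraction`, `genome_percent`. Percentages
#'   are over the total length of the supplied chromosomes.
#' @export
coverage_stats <- function(regions, chrom_lengths) {
  missing_chrom <- setdiff(unique(regions$chrom), names(chrom_lengths))
  assert_that(length(missing_chrom) == 0L,
              "chromosome length missing for: %s",
              paste(missing_chrom, collapse = ", "))
  covered <- vapply(names(chrom_lengths), function(ch) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    sum(r$end - r$start + 1L)
  }, numeric(1))
  assert_that(all(covered <= chrom_lengths),
              "regions exceed chromosome length")
  per_chrom <- data.frame(
    chrom = names(chrom_lengths),
    chrom_length = as.numeric(chrom_lengths),
    covered = covered,
    fraction = covered / as.numeric(chrom_lengths),
    stringsAsFactors = FALSE
  )
  per_chrom$percent <- 100 * per_chrom$fraction
  rownames(per_chrom) <- NULL
  total <- sum(covered)
  total_len <- sum(as.numeric(chrom_lengths))
  list(per_chrom = per_chrom,
       genome_covered_bases = total,
       genome_covered_mb = total / 1e6,
       genome_fraction = total / total_len,
       genome_percent = 100 * total / total_len)
}
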