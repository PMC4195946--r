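# Genome-wide enumeration and scoring of candidate HERV pairs, with the
# identity / length / distance / LCR-exclusion filters of the NAHR
# substrate screen.

#' Keep elements at least `min_length` long
#'
#' The screen considers only elements "not shorter than" the minimum, so
#' the boundary is inclusive: an element of exactly `min_length` is kept.
#'
#' @param elements Element data.frame (see [join_fragments()]).
#' @param min_length Minimum element length in bases (default 4000).
#' @return The filtered element data.frame.
#' @export
filter_elements_by_length <- function(elements, min_length = 4000) {
  assert_that(min_length > 0, "min_length must be positive")
  elements[elements$end - elements$start + 1L >= min_length, , drop = FALSE]
}

#' Enumerate candidate pairs of same-strand elements
#'
#' All unordered pairs of elements on one chromosome, on the same strand,
#' whose separation (bases between the inner edges, i.e. from the end of
#' the proximal element to the start of the distal one) lies within
#' `[min_sep, max_sep]`. Overlapping elements (separation < 0) are never
#' paired.
#'
#' @param elements Length-filtered element data.frame.
#' @param min_sep,max_sep Separation bounds in bases (defaults 10 kb and
#'   10 Mb).
#' @return data.frame of candidate pairs with the proximal element's fields
#'   prefixed `a_`, the distal element's prefixed `b_`, plus `separation`.
#'   Sorted by (`chrom`, `a_start`, `b_start`).
#' @export
enumerate_candidate_pairs <- function(elements, min_sep = 10000,
                                      max_sep = 10000000) {
  assert_that(min_sep >= 0 && max_sep >= min_sep, "invalid separation bounds")
  el <- elements[order(elements$chrom, elements$start, elements$end), ,
                 drop = FALSE]
  out <- list()
  for (chrom in unique(el$chrom)) {
    ec <- el[el$chrom == chrom, , drop = FALSE]
    n <- nrow(ec)
    if (n < 2L) next
    idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    i <- idx[, 1]; j <- idx[, 2]
    sep <- ec$start[j] - ec$end[i] - 1L
    keep <- ec$strand[i] == ec$strand[j] & sep >= min_sep & sep <= max_sep
    if (!any(keep)) next
    i <- i[keep]; j <- j[keep]
    out[[chrom]] <- data.frame(
      chrom = chrom,
      a_start = ec$start[i], a_end = ec$end[i], a_name = ec$name[i],
      a_join_id = ec$join_id[i],
      b_start = ec$start[j], b_end = ec$end[j], b_name = ec$name[j],
      b_join_id = ec$join_id[j],
      strand = ec$strand[i],
      separation = sep[keep],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) return(empty_pairs())
  pairs <- do.call(rbind, out)
  pairs <- pairs[order(pairs$chrom, pairs$a_start, pairs$b_start), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

empty_pairs <- function() {
  df <- data.frame(chrom = character(), a_start = integer(),
                   a_end = integer(), a_name = character(),
                   a_join_id = integer(), b_start = integer(),
                   b_end = integer(), b_name = character(),
                   b_join_id = integer(), strand = character(),
                   separation = integer(), stringsAsFactors = FALSE)
  df$identity <- numeric()
  df$aln_length <- integer()
  df$score <- numeric()
  df$alignment <- I(list())
  df
}

#' Align every candidate pair
#'
#' Extracts both elements' sequences (forward strand; equivalent for
#' same-strand pairs) and computes the optimal local alignment of each.
#'
#' @param candidates Candidate pairs from [enumerate_candidate_pairs()].
#' @param genome DNAStringSet from [read_genome_fasta()].
#' @param scoring A [scoring_scheme()].
#' @param same_family_only If `TRUE`, only align candidates whose two
#'   elements share `name` (a runtime pre-screen; cross-family alignments
#'   essentially never reach the identity/length thresholds). Default
#'   `FALSE`.
#' @return `candidates` with added `identity`, `aln_length`, `score`
#'   columns and an `alignment` list-column of `herv_alignment` objects.
#' @export
align_candidate_pairs <- function(candidates, genome,
                                  scoring = scoring_scheme(),
                                  same_family_only = FALSE) {
  if (nrow(candidates) == 0L) return(empty_pairs())
  if (same_family_only) {
    candidates <- candidates[candidates$a_name == candidates$b_name, ,
                             drop = FALSE]
    if (nrow(candidates) == 0L) return(empty_pairs())
  }
  alns <- vector("list", nrow(candidates))
  for (k in seq_len(nrow(candidates))) {
    chrom_seq <- genome[[candidates$chrom[k]]]
    assert_that(!is.null(chrom_seq), "chromosome %s absent from genome",
                candidates$chrom[k])
    sa <- Biostrings::subseq(chrom_seq, candidates$a_start[k],
                             candidates$a_end[k])
    sb <- Biostrings::subseq(chrom_seq, candidates$b_start[k],
                             candidates$b_end[k])
    alns[[k]] <- local_align(sa, sb, scoring)
  }
  candidates$identity <- vapply(alns, `[[`, numeric(1), "identity")
  candidates$aln_length <- vapply(alns, `[[`, integer(1), "aln_length")
  candidates$score <- vapply(alns, `[[`, numeric(1), "score")
  candidates$alignment <- I(alns)
  candidates
}

#' Apply the identity and alignment-length thresholds
#'
#' Both thresholds are inclusive ("not less than 94%", "greater than or
#' equal to 2 kb"); the alignment-length floor excludes pairs whose only
#' high-identity alignment covers the LTRs alone.
#'
#' @param pairs Aligned pairs from [align_candidate_pairs()].
#' @param min_identity Minimum identity fraction (default 0.94).
#' @param min_aln_length Minimum alignment length in columns (default 2000).
#' @return The surviving pairs.
#' @export
filter_pairs <- function(pairs, min_identity = 0.94, min_aln_length = 2000) {
  keep <- !is.na(pairs$identity) & pairs$identity >= min_identity &
    pairs$aln_length >= min_aln_length
  pairs[keep, , drop = FALSE]
}

#' Drop pairs overlapping qualifying segmental duplications
#'
#' A pair is removed when either of its elements overlaps (by at least one
#' base) either copy of a duplication record whose two copies are directly
#' oriented, lie on the same chromosome, have `fracMatch` above
#' `lcr_min_identity`, and are separated by `lcr_min_sep`..`lcr_max_sep`.
#' Such regions are the classical low-copy-repeat NAHR substrate and are
#' screened out so that predictions are HERV-specific.
#'
#' @param pairs Pair data.frame.
#' @param segdups Segdup table from [read_segdup_table()].
#' @param lcr_min_identity Strict lower bound on `fracMatch` (default 0.94).
#' @param lcr_min_sep,lcr_max_sep Bounds on the separation between the two
#'   duplication copies (defaults 5 kb and 10 Mb).
#' @return The surviving pairs.
#' @export
exclude_lcr_overlapping_pairs <- function(pairs, segdups,
                                          lcr_min_identity = 0.94,
                                          lcr_min_sep = 5000,
                                          lcr_max_sep = 10000000) {
  if (nrow(pairs) == 0L || is.null(segdups) || nrow(segdups) == 0L) {
    return(pairs)
  }
  sd_lo_end <- pmin(segdups$end, segdups$other_end)
  sd_hi_start <- pmax(segdups$start, segdups$other_start)
  sep <- sd_hi_start - sd_lo_end - 1L
  qual <- segdups$other_strand == "+" &
    segdups$chrom == segdups$other_chrom &
    segdups$frac_match > lcr_min_identity &
    sep >= lcr_min_sep & sep <= lcr_max_sep
  sd <- segdups[qual, , drop = FALSE]
  if (nrow(sd) == 0L) return(pairs)
  hit <- vapply(seq_len(nrow(pairs)), function(k) {
    on_chrom <- sd$chrom == pairs$chrom[k]
    if (!any(on_chrom)) return(FALSE)
    s <- sd[on_chrom, , drop = FALSE]
    any(overlaps1(pairs$a_start[k], pairs$a_end[k], s$start, s$end) |
        overlaps1(pairs$a_start[k], pairs$a_end[k], s$other_start, s$other_end) |
        overlaps1(pairs$b_start[k], pairs$b_end[k], s$start, s$end) |
        overlaps1(pairs$b_start[k], pairs$b_end[k], s$other_start, s$other_end))
  }, logical(1))
  pairs[!hit, , drop = FALSE]
}

#' Full HERV pair prediction pipeline
#'
#' Length filter, candidate enumeration, local alignment, identity/length
#' thresholds, and optional LCR exclusion, with the screening defaults
#' (elements >= 4 kb; separation 10 kb - 10 Mb; identity >= 94%; alignment
#' >= 2 kb).
#'
#' @param elements Joined elements (see [join_fragments()]).
#' @param genome DNAStringSet.
#' @param segdups Optional segdup table for LCR exclusion.
#' @param min_length,min_sep,max_sep,min_identity,min_aln_length Filter
#'   parameters (screening defaults).
#' @param scoring A [scoring_scheme()].
#' @param same_family_only Pre-screen candidates by shared element name
#'   before alignment (default `FALSE`).
#' @return Pair data.frame with a `pair_id` column.
#' @export
find_herv_pairs <- function(elements, genome, segdups = NULL,
                            min_length = 4000, min_sep = 10000,
                            max_sep = 10000000, min_identity = 0.94,
                            min_aln_length = 2000,
                            scoring = scoring_scheme(),
                            same_family_only = FALSE) {
  el <- filter_elements_by_length(elements, min_length)
  cand <- enumerate_candidate_pairs(el, min_sep, max_sep)
  aligned <- align_candidate_pairs(cand, genome, scoring, same_family_only)
  pairs <- filter_pairs(aligned, min_identity, min_aln_length)
  if (!is.null(segdups)) {
    pairs <- exclude_lcr_overlapping_pairs(pairs, segdups)
  }
  if (nrow(pairs) > 0L) {
    pairs$pair_id <- sprintf("%s:%d-%d|%d-%d", pairs$chrom, pairs$a_start,
                             pairs$a_end, pairs$b_start, pairs$b_end)
  } else {
    pairs$pair_id <- character(0)
  }
  rownames(pairs) <- NULL
  pairs
}

#' Write a pair table as TSV
#'
#' The header line (starting `#`) records the filter and scoring parameters
#' used, for reproducibility; the `alignment` list-column is dropped.
#'
#' @param pairs Pair data.frame.
#' @param path Output path.
#' @param params Optional named list of parameters to record in the header.
#' @export
write_pairs_tsv <- function(pairs, path, params = NULL) {
  meta <- ""
  if (!is.null(params)) {
    meta <- paste0(" ", paste(names(params), unlist(params), sep = "=",
                              collapse = " "))
  }
  cols <- setdiff(names(pairs), "alignment")
  writeLines(c(sprintf("# hervnahr pairs%s", meta),
               paste0("#", paste(cols, collapse = "\t"))), path)
  write.table(pairs[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a pair table written by [write_pairs_tsv()]
#' @param path TSV path.
#' @return Pair data.frame (without alignments).
#' @export
read_pairs_tsv <- function(path) {
  assert_that(file.exists(path), "pair table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  assert_that(length(hdr) >= 1L, "pair table %s lacks a header", path)
  cols <- strsplit(sub("^#", "", hdr[length(hdr)]), "\t")[[1]]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    df <- empty_pairs()
    df$alignment <- NULL
    df$pair_id <- character(0)
    return(df)
  }
  df <- read.delim(text = body, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- cols
  df
}
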