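# Local (Smith-Waterman) alignment of element sequences with affine gap
# penalties, via Biostrings::pairwiseAlignment, plus the identity statistic
# used by the pair filters.

#' Alignment scoring scheme
#'
#' Only the gap-extension penalty (-25) is fixed by the screening protocol;
#' the remaining parameters default to match = +1, mismatch = -1,
#' gap open = -10. A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (<= 0).
#' @param gap_open Gap-opening score (<= 0).
#' @param gap_extend Per-base gap-extension score (<= 0).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap_open = -10,
                           gap_extend = -25) {
  assert_that(match > 0, "match score must be positive")
  assert_that(mismatch <= 0 && gap_open <= 0 && gap_extend <= 0,
              "mismatch/gap scores must be <= 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

# Substitution matrix over A/C/G/T/N in which N mismatches everything,
# including itself.
substitution_matrix <- function(scoring) {
  letters5 <- c("A", "C", "G", "T", "N")
  mat <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters5, letters5))
  diag(mat) <- scoring$match
  mat["N", "N"] <- scoring$mismatch
  mat
}

sanitize_dna <- function(seq) {
  s <- as_upper_chr(seq)
  gsub("[^ACGT]", "N", s)
}

#' Optimal local alignment of two nucleotide sequences
#'
#' Smith-Waterman alignment under affine gap scoring (via the Biostrings
#' dynamic-programming engine, the implementation used for the original
#' genome screen). `N` (and any non-ACGT letter) mismatches all bases.
#' Tie-breaking among equal-scoring alignments is the deterministic
#' traceback of the engine.
#'
#' @param seq_a,seq_b Nucleotide sequences (character or DNAString),
#'   non-empty.
#' @param scoring A [scoring_scheme()].
#' @param gap_excluded_identity If `TRUE`, identity is computed over
#'   gap-free columns only; the default counts every alignment column in
#'   the denominator (the conservative reading of "fraction of identical
#'   positions over the number of aligned positions").
#' @return A `herv_alignment` list: `aligned_a`/`aligned_b` (gapped strings
#'   of equal length), `a_start`/`a_end`/`b_start`/`b_end` (1-based
#'   coordinates of the aligned segment within each input), `score`,
#'   `identity`, `aln_length`, `n_gap_columns`, and the scoring scheme.
#' @export
local_align <- function(seq_a, seq_b, scoring = scoring_scheme(),
                        gap_excluded_identity = FALSE) {
  a <- sanitize_dna(seq_a)
  b <- sanitize_dna(seq_b)
  assert_that(nchar(a) > 0 && nchar(b) > 0, "empty sequence in local_align")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = substitution_matrix(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend
  )
  aligned_a <- as.character(Biostrings::alignedPattern(pa))
  aligned_b <- as.character(Biostrings::alignedSubject(pa))
  res <- structure(list(
    aligned_a = unname(aligned_a),
    aligned_b = unname(aligned_b),
    a_start = Biostrings::start(Biostrings::pattern(pa)),
    a_end = Biostrings::end(Biostrings::pattern(pa)),
    b_start = Biostrings::start(Biostrings::subject(pa)),
    b_end = Biostrings::end(Biostrings::subject(pa)),
    score = Biostrings::score(pa),
    scoring = scoring
  ), class = "herv_alignment")
  res$aln_length <- nchar(res$aligned_a)
  stats <- alignment_column_stats(res)
  res$n_gap_columns <- stats$gaps
  res$identity <- alignment_identity(res, gap_excluded = gap_excluded_identity)
  res
}

#' Construct a `herv_alignment` from gapped strings
#'
#' Used by the simulator (which knows the planted alignment) and by tests.
#' @param aligned_a,aligned_b Gapped strings of equal length.
#' @param a_start,b_start 1-based positions of the first aligned base within
#'   each full sequence.
#' @param score Optional score.
#' @param scoring Optional [scoring_scheme()].
#' @return A `herv_alignment`.
#' @export
alignment_from_strings <- function(aligned_a, aligned_b, a_start = 1L,
                                   b_start = 1L, score = NA_real_,
                                   scoring = scoring_scheme()) {
  assert_that(nchar(aligned_a) == nchar(aligned_b),
              "aligned strings must have equal length")
  na <- nchar(gsub("-", "", aligned_a))
  nb <- nchar(gsub("-", "", aligned_b))
  res <- structure(list(
    aligned_a = aligned_a, aligned_b = aligned_b,
    a_start = as.integer(a_start), a_end = as.integer(a_start) + na - 1L,
    b_start = as.integer(b_start), b_end = as.integer(b_start) + nb - 1L,
    score = score, scoring = scoring
  ), class = "herv_alignment")
  res$aln_length <- nchar(aligned_a)
  res$n_gap_columns <- alignment_column_stats(res)$gaps
  res$identity <- alignment_identity(res)
  res
}

alignment_chars <- function(alignment) {
  list(a = strsplit(alignment$aligned_a, "", fixed = TRUE)[[1]],
       b = strsplit(alignment$aligned_b, "", fixed = TRUE)[[1]])
}

alignment_column_stats <- function(alignment) {
  ch <- alignment_chars(alignment)
  assert_that(!any(ch$a == "-" & ch$b == "-"),
              "alignment column with gaps in both rows")
  gap <- ch$a == "-" | ch$b == "-"
  ident <- !gap & ch$a == ch$b & ch$a != "N"
  list(identical = sum(ident), gaps = sum(gap),
       columns = length(ch$a), is_identical = ident)
}

#' Fraction of identical positions in an alignment
#'
#' @param alignment A `herv_alignment`.
#' @param gap_excluded If `TRUE`, divide by gap-free columns only; the
#'   default divides by all alignment columns (gap columns count against
#'   identity).
#' @return Identity fraction in \[0, 1\] (`NaN` for an empty alignment).
#' @export
alignment_identity <- function(alignment, gap_excluded = FALSE) {
  st <- alignment_column_stats(alignment)
  denom <- if (gap_excluded) st$columns - st$gaps else st$columns
  st$identical / denom
}

#' @export
print.herv_alignment <- function(x, ...) {
  cat(sprintf(
    "Local alignment: score %.1f, %d columns, identity %.4f (%d gap cols)\n",
    x$score, x$aln_length, x$identity, x$n_gap_columns))
  cat(sprintf("  a: %d-%d   b: %d-%d\n", x$a_start, x$a_end,
              x$b_start, x$b_end))
  invisible(x)
}
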