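# Cataloguing cis-morphisms (paralogous sequence variants) between the two
# HERVs of a pair, localizing a junction sequence's crossover between
# informative cis-morphisms, and the derived uncertainty-width / CNV-size
# arithmetic.

# Per-column coordinate maps of an alignment: for each alignment column,
# the element-local (1-based) position of the base in that row, or of the
# last base before a gap.
alignment_maps <- function(alignment) {
  ch <- alignment_chars(alignment)
  list(chars_a = ch$a, chars_b = ch$b,
       pos_a = alignment$a_start - 1L + cumsum(ch$a != "-"),
       pos_b = alignment$b_start - 1L + cumsum(ch$b != "-"))
}

#' Catalogue cis-morphisms of an aligned element pair
#'
#' One record per alignment column where the two elements differ;
#' consecutive gap columns in one row (an indel run) are counted once.
#' Positions are element-local, 1-based; indels are anchored at their
#' first affected base in the row that carries sequence.
#'
#' @param alignment A `herv_alignment`.
#' @return data.frame with `column` (alignment column of the event's first
#'   column), `kind` (`substitution`, `insertion_in_a`, `insertion_in_b`),
#'   `pos_a`, `pos_b`, `base_a`, `base_b` (indel sequences for indels, `-`
#'   on the gapped side), `length`; sorted by `column`.
#' @export
find_cis_morphisms <- function(alignment) {
  m <- alignment_maps(alignment)
  n <- length(m$chars_a)
  gap_a <- m$chars_a == "-"
  gap_b <- m$chars_b == "-"
  subs <- which(!gap_a & !gap_b & m$chars_a != m$chars_b)
  recs <- list()
  if (length(subs) > 0L) {
    recs[[1]] <- data.frame(
      column = subs, kind = "substitution",
      pos_a = m$pos_a[subs], pos_b = m$pos_b[subs],
      base_a = m$chars_a[subs], base_b = m$chars_b[subs],
      length = 1L, stringsAsFactors = FALSE)
  }
  recs[[length(recs) + 1L]] <- indel_runs(gap_b, m, "insertion_in_a")
  recs[[length(recs) + 1L]] <- indel_runs(gap_a, m, "insertion_in_b")
  cis <- do.call(rbind, recs)
  if (is.null(cis) || nrow(cis) == 0L) {
    return(data.frame(column = integer(), kind = character(),
                      pos_a = integer(), pos_b = integer(),
                      base_a = character(), base_b = character(),
                      length = integer(), stringsAsFactors = FALSE))
  }
  cis <- cis[order(cis$column), , drop = FALSE]
  rownames(cis) <- NULL
  cis
}

indel_runs <- function(is_gap, m, kind) {
  if (!any(is_gap)) return(NULL)
  r <- rle(is_gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gi <- which(r$values)
  first <- starts[gi]; last <- ends[gi]
  seqs <- vapply(seq_along(first), function(k) {
    cols <- first[k]:last[k]
    if (kind == "insertion_in_a") paste(m$chars_a[cols], collapse = "")
    else paste(m$chars_b[cols], collapse = "")
  }, character(1))
  data.frame(
    column = first, kind = kind,
    # anchored at the first affected base of the sequence-bearing row;
    # the gapped row is anchored at the last base before the gap
    pos_a = if (kind == "insertion_in_a") m$pos_a[first] else m$pos_a[first],
    pos_b = m$pos_b[first],
    base_a = if (kind == "insertion_in_a") seqs else "-",
    base_b = if (kind == "insertion_in_b") seqs else "-",
    length = last - first + 1L,
    stringsAsFactors = FALSE)
}

# Junction base(s) indexed by element-local position, derived from a local
# alignment of the junction read (pattern) to the element region (subject).
# Returns a character vector over 1..region_length: the junction base
# aligned at each element position, "-" where the junction shows a
# deletion, NA outside the aligned range.
junction_base_map <- function(junction, region_seq, region_offset, scoring) {
  aln <- local_align(junction, region_seq, scoring)
  ch <- alignment_chars(aln)
  res <- rep(NA_character_, nchar(region_seq) + region_offset - 1L)
  pos <- aln$b_start - 1L + cumsum(ch$b != "-")
  keep <- ch$b != "-"
  res[region_offset - 1L + pos[keep]] <- ch$a[keep]
  res
}

#' Localize a junction sequence's crossover between cis-morphisms
#'
#' The junction (a recombinant read following element A proximally and
#' element B distally) is aligned locally to each element; walking the
#' cis-morphisms of the pair alignment in order, the crossover is bounded
#' by the last cis-morphism at which the junction carries A's allele and
#' the first at which it carries B's allele. Junction positions matching
#' neither allele (or not covered unambiguously) are flagged as
#' uninformative and skipped, never used as bounds.
#'
#' @param junction_seq The breakpoint-spanning read (character/DNAString).
#' @param alignment `herv_alignment` of the two elements.
#' @param elem_a,elem_b Optional single-row element data.frames (or lists)
#'   with `chrom` and `start`; when supplied the reported bounds are
#'   genomic (1-based), otherwise element-local.
#' @param sample_id,locus,cnv_type Optional annotations carried through.
#' @param scoring [scoring_scheme()] for the junction-to-element
#'   alignments.
#' @return A `breakpoint_call`: list with `start_max`, `start_min`,
#'   `stop_min`, `stop_max` (see Details), the crossover's flanking
#'   alignment columns, allele calls per cis-morphism, and the count of
#'   uninformative positions. `start_max`/`start_min` bound the proximal
#'   crossover position on element A (maximal and minimal CNV extent);
#'   `stop_min`/`stop_max` bound it on element B.
#' @export
map_junction <- function(junction_seq, alignment, elem_a = NULL,
                         elem_b = NULL, sample_id = NA_character_,
                         locus = NA_character_, cnv_type = NA_character_,
                         scoring = scoring_scheme()) {
  cis <- find_cis_morphisms(alignment)
  assert_that(nrow(cis) > 0L,
              "elements are identical: no informative cis-morphisms")
  junction <- sanitize_dna(junction_seq)
  seq_a <- gsub("-", "", alignment$aligned_a, fixed = TRUE)
  seq_b <- gsub("-", "", alignment$aligned_b, fixed = TRUE)
  map_a <- junction_base_map(junction, seq_a, alignment$a_start, scoring)
  map_b <- junction_base_map(junction, seq_b, alignment$b_start, scoring)
  alleles <- vapply(seq_len(nrow(cis)), function(k) {
    call_allele(cis[k, ], map_a, map_b)
  }, character(1))
  informative <- alleles %in% c("A", "B")
  inf <- alleles[informative]
  assert_that(any(inf == "A") && any(inf == "B"),
              "junction matches only one element throughout: no crossover")
  idx <- which(informative)
  last_A <- max(idx[alleles[idx] == "A"])
  first_B <- min(idx[alleles[idx] == "B"])
  assert_that(last_A < first_B,
              "A and B alleles interleave: possible complex event")
  g_a <- function(pos) {
    if (is.null(elem_a)) pos else elem_a$start + pos - 1L
  }
  g_b <- function(pos) {
    if (is.null(elem_b)) pos else elem_b$start + pos - 1L
  }
  call <- structure(list(
    sample_id = sample_id, locus = locus, cnv_type = cnv_type,
    chrom = if (!is.null(elem_a)) elem_a$chrom else NA_character_,
    start_max = g_a(cis$pos_a[last_A]),
    start_min = g_a(cis$pos_a[first_B]),
    stop_min = g_b(cis$pos_b[last_A]),
    stop_max = g_b(cis$pos_b[first_B]),
    crossover_columns = c(cis$column[last_A], cis$column[first_B]),
    flanking_cis = cis[c(last_A, first_B), ],
    alleles = alleles,
    n_uninformative = sum(!informative)
  ), class = "breakpoint_call")
  assert_that(call$start_max < call$start_min,
              "degenerate call: adjacent informative cis-morphisms coincide")
  call
}

call_allele <- function(cm, map_a, map_b) {
  if (cm$kind == "substitution") {
    ja <- map_a[cm$pos_a]
    jb <- map_b[cm$pos_b]
    votes <- c(ja == cm$base_a, jb == cm$base_b)  # TRUE -> A, TRUE -> B
    a_vote <- isTRUE(votes[1]) || isTRUE(jb == cm$base_a)
    b_vote <- isTRUE(votes[2]) || isTRUE(ja == cm$base_b)
    if (a_vote && !b_vote) return("A")
    if (b_vote && !a_vote) return("B")
    return("ambiguous")
  }
  if (cm$kind == "insertion_in_a") {
    # A carries extra bases absent from B: the junction holds them iff it
    # follows A here
    state <- indel_state(map_a, cm$pos_a, cm$length)
    if (identical(state, "present")) return("A")
    if (identical(state, "absent")) return("B")
    return("ambiguous")
  }
  # insertion_in_b: B carries extra bases absent from A
  state <- indel_state(map_b, cm$pos_b, cm$length)
  if (identical(state, "present")) return("B")
  if (identical(state, "absent")) return("A")
  "ambiguous"
}

# Whether the junction carries an element's inserted bases. The junction-
# to-element aligner may shift a gap by a few bases within repetitive
# context, so the gap is sought in a window around the event rather than
# at its exact coordinates: a window with no junction gap means the
# insertion is present in the read; a window holding at least the event's
# length of gap means it is absent.
indel_state <- function(map, pos, len) {
  win <- max(1L, pos - len - 5L):min(length(map), pos + 2L * len + 5L)
  vals <- map[win]
  if (any(is.na(vals))) return("uncovered")
  n_gap <- sum(vals == "-")
  if (n_gap == 0L) return("present")
  if (n_gap >= len) return("absent")
  "unclear"
}

#' Proximal and distal breakpoint-uncertainty widths
#' @param call A `breakpoint_call` (or any list with the four bounds).
#' @return Named numeric `c(proximal, distal)` in bases.
#' @export
uncertainty_widths <- function(call) {
  c(proximal = call$start_min - call$start_max,
    distal = call$stop_max - call$stop_min)
}

#' CNV size implied by a breakpoint call
#'
#' The minimal rearranged segment, `stop_min - start_min`; this convention
#' reproduces the published sizes at all four molecularly confirmed loci.
#'
#' @param call A `breakpoint_call` (or list with `start_min`, `stop_min`).
#' @return Size in bases.
#' @export
cnv_size <- function(call) {
  call$stop_min - call$start_min
}

#' Format a CNV size to three significant figures in kb/Mb
#' @param bases Size in bases.
#' @return Character, e.g. `"1.05 Mb"`, `"877 kb"`, `"950 bp"`.
#' @export
format_cnv_size <- function(bases) {
  vapply(bases, function(x) {
    if (x >= 1e6) sprintf("%s Mb", format(signif(x / 1e6, 3)))
    else if (x >= 1e3) sprintf("%s kb", format(signif(x / 1e3, 3)))
    else sprintf("%d bp", as.integer(x))
  }, character(1))
}

#' Windowed identity profile of an alignment
#'
#' For each alignment column, the fraction of identical columns within a
#' window of `window` columns centred on it (truncated at the alignment
#' ends). Gap columns count as non-identical, so indel runs pull the
#' profile toward zero.
#'
#' @param alignment A `herv_alignment`.
#' @param window Window length in columns (default 50).
#' @return Numeric vector, one value per alignment column.
#' @export
windowed_identity <- function(alignment, window = 50) {
  assert_that(window >= 1, "window must be >= 1")
  st <- alignment_column_stats(alignment)
  ident <- as.numeric(st$is_identical)
  n <- length(ident)
  half_l <- (window - 1L) %/% 2L
  half_r <- window - 1L - half_l
  cs <- c(0, cumsum(ident))
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Render a Table-1-style breakpoint report
#'
#' @param calls List of `breakpoint_call` objects.
#' @return data.frame mirroring the published table layout: sample, locus,
#'   type, coordinates (outer span `chrom:start_max-stop_max`), size (3
#'   significant figures) and the four bounds.
#' @export
breakpoint_report <- function(calls) {
  rows <- lapply(calls, function(cl) {
    data.frame(
      sample_id = cl$sample_id, locus = cl$locus, cnv_type = cl$cnv_type,
      coordinates = sprintf("%s:%d-%d", cl$chrom %||% NA_character_,
                            cl$start_max, cl$stop_max),
      size = format_cnv_size(cnv_size(cl)),
      start_max = cl$start_max, start_min = cl$start_min,
      stop_min = cl$stop_min, stop_max = cl$stop_max,
      proximal_uncertainty = unname(uncertainty_widths(cl)["proximal"]),
      distal_uncertainty = unname(uncertainty_widths(cl)["distal"]),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' @export
print.breakpoint_call <- function(x, ...) {
  w <- uncertainty_widths(x)
  cat(sprintf(
    "Breakpoint call %s (%s %s)\n  bounds: %d / %d .. %d / %d\n  uncertainty: %d bp proximal, %d bp distal; size %s\n",
    x$sample_id, x$locus, x$cnv_type, x$start_max, x$start_min, x$stop_min,
    x$stop_max, w["proximal"], w["distal"],
    format_cnv_size(cnv_size(x))))
  invisible(x)
}
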