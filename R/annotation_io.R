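# Reading/writing of repeat annotation tables, genomes and interval files,
# and joining of RepeatMasker fragments into candidate HERV elements.
#
# All coordinates are held internally as 1-based inclusive (the
# Bioconductor/IRanges convention); UCSC rmsk tables (0-based half-open
# genoStart) and BED files are converted on read/write so that round-trips
# are exact.

RMSK_REQUIRED <- c("genoName", "genoStart", "genoEnd", "strand",
                   "repName", "repClass", "repFamily", "id")

#' Read a repeat annotation table
#'
#' Parses either the UCSC rmsk dialect (tab-separated, header line naming
#' `genoName`/`genoStart`/`genoEnd`/`strand`/`repName`/`repClass`/
#' `repFamily`/`id`) or the RepeatMasker `.out` dialect (whitespace-aligned,
#' three header lines beginning with "SW"). The dialect is auto-detected
#' from the first non-empty line.
#'
#' @param path Path to the annotation file.
#' @return A data.frame of repeat annotations with columns `chrom`, `start`,
#'   `end` (1-based inclusive), `strand` (`+`/`-`), `rep_name`, `rep_class`,
#'   `rep_family`, and integer `join_id` (the RepeatMasker ID linking
#'   fragments of one interrupted element).
#' @export
read_rmsk_table <- function(path) {
  assert_that(file.exists(path), "annotation file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- lines[nzchar(trimws(lines))]
  if (length(nonempty) == 0L) stop_fmt("empty annotation file: %s", path)
  first <- nonempty[[1]]
  if (grepl("genoStart", first) || grepl("genoName", first)) {
    ann <- parse_rmsk_ucsc(lines, path)
  } else if (grepl("^\\s*SW\\s", first) || grepl("perc", first)) {
    ann <- parse_rmsk_out(lines, path)
  } else {
    stop_fmt("unknown repeat annotation dialect in %s", path)
  }
  validate_annotations(ann)
  ann
}

parse_rmsk_ucsc <- function(lines, path) {
  header <- sub("^#", "", lines[[1]])
  cols <- strsplit(header, "\t")[[1]]
  if (length(cols) == 1L) cols <- strsplit(trimws(header), "\\s+")[[1]]
  missing_cols <- setdiff(RMSK_REQUIRED, cols)
  assert_that(length(missing_cols) == 0L,
              "rmsk table %s lacks required columns: %s",
              path, paste(missing_cols, collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    return(empty_annotations())
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  n_ok <- lengths(fields) == length(cols)
  if (any(!n_ok)) {
    stop_fmt("malformed rmsk row at line %d of %s", which(!n_ok)[1] + 1L, path)
  }
  mat <- do.call(rbind, fields)
  colnames(mat) <- cols
  start0 <- suppressWarnings(as.integer(mat[, "genoStart"]))
  end0 <- suppressWarnings(as.integer(mat[, "genoEnd"]))
  bad <- is.na(start0) | is.na(end0) | start0 < 0L | end0 <= start0
  if (any(bad)) {
    stop_fmt("unparseable or inverted coordinates at line %d of %s",
             which(bad)[1] + 1L, path)
  }
  data.frame(
    chrom = mat[, "genoName"],
    start = start0 + 1L,             # 0-based half-open -> 1-based inclusive
    end = end0,
    strand = mat[, "strand"],
    rep_name = mat[, "repName"],
    rep_class = mat[, "repClass"],
    rep_family = mat[, "repFamily"],
    join_id = as.integer(mat[, "id"]),
    stringsAsFactors = FALSE
  )
}

parse_rmsk_out <- function(lines, path) {
  # RepeatMasker .out: 3 header lines, then whitespace-separated records:
  # score div del ins query begin end (left) strand repName class/family
  # repBegin repEnd (left) id
  body_idx <- which(grepl("^\\s*[0-9]+\\s", lines))
  if (length(body_idx) == 0L) return(empty_annotations())
  recs <- lapply(body_idx, function(i) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(f) < 15L) stop_fmt("malformed .out row at line %d of %s", i, path)
    start <- suppressWarnings(as.integer(f[6]))
    end <- suppressWarnings(as.integer(f[7]))
    if (is.na(start) || is.na(end) || start < 1L || end < start) {
      stop_fmt("unparseable or inverted coordinates at line %d of %s", i, path)
    }
    cf <- strsplit(f[11], "/", fixed = TRUE)[[1]]
    data.frame(
      chrom = f[5], start = start, end = end,
      strand = if (f[9] == "C") "-" else "+",
      rep_name = f[10],
      rep_class = cf[1],
      rep_family = if (length(cf) > 1L) cf[2] else cf[1],
      join_id = as.integer(f[15]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, recs)
}

empty_annotations <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), rep_name = character(),
             rep_class = character(), rep_family = character(),
             join_id = integer(), stringsAsFactors = FALSE)
}

validate_annotations <- function(ann) {
  assert_that(all(ann$start <= ann$end), "annotation with start > end")
  assert_that(all(ann$strand %in% c("+", "-")),
              "annotation strand must be '+' or '-'")
  assert_that(all(ann$join_id >= 0L), "negative join_id")
  invisible(ann)
}

#' Write annotations in the UCSC rmsk dialect
#'
#' Emits the column subset [read_rmsk_table()] requires, converting starts
#' back to 0-based half-open, so that a write/read round-trip is exact.
#'
#' @param ann Annotation data.frame as returned by [read_rmsk_table()].
#' @param path Output path.
#' @export
write_rmsk_table <- function(ann, path) {
  out <- data.frame(
    genoName = ann$chrom,
    genoStart = to_bed_start(ann$start),
    genoEnd = ann$end,
    strand = ann$strand,
    repName = ann$rep_name,
    repClass = ann$rep_class,
    repFamily = ann$rep_family,
    id = ann$join_id
  )
  header <- paste0("#", paste(colnames(out), collapse = "\t"))
  writeLines(header, path)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Join RepeatMasker fragments into HERV elements
#'
#' Fragments sharing (`chrom`, `strand`, `join_id`) are merged into one
#' element spanning them, provided no gap between consecutive fragments
#' exceeds `max_join_gap`; runs are split at oversized gaps. The element
#' name is the `rep_name` of its longest fragment. Fragments of one
#' `join_id` lying on both strands are treated as separate elements, since
#' downstream pair-orientation logic requires a single strand per element.
#'
#' @param ann Annotation data.frame (see [read_rmsk_table()]).
#' @param max_join_gap Maximum tolerated gap in bases between consecutive
#'   fragments of one element (default 5000).
#' @return A data.frame of elements with columns `chrom`, `start`, `end`,
#'   `strand`, `name`, `join_id`, `length`, `n_fragments`, plus a
#'   `fragments` list-column holding each element's constituent rows.
#' @export
join_fragments <- function(ann, max_join_gap = 5000) {
  assert_that(max_join_gap >= 0, "max_join_gap must be >= 0")
  if (nrow(ann) == 0L) return(empty_elements())
  validate_annotations(ann)
  key <- paste(ann$chrom, ann$strand, ann$join_id, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(ann)), key), function(idx) {
    frags <- ann[idx, , drop = FALSE]
    frags <- frags[order(frags$start, frags$end), , drop = FALSE]
    gap <- c(0L, pmax(frags$start[-1] - cummax(frags$end)[-nrow(frags)] - 1L, 0L))
    run <- cumsum(gap > max_join_gap)
    lapply(split(seq_len(nrow(frags)), run), function(ri) {
      fr <- frags[ri, , drop = FALSE]
      longest <- which.max(fr$end - fr$start + 1L)
      data.frame(
        chrom = fr$chrom[1],
        start = min(fr$start),
        end = max(fr$end),
        strand = fr$strand[1],
        name = fr$rep_name[longest],
        join_id = fr$join_id[1],
        length = max(fr$end) - min(fr$start) + 1L,
        n_fragments = nrow(fr),
        fragments = I(list(fr)),
        stringsAsFactors = FALSE
      )
    })
  })
  el <- do.call(rbind, unlist(pieces, recursive = FALSE))
  el <- el[order(el$chrom, el$start, el$end), , drop = FALSE]
  rownames(el) <- NULL
  el
}

empty_elements <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), name = character(), join_id = integer(),
             length = integer(), n_fragments = integer(),
             fragments = I(list()), stringsAsFactors = FALSE)
}

#' Read a genome FASTA into a named, upper-case DNAStringSet
#'
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet] keyed by chromosome name (first
#'   whitespace-delimited token of each FASTA header).
#' @export
read_genome_fasta <- function(path) {
  assert_that(file.exists(path), "FASTA not found: %s", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  Biostrings::DNAStringSet(toupper(g))
}

#' Chromosome lengths of a genome
#' @param genome A DNAStringSet as returned by [read_genome_fasta()].
#' @return Named integer vector of sequence lengths.
#' @export
genome_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

#' Write intervals as BED
#'
#' Internal 1-based inclusive intervals are written 0-based half-open.
#' BED4 when no `strand` column is present, BED6 otherwise.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  n <- nrow(intervals)
  out <- data.frame(
    chrom = intervals$chrom,
    start = to_bed_start(intervals$start),
    end = intervals$end,
    name = intervals$name %||% rep(".", n)
  )
  if (!is.null(intervals$strand)) {
    out$score <- intervals$score %||% rep(0L, n)
    out$strand <- intervals$strand
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file back into 1-based inclusive intervals
#' @param path BED path.
#' @return data.frame with `chrom`, `start`, `end`, `name` (and `strand`
#'   for BED6).
#' @export
read_bed <- function(path) {
  assert_that(file.exists(path), "BED not found: %s", path)
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 3L, "malformed BED (fewer than 3 columns): %s", path)
  out <- data.frame(chrom = df[[1]], start = as.integer(df[[2]]) + 1L,
                    end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4L) out$name <- df[[4]]
  if (ncol(df) >= 6L) out$strand <- df[[6]]
  bad <- which(is.na(out$start) | is.na(out$end) | out$start > out$end)
  assert_that(length(bad) == 0L, "malformed BED record at line %d of %s",
              bad[1], path)
  out
}

#' Read a segmental-duplication table (UCSC genomicSuperDups dialect)
#'
#' @param path Tab-separated table with a header naming at least `chrom`,
#'   `chromStart`, `chromEnd`, `otherChrom`, `otherStart`, `otherEnd`,
#'   `strand` (orientation of the other copy) and `fracMatch`.
#' @return data.frame with those fields, coordinates 1-based inclusive.
#' @export
read_segdup_table <- function(path) {
  assert_that(file.exists(path), "segdup table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[1] <- sub("^X\\.", "", names(df)[1])  # '#chrom' header
  need <- c("chrom", "chromStart", "chromEnd", "otherChrom", "otherStart",
            "otherEnd", "strand", "fracMatch")
  missing_cols <- setdiff(need, names(df))
  assert_that(length(missing_cols) == 0L,
              "segdup table %s lacks columns: %s", path,
              paste(missing_cols, collapse = ", "))
  out <- data.frame(
    chrom = df$chrom,
    start = as.integer(df$chromStart) + 1L,
    end = as.integer(df$chromEnd),
    other_chrom = df$otherChrom,
    other_start = as.integer(df$otherStart) + 1L,
    other_end = as.integer(df$otherEnd),
    other_strand = df$strand,
    frac_match = as.numeric(df$fracMatch),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(out$start) | is.na(out$end) | out$start > out$end)
  assert_that(length(bad) == 0L,
              "malformed segdup record at line %d of %s", bad[1] + 1L, path)
  out
}

#' Extract element sequences from a genome
#'
#' Sequences are returned on the forward (+) genome strand. For pair
#' alignment this is sufficient: two same-strand elements give the same
#' local alignment whether both are taken forward or both
#' reverse-complemented.
#'
#' @param elements Element data.frame from [join_fragments()].
#' @param genome DNAStringSet from [read_genome_fasta()].
#' @return DNAStringSet, one sequence per element row.
#' @export
element_sequences <- function(elements, genome) {
  missing_chrom <- setdiff(unique(elements$chrom), names(genome))
  assert_that(length(missing_chrom) == 0L,
              "chromosome(s) absent from genome: %s",
              paste(missing_chrom, collapse = ", "))
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(elements)), function(i) {
    as.character(Biostrings::subseq(genome[[elements$chrom[i]]],
                                    elements$start[i], elements$end[i]))
  }, character(1)))
  names(seqs) <- element_id(elements)
  seqs
}

element_id <- function(elements) {
  sprintf("%s:%d-%d(%s)", elements$chrom, elements$start, elements$end,
          elements$strand)
}
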