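# Cross-reference of CNV calls (with probe-bounded breakpoint-uncertainty
# intervals) against predicted HERV elements/pairs, and flanking-probe
# placement for a HERV-targeted array design.

#' Breakpoint-uncertainty intervals from an ordered probe grid
#'
#' The proximal uncertainty interval runs from the last normal probe before
#' the altered run to the first altered probe; the distal interval runs
#' from the last altered probe to the first normal probe after the run.
#'
#' @param probe_positions Sorted probe positions.
#' @param probe_states Character vector, one of `"normal"`/`"N"` or
#'   `"altered"`/`"A"` per probe; altered probes must form one contiguous
#'   run with normal probes on both sides.
#' @return list with `proximal = c(start, end)` and `distal = c(start, end)`
#'   (probe positions, inclusive).
#' @export
uncertainty_intervals_from_probes <- function(probe_positions, probe_states) {
  assert_that(length(probe_positions) == length(probe_states),
              "positions/states length mismatch")
  assert_that(!is.unsorted(probe_positions), "probes must be sorted")
  st <- toupper(substr(probe_states, 1, 1))
  assert_that(all(st %in% c("N", "A")),
              "probe states must be normal/altered")
  alt <- which(st == "A")
  assert_that(length(alt) > 0L, "no altered probes: no CNV to bound")
  assert_that(all(diff(alt) == 1L), "altered probes are not contiguous")
  first_alt <- alt[1]; last_alt <- alt[length(alt)]
  assert_that(first_alt > 1L && last_alt < length(st),
              "altered run at array edge: uncertainty interval unbounded")
  list(proximal = c(probe_positions[first_alt - 1L],
                    probe_positions[first_alt]),
       distal = c(probe_positions[last_alt],
                  probe_positions[last_alt + 1L]))
}

#' Read a CNV call table
#'
#' TSV with header columns `sample_id`, `chrom`, `cnv_type`
#' (deletion/duplication), and four probe-bound coordinates `start_max`,
#' `start_min`, `stop_min`, `stop_max`: the proximal uncertainty interval
#' is `[start_max, start_min]`, the distal `[stop_min, stop_max]`.
#'
#' @param path TSV path.
#' @return data.frame of CNV calls (1-based coordinates).
#' @export
read_cnv_table <- function(path) {
  assert_that(file.exists(path), "CNV table not found: %s", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "cnv_type", "start_max", "start_min",
            "stop_min", "stop_max")
  missing_cols <- setdiff(need, names(df))
  assert_that(length(missing_cols) == 0L, "CNV table %s lacks columns: %s",
              path, paste(missing_cols, collapse = ", "))
  validate_cnv_calls(df)
  df
}

validate_cnv_calls <- function(cnvs) {
  ok <- cnvs$start_max <= cnvs$start_min & cnvs$start_min <= cnvs$stop_min &
    cnvs$stop_min <= cnvs$stop_max
  assert_that(all(ok), "CNV call with disordered bounds (row %d)",
              which(!ok)[1])
  assert_that(all(cnvs$cnv_type %in% c("deletion", "duplication")),
              "cnv_type must be deletion or duplication")
  invisible(cnvs)
}

#' Flag CNVs whose both uncertainty intervals contain a HERV
#'
#' A CNV is flagged as potentially HERV-mediated iff at least one element
#' overlaps its proximal uncertainty interval and at least one overlaps its
#' distal interval. In strict mode (a pair table supplied) the proximal and
#' distal elements must additionally form an emitted pair, whose id is
#' reported.
#'
#' @param cnvs CNV data.frame (see [read_cnv_table()]).
#' @param elements Element data.frame.
#' @param pairs Optional pair data.frame; when supplied, strict matching is
#'   used.
#' @return `cnvs` with logical `herv_mediated` and character `pair_id`
#'   columns added.
#' @export
match_cnvs_to_pairs <- function(cnvs, elements, pairs = NULL) {
  validate_cnv_calls(cnvs)
  n <- nrow(cnvs)
  flagged <- logical(n)
  pair_id <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    el <- elements[elements$chrom == cnvs$chrom[k], , drop = FALSE]
    if (nrow(el) == 0L) next
    in_prox <- overlaps1(el$start, el$end, cnvs$start_max[k], cnvs$start_min[k])
    in_dist <- overlaps1(el$start, el$end, cnvs$stop_min[k], cnvs$stop_max[k])
    if (is.null(pairs)) {
      flagged[k] <- any(in_prox) && any(in_dist)
    } else {
      pr <- pairs[pairs$chrom == cnvs$chrom[k], , drop = FALSE]
      if (nrow(pr) == 0L) next
      a_ok <- overlaps1(pr$a_start, pr$a_end, cnvs$start_max[k],
                        cnvs$start_min[k])
      b_ok <- overlaps1(pr$b_start, pr$b_end, cnvs$stop_min[k],
                        cnvs$stop_max[k])
      hit <- which(a_ok & b_ok)
      if (length(hit) > 0L) {
        flagged[k] <- TRUE
        pair_id[k] <- pr$pair_id[hit[1]]
      }
    }
  }
  cnvs$herv_mediated <- flagged
  cnvs$pair_id <- pair_id
  cnvs
}

#' Place flanking oligonucleotide probes around each pair's elements
#'
#' For every element of every pair, `n_per_side` probes are placed
#' immediately outside each element edge, stepping outward at `spacing`
#' intervals and skipping candidate positions that overlap any annotated
#' repeat (when a repeat mask is supplied). A side is reported unplaceable
#' (rather than raising an error) when the required probes cannot be
#' placed within `search_window` bases of the element edge or within the
#' contig.
#'
#' @param pairs Pair data.frame.
#' @param chrom_lengths Named chromosome lengths.
#' @param n_per_side Probes per element side (default 5).
#' @param probe_length Probe length in bases (default 60).
#' @param spacing Distance between consecutive probe starts (default 100).
#' @param repeat_mask Optional data.frame (`chrom`, `start`, `end`) of
#'   intervals probes must not overlap.
#' @param search_window Maximum distance from the element edge searched for
#'   placeable positions (default 10000).
#' @return data.frame of probes (`pair_id`, `element` "a"/"b", `side`
#'   "left"/"right", `chrom`, `start`, `end`, `placeable`); unplaceable
#'   sides yield a single row with `placeable = FALSE` and NA coordinates.
#' @export
place_flanking_probes <- function(pairs, chrom_lengths, n_per_side = 5,
                                  probe_length = 60, spacing = 100,
                                  repeat_mask = NULL, search_window = 10000) {
  assert_that(spacing >= probe_length,
              "spacing must be at least probe_length")
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    chrom <- pairs$chrom[k]
    clen <- chrom_lengths[[chrom]]
    assert_that(!is.null(clen) && !is.na(clen),
                "chromosome length missing for %s", chrom)
    mask <- if (is.null(repeat_mask)) NULL else
      repeat_mask[repeat_mask$chrom == chrom, , drop = FALSE]
    for (elem in c("a", "b")) {
      es <- pairs[[paste0(elem, "_start")]][k]
      ee <- pairs[[paste0(elem, "_end")]][k]
      for (side in c("left", "right")) {
        probes <- place_probes_one_side(es, ee, side, clen, n_per_side,
                                        probe_length, spacing, mask,
                                        search_window)
        if (is.null(probes)) {
          out[[length(out) + 1L]] <- data.frame(
            pair_id = pairs$pair_id[k], element = elem, side = side,
            chrom = chrom, start = NA_integer_, end = NA_integer_,
            placeable = FALSE, stringsAsFactors = FALSE)
        } else {
          out[[length(out) + 1L]] <- data.frame(
            pair_id = pairs$pair_id[k], element = elem, side = side,
            chrom = chrom, start = probes, end = probes + probe_length - 1L,
            placeable = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

place_probes_one_side <- function(elem_start, elem_end, side, chrom_length,
                                  n, probe_length, spacing, mask,
                                  search_window) {
  if (side == "left") {
    starts <- seq(elem_start - probe_length, by = -spacing,
                  length.out = ceiling(search_window / spacing))
    starts <- starts[starts >= 1L &
                       starts >= elem_start - search_window]
  } else {
    starts <- seq(elem_end + 1L, by = spacing,
                  length.out = ceiling(search_window / spacing))
    starts <- starts[starts + probe_length - 1L <= chrom_length &
                       starts <= elem_end + search_window]
  }
  if (!is.null(mask) && nrow(mask) > 0L && length(starts) > 0L) {
    clear <- vapply(starts, function(s) {
      !any(overlaps1(s, s + probe_length - 1L, mask$start, mask$end))
    }, logical(1))
    starts <- starts[clear]
  }
  # probes must not overlap the element they flank (guaranteed by
  # construction above; kept as a safety check)
  starts <- starts[!overlaps1(starts, starts + probe_length - 1L,
                              elem_start, elem_end)]
  if (length(starts) < n) return(NULL)
  sort(starts[seq_len(n)])
}
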