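# Synthetic genomes with planted HERV-like element pairs, recombinant
# junctions, probe grids and hotspot motifs, with recorded ground truth,
# so that every pipeline stage has an offline recovery test.

random_dna <- function(n, base_probs = rep(0.25, 4)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = base_probs),
        collapse = "")
}

#' Ancestral HERV-like element blueprint
#'
#' Emulates the structure of the CNV-mediating elements: two identical
#' intact LTRs (~450 bp) flanking an internal retroviral sequence from
#' which a large env-like span has been deleted.
#'
#' @param ltr_length LTR length in bases (default 450).
#' @param internal_length Internal sequence length after the env deletion
#'   (default 5000).
#' @param env_deletion_length Length of the deleted env-like span recorded
#'   in the blueprint (default 1000); the deletion is applied to a longer
#'   simulated consensus, so `internal_length` is the emitted length.
#' @param base_probs Base composition (A, C, G, T; default uniform).
#' @return A `herv_blueprint` list: `seq` (the ancestral element),
#'   `ltr_length`, `internal_length`, `env_deletion` (the deleted span's
#'   coordinates on the simulated consensus).
#' @export
herv_blueprint <- function(ltr_length = 450, internal_length = 5000,
                           env_deletion_length = 1000,
                           base_probs = rep(0.25, 4)) {
  consensus_internal <- random_dna(internal_length + env_deletion_length,
                                   base_probs)
  del_start <- floor(internal_length / 2)
  del_end <- del_start + env_deletion_length - 1L
  internal <- paste0(substr(consensus_internal, 1, del_start - 1L),
                     substr(consensus_internal, del_end + 1L,
                            nchar(consensus_internal)))
  ltr <- random_dna(ltr_length, base_probs)
  structure(list(
    seq = paste0(ltr, internal, ltr),
    ltr_length = ltr_length,
    internal_length = nchar(internal),
    env_deletion = c(del_start, del_end)
  ), class = "herv_blueprint")
}

#' Derive a diverged element pair with a known alignment
#'
#' `seq_b` is derived from `seq_a` (the ancestor) so that the planted
#' alignment has identity `1 - divergence`: the difference budget
#' `round(divergence * L)` alignment columns is split between point
#' substitutions and short indels (geometric lengths, mean
#' `indel_mean_len`), `indel_fraction` of the budget going to indel
#' columns. The planted gapped alignment and the exact variant
#' (cis-morphism) list are recorded as ground truth.
#'
#' @param ancestor Ancestral sequence (character, or a `herv_blueprint`).
#' @param divergence Target divergence in \[0, 0.3\].
#' @param seed Optional integer seed (`NULL` continues the current RNG
#'   stream, as when called from [make_genome()]).
#' @param indel_fraction Fraction of the difference budget spent on indel
#'   columns (default 0.1).
#' @param indel_mean_len Mean indel length (default 2).
#' @return List: `seq_a`, `seq_b`, `alignment` (a `herv_alignment` of the
#'   planted truth), `variants` (its cis-morphism table),
#'   `realized_identity`.
#' @export
make_element_pair <- function(ancestor, divergence, seed = NULL,
                              indel_fraction = 0.1, indel_mean_len = 2) {
  assert_that(divergence >= 0 && divergence <= 0.3,
              "divergence must be in [0, 0.3]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (inherits(ancestor, "herv_blueprint")) ancestor <- ancestor$seq
  a <- strsplit(as_upper_chr(ancestor), "")[[1]]
  L <- length(a)
  total_diff <- round(divergence * L)
  n_indel_cols <- round(indel_fraction * total_diff)
  n_sub <- total_diff - n_indel_cols

  # indel events: geometric lengths with the requested mean, consuming the
  # indel column budget
  indel_lens <- integer(0)
  while (sum(indel_lens) < n_indel_cols) {
    l <- 1L + rgeom(1, 1 / indel_mean_len)
    indel_lens <- c(indel_lens, min(l, n_indel_cols - sum(indel_lens)))
  }
  n_events <- length(indel_lens)
  # Indel events are kept >= ~150 bp apart (and clear of the sequence
  # ends): under heavy gap penalties a local aligner otherwise merges
  # nearby opposite-sense indels into mismatch runs, so the planted
  # alignment would no longer be the score optimum and realized identity
  # would drift below the target. Anchors are drawn from a grid whose
  # pitch enforces the spacing; the pitch is relaxed only if the sequence
  # cannot hold the requested events.
  margin <- 20L
  anchors <- integer(0)
  if (n_events > 0L) {
    max_len <- max(indel_lens)
    pitch <- 150L + max_len
    repeat {
      grid <- seq(margin, L - margin - max_len, by = pitch)
      if (length(grid) >= n_events || pitch <= max_len + 2L) break
      pitch <- max(pitch %/% 2L, max_len + 2L)
    }
    assert_that(length(grid) >= n_events,
                "sequence too short for requested indel load")
    anchors <- sort(sample(grid, n_events))
    is_del <- sample(c(TRUE, FALSE), n_events, replace = TRUE)
  } else {
    is_del <- logical(0)
  }
  blocked <- unique(unlist(lapply(seq_len(n_events), function(k) {
    (anchors[k] - 1L):(anchors[k] + indel_lens[k] + 1L)
  })))
  sub_pool <- setdiff(seq_len(L), blocked)
  assert_that(length(sub_pool) >= n_sub,
              "sequence too short for requested divergence")
  subs <- sort(sample(sub_pool, n_sub))

  b <- a
  for (p in subs) {
    b[p] <- sample(setdiff(DNA_BASES, a[p]), 1)
  }
  # deletions from b: gap columns in the b row over existing a bases
  del_events <- which(is_del)
  for (k in del_events) {
    b[anchors[k]:(anchors[k] + indel_lens[k] - 1L)] <- "-"
  }
  # insertions in b: new columns (gap in a row) spliced in after anchors
  aligned_a <- a
  aligned_b <- b
  ins_events <- which(!is_del)
  if (length(ins_events) > 0L) {
    pieces_a <- list(); pieces_b <- list()
    bounds <- c(0L, anchors[ins_events], L)
    for (k in seq_along(ins_events)) {
      seg <- (bounds[k] + 1L):bounds[k + 1L]
      pieces_a[[length(pieces_a) + 1L]] <- a[seg]
      pieces_b[[length(pieces_b) + 1L]] <- b[seg]
      len <- indel_lens[ins_events[k]]
      pieces_a[[length(pieces_a) + 1L]] <- rep("-", len)
      pieces_b[[length(pieces_b) + 1L]] <-
        sample(DNA_BASES, len, replace = TRUE)
    }
    seg <- (bounds[length(ins_events) + 1L] + 1L):L
    pieces_a[[length(pieces_a) + 1L]] <- a[seg]
    pieces_b[[length(pieces_b) + 1L]] <- b[seg]
    aligned_a <- unlist(pieces_a)
    aligned_b <- unlist(pieces_b)
  }
  alignment <- alignment_from_strings(paste(aligned_a, collapse = ""),
                                      paste(aligned_b, collapse = ""))
  list(seq_a = paste(a, collapse = ""),
       seq_b = gsub("-", "", paste(aligned_b, collapse = ""), fixed = TRUE),
       alignment = alignment,
       variants = find_cis_morphisms(alignment),
       realized_identity = alignment$identity)
}

#' Simulation configuration
#'
#' @param seed Integer RNG seed (bit-reproducibility: identical configs
#'   give identical genomes).
#' @param pairs data.frame with one row per planted pair: `divergence`
#'   (target 1 - identity), `separation` (bases between element inner
#'   edges) and `strand`. Decoy pairs are simply rows with divergence
#'   above the screening threshold.
#' @param ltr_length,internal_length Element blueprint (defaults 450 bp
#'   LTRs, 5 kb internal sequence).
#' @param margin Background bases on either side of each pair (default
#'   12000).
#' @param base_probs Background base composition (default uniform).
#' @param fragment_elements Emit each element as two annotation fragments
#'   separated by a small annotation gap sharing one join id, to exercise
#'   fragment joining (default `FALSE`).
#' @param fragment_gap Annotation gap width when fragmenting (default 200).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              pairs = data.frame(
                                divergence = c(0.01, 0.04, 0.055, 0.12),
                                separation = c(50000, 80000, 120000, 60000),
                                strand = c("+", "+", "-", "+")),
                              ltr_length = 450, internal_length = 5000,
                              margin = 12000, base_probs = rep(0.25, 4),
                              fragment_elements = FALSE,
                              fragment_gap = 200) {
  assert_that(all(pairs$divergence >= 0 & pairs$divergence <= 0.3),
              "divergence must be in [0, 0.3]")
  assert_that(all(pairs$strand %in% c("+", "-")), "strand must be +/-")
  structure(list(seed = as.integer(seed), pairs = pairs,
                 ltr_length = ltr_length,
                 internal_length = internal_length, margin = margin,
                 base_probs = base_probs,
                 fragment_elements = fragment_elements,
                 fragment_gap = fragment_gap),
            class = "simulation_config")
}

#' Simulate a genome with planted element pairs and ground truth
#'
#' Each planted pair receives its own chromosome: background sequence, the
#' ancestral-derived element A, `separation` background bases, the diverged
#' element B, background sequence. Annotations carry one join id per
#' element (two fragments per element when `fragment_elements`).
#'
#' @param config A [simulation_config()].
#' @return List: `genome` (DNAStringSet), `rmsk` (annotation data.frame in
#'   the layout of [read_rmsk_table()]), `truth` (list with `elements`,
#'   `pairs` data.frames and per-pair `details` holding the planted
#'   alignment and variant table).
#' @export
make_genome <- function(config) {
  set.seed(config$seed)
  genome <- list(); ann <- list(); t_el <- list(); t_pair <- list()
  details <- list()
  for (i in seq_len(nrow(config$pairs))) {
    chrom <- sprintf("chrSim%d", i)
    bp <- herv_blueprint(config$ltr_length, config$internal_length,
                         base_probs = config$base_probs)
    pr <- make_element_pair(bp, config$pairs$divergence[i])
    sep <- config$pairs$separation[i]
    left <- random_dna(config$margin, config$base_probs)
    mid <- random_dna(sep, config$base_probs)
    right <- random_dna(config$margin, config$base_probs)
    a_start <- nchar(left) + 1L
    a_end <- a_start + nchar(pr$seq_a) - 1L
    b_start <- a_end + sep + 1L
    b_end <- b_start + nchar(pr$seq_b) - 1L
    genome[[chrom]] <- paste0(left, pr$seq_a, mid, pr$seq_b, right)
    strand <- config$pairs$strand[i]
    name <- sprintf("HERVH-sim%d", i)
    ann[[chrom]] <- rbind(
      element_annotation(chrom, a_start, a_end, strand, name, 2L * i - 1L,
                         config),
      element_annotation(chrom, b_start, b_end, strand, name, 2L * i,
                         config))
    t_el[[chrom]] <- data.frame(
      chrom = chrom, start = c(a_start, b_start), end = c(a_end, b_end),
      strand = strand, name = name, join_id = c(2L * i - 1L, 2L * i),
      pair = i, role = c("a", "b"), stringsAsFactors = FALSE)
    t_pair[[chrom]] <- data.frame(
      chrom = chrom, pair = i, a_start = a_start, a_end = a_end,
      b_start = b_start, b_end = b_end, strand = strand,
      separation = sep, divergence = config$pairs$divergence[i],
      planted_identity = pr$realized_identity, stringsAsFactors = FALSE)
    details[[i]] <- pr
  }
  list(
    genome = Biostrings::DNAStringSet(unlist(genome)),
    rmsk = do.call(rbind, unname(ann)),
    truth = list(elements = do.call(rbind, unname(t_el)),
                 pairs = do.call(rbind, unname(t_pair)),
                 details = details)
  )
}

element_annotation <- function(chrom, start, end, strand, name, join_id,
                               config) {
  base <- data.frame(chrom = chrom, start = start, end = end,
                     strand = strand, rep_name = name,
                     rep_class = "LTR", rep_family = "ERV1",
                     join_id = join_id, stringsAsFactors = FALSE)
  if (!isTRUE(config$fragment_elements)) return(base)
  mid <- (start + end) %/% 2L
  gap <- config$fragment_gap
  rbind(
    transform(base, end = mid),
    transform(base, start = mid + gap + 1L)
  )
}

#' Build a recombinant junction sequence from a planted pair
#'
#' The junction follows element A through the crossover alignment column
#' and element B after it, optionally trimmed to `read_length` bases
#' centred on the crossover (emulating a Sanger read across the
#' breakpoint).
#'
#' @param pair A pair as returned by [make_element_pair()] (needs
#'   `alignment`).
#' @param crossover_column Alignment column of the template switch
#'   (`0` yields element B's sequence unchanged).
#' @param read_length Optional trimmed read length.
#' @return List: `junction` (character), `crossover_column`,
#'   `last_a_variant`/`first_b_variant` (columns of the planted variants
#'   bracketing the crossover, `NA` when absent).
#' @export
make_junction <- function(pair, crossover_column, read_length = NULL) {
  aln <- pair$alignment
  assert_that(crossover_column >= 0 &&
                crossover_column <= aln$aln_length,
              "crossover outside the alignment")
  ch <- alignment_chars(aln)
  pre <- if (crossover_column > 0)
    ch$a[seq_len(crossover_column)] else character(0)
  post <- if (crossover_column < aln$aln_length)
    ch$b[(crossover_column + 1L):aln$aln_length] else character(0)
  junction <- paste(c(pre[pre != "-"], post[post != "-"]), collapse = "")
  cross_pos <- sum(pre != "-")
  if (!is.null(read_length)) {
    half <- read_length %/% 2L
    lo <- max(cross_pos - half + 1L, 1L)
    hi <- min(lo + read_length - 1L, nchar(junction))
    junction <- substr(junction, lo, hi)
  }
  vcols <- pair$variants$column
  last_a <- vcols[vcols <= crossover_column]
  first_b <- vcols[vcols > crossover_column]
  list(junction = junction,
       crossover_column = crossover_column,
       last_a_variant = if (length(last_a)) max(last_a) else NA_integer_,
       first_b_variant = if (length(first_b)) min(first_b) else NA_integer_)
}

#' Simulate an aCGH probe grid over a planted CNV
#'
#' Probes every `spacing` bases across `extent`; a probe is altered iff it
#' lies inside the true CNV, so the resulting uncertainty intervals always
#' bracket the planted breakpoints and are at most `spacing` wide on each
#' side.
#'
#' @param cnv_truth `c(start, end)` of the planted CNV (1-based inclusive).
#' @param spacing Probe spacing in bases.
#' @param extent `c(from, to)` covered by the grid (must extend beyond the
#'   CNV on both sides).
#' @return List: `positions`, `states` (`"normal"`/`"altered"`), `truth`.
#' @export
make_probe_grid <- function(cnv_truth, spacing, extent) {
  assert_that(extent[1] < cnv_truth[1] && extent[2] > cnv_truth[2],
              "probe grid must extend beyond the CNV")
  positions <- seq(extent[1], extent[2], by = spacing)
  states <- ifelse(positions >= cnv_truth[1] & positions <= cnv_truth[2],
                   "altered", "normal")
  list(positions = positions, states = states, truth = cnv_truth)
}

#' Plant motif copies into a sequence
#'
#' Writes instances of the consensus at the given offsets, filling
#' degenerate `N` positions with random bases. Overlapping or out-of-bound
#' plantings are rejected.
#'
#' @param seq Host sequence.
#' @param offsets 1-based start offsets.
#' @param consensus IUPAC consensus (default the hotspot 13-mer).
#' @return The modified sequence (character).
#' @export
plant_motifs <- function(seq, offsets, consensus = HOTSPOT_CONSENSUS) {
  s <- strsplit(as_upper_chr(seq), "")[[1]]
  w <- nchar(consensus)
  offsets <- sort(offsets)
  assert_that(all(offsets >= 1 & offsets + w - 1L <= length(s)),
              "motif planting out of sequence bounds")
  assert_that(all(diff(offsets) >= w), "planted motifs overlap")
  cons <- strsplit(toupper(consensus), "")[[1]]
  for (o in offsets) {
    inst <- vapply(cons, function(ch) {
      allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]]
      if (length(allowed) == 1L) allowed else sample(allowed, 1)
    }, character(1))
    s[o:(o + w - 1L)] <- inst
  }
  paste(s, collapse = "")
}

#' Write a genome to FASTA
#' @param genome DNAStringSet.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
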