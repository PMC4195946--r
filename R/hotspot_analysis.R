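# PRDM9 recombination-hotspot motif scanning (position weight matrix over
# the degenerate 13-mer consensus) and the two enrichment statistics:
# a one-sided exact Poisson test of motif counts in breakpoint clusters,
# and signed-rank / rank-sum comparisons of per-element motif densities.

HOTSPOT_CONSENSUS <- "CCNCCNTNNCCNC"
DNA_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from a degenerate consensus
#'
#' Each column gives probability `specified_base_weight` to the consensus
#' base(s) (split equally over the bases an IUPAC degenerate code allows;
#' uniform for `N`), with the remainder split equally over the other bases.
#' Weights are log-odds against a uniform background, then shifted per
#' column so the minimum achievable score is 0, which makes the
#' "fraction of maximum score" threshold well-defined.
#'
#' @param consensus IUPAC consensus string (default the degenerate 13-mer
#'   PRDM9 hotspot motif `CCNCCNTNNCCNC`).
#' @param specified_base_weight Total probability assigned to the allowed
#'   bases of each column (default 0.85).
#' @return A `motif_pwm` list: `matrix` (4 x L shifted log-odds, rows
#'   A/C/G/T), `max_score`, `consensus`, `specified_base_weight`.
#' @export
build_pwm <- function(consensus = HOTSPOT_CONSENSUS,
                      specified_base_weight = 0.85) {
  letters_cons <- strsplit(toupper(consensus), "")[[1]]
  code_map <- Biostrings::IUPAC_CODE_MAP
  assert_that(all(letters_cons %in% names(code_map)),
              "consensus contains non-IUPAC letters")
  L <- length(letters_cons)
  probs <- matrix(0, 4, L, dimnames = list(DNA_BASES, NULL))
  for (j in seq_len(L)) {
    allowed <- strsplit(code_map[[letters_cons[j]]], "")[[1]]
    if (length(allowed) == 4L) {
      probs[, j] <- 0.25
    } else {
      probs[allowed, j] <- specified_base_weight / length(allowed)
      others <- setdiff(DNA_BASES, allowed)
      probs[others, j] <- (1 - specified_base_weight) / length(others)
    }
  }
  logodds <- log(probs / 0.25)
  shifted <- sweep(logodds, 2, apply(logodds, 2, min))
  structure(list(
    matrix = shifted,
    max_score = sum(apply(shifted, 2, max)),
    consensus = toupper(consensus),
    specified_base_weight = specified_base_weight
  ), class = "motif_pwm")
}

motif_length <- function(pwm) ncol(pwm$matrix)

# Score every offset of a sequence on the forward strand; NA where the
# window contains a non-ACGT base.
pwm_scores_forward <- function(seq, pwm) {
  s <- as_upper_chr(seq)
  w <- motif_length(pwm)
  n <- nchar(s)
  if (n < w) return(numeric(0))
  codes <- match(strsplit(s, "")[[1]], DNA_BASES)
  n_off <- n - w + 1L
  scores <- numeric(n_off)
  ok <- !logical(n_off)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n_off - 1L)]
    ok <- ok & !is.na(cj)
    scores <- scores + ifelse(is.na(cj), 0, pwm$matrix[cbind(cj, j)])
  }
  scores[!ok] <- NA_real_
  scores
}

#' Scan a sequence for strong PWM matches on both strands
#'
#' Slides the PWM over the sequence and its reverse complement; emits
#' offsets whose score exceeds `threshold` as a fraction of the maximum
#' achievable score (strictly greater, per the "strong match" definition).
#' Windows containing `N` are skipped. Reverse-strand hits are reported at
#' their forward-strand start so that both strands share one coordinate
#' system.
#'
#' @param seq Nucleotide sequence (character or DNAString).
#' @param pwm A `motif_pwm` from [build_pwm()].
#' @param threshold Score fraction cutoff (default 0.85).
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @param seq_id Optional sequence identifier carried into the result.
#' @return data.frame of hits: `seq_id`, `offset` (1-based forward-strand
#'   start), `strand`, `score`, `score_fraction`.
#' @export
scan_sequence <- function(seq, pwm, threshold = 0.85, both_strands = TRUE,
                          seq_id = NA_character_) {
  s <- as_upper_chr(seq)
  w <- motif_length(pwm)
  n <- nchar(s)
  hits <- list()
  fwd <- pwm_scores_forward(s, pwm)
  keep <- which(!is.na(fwd) & fwd / pwm$max_score > threshold)
  if (length(keep) > 0L) {
    hits$fwd <- data.frame(seq_id = seq_id, offset = keep, strand = "+",
                           score = fwd[keep],
                           score_fraction = fwd[keep] / pwm$max_score,
                           stringsAsFactors = FALSE)
  }
  if (both_strands) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    rev <- pwm_scores_forward(rc, pwm)
    keep <- which(!is.na(rev) & rev / pwm$max_score > threshold)
    if (length(keep) > 0L) {
      hits$rev <- data.frame(seq_id = seq_id,
                             offset = n - (keep + w - 1L) + 1L,
                             strand = "-", score = rev[keep],
                             score_fraction = rev[keep] / pwm$max_score,
                             stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(seq_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      score_fraction = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, hits)
  res <- res[order(res$offset, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Motif hit density of a sequence
#' @param seq Nucleotide sequence.
#' @param pwm A `motif_pwm`.
#' @param threshold Score-fraction cutoff (default 0.85).
#' @return Hits per kilobase.
#' @export
motif_density <- function(seq, pwm, threshold = 0.85) {
  n_hits <- nrow(scan_sequence(seq, pwm, threshold))
  n_hits / (nchar(as_upper_chr(seq)) / 1000)
}

#' Sample background sequences of comparable length from a genome
#'
#' Draws `n` intervals: a chromosome is chosen with probability
#' proportional to its length, the start uniformly, and the interval
#' length with replacement from the supplied empirical `lengths`. Samples
#' whose fraction of `N` exceeds `max_n_frac` are redrawn.
#'
#' @param genome DNAStringSet.
#' @param lengths Empirical lengths of the query elements.
#' @param n Number of background sequences (default 10000).
#' @param seed Integer RNG seed.
#' @param max_n_frac Maximum tolerated fraction of `N` (default 0.1).
#' @return DNAStringSet named `chrom:start-end`.
#' @export
sample_background <- function(genome, lengths, n = 10000, seed,
                              max_n_frac = 0.1) {
  assert_that(!missing(seed) && is.finite(seed), "an RNG seed is required")
  clen <- genome_lengths(genome)
  lengths <- lengths[lengths <= max(clen)]
  assert_that(length(lengths) > 0L, "no feasible background length")
  set.seed(as.integer(seed))
  seqs <- character(n)
  ids <- character(n)
  for (k in seq_len(n)) {
    repeat {
      len <- sample(lengths, 1)
      feas <- clen >= len
      chrom <- sample(names(clen)[feas], 1,
                      prob = as.numeric(clen[feas]))
      start <- sample.int(clen[[chrom]] - len + 1L, 1)
      s <- as.character(Biostrings::subseq(genome[[chrom]], start,
                                           start + len - 1L))
      n_frac <- sum(strsplit(s, "")[[1]] == "N") / len
      if (n_frac <= max_n_frac) break
    }
    seqs[k] <- s
    ids[k] <- sprintf("%s:%d-%d", chrom, start, start + len - 1L)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Poisson enrichment test of motifs in breakpoint clusters
#'
#' Counts motif hits whose start falls within any breakpoint cluster
#' extended by `flank` bases on each side (clipped to the sequence and
#' merged where extended clusters overlap), compares the total against a
#' background hit rate with a one-sided ("greater") exact Poisson test.
#'
#' @param element_seqs Named list/DNAStringSet of element sequences.
#' @param clusters data.frame with `seq_id`, `start`, `end` (element-local,
#'   1-based) breakpoint-cluster intervals.
#' @param pwm A `motif_pwm`.
#' @param background_rate Background motif rate in hits per base.
#' @param threshold Score-fraction cutoff (default 0.85).
#' @param flank Flanking bases added to each cluster side (default 500).
#' @return An `enrichment_report` list: `observed`, `expected`,
#'   `interrogated_bases`, `test`, `p_value`, `background_rate`.
#' @export
cluster_enrichment <- function(element_seqs, clusters, pwm, background_rate,
                               threshold = 0.85, flank = 500) {
  assert_that(background_rate >= 0, "background_rate must be >= 0")
  observed <- 0L
  interrogated <- 0
  for (id in unique(clusters$seq_id)) {
    seq <- as_upper_chr(element_seqs[[id]])
    assert_that(nchar(seq) > 0, "cluster names an unknown sequence: %s", id)
    cl <- clusters[clusters$seq_id == id, , drop = FALSE]
    ext <- IRanges::reduce(IRanges::IRanges(
      pmax(cl$start - flank, 1L), pmin(cl$end + flank, nchar(seq))))
    interrogated <- interrogated + sum(IRanges::width(ext))
    hits <- scan_sequence(seq, pwm, threshold, seq_id = id)
    if (nrow(hits) > 0L) {
      inside <- vapply(hits$offset, function(o) {
        any(o >= IRanges::start(ext) & o <= IRanges::end(ext))
      }, logical(1))
      observed <- observed + sum(inside)
    }
  }
  expected <- background_rate * interrogated
  p <- poisson.test(observed, r = max(expected, .Machine$double.eps),
                    alternative = "greater")$p.value
  structure(list(observed = observed, expected = expected,
                 interrogated_bases = interrogated,
                 test = "one-sided exact Poisson",
                 p_value = p, background_rate = background_rate),
            class = "enrichment_report")
}

#' Compare per-element motif densities against a reference
#'
#' Mode `"one-sample"`: Wilcoxon signed-rank test of the element densities
#' against a scalar genome-wide average density. Mode `"two-sample"`:
#' rank-sum comparison against the density list of a reference element set
#' (e.g. the other HERV-H elements with intact LTRs). Exact and
#' normal-approximation variants are both available because the published
#' convention is not recoverable; `exact = NA` lets `wilcox.test` choose.
#'
#' @param densities Numeric densities of the query elements (hits/kb).
#' @param reference Scalar (one-sample) or numeric vector (two-sample).
#' @param mode `"one-sample"` or `"two-sample"`.
#' @param alternative Test sidedness (default `"greater"` for enrichment).
#' @param exact Passed to [stats::wilcox.test()].
#' @return An `enrichment_report` list with the p-value and test label.
#' @export
density_comparison <- function(densities,
                               reference,
                               mode = c("one-sample", "two-sample"),
                               alternative = "greater", exact = NA) {
  mode <- match.arg(mode)
  exact_arg <- if (is.na(exact)) NULL else exact
  if (mode == "one-sample") {
    assert_that(length(reference) == 1L,
                "one-sample mode needs a scalar reference")
    if (all(densities == reference)) {
      p <- 1
      test <- "Wilcoxon signed rank (degenerate: all differences zero)"
    } else {
      ht <- suppressWarnings(wilcox.test(
        densities, mu = reference, alternative = alternative,
        exact = exact_arg))
      p <- ht$p.value
      test <- "Wilcoxon signed rank"
    }
  } else {
    ht <- suppressWarnings(wilcox.test(densities, reference,
                                       alternative = alternative,
                                       exact = exact_arg))
    p <- ht$p.value
    test <- "Wilcoxon rank sum"
  }
  structure(list(observed = mean(densities),
                 expected = mean(reference),
                 test = test, p_value = p,
                 n = length(densities)),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("%s: observed %.4g vs expected %.4g, P = %.3g\n",
              x$test, x$observed, x$expected, x$p_value))
  invisible(x)
}
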