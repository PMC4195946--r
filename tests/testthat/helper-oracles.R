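# Independent oracles used by the test suite. These deliberately share no
# code with the package implementation: brute-force dynamic programming,
# sweep-line interval merging, O(n^2) pair enumeration and per-offset PWM
# rescoring.

# --- affine-gap Smith-Waterman, score only (row-vectorized quadratic DP) ---
sw_score_oracle <- function(a, b, sc = scoring_scheme()) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  m <- length(A); n <- length(B)
  go <- sc$gap_open; ge <- sc$gap_extend
  NEG <- -1e9
  Mp <- rep(NEG, n); Xp <- rep(NEG, n); Yp <- rep(NEG, n)
  best <- 0
  j_seq <- seq_len(n)
  for (i in seq_len(m)) {
    sub <- ifelse(A[i] == B & A[i] != "N", sc$match, sc$mismatch)
    prev <- pmax(0, c(0, Mp[-n]), c(NEG, Xp[-n]), c(NEG, Yp[-n]))
    Mi <- sub + prev
    Xi <- pmax(Mp + go + ge, Xp + ge)
    t <- Mi - j_seq * ge
    ct <- cummax(t)
    Yi <- c(NEG, go + ge * j_seq[-1] + ct[-n])
    best <- max(best, Mi)
    Mp <- Mi; Xp <- Xi; Yp <- Yi
  }
  best
}

# --- affine-gap Smith-Waterman with traceback (scalar quadratic DP) ---
# Tie-break: diagonal, then gap-in-b, then gap-in-a, then fresh start.
sw_full_oracle <- function(a, b, sc = scoring_scheme()) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  m <- length(A); n <- length(B)
  go <- sc$gap_open; ge <- sc$gap_extend
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  for (i in 1:m) {
    for (j in 1:n) {
      s <- if (A[i] == B[j] && A[i] != "N") sc$match else sc$mismatch
      M[i + 1, j + 1] <- s + max(0, M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] + go + ge, X[i, j + 1] + ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + go + ge, Y[i + 1, j] + ge)
    }
  }
  best <- max(0, M)
  if (best == 0) {
    return(list(score = 0, identity = NaN, aln_length = 0L))
  }
  hit <- which(M == best, arr.ind = TRUE)[1, ]
  i <- hit[1] - 1L; j <- hit[2] - 1L
  state <- "M"
  cols_a <- character(0); cols_b <- character(0)
  repeat {
    if (state == "M") {
      cols_a <- c(A[i], cols_a); cols_b <- c(B[j], cols_b)
      s <- if (A[i] == B[j] && A[i] != "N") sc$match else sc$mismatch
      need <- M[i + 1, j + 1] - s
      i <- i - 1L; j <- j - 1L
      # border cells hold a large negative sentinel, so when i or j reaches
      # 0 none of these match and the fresh-start branch fires
      state <- if (need == M[i + 1, j + 1]) "M"
      else if (need == X[i + 1, j + 1]) "X"
      else if (need == Y[i + 1, j + 1]) "Y"
      else break  # need == 0: fresh start
    } else if (state == "X") {
      cols_a <- c(A[i], cols_a); cols_b <- c("-", cols_b)
      val <- X[i + 1, j + 1]
      i <- i - 1L
      state <- if (val == M[i + 1, j + 1] + go + ge) "M" else "X"
    } else {
      cols_a <- c("-", cols_a); cols_b <- c(B[j], cols_b)
      val <- Y[i + 1, j + 1]
      j <- j - 1L
      state <- if (val == M[i + 1, j + 1] + go + ge) "M" else "Y"
    }
  }
  ident <- sum(cols_a == cols_b & cols_a != "-" & cols_a != "N")
  list(score = best, identity = ident / length(cols_a),
       aln_length = length(cols_a),
       aligned_a = paste(cols_a, collapse = ""),
       aligned_b = paste(cols_b, collapse = ""))
}

# Re-score a gapped alignment under the affine scheme (validity check for
# implementation output).
score_gapped_oracle <- function(aligned_a, aligned_b, sc = scoring_scheme()) {
  a <- strsplit(aligned_a, "")[[1]]; b <- strsplit(aligned_b, "")[[1]]
  gap_a <- a == "-"; gap_b <- b == "-"
  matches <- sum(!gap_a & !gap_b & a == b & a != "N")
  mism <- sum(!gap_a & !gap_b & (a != b | a == "N"))
  n_open <- sum(rle(gap_a)$values) + sum(rle(gap_b)$values)
  n_gap <- sum(gap_a) + sum(gap_b)
  matches * sc$match + mism * sc$mismatch + n_open * sc$gap_open +
    n_gap * sc$gap_extend
}

# --- sweep-line interval merge (>= 1 bp overlap, 1-based inclusive) ---
merge_oracle <- function(spans) {
  out <- list()
  for (ch in sort(unique(spans$chrom))) {
    s <- spans[spans$chrom == ch, , drop = FALSE]
    s <- s[order(s$start, s$end), , drop = FALSE]
    cur_s <- s$start[1]; cur_e <- s$end[1]
    for (k in seq_len(nrow(s))[-1]) {
      if (s$start[k] <= cur_e) {  # true overlap (bookended would be cur_e+1)
        cur_e <- max(cur_e, s$end[k])
      } else {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cur_s,
                                              end = cur_e)
        cur_s <- s$start[k]; cur_e <- s$end[k]
      }
    }
    out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cur_s,
                                          end = cur_e)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# --- O(n^2) candidate pair enumeration ---
pairs_oracle <- function(elements, min_sep = 10000, max_sep = 10000000) {
  found <- list()
  n <- nrow(elements)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- elements[i, ]; b <- elements[j, ]
    if (a$start > b$start) next
    if (a$start == b$start && i > j) next
    sep <- b$start - a$end - 1L
    if (a$chrom == b$chrom && a$strand == b$strand &&
        sep >= min_sep && sep <= max_sep) {
      found[[length(found) + 1L]] <-
        data.frame(chrom = a$chrom, a_start = a$start, b_start = b$start)
    }
  }
  if (length(found) == 0L) return(NULL)
  res <- unique(do.call(rbind, found))
  res[order(res$chrom, res$a_start, res$b_start), , drop = FALSE]
}

# --- per-offset PWM rescoring on both strands ---
revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

pwm_rescan_oracle <- function(seq, pwm, threshold = 0.85) {
  score_at <- function(s, o, w) {
    chars <- strsplit(substr(s, o, o + w - 1L), "")[[1]]
    if (any(!chars %in% c("A", "C", "G", "T"))) return(NA_real_)
    sum(vapply(seq_len(w),
               function(j) pwm$matrix[chars[j], j], numeric(1)))
  }
  s <- toupper(seq)
  w <- ncol(pwm$matrix)
  n <- nchar(s)
  rc <- revcomp_chr(s)
  hits <- list()
  for (o in seq_len(max(n - w + 1L, 0L))) {
    sc <- score_at(s, o, w)
    if (!is.na(sc) && sc / pwm$max_score > threshold) {
      hits[[length(hits) + 1L]] <- data.frame(offset = o, strand = "+",
                                              score = sc)
    }
    sc <- score_at(rc, o, w)
    if (!is.na(sc) && sc / pwm$max_score > threshold) {
      hits[[length(hits) + 1L]] <- data.frame(offset = n - (o + w - 1L) + 1L,
                                              strand = "-", score = sc)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  }
  res <- do.call(rbind, hits)
  res <- res[order(res$offset, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# --- shared fixtures ---
random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a small diverged pair with its planted alignment, fast enough for reuse
fixture_pair <- function(seed = 7, len = 3000, divergence = 0.03) {
  set.seed(seed)
  make_element_pair(random_seq(len), divergence)
}
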