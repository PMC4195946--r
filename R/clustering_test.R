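# Monte-Carlo test of breakpoint clustering within an aligned HERV pair,
# conditioned on local sequence identity: observed statistic is the median
# pairwise distance between proximal cis-morphisms of the observed
# breakpoints; the null resamples equally sized position sets from
# identity-eligible columns and maps each to its next most proximal
# cis-morphism.

#' Median all-pairs distance between breakpoint positions
#'
#' @param positions Numeric vector of >= 2 positions (alignment columns or
#'   coordinates of the proximal cis-morphisms of observed breakpoints).
#' @return The median of the `choose(n, 2)` pairwise absolute distances,
#'   with attribute `n_pairs`.
#' @export
observed_statistic <- function(positions) {
  assert_that(length(positions) >= 2L, "need at least 2 breakpoints")
  d <- as.numeric(stats::dist(matrix(positions, ncol = 1)))
  structure(median(d), n_pairs = length(d))
}

#' Alignment columns eligible for null breakpoint placement
#'
#' Columns whose 50-bp windowed identity is at least `min_identity`. When
#' `min_identity` is omitted, it defaults to the minimum windowed identity
#' observed at the supplied breakpoint columns (the conditioning used in
#' the original analysis, e.g. >= 92.1% at the 3q13.2q13.31 locus).
#'
#' @param alignment A `herv_alignment`.
#' @param min_identity Identity threshold in \[0, 1\], or `NULL` to derive
#'   it from `breakpoints`.
#' @param window Identity window in columns (default 50).
#' @param breakpoints Observed breakpoint columns (required when
#'   `min_identity` is `NULL`).
#' @return Integer vector of eligible alignment columns.
#' @export
eligible_positions <- function(alignment, min_identity = NULL, window = 50,
                               breakpoints = NULL) {
  prof <- windowed_identity(alignment, window)
  if (is.null(min_identity)) {
    assert_that(!is.null(breakpoints) && length(breakpoints) > 0L,
                "supply min_identity or observed breakpoints")
    min_identity <- min(prof[breakpoints])
  }
  which(prof >= min_identity)
}

#' Monte-Carlo null distribution of the clustering statistic
#'
#' For each of `n_sets` draws: sample `n_breakpoints` positions (without
#' replacement) uniformly from the eligible columns, map each to the
#' nearest cis-morphism at or upstream of it (the "next most proximal"
#' cis-morphism), and record the median all-pairs distance between the
#' selected cis-morphisms.
#'
#' Eligible positions upstream of the first cis-morphism have no proximal
#' cis-morphism and are excluded from sampling.
#'
#' @param alignment A `herv_alignment`.
#' @param n_breakpoints Number of breakpoints per simulated set.
#' @param n_sets Number of simulated sets (default 10000).
#' @param min_identity Identity threshold for eligibility (see
#'   [eligible_positions()]).
#' @param seed Integer RNG seed (required; logged in the result).
#' @param window Identity window (default 50).
#' @param cis_positions Optional precomputed cis-morphism columns;
#'   defaults to `find_cis_morphisms(alignment)$column`.
#' @param eligible Optional precomputed eligible columns.
#' @return Numeric vector of `n_sets` null statistics.
#' @export
mc_null <- function(alignment, n_breakpoints, n_sets = 10000,
                    min_identity = NULL, seed, window = 50,
                    cis_positions = NULL, eligible = NULL) {
  assert_that(!missing(seed) && is.finite(seed), "an RNG seed is required")
  if (is.null(cis_positions)) {
    cis_positions <- find_cis_morphisms(alignment)$column
  }
  assert_that(length(cis_positions) > 0L, "alignment has no cis-morphisms")
  cis_positions <- sort(cis_positions)
  if (is.null(eligible)) {
    eligible <- eligible_positions(alignment, min_identity, window)
  }
  eligible <- eligible[eligible >= cis_positions[1]]
  assert_that(length(eligible) >= n_breakpoints,
              "fewer eligible positions (%d) than breakpoints (%d)",
              length(eligible), n_breakpoints)
  set.seed(as.integer(seed))
  pair_i <- utils::combn(n_breakpoints, 2)
  vapply(seq_len(n_sets), function(s) {
    pos <- sample(eligible, n_breakpoints, replace = FALSE)
    mapped <- cis_positions[findInterval(pos, cis_positions)]
    median(abs(mapped[pair_i[1, ]] - mapped[pair_i[2, ]]))
  }, numeric(1))
}

#' Lower-tail Monte-Carlo p-value
#'
#' Clustering means a small median pairwise distance, so the p-value is the
#' lower-tail probability with the standard add-one correction:
#' `(1 + #\{null <= observed\}) / (1 + n_sets)`. Never zero.
#'
#' @param observed Observed statistic.
#' @param null_samples Null statistics from [mc_null()].
#' @return Empirical p-value in (0, 1].
#' @export
empirical_p <- function(observed, null_samples) {
  (1 + sum(null_samples <= observed)) / (1 + length(null_samples))
}

#' Full breakpoint clustering test
#'
#' @param alignment A `herv_alignment`.
#' @param breakpoint_columns Alignment columns of the observed proximal
#'   cis-morphisms (>= 2).
#' @param n_sets Number of Monte-Carlo sets (default 10000).
#' @param seed Integer RNG seed.
#' @param min_identity Identity threshold; defaults to the minimum windowed
#'   identity at the observed breakpoints.
#' @param window Identity window (default 50).
#' @return A `clustering_result` list: `observed_statistic`,
#'   `null_samples`, `n_sets`, `empirical_p`, `min_identity_used`,
#'   `rng_seed`, `n_breakpoints`.
#' @export
cluster_breakpoints <- function(alignment, breakpoint_columns,
                                n_sets = 10000, seed, min_identity = NULL,
                                window = 50) {
  assert_that(length(breakpoint_columns) >= 2L,
              "need at least 2 observed breakpoints")
  prof <- windowed_identity(alignment, window)
  if (is.null(min_identity)) min_identity <- min(prof[breakpoint_columns])
  obs <- observed_statistic(breakpoint_columns)
  nulls <- mc_null(alignment, length(breakpoint_columns), n_sets,
                   min_identity, seed, window)
  structure(list(
    observed_statistic = as.numeric(obs),
    n_pairs = attr(obs, "n_pairs"),
    null_samples = nulls,
    n_sets = n_sets,
    empirical_p = empirical_p(as.numeric(obs), nulls),
    min_identity_used = min_identity,
    rng_seed = as.integer(seed),
    n_breakpoints = length(breakpoint_columns)
  ), class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf(
    "Breakpoint clustering: %d breakpoints (%d pairs), observed median distance %.1f\n  %d Monte-Carlo sets (seed %d, identity >= %.3f): P = %.3g\n",
    x$n_breakpoints, x$n_pairs, x$observed_statistic, x$n_sets, x$rng_seed,
    x$min_identity_used, x$empirical_p))
  invisible(x)
}
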