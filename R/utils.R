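#' @keywords internal
"_PACKAGE"

#' @importFrom stats median ppois rgeom runif setNames wilcox.test poisson.test
#' @importFrom utils read.delim write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_fmt(...)
  invisible(TRUE)
}

# 1-based inclusive interval overlap (>= 1 bp)
overlaps1 <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

#' Convert between internal 1-based inclusive and BED 0-based half-open starts
#'
#' Internal coordinates follow the Bioconductor convention (1-based,
#' inclusive); BED output is 0-based half-open. The conversion is bijective.
#' @param start 1-based start positions.
#' @return 0-based starts.
#' @keywords internal
to_bed_start <- function(start) as.integer(start) - 1L

as_upper_chr <- function(seq) {
  if (methods::is(seq, "DNAString") || methods::is(seq, "DNAStringSet")) {
    seq <- as.character(seq)
  }
  toupper(seq)
}
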