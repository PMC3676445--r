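#' Round half-up
#'
#' Decimal rounding where ties go away from zero (the convention used by the
#' percentage columns of alignment-summary tables), unlike [round()] which
#' rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, halves rounded up.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # small relative nudge so values that are exactly *.5 up to float error
  # (e.g. 100*count/total) land on the intended side
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' @noRd
logsumexp <- function(lx) {
  if (length(lx) == 0L) return(-Inf)
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

# 0-based half-open intervals -> IRanges (1-based closed) for overlap work
#' @noRd
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# overlap hits between two sets of 0-based half-open intervals on one chromosome;
# returns a data.frame(query, subject) of index pairs with >=1 bp overlap
#' @noRd
overlap_hits0 <- function(qstart, qend, sstart, send) {
  if (length(qstart) == 0L || length(sstart) == 0L) {
    return(data.frame(query = integer(0), subject = integer(0)))
  }
  hits <- IRanges::findOverlaps(as_iranges0(qstart, qend),
                                as_iranges0(sstart, send))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

# merge possibly-overlapping 0-based half-open intervals into a disjoint union
#' @noRd
reduce_intervals0 <- function(start, end) {
  if (length(start) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  r <- IRanges::reduce(as_iranges0(start, end))
  data.frame(start = IRanges::start(r) - 1L, end = IRanges::end(r))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
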