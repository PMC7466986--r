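## Small shared helpers. Internal coordinates throughout the package are
## 0-based half-open; conversion to 1-based report/Biostrings coordinates
## happens only at the edges (see toReportCoords/fromReportCoords).

#' Convert internal 0-based half-open coordinates to 1-based report coordinates
#'
#' Internal intervals `[start, end)` become 1-based `start + 1` with the same
#' width. The inverse is [fromReportCoords()].
#'
#' @param start,end numeric vectors of 0-based half-open interval bounds.
#' @return data.frame with 1-based inclusive `start` and `end`.
#' @export
#' @examples
#' toReportCoords(0, 10) # 1..10
toReportCoords <- function(start, end) {
    stopifnot(all(end > start))
    data.frame(start = start + 1, end = end)
}

#' Convert 1-based inclusive coordinates back to 0-based half-open
#'
#' @param start,end numeric vectors of 1-based inclusive interval bounds.
#' @return data.frame with 0-based half-open `start` and `end`.
#' @export
fromReportCoords <- function(start, end) {
    stopifnot(all(end >= start))
    data.frame(start = start - 1, end = end)
}

## chromosome naming used by the simulator: LG01..LGnn
lgName <- function(i) sprintf("LG%02d", as.integer(i))

## reverse complement on plain character vectors
revcompChar <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Hamming identity between equal-length strings
hammingIdentity <- function(a, b) {
    stopifnot(nchar(a) == nchar(b))
    if (nchar(a) == 0L) return(NA_real_)
    av <- charToRaw(a)
    bv <- charToRaw(b)
    sum(av == bv) / length(av)
}

## AT fraction of a sequence string
atFractionOf <- function(x) {
    n <- nchar(x)
    if (n == 0L) return(NA_real_)
    v <- charToRaw(x)
    sum(v == charToRaw("A") | v == charToRaw("T")) / n
}

## draw a fixed-composition random sequence: exactly round(at * n) A/T bases
## (positions and purine/pyrimidine choice random), guaranteeing the realized
## AT fraction rather than only its expectation
randomSeqExactAT <- function(n, at) {
    nAT <- round(at * n)
    bases <- c(sample(c("A", "T"), nAT, replace = TRUE),
               sample(c("C", "G"), n - nAT, replace = TRUE))
    paste(sample(bases), collapse = "")
}

## deterministic sub-seed derivation, kept below 2^31
subSeed <- function(seed, offset) {
    (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483647L
}
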