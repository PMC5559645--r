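#' @useDynLib phyloCCF, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical 96 trinucleotide substitution channels
#'
#' Returns the 96 channel labels in the COSMIC convention: six pyrimidine
#' substitution classes (C>A, C>G, C>T, T>A, T>C, T>G), each expanded over
#' the 16 flanking-base contexts with the 5' base as the outer index and the
#' 3' base as the inner index (both ordered A, C, G, T).
#'
#' @return Character vector of length 96, e.g. \code{"A[C>A]A"}.
#' @export
#' @examples
#' head(channelNames())
channelNames <- function() {
    subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
    bases <- c("A", "C", "G", "T")
    unlist(lapply(subs, function(s) {
        as.vector(t(outer(bases, bases, function(p5, p3) {
            paste0(p5, "[", s, "]", p3)
        })))
    }))
}

#' Collapse a substitution to its pyrimidine-reference channel
#'
#' Substitutions reported on the purine strand are reverse-complemented so
#' that the reference base is a pyrimidine, following the COSMIC convention
#' for 96-channel spectra.
#'
#' @param ref,alt Single reference/alternate bases.
#' @param fiveprime,threeprime Flanking bases on the reported strand.
#' @return Channel label, e.g. \code{"T[C>T]G"}.
#' @export
pyrimidineChannel <- function(ref, alt, fiveprime, threeprime) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    flip <- ref %in% c("A", "G")
    r <- ifelse(flip, comp[ref], ref)
    a <- ifelse(flip, comp[alt], alt)
    p5 <- ifelse(flip, comp[threeprime], fiveprime)
    p3 <- ifelse(flip, comp[fiveprime], threeprime)
    paste0(p5, "[", r, ">", a, "]", p3)
}

## 1-based mutation position <-> 0-based half-open segment interval.
## A mutation at 1-based pos lies in segment [start0, end0) iff
## start0 < pos <= end0, i.e. zero-based index pos-1 in [start0, end0).
posInSegment <- function(pos, start0, end0) {
    (pos - 1L) >= start0 & (pos - 1L) < end0
}

logSumExp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
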