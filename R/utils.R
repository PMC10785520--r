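## Coordinate helpers and seed plumbing.

#' BED-convention coordinates of a GRanges
#'
#' The package stores ranges 1-based closed (GRanges convention) and
#' converts to the BED convention (0-based half-open) at file boundaries
#' and wherever an arithmetic rule is defined on BED coordinates.
#'
#' @param gr a \code{GRanges}.
#' @return integer vector of 0-based starts (\code{bedStart0}) or
#'   exclusive ends (\code{bedEnd0}).
#' @export
bedStart0 <- function(gr) GenomicRanges::start(gr) - 1L

#' @rdname bedStart0
#' @export
bedEnd0 <- function(gr) GenomicRanges::end(gr)

#' Peak center (BED coordinates)
#'
#' \code{floor((start + end) / 2)} on BED coordinates; the anchor position
#' used for genomic distance and for bin assignment.
#'
#' @param gr a \code{GRanges}.
#' @return integer vector of 0-based center positions.
#' @export
peakCenter0 <- function(gr) {
    (bedStart0(gr) + bedEnd0(gr)) %/% 2L
}

## GRanges from BED fields (0-based half-open in, 1-based closed out).
grFromBed <- function(chrom, start0, end0, ...) {
    GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = as.integer(start0) + 1L,
                         end = as.integer(end0)), ...)
}

## Midpoint positions of ranges as width-1 GRanges, for the
## midpoint-containment rules (reads in peaks, motifs in peaks).
midpointRanges <- function(gr) {
    c0 <- peakCenter0(gr)
    GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
        IRanges::IRanges(start = c0 + 1L, width = 1L))
}

#' Derive a component seed from a base seed
#'
#' All randomness in the simulator and the evaluation procedures flows
#' from one base seed through named substreams, so each component can be
#' regenerated in isolation.  The derived seed is a deterministic hash of
#' the base seed and the stream name, kept within the 32-bit integer
#' range.
#'
#' @param seed base integer seed.
#' @param name substream name.
#' @return an integer seed.
#' @export
subSeed <- function(seed, name) {
    h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
    as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
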