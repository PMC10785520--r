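## The six model inputs, computed per anchor pair:
##   1. linear genomic distance between peak centers (kb)
##   2. RAD21 ChIP-Seq signal at both anchors (per-chromosome RPKM)
##   3. H3K27ac RPKM at both anchors
##   4. H3K27me3 RPKM at both anchors
##   5. GC percentage of both anchors
##   6. CTCF motif convergence flag (1 = convergent, 0 otherwise)

#' Genomic distance between two peaks, in kilobases
#'
#' Absolute distance between the peak centers, where the center is
#' \code{floor((start + end) / 2)} on BED coordinates.  Vectorized over
#' parallel \code{GRanges}.
#'
#' @param p1,p2 parallel \code{GRanges} on the same chromosomes.
#' @return numeric vector of distances in kb (>= 0).
#' @examples
#' p1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2000))
#' p2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(99001, 101000))
#' genomicDistanceKb(p1, p2)  # 99
#' @export
genomicDistanceKb <- function(p1, p2) {
    if (!all(as.character(GenomicRanges::seqnames(p1)) ==
             as.character(GenomicRanges::seqnames(p2))))
        stop("peaks must be on the same chromosome")
    abs(peakCenter0(p1) - peakCenter0(p2)) / 1000
}

#' Count reads whose midpoint falls inside each peak
#'
#' A read is assigned to a peak when its midpoint lies in the half-open
#' peak interval \code{[start, end)} (BED coordinates).  The midpoint rule
#' is symmetric in read orientation and robust to fragment length.
#' Chromosomes absent from the track contribute zero counts, with a
#' warning.
#'
#' @param track a \link{ReadTrack}.
#' @param peaks \code{GRanges} of peaks.
#' @return integer vector of counts, parallel to \code{peaks}.
#' @export
countReadsInPeaks <- function(track, peaks) {
    if (!length(peaks)) return(integer())
    trackChroms <- names(chromTotals(track))
    missing <- setdiff(unique(as.character(GenomicRanges::seqnames(peaks))),
                       trackChroms)
    if (length(missing))
        warning(sprintf("chromosome(s) %s absent from read track; counts 0",
                        paste(missing, collapse = ", ")))
    mids <- midpointRanges(reads(track))
    GenomicRanges::countOverlaps(peaks, mids, ignore.strand = TRUE)
}

#' Per-chromosome RPKM normalization
#'
#' Reads per kilobase per million: the raw count divided by the
#' per-million scaling factor (total reads on the chromosome / 1e6), then
#' by the peak length in kb.  The per-chromosome (rather than
#' genome-wide) library size makes anchors comparable across chromosomes
#' with uneven coverage.
#'
#' @param readCount integer read count(s) in the peak.
#' @param totalChromReads total reads on the peak's chromosome (> 0).
#' @param peakLengthBp peak length in bp (> 0).
#' @param chrom optional chromosome name, used in the error message.
#' @return numeric RPKM.
#' @examples
#' rpkm(200, 5e6, 2000)  # 20
#' @export
rpkm <- function(readCount, totalChromReads, peakLengthBp, chrom = NULL) {
    if (any(totalChromReads <= 0))
        stop(sprintf("zero total reads on chromosome %s",
                     if (is.null(chrom)) "?" else
                         paste(chrom[totalChromReads <= 0], collapse = ",")))
    if (any(peakLengthBp <= 0)) stop("peak length must be positive")
    readCount / (totalChromReads / 1e6) / (peakLengthBp / 1000)
}

#' GC percentage of a DNA sequence
#'
#' 100 * (#G + #C) / length; characters other than A, C, G, T (e.g. N)
#' count in the denominator only.
#'
#' @param sequence character vector of DNA sequences (case-insensitive),
#'   or a \code{DNAStringSet}.
#' @return numeric vector of percentages in [0, 100].
#' @examples
#' gcContentPercent(c("ATGC", "GGCC", "ANGC"))  # 50 100 50
#' @export
gcContentPercent <- function(sequence) {
    if (methods::is(sequence, "XStringSet"))
        sequence <- as.character(sequence)
    if (any(!nzchar(sequence)))
        stop("empty sequence")
    s <- toupper(sequence)
    gc <- vapply(s, function(z) {
        v <- strsplit(z, "", fixed = TRUE)[[1]]
        sum(v == "G" | v == "C")
    }, 1L, USE.NAMES = FALSE)
    100 * gc / nchar(s)
}

## Fast path for many peaks against a genome: Biostrings letter counting.
.gcOfPeaks <- function(genome, peaks) {
    if (!length(peaks)) return(numeric())
    chroms <- as.character(GenomicRanges::seqnames(peaks))
    bad <- !chroms %in% names(genome)
    if (any(bad))
        stop(sprintf("chromosome %s absent from genome", chroms[bad][1]))
    tooLong <- GenomicRanges::end(peaks) >
        Biostrings::width(genome)[match(chroms, names(genome))]
    if (any(tooLong))
        stop("peak extends beyond chromosome sequence length")
    seqs <- Biostrings::DNAStringSet(genome[chroms],
        start = GenomicRanges::start(peaks), end = GenomicRanges::end(peaks))
    counts <- Biostrings::letterFrequency(seqs, letters = c("G", "C"))
    100 * rowSums(counts) / Biostrings::width(seqs)
}

#' Assign the best motif hit to each peak
#'
#' A hit belongs to a peak when the hit midpoint lies within the peak
#' (half-open, BED coordinates).  When several hits fall in one peak, the
#' highest-scoring one is kept, mirroring one-best-hit-per-peak motif
#' scanning output; score ties break deterministically by leftmost start.
#'
#' @param hits \code{GRanges} of motif hits with \code{score} and strand.
#' @param peaks \code{GRanges} of peaks.
#' @return A list with \code{strand} (character, \code{NA} where no hit)
#'   and \code{score} (numeric, \code{NA} where no hit), parallel to
#'   \code{peaks}.
#' @export
assignMotifToPeaks <- function(hits, peaks) {
    n <- length(peaks)
    out <- list(strand = rep(NA_character_, n), score = rep(NA_real_, n))
    if (!length(hits) || !n) return(out)
    mids <- midpointRanges(hits)
    ov <- GenomicRanges::findOverlaps(mids, peaks, ignore.strand = TRUE)
    if (!length(ov)) return(out)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    ## order: by peak, score descending, start ascending -> first per peak
    o <- order(sh, -hits$score[qh], GenomicRanges::start(hits)[qh])
    keep <- o[!duplicated(sh[o])]
    out$strand[sh[keep]] <- as.character(GenomicRanges::strand(hits))[qh[keep]]
    out$score[sh[keep]] <- hits$score[qh[keep]]
    out
}

#' CTCF motif convergence flag
#'
#' 1 if and only if the motif in the leftmost anchor is on the forward
#' strand and the motif in the rightmost anchor on the reverse strand
#' (convergent orientation); divergent, tandem, and absent-in-either-peak
#' configurations all yield 0.
#'
#' @param strandLeft,strandRight motif strands (\code{"+"}, \code{"-"}) of
#'   the leftmost and rightmost anchor, or \code{NA} where no motif.
#' @return integer vector of 0/1 flags.
#' @examples
#' ctcfOrientationFlag("+", "-")   # 1 (convergent)
#' ctcfOrientationFlag("-", "+")   # 0 (divergent)
#' ctcfOrientationFlag(NA, "-")    # 0 (absent in one peak)
#' @export
ctcfOrientationFlag <- function(strandLeft, strandRight) {
    as.integer(!is.na(strandLeft) & !is.na(strandRight) &
               strandLeft == "+" & strandRight == "-")
}

#' Build the model feature matrix for a set of interactions
#'
#' Computes, for every anchor pair, the features named by the schema:
#' center-to-center genomic distance (kb), per-chromosome-RPKM RAD21 /
#' H3K27ac / H3K27me3 signal at both anchors, GC percentage of both
#' anchors, and the CTCF convergence flag.  Rows follow the input
#' interaction order; the target vector is the stored strength.
#'
#' @param loops a \link{LoopSet}.
#' @param tracks named list of \link{ReadTrack}s; needs \code{rad21} and,
#'   for the full schema, \code{h3k27ac} and \code{h3k27me3}.
#' @param genome named \code{DNAStringSet} covering every interaction
#'   chromosome.
#' @param motifs \code{GRanges} of stranded CTCF motif hits with scores.
#' @param schema a \link{featureSchema} (\code{"full"} or
#'   \code{"minimal"}).
#' @return list with feature matrix \code{x} (one row per interaction,
#'   columns per schema) and target vector \code{y}.
#' @export
buildFeatureMatrix <- function(loops, tracks, genome, motifs,
                               schema = featureSchema("full")) {
    a1 <- anchorOne(loops)
    a2 <- anchorTwo(loops)
    n <- length(loops)
    cols <- schemaColumns(schema)

    sig <- function(trackName, anchors) {
        track <- tracks[[trackName]]
        if (is.null(track))
            stop(sprintf("track '%s' required by schema", trackName))
        counts <- countReadsInPeaks(track, anchors)
        tot <- chromTotals(track)[
            as.character(GenomicRanges::seqnames(anchors))]
        rpkm(counts, tot, GenomicRanges::width(anchors),
             chrom = as.character(GenomicRanges::seqnames(anchors)))
    }

    x <- matrix(0, nrow = n, ncol = length(cols),
                dimnames = list(NULL, cols))
    if ("distance_kb" %in% cols)
        x[, "distance_kb"] <- genomicDistanceKb(a1, a2)
    if ("rad21_p1" %in% cols) {
        x[, "rad21_p1"] <- sig("rad21", a1)
        x[, "rad21_p2"] <- sig("rad21", a2)
    }
    if ("h3k27ac_p1" %in% cols) {
        x[, "h3k27ac_p1"] <- sig("h3k27ac", a1)
        x[, "h3k27ac_p2"] <- sig("h3k27ac", a2)
    }
    if ("h3k27me3_p1" %in% cols) {
        x[, "h3k27me3_p1"] <- sig("h3k27me3", a1)
        x[, "h3k27me3_p2"] <- sig("h3k27me3", a2)
    }
    if ("gc_p1" %in% cols) {
        x[, "gc_p1"] <- .gcOfPeaks(genome, a1)
        x[, "gc_p2"] <- .gcOfPeaks(genome, a2)
    }
    if ("ctcf_flag" %in% cols) {
        m1 <- assignMotifToPeaks(motifs, a1)
        m2 <- assignMotifToPeaks(motifs, a2)
        x[, "ctcf_flag"] <- ctcfOrientationFlag(m1$strand, m2$strand)
    }
    list(x = x, y = strength(loops))
}
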