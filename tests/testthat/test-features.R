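test_that("genomic distance uses floored peak centers in kb", {
    p <- function(s0, e0) GRanges("chr1", IRanges(s0 + 1, e0))
    expect_equal(genomicDistanceKb(p(9000, 11000), p(59000, 61000)), 50)
    expect_equal(genomicDistanceKb(p(100, 2100), p(100, 2100)), 0)
    expect_equal(genomicDistanceKb(p(0, 2000), p(99000, 101000)), 99)
    expect_error(genomicDistanceKb(p(0, 10), GRanges("chr2",
                 IRanges(1, 10))), "same chromosome")
})

test_that("read counting assigns by midpoint with half-open peaks", {
    ## read [100,136) has midpoint 118, inside peak [100,2100)
    trk <- ReadTrack(GRanges("chr1", IRanges(101, 136)))
    peak <- GRanges("chr1", IRanges(101, 2100))
    expect_equal(countReadsInPeaks(trk, peak), 1L)

    ## read midpoint exactly at peak end is outside (half-open rule):
    ## peak [0,100), read [82,118) -> midpoint 100
    trk2 <- ReadTrack(GRanges("chr1", IRanges(83, 118)))
    peak2 <- GRanges("chr1", IRanges(1, 100))
    expect_equal(countReadsInPeaks(trk2, peak2), 0L)

    ## absent chromosome warns and returns 0
    w <- capture_warnings(n <- countReadsInPeaks(trk, GRanges("chrZ",
        IRanges(1, 100))))
    expect_true(any(grepl("absent", w)))
    expect_equal(n, 0L)
})

test_that("uniform reads land in a peak proportionally to its span", {
    ## 1000 uniform reads on a 10 kb chromosome, peak covering 20%
    set.seed(31)
    start0 <- floor(runif(1000, 0, 10000 - 36))
    trk <- ReadTrack(GRanges("chr1", IRanges(start0 + 1, start0 + 36)))
    peak <- GRanges("chr1", IRanges(2001, 4000))
    n <- countReadsInPeaks(trk, peak)
    ## binomial(1000, ~0.2): 4 sd ~ 51
    expect_gt(n, 200 - 51)
    expect_lt(n, 200 + 51)
})

test_that("per-chromosome RPKM follows the two-step scaling", {
    expect_equal(rpkm(200, 5e6, 2000), 20)
    expect_equal(rpkm(0, 5e6, 2000), 0)
    ## doubling the chromosome total halves the value
    expect_equal(rpkm(200, 1e7, 2000), 10)
    ## joint scaling of count and total leaves RPKM unchanged
    expect_equal(rpkm(400, 1e7, 2000), rpkm(200, 5e6, 2000))
    expect_error(rpkm(5, 0, 2000, chrom = "chr7"), "chr7")
})

test_that("GC percentage counts non-ACGT bases in the denominator only", {
    expect_equal(gcContentPercent(c("ATGC", "GGCC", "ANGC")),
                 c(50, 100, 50))
    expect_error(gcContentPercent(""), "empty")
    ## reverse-complement invariance (A<->T, C<->G preserves GC)
    set.seed(8)
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    expect_equal(gcContentPercent(s), gcContentPercent(rc))
})

test_that("motif-to-peak assignment keeps the best-scoring inside hit", {
    peak <- GRanges("chr1", IRanges(1001, 3000))
    hits <- GRanges("chr1", IRanges(c(1101, 1501, 5001), width = 19),
                    strand = c("+", "-", "+"), score = c(5, 9, 99))
    a <- assignMotifToPeaks(hits, peak)
    expect_equal(a$strand, "-")
    expect_equal(a$score, 9)

    ## no hit inside
    far <- GRanges("chr1", IRanges(9001, 9019), strand = "+", score = 3)
    expect_true(is.na(assignMotifToPeaks(far, peak)$strand))

    ## score tie breaks to the leftmost start
    tie <- GRanges("chr1", IRanges(c(1601, 1201), width = 19),
                   strand = c("-", "+"), score = c(7, 7))
    expect_equal(assignMotifToPeaks(tie, peak)$strand, "+")
})

test_that("the convergence flag is 1 only for (+, -) pairs", {
    expect_equal(ctcfOrientationFlag("+", "-"), 1L)
    expect_equal(ctcfOrientationFlag("-", "+"), 0L)
    expect_equal(ctcfOrientationFlag("+", "+"), 0L)
    expect_equal(ctcfOrientationFlag("-", "-"), 0L)
    expect_equal(ctcfOrientationFlag(NA, "-"), 0L)
    expect_equal(ctcfOrientationFlag("+", NA), 0L)
    expect_equal(ctcfOrientationFlag(NA, NA), 0L)
    ## convergence is orientation-specific, not symmetric
    expect_false(ctcfOrientationFlag("+", "-") ==
                 ctcfOrientationFlag("-", "+"))
})

## A fully hand-computable two-interaction fixture: every expected value
## below was derived from the scalar definitions independently of
## buildFeatureMatrix.
.tinyFixture <- function() {
    genome <- Biostrings::DNAStringSet(c(chrT = paste0(
        strrep("ACGT", 1500),   # [0,6000)    GC 50%
        strrep("AAAC", 500),    # [6000,8000) GC 25%
        strrep("ACGT", 500))))  # [8000,10000) GC 50%
    peakA <- GRanges("chrT", IRanges(1, 2000))      # [0,2000)
    peakB <- GRanges("chrT", IRanges(6001, 8000))   # [6000,8000)
    mkTrack <- function(starts0)
        ReadTrack(GRanges("chrT", IRanges(starts0 + 1, starts0 + 36)))
    tracks <- list(
        ## rad21: 3 mids in A, 1 in B, 6 elsewhere -> total 10
        rad21 = mkTrack(c(100, 200, 300, 6500,
                          3000, 3500, 4000, 4500, 5000, 9000)),
        ## h3k27ac: 2 in A, 1 in B, 1 elsewhere -> total 4
        h3k27ac = mkTrack(c(120, 900, 7000, 4200)),
        ## h3k27me3: 1 in A, 0 in B, 1 elsewhere -> total 2
        h3k27me3 = mkTrack(c(150, 4800)))
    motifs <- GRanges("chrT", IRanges(c(501, 701, 6901), width = 19),
                      strand = c("+", "+", "-"), score = c(9, 5, 7))
    loops <- LoopSet(peakA, peakB, strength = 4)
    list(genome = genome, tracks = tracks, motifs = motifs,
         loops = loops, peakA = peakA, peakB = peakB)
}

test_that("the assembled feature matrix matches scalar-op arithmetic", {
    fx <- .tinyFixture()
    fm <- buildFeatureMatrix(fx$loops, fx$tracks, fx$genome, fx$motifs,
                             featureSchema("full"))
    expect_equal(dim(fm$x), c(1L, 10L))
    expect_equal(colnames(fm$x), schemaColumns(featureSchema("full")))
    ## centers 1000 and 7000 -> 6 kb
    ## rad21: 3/(10/1e6)/2 = 150000 ; 1/(10/1e6)/2 = 50000
    ## h3k27ac: 2/(4/1e6)/2 = 250000 ; 1/(4/1e6)/2 = 125000
    ## h3k27me3: 1/(2/1e6)/2 = 250000 ; 0
    ## GC: 50 and 25 ; motifs (+ best score 9, -) -> flag 1
    expect_equal(as.numeric(fm$x[1, ]),
                 c(6, 150000, 50000, 250000, 125000, 250000, 0, 50, 25, 1))
    expect_equal(fm$y, 4)

    fmMin <- buildFeatureMatrix(fx$loops, fx$tracks, fx$genome, fx$motifs,
                                featureSchema("minimal"))
    expect_equal(dim(fmMin$x), c(1L, 6L))
    expect_false(any(grepl("h3k27", colnames(fmMin$x))))
    expect_equal(fmMin$x[1, ],
                 fm$x[1, schemaColumns(featureSchema("minimal"))])
})

test_that("feature rows follow interaction order and anchors are bounded", {
    fx <- .tinyFixture()
    two <- LoopSet(c(fx$peakA, fx$peakB), c(fx$peakB, fx$peakA),
                   strength = c(4, 9))
    fm <- buildFeatureMatrix(two, fx$tracks, fx$genome, fx$motifs,
                             featureSchema("full"))
    ## both records normalize to the same leftmost-first pair
    expect_equal(fm$x[1, ], fm$x[2, ])
    expect_equal(fm$y, c(4, 9))

    beyond <- LoopSet(fx$peakA, GRanges("chrT", IRanges(9501, 11500)),
                      strength = 1)
    expect_error(buildFeatureMatrix(beyond, fx$tracks, fx$genome,
                                    fx$motifs, featureSchema("full")),
                 "beyond chromosome")
})
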