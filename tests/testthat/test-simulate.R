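test_that("the simulated genome is reproducible with block-wise GC", {
    cfg <- simConfig(nChromosomes = 1L, chromLengthBp = 500000L, seed = 4)
    g1 <- simulateGenome(cfg)
    g2 <- simulateGenome(cfg)
    expect_identical(as.character(g1$genome), as.character(g2$genome))
    expect_equal(Biostrings::width(g1$genome), 500000L)

    ## measured GC of each 100-kb block within 3 points of its target
    for (b in seq_len(nrow(g1$blockGc))) {
        s0 <- g1$blockGc$blockStart0[b]
        seq <- Biostrings::subseq(g1$genome[[1]], s0 + 1,
                                  min(s0 + cfg$gcBlockBp, 500000L))
        gcMeasured <- sum(Biostrings::letterFrequency(
            Biostrings::DNAStringSet(seq), c("G", "C"))) /
            length(seq)
        expect_lt(abs(gcMeasured - g1$blockGc$gcTarget[b]), 0.03)
    }
})

test_that("peaks do not overlap and tracks carry the designed structure", {
    cfg <- simConfig(seed = 6)
    pt <- simulatePeaksAndTracks(cfg)
    ## non-overlapping peaks
    expect_equal(length(GenomicRanges::reduce(pt$peaks)),
                 length(pt$peaks))

    ## in-peak read density about enrichmentFold x background (rad21)
    rd <- reads(pt$tracks$rad21)
    inPeak <- sum(countReadsInPeaks(pt$tracks$rad21, pt$peaks))
    total <- length(rd)
    peakBp <- sum(GenomicRanges::width(pt$peaks))
    genomeBp <- cfg$nChromosomes * cfg$chromLengthBp
    densIn <- inPeak / peakBp
    densOut <- (total - inPeak) / (genomeBp - peakBp)
    expect_gt(densIn / densOut, cfg$enrichmentFold * 0.7)
    expect_lt(densIn / densOut, cfg$enrichmentFold * 1.3)

    ## active and repressive marks anti-correlated across peaks
    ac <- countReadsInPeaks(pt$tracks$h3k27ac, pt$peaks)
    me <- countReadsInPeaks(pt$tracks$h3k27me3, pt$peaks)
    expect_lt(cor(ac, me), 0)

    ## motif strand frequency near the configured probability
    strands <- as.character(strand(pt$motifs))
    nm <- length(strands)
    phat <- mean(strands == "+")
    expect_lt(abs(phat - cfg$motifPlusProb),
              4 * sqrt(0.25 / nm) + 0.01)

    ## infeasible peak packing errors out
    expect_error(simulatePeaksAndTracks(
        simConfig(nPeaksPerChrom = 900L, peakLengthBp = 3000L,
                  chromLengthBp = 2000000L)), "cannot fit")
})

test_that("interaction strengths decay with distance and are seeded", {
    ## distance-only configuration
    cfg <- simConfig(beta = 0, gamma = 0, nInteractions = 5000L, seed = 2)
    sim <- simulateDataset(cfg)
    d <- sim$truth$distanceKb
    s <- sim$truth$strength
    dec <- cut(d, quantile(d, probs = seq(0, 1, 0.1)),
               include.lowest = TRUE, labels = FALSE)
    means <- tapply(s, dec, mean)
    expect_gt(means[[1]], means[[10]])
    expect_gt(means[[1]], 3 * means[[10]])

    sim2 <- simulateDataset(cfg)
    expect_identical(sim$truth, sim2$truth)
    expect_true(all(strength(sim$loops) >= 0))
    expect_true(validObject(sim$loops))
})

test_that("large dispersion approaches the Poisson variance-mean limit", {
    ## flat mean (no decay, no modifiers) isolates the count noise
    cfg <- simConfig(beta = 0, gamma = 0, lambdaKb = 1e9,
                     dispersion = 1000, nInteractions = 5000L, seed = 3)
    sim <- simulateDataset(cfg)
    s <- sim$truth$strength
    expect_lt(abs(var(s) / mean(s) - 1), 0.1)
})

test_that("a gradient-boosted model recovers the planted signal", {
    fx <- defaultFixture()
    m <- fixtureModel("gb")
    xt <- fx$full$x[fx$split$testIdx, ]
    yt <- fx$full$y[fx$split$testIdx]
    r <- correlate(predictStrength(m, xt), yt)
    expect_gte(r, 0.6)
    ctrl <- sampleNbControl(yt, seed = 7)
    expect_gt(r, correlate(ctrl, yt) + 0.3)
})
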