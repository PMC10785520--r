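test_that("negative-binomial moment matching solves the two equations", {
    par <- nbMomentMatch(5, 20)
    expect_equal(par$prob, 0.25)
    expect_equal(par$size, 5 / 3)
    ## round trip: implied mean r(1-p)/p and variance r(1-p)/p^2
    expect_equal(par$size * (1 - par$prob) / par$prob, 5)
    expect_equal(par$size * (1 - par$prob) / par$prob^2, 20)
    expect_false(par$poissonFallback)

    expect_warning(pp <- nbMomentMatch(5, 5), "Poisson")
    expect_true(pp$poissonFallback)
})

test_that("NB controls are seeded, sized and fall back for equal moments", {
    s <- c(1, 5, 9, 2, 8, 0, 3)
    c1 <- sampleNbControl(s, seed = 7)
    expect_length(c1, length(s))
    expect_identical(c1, sampleNbControl(s, seed = 7))
    expect_error(sampleNbControl(3), "at least 2")
    expect_warning(sampleNbControl(rep(4, 50), seed = 1), "Poisson")
})

test_that("correlation handles both methods and degenerate input", {
    x <- c(1, 3, 2, 8, 5)
    expect_equal(correlate(x, 2 * x + 1), 1)
    expect_equal(correlate(x, exp(x), method = "spearman"), 1)
    expect_true(is.na(correlate(rep(1, 5), x)))
    expect_true(is.na(correlate(x, rep(0, 5))))
    expect_error(correlate(1:2, 1:2))
})

test_that("SCC is 1 on self, symmetric, and drops under perturbation", {
    set.seed(21)
    M <- randomSymMap(30)
    expect_equal(scc(M, M, h = 1, maxDistanceBp = 10000)$scc, 1)

    ## permuting the entries of one stratum lowers the correlation
    m2 <- as.matrix(contactMatrix(M))
    k <- 2L
    i <- seq_len(nrow(m2) - k)
    set.seed(3)
    prm <- sample(length(i))
    vals <- m2[cbind(i, i + k)]
    m2[cbind(i, i + k)] <- vals[prm]
    m2[cbind(i + k, i)] <- vals[prm]
    M2 <- ContactMap("chr1", 1000, m2)
    expect_lt(scc(M, M2, h = 0, maxDistanceBp = 10000)$scc, 1)

    set.seed(22)
    A <- randomSymMap(25); B <- randomSymMap(25)
    expect_equal(scc(A, B, h = 2, maxDistanceBp = 8000)$scc,
                 scc(B, A, h = 2, maxDistanceBp = 8000)$scc,
                 tolerance = 1e-12)
    expect_error(scc(A, randomSymMap(10), h = 1, maxDistanceBp = 8000),
                 "share bin size")
})

test_that("first-anchor shuffling permutes within chromosomes", {
    a1 <- GRanges("chr1", IRanges(c(1001, 20001), width = 2000))
    a2 <- GRanges("chr1", IRanges(c(50001, 80001), width = 2000))
    loops <- LoopSet(a1, a2, c(5, 7))
    sh <- shuffleFirstAnchor(loops, seed = 1)
    expect_length(sh, 2)
    ## only derangement of two loops: first anchors swapped
    expect_equal(start(anchorOne(sh)), start(a1)[c(2, 1)])
    expect_equal(start(anchorTwo(sh)), start(a2))

    fx <- defaultFixture()
    sub <- fx$sim$loops[1:200]
    sh2 <- shuffleFirstAnchor(sub, seed = 5)
    expect_length(sh2, 200)
    ## the shuffle only recombines existing anchors: per chromosome, the
    ## combined anchor-coordinate multiset is preserved (pairs whose
    ## permuted first anchor lands right of the second are re-ordered,
    ## so the leftmost-first invariant still holds)
    key <- function(gr) split(paste(start(gr), end(gr)),
                              as.character(seqnames(gr)))
    allAnchors <- function(ls) {
        k1 <- key(anchorOne(ls)); k2 <- key(anchorTwo(ls))
        lapply(stats::setNames(nm = names(k1)),
               function(ch) sort(c(k1[[ch]], k2[[ch]])))
    }
    expect_equal(allAnchors(sub), allAnchors(sh2))
    expect_true(all(start(anchorOne(sh2)) <= start(anchorTwo(sh2))))

    single <- LoopSet(GRanges("chr9", IRanges(1, 100)),
                      GRanges("chr9", IRanges(1001, 1100)), 4)
    expect_warning(shuffleFirstAnchor(single, seed = 1), "unshuffled")
})

test_that("capture rate counts respective-anchor overlaps of strong calls", {
    a1 <- GRanges("chr1", IRanges((0:9) * 10000 + 1, width = 2000))
    a2 <- GRanges("chr1", IRanges((0:9) * 10000 + 500001, width = 2000))
    ref <- LoopSet(a1, a2, strength = rep(5, 10))

    ## identical list, all strong
    expect_equal(captureRate(ref, ref), 100)
    ## nothing strong
    weak <- LoopSet(a1, a2, strength = rep(1, 10))
    expect_equal(captureRate(weak, ref), 0)
    ## exactly half the references matched by strong predictions
    half <- LoopSet(a1[1:5], a2[1:5], strength = rep(9, 5))
    expect_equal(captureRate(half, ref), 50)
    ## boundary-touching anchors do not match (needs >= 1 bp overlap)
    shifted <- LoopSet(GenomicRanges::shift(a1, 2000),
                       GenomicRanges::shift(a2, 2000),
                       strength = rep(9, 10))
    expect_equal(captureRate(shifted, ref), 0)
    expect_error(captureRate(ref, ref[integer()]), "empty")
})

test_that("permutation importance is zero for constants, seeded", {
    fx <- defaultFixture()
    m <- fixtureModel("gb")
    xt <- fx$full$x[fx$split$testIdx, ]
    yt <- fx$full$y[fx$split$testIdx]
    ## a constant column permutes to itself
    xc <- xt; xc[, "ctcf_flag"] <- 1
    mc <- trainModel("gb", fx$full$x[fx$split$trainIdx, ],
                     fx$full$y[fx$split$trainIdx], seed = 1)
    expect_equal(permutationImportance(mc, xc, yt, "ctcf_flag", seed = 2),
                 0)
    expect_equal(
        permutationImportance(m, xt, yt, "distance_kb", seed = 4,
                              repeats = 1L),
        permutationImportance(m, xt, yt, "distance_kb", seed = 4,
                              repeats = 1L))
    expect_error(permutationImportance(m, xt, yt, "no_such"), "unknown")
})

test_that("ablation of nothing scores zero and guards its inputs", {
    fx <- defaultFixture()
    idx <- fx$split$trainIdx[1:500]
    tidx <- fx$split$testIdx[1:200]
    x <- fx$full$x[idx, ]; y <- fx$full$y[idx]
    xt <- fx$full$x[tidx, ]; yt <- fx$full$y[tidx]
    res <- ablationImportance("gb", x, y, xt, yt, drop = NULL, seed = 1)
    expect_equal(res$importance, 0)
    expect_error(ablationImportance("gb", x, y, xt, yt, drop = "zzz"),
                 "not in schema")
    expect_error(ablationImportance("gb", x[, 1, drop = FALSE], y,
                                    xt[, 1, drop = FALSE], yt,
                                    drop = "distance_kb"), "cannot drop")
})

test_that("CTCF occupancy classes follow 1-bp-overlap anchors", {
    a1 <- GRanges("chr1", IRanges(c(1001, 1001, 1001), width = 1000))
    a2 <- GRanges("chr1", IRanges(c(50001, 50001, 50001), width = 1000))
    loops <- LoopSet(a1, a2, strength = c(1, 2, 3))
    ## peaks overlapping: both anchors; only left; neither (touching only)
    ctcf <- GRanges("chr1", IRanges(c(1500, 50500, 2001),
                                    width = c(100, 100, 100)))
    cls <- classifyCtcfOccupancy(loops, ctcf[1:2])
    expect_equal(as.character(cls[1]), "both")
    cls2 <- classifyCtcfOccupancy(loops, ctcf[1])
    expect_equal(as.character(cls2[1]), "one")
    ## a CTCF peak starting exactly at the anchor end (BED-touching)
    touch <- GRanges("chr1", IRanges(2001, 2100))
    cls3 <- classifyCtcfOccupancy(loops, touch)
    expect_equal(as.character(cls3[1]), "none")
})

test_that("the empirical overlap test matches hypergeometric expectations", {
    ## target = class = universe: nothing can exceed the observed overlap
    res <- empiricalOverlapTest(1:50, 1:50, 50, nSim = 100, seed = 1)
    expect_equal(res$pValue, 0)
    expect_equal(res$observedOverlap, 50)

    set.seed(9)
    target <- sample(1000, 200)
    cls <- sample(1000, 400)
    res2 <- empiricalOverlapTest(target, cls, 1000, nSim = 2000, seed = 3)
    ## E[overlap] = |target| * |class| / |universe| = 80
    expect_equal(res2$expectedOverlap, 80, tolerance = 0.05)
    expect_true(res2$pValue >= 0 && res2$pValue <= 1)
    expect_error(empiricalOverlapTest(1:20, 1:5, 10), "larger")
})

test_that("shuffled-input controls permute the prediction multiset", {
    fx <- defaultFixture()
    m <- fixtureModel("gb")
    xt <- fx$full$x[fx$split$testIdx[1:300], ]
    normal <- predictStrength(m, xt)
    ctrl <- shuffledInputControl(m, xt, seed = 8)
    expect_equal(sort(ctrl), sort(normal))
    ## n = 1 only admits the identity permutation
    one <- xt[1, , drop = FALSE]
    expect_equal(shuffledInputControl(m, one, seed = 1),
                 predictStrength(m, one))
})
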