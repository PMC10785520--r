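test_that("the random split is 75/25, reproducible and exhaustive", {
    sp <- splitRandom(100L, seed = 11)
    expect_length(sp$trainIdx, 75)
    expect_length(sp$testIdx, 25)
    expect_equal(sort(c(sp$trainIdx, sp$testIdx)), 1:100)
    expect_identical(sp, splitRandom(100L, seed = 11))
    expect_false(identical(sp$trainIdx, splitRandom(100L, seed = 12)$trainIdx))
    expect_error(splitRandom(3L), "at least 4")

    a <- GRanges("chr1", IRanges((1:8) * 1000, width = 100))
    loops <- LoopSet(a, GenomicRanges::shift(a, 50000), strength = 1:8)
    sp2 <- splitRandom(loops, seed = 3)
    expect_s4_class(sp2$train, "LoopSet")
    expect_equal(length(sp2$train) + length(sp2$test), 8)
})

test_that("parity split sends odd chromosomes to training", {
    mk <- function(chrom) {
        a <- GRanges(chrom, IRanges(1000, 2000))
        LoopSet(a, GenomicRanges::shift(a, 30000), strength = 5)
    }
    a1 <- suppressWarnings(
        c(anchorOne(mk("chr1")), anchorOne(mk("chr2")),
          anchorOne(mk("chr3")), anchorOne(mk("chrX"))))
    a2 <- suppressWarnings(
        c(anchorTwo(mk("chr1")), anchorTwo(mk("chr2")),
          anchorTwo(mk("chr3")), anchorTwo(mk("chrX"))))
    loops <- LoopSet(a1, a2, strength = rep(5, 4))
    expect_message(sp <- splitByChromosomeParity(loops), "excluded 1")
    expect_equal(as.character(seqnames(anchorOne(sp$odd))),
                 c("chr1", "chr3"))
    expect_equal(as.character(seqnames(anchorOne(sp$even))), "chr2")
    expect_equal(sp$nExcluded, 1L)

    empty <- loops[integer()]
    spE <- splitByChromosomeParity(empty)
    expect_equal(length(spE$odd), 0)
    expect_equal(length(spE$even), 0)
})

test_that("input validation rejects bad matrices and targets", {
    x <- matrix(runif(40), 10, 4, dimnames = list(NULL, letters[1:4]))
    y <- runif(10)
    expect_error(trainModel("rf", x[1:5, ], y[1:5]), "at least 10")
    xb <- x; xb[3, 2] <- NA
    expect_error(trainModel("rf", xb, y), "row\\(s\\) 3")
    expect_error(trainModel("rf", x, -y), "non-negative")
    expect_error(trainModel("rf", unname(x), y), "column names")
})

test_that("a random forest reproduces a constant target exactly", {
    x <- matrix(runif(100), 20, 5, dimnames = list(NULL, letters[1:5]))
    m <- suppressWarnings(trainModel("rf", x, rep(4, 20), seed = 2))
    expect_equal(predictStrength(m, x), rep(4, 20))
})

test_that("gradient boosting fits a deterministic distance law", {
    set.seed(1)
    n <- 5000
    x <- cbind(distance_kb = runif(n, 5, 2000))
    y <- 20 * exp(-x[, "distance_kb"] / 150)
    m <- trainModel("gb", x, y, seed = 1)
    expect_gte(cor(predictStrength(m, x), y), 0.95)
})

test_that("tree-model training is bit-reproducible under a seed", {
    fx <- defaultFixture()
    idx <- fx$split$trainIdx[1:400]
    x <- fx$full$x[idx, ]; y <- fx$full$y[idx]
    xt <- fx$full$x[fx$split$testIdx[1:100], ]
    for (v in c("rf", "gb")) {
        m1 <- trainModel(v, x, y, schema = featureSchema("full"), seed = 9)
        m2 <- trainModel(v, x, y, schema = featureSchema("full"), seed = 9)
        expect_identical(predictStrength(m1, xt), predictStrength(m2, xt))
    }
})

test_that("the dnn stops early when the validation loss plateaus", {
    set.seed(4)
    x <- matrix(runif(600), 150, 4, dimnames = list(NULL, letters[1:4]))
    y <- 2 + 3 * x[, 1]
    ## a large learning rate converges fast, then plateaus within the
    ## patience window well before the epoch cap
    m <- trainModel("dnn", x, y,
                    config = dnnConfig(maxEpochs = 400L,
                                       learningRate = 0.01,
                                       dropoutRate = 0,
                                       earlyStopPatience = 10L),
                    seed = 1)
    expect_lt(m@metadata$epochsRun, 400)
    expect_true(all(is.finite(predictStrength(m, x))))
})

test_that("predictions are non-negative, aligned and schema-checked", {
    fx <- defaultFixture()
    m <- fixtureModel("gb")
    xt <- fx$full$x[fx$split$testIdx, ]
    p <- predictStrength(m, xt)
    expect_true(all(p >= 0))
    expect_true(all(is.finite(p)))
    expect_length(predictStrength(m, xt[1, , drop = FALSE]), 1)

    ## permuting rows permutes predictions identically
    perm <- rev(seq_len(50))
    expect_equal(predictStrength(m, xt[perm, ]), p[perm])

    ## schema mismatch names the offending columns
    bad <- xt[, -2]
    expect_error(predictStrength(m, bad), "rad21_p1")
    extra <- cbind(xt, junk = 1)
    expect_error(predictStrength(m, extra), "junk")
})

test_that("strong interactions are called at the PET >= 3 threshold", {
    expect_equal(isStrong(c(3, 2.999, 0, 10)),
                 c(TRUE, FALSE, FALSE, TRUE))
    expect_equal(isStrong(5, threshold = 6), FALSE)
})
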