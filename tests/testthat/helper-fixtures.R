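suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
})

## ---- shared expensive fixture (built once per test session) ----------

.fixtureCache <- new.env(parent = emptyenv())

## The standard synthetic dataset: 5,000 interactions, seed 1, plus its
## full/minimal feature matrices and the 75/25 split.
defaultFixture <- function() {
    if (!is.null(.fixtureCache$fx)) return(.fixtureCache$fx)
    sim <- simulateDataset(simConfig(seed = 1))
    full <- buildFeatureMatrix(sim$loops, sim$tracks, sim$genome,
                               sim$motifs, featureSchema("full"))
    minCols <- schemaColumns(featureSchema("minimal"))
    minimal <- list(x = full$x[, minCols, drop = FALSE], y = full$y)
    split <- splitRandom(length(sim$loops), 0.75, seed = 1)
    .fixtureCache$fx <- list(sim = sim, full = full, minimal = minimal,
                             split = split)
    .fixtureCache$fx
}

## Models trained on the fixture's training rows, cached per variant and
## schema.  The dnn uses a 200-epoch cap (its desk-scale test profile).
fixtureModel <- function(variant, schema = "full") {
    key <- paste(variant, schema, sep = "-")
    if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
    fx <- defaultFixture()
    fm <- if (schema == "full") fx$full else fx$minimal
    cfg <- if (variant == "dnn") dnnConfig(maxEpochs = 200L) else NULL
    m <- trainModel(variant, fm$x[fx$split$trainIdx, , drop = FALSE],
                    fm$y[fx$split$trainIdx],
                    schema = featureSchema(schema), config = cfg, seed = 1)
    .fixtureCache[[key]] <- m
    m
}

## ---- small deterministic helpers -------------------------------------

writeTempLines <- function(lines) {
    path <- tempfile(fileext = ".txt")
    writeLines(lines, path)
    path
}

## A random sparse symmetric contact map with Poisson-ish entries.
randomSymMap <- function(n, binSize = 1000L, chrom = "chr1",
                         density = 0.4) {
    m <- matrix(0, n, n)
    idx <- which(upper.tri(m, diag = TRUE))
    m[idx] <- stats::rpois(length(idx), 3) *
        stats::rbinom(length(idx), 1L, density)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    ContactMap(chrom, binSize, m)
}

## ---- independent oracles ---------------------------------------------

## Dense brute-force mean-filter smoothing: explicit window loops.
bruteSmooth <- function(m, h) {
    n <- nrow(m)
    out <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        ri <- max(1L, i - h):min(n, i + h)
        rj <- max(1L, j - h):min(n, j + h)
        out[i, j] <- mean(m[ri, rj])
    }
    out
}

## Dense brute-force stratum-adjusted correlation, coded directly from
## the definition (smooth, per-diagonal Pearson, rank-variance weights),
## independent of the package's sparse implementation.
bruteScc <- function(A, B, h, maxDistBins) {
    A <- bruteSmooth(A, h)
    B <- bruteSmooth(B, h)
    n <- nrow(A)
    num <- 0
    den <- 0
    for (k in 0:min(maxDistBins, n - 1L)) {
        x <- vapply(seq_len(n - k), function(i) A[i, i + k], 1)
        y <- vapply(seq_len(n - k), function(i) B[i, i + k], 1)
        if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) next
        w <- length(x) * sqrt(stats::var(rank(x)) * stats::var(rank(y)))
        num <- num + w * stats::cor(x, y)
        den <- den + w
    }
    if (den == 0) stop("no usable stratum")
    num / den
}
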