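## The evaluation stack: negative-binomial control interactions,
## correlations, stratum-adjusted correlation between contact maps,
## loop-capture analysis with shuffled-first-anchor nulls, permutation
## and ablation feature importance, CTCF occupancy classes, and the
## empirical resampling overlap test.

#' Moment-match a negative binomial to a mean and variance
#'
#' Solves for the size/probability parameterization with the given mean m
#' and variance v: p = m/v, r = m^2/(v - m).  When v <= m there is no
#' overdispersion to fit and the sampler falls back to Poisson(m); the
#' result is flagged accordingly and a warning is raised.
#'
#' @param m target mean (> 0).
#' @param v target variance.
#' @return list with \code{size}, \code{prob}, \code{mu} and logical
#'   \code{poissonFallback}.
#' @examples
#' nbMomentMatch(5, 20)  # prob 0.25, size 5/3
#' @export
nbMomentMatch <- function(m, v) {
    stopifnot(m > 0)
    if (v <= m) {
        warning("variance <= mean; falling back to Poisson")
        return(list(size = Inf, prob = NA_real_, mu = m,
                    poissonFallback = TRUE))
    }
    list(size = m^2 / (v - m), prob = m / v, mu = m,
         poissonFallback = FALSE)
}

#' Negative-binomial control strengths
#'
#' For each interaction, draws a control strength from a negative
#' binomial fitted (by moment matching) to the sample mean and variance
#' of the observed strengths — the null model against which prediction
#' correlations are judged, since observed PET counts are themselves
#' negative-binomially distributed.
#'
#' @param strengths observed strength vector (length >= 2), or a
#'   \link{LoopSet}.
#' @param seed integer seed.
#' @return numeric vector of control strengths, one per interaction.
#' @export
sampleNbControl <- function(strengths, seed = 1L) {
    if (methods::is(strengths, "LoopSet"))
        strengths <- strength(strengths)
    if (length(strengths) < 2L) stop("need at least 2 interactions")
    m <- mean(strengths)
    v <- var(strengths)
    par <- if (v <= m) {
        warning("strength variance <= mean; Poisson control")
        list(poissonFallback = TRUE, mu = m)
    } else nbMomentMatch(m, v)
    set.seed(seed)
    if (isTRUE(par$poissonFallback))
        rpois(length(strengths), lambda = par$mu)
    else
        rnbinom(length(strengths), size = par$size, mu = par$mu)
}

#' Pearson or Spearman correlation with explicit degenerate handling
#'
#' @param x,y equal-length numeric vectors (length >= 3, finite).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return the coefficient, or \code{NA} when either vector has zero
#'   variance.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    stopifnot(length(x) == length(y), length(x) >= 3L,
              all(is.finite(x)), all(is.finite(y)))
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y, method = method)
}

#' Stratum-adjusted correlation coefficient between two contact maps
#'
#' Both maps are smoothed with a (2h+1)-wide mean filter, split into
#' distance strata (diagonals) up to the maximum genomic distance, and a
#' Pearson correlation is computed per stratum.  The SCC is the weighted
#' mean of the per-stratum correlations with variance-stabilized weights
#' w_k = N_k * sqrt(var(rank(X_k)) * var(rank(Y_k))); strata with zero
#' variance in either map are excluded.
#'
#' @param mapA,mapB \link{ContactMap}s with identical chromosome, bin
#'   size and bin count.
#' @param h smoothing window half-size (default 2).
#' @param maxDistanceBp maximum genomic distance included (default
#'   25 Mb).
#' @return list with \code{scc}, per-stratum \code{rho}, \code{weights}
#'   and the indices of \code{strataUsed} (0-based diagonal offsets).
#' @export
scc <- function(mapA, mapB, h = 2L, maxDistanceBp = 25e6) {
    if (binSize(mapA) != binSize(mapB) || nBins(mapA) != nBins(mapB))
        stop("maps must share bin size and bin count")
    sA <- stratify(smoothMap(mapA, h), maxDistanceBp)
    sB <- stratify(smoothMap(mapB, h), maxDistanceBp)
    nStrata <- length(sA)
    rho <- rep(NA_real_, nStrata)
    w <- rep(NA_real_, nStrata)
    for (k in seq_len(nStrata)) {
        xk <- sA[[k]]
        yk <- sB[[k]]
        if (length(xk) < 2L || sd(xk) == 0 || sd(yk) == 0) next
        rho[k] <- cor(xk, yk)
        ## variance-stabilized weight on the rank transforms
        w[k] <- length(xk) * sqrt(var(rank(xk)) * var(rank(yk)))
    }
    keep <- which(!is.na(rho) & !is.na(w) & w > 0)
    if (!length(keep)) stop("no stratum with nonzero variance in both maps")
    list(scc = sum(w[keep] * rho[keep]) / sum(w[keep]),
         rho = rho, weights = w, strataUsed = keep - 1L)
}

#' Shuffle the first anchors of a loop list (random-loop null)
#'
#' Within each chromosome, the multiset of first-anchor (leftmost)
#' coordinates is permuted across loops while second anchors stay put,
#' producing the random control loops for the capture analysis.  A
#' derangement (no loop keeps its own first anchor) is preferred and
#' retried for; chromosomes with a single loop cannot be shuffled and are
#' left unchanged with a warning.  Anchor pairs are re-ordered after the
#' shuffle so that the invariant "anchor one is leftmost" still holds.
#'
#' @param loops a \link{LoopSet}.
#' @param seed integer seed.
#' @return a shuffled \code{LoopSet} of the same length.
#' @export
shuffleFirstAnchor <- function(loops, seed = 1L) {
    set.seed(seed)
    a1 <- anchorOne(loops)
    a2 <- anchorTwo(loops)
    chrom <- as.character(GenomicRanges::seqnames(a1))
    newA1 <- a1
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        if (length(idx) < 2L) {
            warning(sprintf(
                "single loop on %s left unshuffled", ch))
            next
        }
        perm <- sample(length(idx))
        for (try in seq_len(100L)) {
            if (!any(perm == seq_along(idx))) break
            perm <- sample(length(idx))
        }
        newA1[idx] <- a1[idx[perm]]
    }
    LoopSet(newA1, a2, strength(loops), metadata = loops@metadata)
}

#' Fraction of reference loops captured as strong predictions
#'
#' A reference loop is captured when some predicted interaction with
#' strength >= threshold matches it, where a match requires at least 1 bp
#' of overlap between the respective anchors (leftmost with leftmost,
#' rightmost with rightmost, after coordinate ordering).
#'
#' @param predicted a \link{LoopSet} of predicted interactions (strength
#'   = predicted strength).
#' @param referenceLoops a non-empty \code{LoopSet} of reference loops.
#' @param threshold strength threshold for a strong prediction
#'   (default 3).
#' @return percentage in [0, 100].
#' @export
captureRate <- function(predicted, referenceLoops, threshold = 3) {
    if (!length(referenceLoops)) stop("empty reference loop list")
    strong <- predicted[which(isStrong(strength(predicted), threshold))]
    if (!length(strong)) return(0)
    ov1 <- GenomicRanges::findOverlaps(anchorOne(referenceLoops),
                                       anchorOne(strong),
                                       ignore.strand = TRUE)
    ov2 <- GenomicRanges::findOverlaps(anchorTwo(referenceLoops),
                                       anchorTwo(strong),
                                       ignore.strand = TRUE)
    k1 <- paste(S4Vectors::queryHits(ov1), S4Vectors::subjectHits(ov1))
    k2 <- paste(S4Vectors::queryHits(ov2), S4Vectors::subjectHits(ov2))
    captured <- unique(S4Vectors::queryHits(ov1)[k1 %in% k2])
    100 * length(captured) / length(referenceLoops)
}

#' Permutation feature importance
#'
#' The evaluation metric (mean absolute error by default) is computed on
#' the test data, then recomputed after permuting one feature column;
#' the importance is the mean, over repeats, of (permuted metric -
#' baseline metric).  Larger values mean more important features.
#'
#' @param model a \link{LoopModel}.
#' @param x test feature matrix (>= 10 rows) matching the model schema.
#' @param y test targets.
#' @param column feature column name to permute.
#' @param metric \code{"mae"} (mean absolute error) or \code{"mse"}.
#' @param seed integer seed.
#' @param repeats number of permutations averaged (default 10).
#' @return the importance (a number).
#' @export
permutationImportance <- function(model, x, y, column, metric = c("mae",
                                  "mse"), seed = 1L, repeats = 10L) {
    metric <- match.arg(metric)
    if (!column %in% colnames(x))
        stop(sprintf("unknown column '%s'", column))
    stopifnot(nrow(x) >= 10L)
    lossFun <- switch(metric,
        mae = function(p, t) mean(abs(p - t)),
        mse = function(p, t) mean((p - t)^2))
    baseline <- lossFun(predictStrength(model, x), y)
    set.seed(seed)
    deltas <- vapply(seq_len(repeats), function(r) {
        xp <- x
        xp[, column] <- xp[sample.int(nrow(x)), column]
        lossFun(predictStrength(model, xp), y) - baseline
    }, 1)
    mean(deltas)
}

#' Ablation (drop-one-feature retraining) importance
#'
#' Retrains the model without a feature (or without the H3K27ac +
#' H3K27me3 pair jointly) on the training data and measures the increase
#' in test mean absolute error over the full model — the
#' odd-chromosome-train / even-chromosome-test protocol of the
#' feature-contribution analysis.
#'
#' @param variant model variant passed to \link{trainModel}.
#' @param xTrain,yTrain training features/targets (e.g. odd chromosomes).
#' @param xTest,yTest test features/targets (e.g. even chromosomes).
#' @param drop what to drop: a feature column name; a feature name
#'   spanning both anchors (\code{"rad21"}, \code{"h3k27ac"},
#'   \code{"h3k27me3"}, \code{"gc"} expand to their \code{_p1}/\code{_p2}
#'   column pair); \code{"histones"} for the joint H3K27ac + H3K27me3
#'   drop; or \code{NULL} to retrain with all features (importance 0 by
#'   construction).
#' @param config,seed passed to \link{trainModel}.
#' @return list with \code{importance} (MAE(model without feature) -
#'   MAE(full model)), \code{maeFull} and \code{maeDropped}.
#' @export
ablationImportance <- function(variant, xTrain, yTrain, xTest, yTest,
                               drop = NULL, config = NULL, seed = 1L) {
    dropCols <- if (is.null(drop)) character()
        else if (identical(drop, "histones")) .HISTONE_COLUMNS
        else if (drop %in% c("rad21", "h3k27ac", "h3k27me3", "gc"))
            paste0(drop, c("_p1", "_p2"))
        else drop
    if (length(dropCols) && !all(dropCols %in% colnames(xTrain)))
        stop(sprintf("feature '%s' not in schema",
                     setdiff(dropCols, colnames(xTrain))[1]))
    keep <- setdiff(colnames(xTrain), dropCols)
    if (!length(keep)) stop("cannot drop all features")
    full <- trainModel(variant, xTrain, yTrain, config = config, seed = seed)
    maeFull <- mean(abs(predictStrength(full, xTest) - yTest))
    reduced <- trainModel(variant, xTrain[, keep, drop = FALSE], yTrain,
                          config = config, seed = seed)
    maeDropped <- mean(abs(
        predictStrength(reduced, xTest[, keep, drop = FALSE]) - yTest))
    list(importance = maeDropped - maeFull, maeFull = maeFull,
         maeDropped = maeDropped)
}

#' Classify interactions by CTCF occupancy of their anchors
#'
#' An anchor is occupied when it overlaps any CTCF ChIP-Seq peak by at
#' least 1 bp (intervals merely touching at a shared boundary do not
#' overlap under the half-open convention).  Each interaction falls in
#' exactly one of the classes \code{both}, \code{one}, \code{none}.
#'
#' @param loops a \link{LoopSet}.
#' @param ctcfPeaks \code{GRanges} of CTCF ChIP-Seq peaks.
#' @return factor with levels \code{both}, \code{one}, \code{none},
#'   parallel to \code{loops}.
#' @export
classifyCtcfOccupancy <- function(loops, ctcfPeaks) {
    occ1 <- GenomicRanges::countOverlaps(anchorOne(loops), ctcfPeaks,
                                         ignore.strand = TRUE) > 0L
    occ2 <- GenomicRanges::countOverlaps(anchorTwo(loops), ctcfPeaks,
                                         ignore.strand = TRUE) > 0L
    cls <- ifelse(occ1 & occ2, "both", ifelse(occ1 | occ2, "one", "none"))
    factor(cls, levels = c("both", "one", "none"))
}

#' Empirical resampling test for interaction-set overlap
#'
#' Tests whether the observed overlap between a target interaction subset
#' (e.g. enhancer-enhancer interactions) and a comparison class (e.g.
#' interactions with CTCF in both anchors) is larger than expected by
#' chance.  Each simulation samples |target| interactions from the
#' universe without replacement and counts the intersection with the
#' class; the p-value is the fraction of simulations whose intersection
#' strictly exceeds the observed one (ties do not count), and the
#' expected overlap is the mean simulated intersection.
#'
#' @param targetIdx,classIdx integer indices (into the universe) of the
#'   target subset and comparison class.
#' @param universeSize number of interactions in the universe.
#' @param nSim number of simulations (default 10000).
#' @param seed integer seed.
#' @return list with \code{pValue}, \code{expectedOverlap},
#'   \code{observedOverlap}.
#' @export
empiricalOverlapTest <- function(targetIdx, classIdx, universeSize,
                                 nSim = 10000L, seed = 1L) {
    if (length(targetIdx) > universeSize)
        stop("target larger than universe")
    observed <- length(intersect(targetIdx, classIdx))
    inClass <- logical(universeSize)
    inClass[classIdx] <- TRUE
    set.seed(seed)
    sims <- vapply(seq_len(nSim), function(s)
        sum(inClass[sample.int(universeSize, length(targetIdx))]), 1L)
    list(pValue = sum(sims > observed) / nSim,
         expectedOverlap = mean(sims),
         observedOverlap = observed)
}

#' Shuffled-input control predictions
#'
#' Permutes whole rows of the feature matrix jointly and predicts on the
#' shuffled rows — a control that preserves every marginal feature
#' distribution (in particular the genomic-distance distribution) while
#' destroying the row-to-target pairing.  The returned vector is in the
#' shuffled-row order, for comparison against the original targets in
#' their original order.
#'
#' @param model a \link{LoopModel}.
#' @param x feature matrix matching the model schema.
#' @param seed integer seed.
#' @return numeric vector of control predictions (a permutation of the
#'   unshuffled predictions).
#' @export
shuffledInputControl <- function(model, x, seed = 1L) {
    set.seed(seed)
    perm <- sample.int(nrow(x))
    predictStrength(model, x[perm, , drop = FALSE])
}
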