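## Training and applying the three regressor variants (dnn, rf, gb) with
## the data splits used throughout: a random 75/25 split for the main
## models, and an odd/even chromosome split for the feature-importance
## experiments.

#' Default configuration for the deep-neural-network variant
#'
#' Three hidden layers of 128 rectified-linear units, rectified-linear
#' output (predictions always non-negative), dropout 0.2, batch size 32,
#' Adam with learning rate 1e-5, mean-squared-error loss, up to 750
#' epochs with early stopping after 50 epochs without improvement of the
#' validation MSE.  The validation slice is the last 10\% of the shuffled
#' training rows.  Inputs are z-scaled on training-set statistics by
#' default (\code{standardize}): with the small fixed learning rate, the
#' network cannot traverse the raw feature scales (distances in the
#' thousands of kb, RPKM in the thousands) within the epoch budget, and
#' the scaling is folded into the stored model so prediction is
#' transparent.  Set \code{standardize = FALSE} to train on raw values.
#'
#' @param maxEpochs upper bound on training epochs.
#' @param standardize z-scale inputs before training (logical).
#' @param ... overrides for any listed field.
#' @return named list of configuration values.
#' @export
dnnConfig <- function(maxEpochs = 750L, standardize = TRUE, ...) {
    cfg <- list(hiddenLayers = 3L, unitsPerLayer = 128L,
                dropoutRate = 0.2, batchSize = 32L,
                learningRate = 1e-5, maxEpochs = as.integer(maxEpochs),
                earlyStopPatience = 50L, validationFraction = 0.1,
                standardize = standardize)
    over <- list(...)
    cfg[names(over)] <- over
    stopifnot(cfg$earlyStopPatience < cfg$maxEpochs,
              cfg$dropoutRate >= 0, cfg$dropoutRate < 1,
              cfg$learningRate > 0)
    cfg
}

#' Default configurations for the tree-ensemble variants
#'
#' Pinned numerically so behavior does not drift across library versions:
#' random forest = 100 trees, unlimited depth, bootstrap resampling, mean
#' aggregation; gradient boosting = 100 stages, shrinkage 0.1, depth-3
#' trees, squared-error loss.
#'
#' @param kind \code{"rf"} or \code{"gb"}.
#' @param ... overrides.
#' @return named list of configuration values.
#' @export
treeConfig <- function(kind = c("rf", "gb"), ...) {
    kind <- match.arg(kind)
    cfg <- switch(kind,
        rf = list(nTrees = 100L),
        gb = list(nRounds = 100L, shrinkage = 0.1, maxDepth = 3L))
    over <- list(...)
    cfg[names(over)] <- over
    cfg
}

#' Random 75/25 train/test split
#'
#' Partitions interactions (or any indexable collection) into a training
#' set of \code{round(trainFraction * N)} records and the complementary
#' test set, reproducibly under the seed.
#'
#' @param x a \link{LoopSet}, or an integer count of records.
#' @param trainFraction fraction assigned to training (default 0.75).
#' @param seed integer seed.
#' @return list with \code{trainIdx} and \code{testIdx} (and, when
#'   \code{x} is a \code{LoopSet}, the subsets \code{train} and
#'   \code{test}).
#' @export
splitRandom <- function(x, trainFraction = 0.75, seed = 1L) {
    n <- if (is.numeric(x) && length(x) == 1L) as.integer(x) else length(x)
    if (n < 4L) stop("need at least 4 records to split")
    set.seed(seed)
    nTrain <- round(trainFraction * n)
    trainIdx <- sort(sample.int(n, nTrain))
    testIdx <- setdiff(seq_len(n), trainIdx)
    out <- list(trainIdx = trainIdx, testIdx = testIdx)
    if (methods::is(x, "LoopSet")) {
        out$train <- x[trainIdx]
        out$test <- x[testIdx]
    }
    out
}

#' Split interactions by chromosome parity
#'
#' Training on odd-numbered autosomes and testing on even-numbered ones
#' is the split used by the ablation (drop-one-feature) experiments.
#' Records on non-numeric chromosomes (chrX, chrY, chrM, ...) are
#' excluded, with the count reported in the result.
#'
#' @param loops a \link{LoopSet} with chromosome names of the form
#'   \code{chrN}.
#' @return list with \code{odd} and \code{even} \code{LoopSet}s and the
#'   integer \code{nExcluded}.
#' @export
splitByChromosomeParity <- function(loops) {
    chrom <- as.character(GenomicRanges::seqnames(anchorOne(loops)))
    num <- suppressWarnings(as.integer(sub("^chr", "", chrom)))
    excluded <- is.na(num)
    if (any(excluded))
        message(sprintf("excluded %d record(s) on non-numeric chromosomes",
                        sum(excluded)))
    list(odd = loops[which(!excluded & num %% 2L == 1L)],
         even = loops[which(!excluded & num %% 2L == 0L)],
         nExcluded = sum(excluded))
}

#' Train an interaction-strength regressor
#'
#' @param variant \code{"dnn"}, \code{"rf"} or \code{"gb"}.
#' @param x numeric feature matrix with column names (one row per
#'   interaction).
#' @param y non-negative numeric target vector (PET strengths).
#' @param schema the \link{featureSchema} describing \code{x}'s columns;
#'   defaults to a custom schema over \code{colnames(x)}.
#' @param config variant configuration (\link{dnnConfig} /
#'   \link{treeConfig}); defaults applied when \code{NULL}.
#' @param seed integer seed; rf/gb training is bit-reproducible under it,
#'   the dnn up to floating-point scheduling.
#' @return A \link{LoopModel}.
#' @export
trainModel <- function(variant = c("dnn", "rf", "gb"), x, y,
                       schema = NULL, config = NULL, seed = 1L) {
    variant <- match.arg(variant)
    if (is.null(colnames(x)))
        stop("feature matrix must have column names")
    if (is.null(schema))
        schema <- featureSchema("custom", columns = colnames(x))
    if (!identical(colnames(x), schemaColumns(schema)))
        stop("feature matrix columns do not match schema")
    if (nrow(x) < 10L) stop("need at least 10 training rows")
    badRows <- which(!apply(is.finite(x), 1L, all))
    if (length(badRows))
        stop(sprintf("non-finite feature values in row(s) %s",
                     paste(head(badRows, 10L), collapse = ", ")))
    if (any(!is.finite(y)) || any(y < 0))
        stop("targets must be finite and non-negative")
    seed <- as.integer(seed)

    meta <- list(nTrain = nrow(x))
    if (variant == "rf") {
        if (is.null(config)) config <- treeConfig("rf")
        set.seed(seed)
        fit <- randomForest::randomForest(x = x, y = y,
                                          ntree = config$nTrees)
    } else if (variant == "gb") {
        if (is.null(config)) config <- treeConfig("gb")
        dtrain <- xgboost::xgb.DMatrix(x, label = y)
        fit <- xgboost::xgb.train(
            params = xgboost::xgb.params(
                eta = config$shrinkage, max_depth = config$maxDepth,
                objective = "reg:squarederror", nthread = 1L,
                seed = seed),
            data = dtrain, nrounds = config$nRounds, verbose = 0)
        ## keep a version-stable serialized form alongside the handle
        fit <- list(raw = xgboost::xgb.save.raw(fit),
                    featureNames = colnames(x))
    } else {
        if (is.null(config)) config <- dnnConfig()
        fit <- .mlpTrain(x, y, config, seed)
        meta$epochsRun <- fit$epochsRun
        meta$bestEpoch <- fit$bestEpoch
        meta$valMse <- fit$valMse
    }
    meta$config <- config
    new("LoopModel", variant = variant, schema = schema, fit = fit,
        seed = seed, metadata = meta)
}

#' @describeIn trainModel Predict interaction strengths for a feature
#'   matrix whose columns must match the model's schema (an error names
#'   missing or extra columns).  Predictions are finite and non-negative:
#'   the dnn by its rectified output, tree models clipped at zero.
#' @param object a \code{LoopModel}.
#' @export
setMethod("predictStrength", "LoopModel", function(object, x, ...) {
    want <- schemaColumns(object@schema)
    have <- colnames(x)
    if (!identical(have, want)) {
        missingCols <- setdiff(want, have)
        extraCols <- setdiff(have, want)
        if (length(missingCols) || length(extraCols))
            stop(sprintf("schema mismatch: missing [%s], extra [%s]",
                         paste(missingCols, collapse = ", "),
                         paste(extraCols, collapse = ", ")))
        x <- x[, want, drop = FALSE]  # same columns, different order
    }
    p <- switch(object@variant,
        rf = predict(object@fit, x),
        gb = predict(xgboost::xgb.load.raw(object@fit$raw),
                     xgboost::xgb.DMatrix(x)),
        dnn = .mlpPredict(object@fit, x))
    pmax(as.numeric(p), 0)
})

#' @export
setMethod("predict", "LoopModel", function(object, ...)
    predictStrength(object, ...))

#' Is an interaction strong?
#'
#' An interaction is called strong when its (observed or predicted)
#' strength is at least 3 PETs, the threshold used throughout the
#' loop-capture analyses.
#'
#' @param strength numeric strength(s).
#' @param threshold strength threshold (default 3).
#' @return logical vector.
#' @examples
#' isStrong(c(3, 2.999, 0))  # TRUE FALSE FALSE
#' @export
isStrong <- function(strength, threshold = 3) {
    strength >= threshold
}
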