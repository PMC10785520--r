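## Workflow runners tying the modules into end-to-end steps.  Each run*
## function writes its artifacts plus a JSON manifest (inputs, seed,
## parameters, package version) into an output directory, removes partial
## outputs on failure, and returns the artifact paths invisibly.  A thin
## command-line wrapper over these functions is installed under
## exec/loopstrength.

.writeManifest <- function(outDir, step, inputs, params) {
    manifest <- list(step = step, inputs = inputs, params = params,
                     package = "loopStrength",
                     version = as.character(packageVersion("loopStrength")))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

## Run `expr`; on error remove every path in `created` before rethrowing,
## so failed steps leave no partial artifacts behind.
.atomically <- function(created, expr) {
    tryCatch(expr, error = function(e) {
        unlink(created, recursive = TRUE)
        stop(e)
    })
}

#' Pipeline runners
#'
#' \code{runSimulate} writes the complete synthetic fixture (FASTA
#' genome, BED peaks and reads, BED6 motifs, BED CTCF peaks, BEDPE
#' interactions, ground-truth table); \code{runFeaturize} computes the
#' feature matrix for an interaction file; \code{runTrain} fits one model
#' variant on a random 75/25 split of a feature file; \code{runPredict}
#' writes predictions as BEDPE with the predicted strength in the PET
#' column (so predicted files are drop-in inputs to every evaluator);
#' \code{runEvaluate} compares a predicted BEDPE against a truth BEDPE
#' (correlations, optional binned-map SCC, optional capture rate) and
#' writes a JSON metric summary.
#'
#' @param config a \link{simConfig}.
#' @param outDir output directory (created if needed).
#' @return invisibly, a named list of artifact paths.
#' @rdname pipeline
#' @export
runSimulate <- function(config = simConfig(), outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(outDir, c(
        genome = "genome.fa", peaks = "peaks.bed",
        rad21 = "reads_rad21.bed", h3k27ac = "reads_h3k27ac.bed",
        h3k27me3 = "reads_h3k27me3.bed", motifs = "motifs.bed6",
        ctcf = "ctcf_peaks.bed", loops = "interactions.bedpe",
        truth = "truth.tsv", manifest = "manifest.json"))
    names(paths) <- c("genome", "peaks", "rad21", "h3k27ac", "h3k27me3",
                      "motifs", "ctcf", "loops", "truth", "manifest")
    .atomically(paths, {
        sim <- simulateDataset(config)
        Biostrings::writeXStringSet(sim$genome, paths["genome"])
        writeBed(sim$peaks, paths["peaks"])
        for (trk in c("rad21", "h3k27ac", "h3k27me3"))
            writeBed(reads(sim$tracks[[trk]]), paths[trk])
        writeBed(sim$motifs, paths["motifs"])
        writeBed(sim$ctcfPeaks, paths["ctcf"])
        writeInteractions(sim$loops, paths["loops"])
        write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                    row.names = FALSE)
        .writeManifest(outDir, "simulate", inputs = list(),
                       params = unclass(config))
    })
    invisible(as.list(paths))
}

#' @param interactions path to a BEDPE interaction file.
#' @param rad21,h3k27ac,h3k27me3 paths to read BED files (histone tracks
#'   may be \code{NULL} for the minimal schema).
#' @param genome path to the genome FASTA.
#' @param motifs path to the BED6 motif-hit file.
#' @param schema \code{"full"} or \code{"minimal"}.
#' @param strengthColumn strength column index in the BEDPE.
#' @rdname pipeline
#' @export
runFeaturize <- function(interactions, rad21, h3k27ac = NULL,
                         h3k27me3 = NULL, genome, motifs,
                         schema = "full", strengthColumn = 7L, outDir) {
    for (p in c(interactions, rad21, h3k27ac, h3k27me3, genome, motifs))
        if (!file.exists(p)) stop(sprintf("missing input: %s", p))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(features = file.path(outDir, "features.tsv"),
               manifest = file.path(outDir, "manifest.json"))
    .atomically(paths, {
        loops <- readInteractions(interactions, strengthColumn)
        tracks <- list(rad21 = readReads(rad21))
        if (schema == "full") {
            tracks$h3k27ac <- readReads(h3k27ac)
            tracks$h3k27me3 <- readReads(h3k27me3)
        }
        fm <- buildFeatureMatrix(loops, tracks, readGenome(genome),
                                 readMotifHits(motifs),
                                 featureSchema(schema))
        writeFeatureMatrix(fm$x, paths["features"], y = fm$y)
        .writeManifest(outDir, "featurize",
                       inputs = list(interactions = interactions,
                                     rad21 = rad21, genome = genome,
                                     motifs = motifs),
                       params = list(schema = schema,
                                     strengthColumn = strengthColumn))
    })
    invisible(as.list(paths))
}

#' @param features path to a feature TSV written by \code{runFeaturize}.
#' @param variant \code{"dnn"}, \code{"rf"} or \code{"gb"}.
#' @param trainFraction training fraction for the random split.
#' @param seed integer seed.
#' @param modelConfig optional variant configuration.
#' @rdname pipeline
#' @export
runTrain <- function(features, variant = "gb", schema = "full",
                     trainFraction = 0.75, seed = 1L, modelConfig = NULL,
                     outDir) {
    if (!file.exists(features)) stop(sprintf("missing input: %s", features))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(model = file.path(outDir, "model.rds"),
               split = file.path(outDir, "split.json"),
               manifest = file.path(outDir, "manifest.json"))
    .atomically(paths, {
        fm <- readFeatureMatrix(features)
        if (is.null(fm$y)) stop("feature file has no strength column")
        sp <- splitRandom(nrow(fm$x), trainFraction, seed)
        sch <- if (schema %in% c("full", "minimal")) featureSchema(schema)
               else featureSchema("custom", columns = colnames(fm$x))
        model <- trainModel(variant, fm$x[sp$trainIdx, , drop = FALSE],
                            fm$y[sp$trainIdx], schema = sch,
                            config = modelConfig, seed = seed)
        saveRDS(model, paths["model"])
        jsonlite::write_json(sp[c("trainIdx", "testIdx")], paths["split"])
        .writeManifest(outDir, "train",
                       inputs = list(features = features),
                       params = list(variant = variant, schema = schema,
                                     trainFraction = trainFraction,
                                     seed = seed))
    })
    invisible(as.list(paths))
}

#' @param model path to a model.rds written by \code{runTrain}.
#' @rdname pipeline
#' @export
runPredict <- function(model, features, interactions,
                       strengthColumn = 7L, outDir) {
    for (p in c(model, features, interactions))
        if (!file.exists(p)) stop(sprintf("missing input: %s", p))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(predictions = file.path(outDir, "predictions.bedpe"),
               manifest = file.path(outDir, "manifest.json"))
    .atomically(paths, {
        mod <- readRDS(model)
        fm <- readFeatureMatrix(features)
        x <- fm$x[, schemaColumns(modelSchema(mod)), drop = FALSE]
        loops <- readInteractions(interactions, strengthColumn)
        if (length(loops) != nrow(x))
            stop("feature rows and interaction records disagree")
        strength(loops) <- predictStrength(mod, x)
        writeInteractions(loops, paths["predictions"])
        .writeManifest(outDir, "predict",
                       inputs = list(model = model, features = features,
                                     interactions = interactions),
                       params = list())
    })
    invisible(as.list(paths))
}

#' @param predicted path to a predicted BEDPE.
#' @param truth path to the truth BEDPE.
#' @param sccBinSize if not \code{NULL}, also compute the
#'   stratum-adjusted correlation between per-chromosome maps binned at
#'   this size.
#' @param sccH,sccMaxDistanceBp SCC smoothing half-size and maximum
#'   distance (defaults 2 and 25 Mb).
#' @param captureThreshold if not \code{NULL}, also report the capture
#'   rate of truth loops with strength >= 3 by strong predictions at this
#'   threshold.
#' @param chromLengthBp chromosome length used for binning.
#' @rdname pipeline
#' @export
runEvaluate <- function(predicted, truth, sccBinSize = NULL, sccH = 2L,
                        sccMaxDistanceBp = 25e6, captureThreshold = 3,
                        chromLengthBp = NULL, outDir) {
    for (p in c(predicted, truth))
        if (!file.exists(p)) stop(sprintf("missing input: %s", p))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(metrics = file.path(outDir, "metrics.json"),
               manifest = file.path(outDir, "manifest.json"))
    .atomically(paths, {
        pred <- readInteractions(predicted)
        tru <- readInteractions(truth)
        if (length(pred) != length(tru))
            stop("predicted and truth files have different record counts")
        metrics <- list(
            n = length(tru),
            pearson = correlate(strength(pred), strength(tru)),
            spearman = correlate(strength(pred), strength(tru),
                                 method = "spearman"))
        if (!is.null(sccBinSize)) {
            chrom <- as.character(
                GenomicRanges::seqnames(anchorOne(tru)))
            if (is.null(chromLengthBp))
                chromLengthBp <- max(bedEnd0(anchorTwo(tru))) + 1
            sccVals <- vapply(unique(chrom), function(ch) {
                sel <- which(chrom == ch)
                mp <- binInteractions(pred[sel], sccBinSize, chromLengthBp)
                mt <- binInteractions(tru[sel], sccBinSize, chromLengthBp)
                scc(mp, mt, h = sccH,
                    maxDistanceBp = sccMaxDistanceBp)$scc
            }, 1)
            metrics$sccPerChrom <- as.list(sccVals)
            metrics$sccMean <- mean(sccVals)
        }
        if (!is.null(captureThreshold)) {
            strongTruth <- tru[which(isStrong(strength(tru)))]
            if (length(strongTruth))
                metrics$captureRate <- captureRate(pred, strongTruth,
                                                   captureThreshold)
        }
        jsonlite::write_json(metrics, paths["metrics"], auto_unbox = TRUE,
                             pretty = TRUE, digits = NA)
        .writeManifest(outDir, "evaluate",
                       inputs = list(predicted = predicted, truth = truth),
                       params = list(sccBinSize = sccBinSize, sccH = sccH,
                                     sccMaxDistanceBp = sccMaxDistanceBp,
                                     captureThreshold = captureThreshold))
    })
    invisible(as.list(paths))
}
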