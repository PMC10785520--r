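## Central S4 containers.
##
## All genomic coordinates are held as GRanges (1-based, closed) and
## converted from/to the BED convention (0-based, half-open) only at the
## file boundary.  Helpers bedStart0()/bedEnd0() recover BED coordinates,
## and peakCenter0() implements the peak-center rule used throughout:
## center = floor((bed_start + bed_end) / 2).

#' LoopSet: pairwise anchor interactions with PET strengths
#'
#' A \code{LoopSet} stores intra-chromosomal chromatin interactions as two
#' parallel \link[GenomicRanges]{GRanges} of anchor peaks plus a numeric
#' strength vector (observed PET counts or predicted strengths).  Anchors
#' are kept in coordinate order: \code{anchorOne} is always the leftmost
#' anchor of each pair.
#'
#' @slot anchorOne,anchorTwo parallel \code{GRanges}; the leftmost and
#'   rightmost anchor peak of each interaction.
#' @slot strength numeric, non-negative; PET count (or predicted strength).
#' @slot metadata list of free-form provenance (e.g. the number of
#'   inter-chromosomal records dropped at parse time).
#'
#' @aliases LoopSet
#' @exportClass LoopSet
setClass("LoopSet",
    representation(
        anchorOne = "GRanges",
        anchorTwo = "GRanges",
        strength  = "numeric",
        metadata  = "list"
    ),
    prototype(metadata = list())
)

setValidity("LoopSet", function(object) {
    a1 <- object@anchorOne
    a2 <- object@anchorTwo
    s  <- object@strength
    msgs <- character()
    if (length(a1) != length(a2) || length(a1) != length(s))
        msgs <- c(msgs, "anchorOne, anchorTwo and strength must be parallel")
    if (length(a1) == length(a2) && length(a1) > 0L) {
        if (!all(as.character(GenomicRanges::seqnames(a1)) ==
                 as.character(GenomicRanges::seqnames(a2))))
            msgs <- c(msgs, "interactions must be intra-chromosomal")
        if (!all(GenomicRanges::start(a1) <= GenomicRanges::start(a2)))
            msgs <- c(msgs, "anchorOne must be the leftmost anchor")
    }
    if (length(s) && (any(!is.finite(s)) || any(s < 0)))
        msgs <- c(msgs, "strength must be finite and non-negative")
    if (length(msgs)) msgs else TRUE
})

#' Construct a LoopSet
#'
#' Anchors given in arbitrary order are swapped so that the leftmost peak
#' (smaller start) is \code{anchorOne}, matching the orientation needed by
#' the CTCF convergence flag and the first-anchor shuffle.
#'
#' @param anchor1,anchor2 parallel \code{GRanges} of anchor peaks.
#' @param strength numeric vector of non-negative interaction strengths.
#' @param metadata optional list of provenance.
#' @return A \code{LoopSet}.
#' @examples
#' a1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 3000))
#' a2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50001, 52000))
#' LoopSet(a1, a2, strength = 7)
#' @export
LoopSet <- function(anchor1, anchor2, strength, metadata = list()) {
    stopifnot(length(anchor1) == length(anchor2),
              length(anchor1) == length(strength))
    swap <- GenomicRanges::start(anchor2) < GenomicRanges::start(anchor1)
    if (any(swap)) {
        tmp <- anchor1[swap]
        anchor1[swap] <- anchor2[swap]
        anchor2[swap] <- tmp
    }
    new("LoopSet", anchorOne = anchor1, anchorTwo = anchor2,
        strength = as.numeric(strength), metadata = metadata)
}

#' @describeIn LoopSet leftmost anchor peaks.
#' @param x a \code{LoopSet}.
#' @export
setMethod("anchorOne", "LoopSet", function(x) x@anchorOne)

#' @describeIn LoopSet rightmost anchor peaks.
#' @export
setMethod("anchorTwo", "LoopSet", function(x) x@anchorTwo)

#' @describeIn LoopSet interaction strengths.
#' @export
setMethod("strength", "LoopSet", function(x) x@strength)

#' @describeIn LoopSet replace interaction strengths.
#' @param value replacement numeric vector.
#' @export
setReplaceMethod("strength", "LoopSet", function(x, value) {
    x@strength <- as.numeric(value)
    validObject(x)
    x
})

#' @export
setMethod("length", "LoopSet", function(x) length(x@anchorOne))

#' @export
setMethod("[", "LoopSet", function(x, i, j, ..., drop = FALSE) {
    new("LoopSet", anchorOne = x@anchorOne[i], anchorTwo = x@anchorTwo[i],
        strength = x@strength[i], metadata = x@metadata)
})

#' @export
setMethod("show", "LoopSet", function(object) {
    cat("LoopSet with", length(object), "interactions on",
        length(unique(as.character(
            GenomicRanges::seqnames(object@anchorOne)))),
        "chromosome(s)\n")
    if (length(object)) {
        s <- object@strength
        cat(sprintf("  strength: min %.3g / median %.3g / max %.3g\n",
                    min(s), stats::median(s), max(s)))
    }
})

#' @export
setMethod("as.data.frame", "LoopSet", function(x, ...) {
    data.frame(
        chrom1 = as.character(GenomicRanges::seqnames(x@anchorOne)),
        start1 = bedStart0(x@anchorOne),
        end1   = bedEnd0(x@anchorOne),
        chrom2 = as.character(GenomicRanges::seqnames(x@anchorTwo)),
        start2 = bedStart0(x@anchorTwo),
        end2   = bedEnd0(x@anchorTwo),
        strength = x@strength,
        stringsAsFactors = FALSE
    )
})

#' ReadTrack: ChIP-Seq read positions with per-chromosome totals
#'
#' Holds sequenced-read intervals (one range per read, duplicates retained)
#' together with the per-chromosome read totals used as the library-size
#' denominator in per-chromosome RPKM normalization.
#'
#' @slot reads \code{GRanges} of read intervals.
#' @slot totals named integer vector; reads per chromosome.
#' @exportClass ReadTrack
setClass("ReadTrack",
    representation(reads = "GRanges", totals = "integer"))

setValidity("ReadTrack", function(object) {
    tab <- table(as.character(GenomicRanges::seqnames(object@reads)))
    tot <- object@totals
    if (length(tot) != length(tab) ||
        !all(sort(names(tot)) == sort(names(tab))) ||
        !all(tot[names(tab)] == as.integer(tab)))
        return("totals must equal the per-chromosome read counts")
    TRUE
})

#' Construct a ReadTrack
#' @param reads \code{GRanges} of read intervals (one per sequenced read).
#' @return A \code{ReadTrack}; totals are derived from \code{reads}.
#' @export
ReadTrack <- function(reads) {
    tab <- table(as.character(GenomicRanges::seqnames(reads)))
    totals <- stats::setNames(as.integer(tab), names(tab))
    new("ReadTrack", reads = reads, totals = totals)
}

#' @describeIn ReadTrack the read intervals.
#' @param x a \code{ReadTrack}.
#' @export
setMethod("reads", "ReadTrack", function(x) x@reads)

#' @describeIn ReadTrack named per-chromosome read totals.
#' @export
setMethod("chromTotals", "ReadTrack", function(x) x@totals)

#' @export
setMethod("length", "ReadTrack", function(x) length(x@reads))

#' @export
setMethod("show", "ReadTrack", function(object) {
    cat("ReadTrack with", length(object@reads), "reads on",
        length(object@totals), "chromosome(s)\n")
})

#' ContactMap: binned symmetric interaction-strength matrix
#'
#' A per-chromosome contact map at a fixed bin size.  Entry (i, j) is the
#' summed strength of all interactions whose anchor centers fall in bins i
#' and j.  The matrix is symmetric with non-negative entries and is stored
#' sparsely.
#'
#' @slot chrom chromosome name.
#' @slot binSize bin width in bp (e.g. 5000, 25000, 500000).
#' @slot counts sparse symmetric numeric matrix, \code{nBins x nBins}.
#' @exportClass ContactMap
setClass("ContactMap",
    representation(chrom = "character", binSize = "integer",
                   counts = "Matrix"))

setValidity("ContactMap", function(object) {
    m <- object@counts
    msgs <- character()
    if (object@binSize <= 0L) msgs <- c(msgs, "binSize must be positive")
    if (nrow(m) != ncol(m)) msgs <- c(msgs, "counts must be square")
    if (!Matrix::isSymmetric(m, tol = 0))
        msgs <- c(msgs, "counts must be symmetric")
    if (length(m@x) && any(m@x < 0))
        msgs <- c(msgs, "counts must be non-negative")
    if (length(msgs)) msgs else TRUE
})

#' Construct a ContactMap
#' @param chrom chromosome name.
#' @param binSize bin width in bp.
#' @param counts square symmetric matrix (dense or sparse).
#' @return A \code{ContactMap}.
#' @export
ContactMap <- function(chrom, binSize, counts) {
    counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                      "generalMatrix"), "CsparseMatrix")
    new("ContactMap", chrom = as.character(chrom),
        binSize = as.integer(binSize), counts = counts)
}

#' @describeIn ContactMap bin width in bp.
#' @param x a \code{ContactMap}.
#' @export
setMethod("binSize", "ContactMap", function(x) x@binSize)

#' @describeIn ContactMap number of bins.
#' @export
setMethod("nBins", "ContactMap", function(x) nrow(x@counts))

#' @describeIn ContactMap the underlying sparse matrix.
#' @export
setMethod("contactMatrix", "ContactMap", function(x) x@counts)

#' @export
setMethod("show", "ContactMap", function(object) {
    cat(sprintf("ContactMap %s: %d bins of %d bp, total mass %.6g\n",
                object@chrom, nrow(object@counts), object@binSize,
                contactMapMass(object)))
})

#' Total mass of a contact map
#'
#' Sum over the upper triangle plus the diagonal, i.e. the total PET
#' strength that went into the map (each interaction counted once).
#' @param map a \code{ContactMap}.
#' @return a number.
#' @export
contactMapMass <- function(map) {
    m <- contactMatrix(map)
    (sum(m) + sum(Matrix::diag(m))) / 2
}

#' FeatureSchema: which model inputs are in play
#'
#' The full schema carries all six features of the two interacting peaks
#' (10 columns); the minimal schema keeps only the RAD21 signal, the
#' genomic distance, the GC content and the CTCF orientation flag
#' (6 columns), dropping exactly the four histone-mark columns.  A custom
#' schema (arbitrary column set) supports the ablation experiments.
#'
#' @slot mode one of \code{"full"}, \code{"minimal"}, \code{"custom"}.
#' @slot columns ordered feature column names.
#' @exportClass FeatureSchema
setClass("FeatureSchema",
    representation(mode = "character", columns = "character"))

.FULL_COLUMNS <- c("distance_kb", "rad21_p1", "rad21_p2",
                   "h3k27ac_p1", "h3k27ac_p2",
                   "h3k27me3_p1", "h3k27me3_p2",
                   "gc_p1", "gc_p2", "ctcf_flag")
.HISTONE_COLUMNS <- c("h3k27ac_p1", "h3k27ac_p2",
                      "h3k27me3_p1", "h3k27me3_p2")

setValidity("FeatureSchema", function(object) {
    if (!object@mode %in% c("full", "minimal", "custom"))
        return("mode must be 'full', 'minimal' or 'custom'")
    if (object@mode == "full" && !identical(object@columns, .FULL_COLUMNS))
        return("full schema must carry the 10 canonical columns")
    if (object@mode == "minimal" &&
        !identical(object@columns, setdiff(.FULL_COLUMNS, .HISTONE_COLUMNS)))
        return("minimal schema must drop exactly the four histone columns")
    if (anyDuplicated(object@columns))
        return("duplicate column names")
    TRUE
})

#' Construct a FeatureSchema
#' @param mode \code{"full"} (10 columns), \code{"minimal"} (6 columns) or
#'   \code{"custom"}.
#' @param columns for \code{"custom"} mode only: the ordered column names.
#' @return A \code{FeatureSchema}.
#' @examples
#' featureSchema("minimal")
#' @export
featureSchema <- function(mode = c("full", "minimal", "custom"),
                          columns = NULL) {
    mode <- match.arg(mode)
    columns <- switch(mode,
        full = .FULL_COLUMNS,
        minimal = setdiff(.FULL_COLUMNS, .HISTONE_COLUMNS),
        custom = {
            if (is.null(columns)) stop("custom schema needs 'columns'")
            as.character(columns)
        })
    new("FeatureSchema", mode = mode, columns = columns)
}

#' @describeIn featureSchema ordered column names of a schema.
#' @param x a \code{FeatureSchema}.
#' @export
setMethod("schemaColumns", "FeatureSchema", function(x) x@columns)

#' @describeIn featureSchema the schema mode.
#' @export
setMethod("schemaMode", "FeatureSchema", function(x) x@mode)

#' @export
setMethod("show", "FeatureSchema", function(object) {
    cat(sprintf("FeatureSchema '%s' (%d columns): %s\n", object@mode,
                length(object@columns),
                paste(object@columns, collapse = ", ")))
})

#' LoopModel: a fitted interaction-strength regressor
#'
#' One trained regressor (deep neural network, random forest or gradient
#' boosting) bound to the feature schema it was trained on, together with
#' the training metadata needed to reproduce it.
#'
#' @slot variant \code{"dnn"}, \code{"rf"} or \code{"gb"}.
#' @slot schema the \code{FeatureSchema} the model expects at prediction.
#' @slot fit fitted state (backend-specific).
#' @slot seed integer seed used for training.
#' @slot metadata list: config used, epochs run (dnn), training size.
#' @exportClass LoopModel
setClass("LoopModel",
    representation(variant = "character", schema = "FeatureSchema",
                   fit = "ANY", seed = "integer", metadata = "list"),
    prototype(metadata = list()))

setValidity("LoopModel", function(object) {
    if (!object@variant %in% c("dnn", "rf", "gb"))
        return("variant must be 'dnn', 'rf' or 'gb'")
    TRUE
})

#' @describeIn LoopModel the model variant.
#' @param x a \code{LoopModel}.
#' @export
setMethod("modelVariant", "LoopModel", function(x) x@variant)

#' @describeIn LoopModel the bound feature schema.
#' @export
setMethod("modelSchema", "LoopModel", function(x) x@schema)

#' @export
setMethod("show", "LoopModel", function(object) {
    cat(sprintf("LoopModel variant '%s' on schema '%s' (%d features)\n",
                object@variant, schemaMode(object@schema),
                length(schemaColumns(object@schema))))
    if (!is.null(object@metadata$epochsRun))
        cat("  dnn epochs run:", object@metadata$epochsRun, "\n")
})
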