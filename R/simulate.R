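## Self-contained synthetic fixtures: a miniature genome with isochore-
## like GC blocks, anchor peaks, enriched ChIP-Seq read pileups
## (anti-correlated active/repressive marks), stranded CTCF motif
## placements, CTCF ChIP peaks, and negative-binomially distributed
## interaction strengths whose mean decays exponentially with genomic
## distance and rises with anchor RAD21 signal and CTCF convergence.
## Every other module is testable against this ground truth without any
## external download.

#' Simulation configuration
#'
#' Defaults define the standard desk-scale fixture: 2 chromosomes of
#' 2 Mb, 80 non-overlapping 2-kb peaks per chromosome, 50,000 reads per
#' track and chromosome with 10-fold enrichment at peaks, isochore-like
#' 100-kb GC blocks spanning 30-70\% GC, motifs in 35\% of peaks with
#' equal strand probabilities, and 5,000 interactions whose
#' negative-binomial mean is
#' \code{mu0 * exp(-d_kb / lambdaKb) * (1 + beta * meanRad21Rpkm) *
#' (1 + gamma * ctcfFlag)} with dispersion \code{k}
#' (variance \code{mu + mu^2 / k}).
#'
#' @param nChromosomes number of chromosomes (named chr1, chr2, ...).
#' @param chromLengthBp chromosome length in bp.
#' @param nPeaksPerChrom anchor peaks per chromosome.
#' @param peakLengthBp peak length in bp (default 2000, the typical
#'   anchor-peak size).
#' @param readsPerChrom reads per ChIP track and chromosome.
#' @param readLengthBp read length in bp.
#' @param enrichmentFold in-peak read density relative to background.
#' @param gcBlockBp isochore block length.
#' @param gcRange GC-fraction range across blocks.
#' @param motifProb probability a peak carries a CTCF motif.
#' @param motifPlusProb probability a motif is on the forward strand.
#' @param ctcfPeakProbMotif,ctcfPeakProbNoMotif probability of a CTCF
#'   ChIP peak at motif-bearing / motif-free anchor peaks (CTCF
#'   occupancy without a detectable motif does occur).
#' @param nInteractions number of interactions to draw.
#' @param mu0 baseline interaction mean at zero distance.
#' @param lambdaKb exponential distance-decay scale in kb.
#' @param beta RAD21-signal coefficient (per RPKM unit).
#' @param gamma convergent-CTCF strength bonus.
#' @param dispersion negative-binomial dispersion k.
#' @param seed base seed; all components draw from named substreams of
#'   it.
#' @return named list of class \code{simConfig}.
#' @export
simConfig <- function(nChromosomes = 2L, chromLengthBp = 2e6L,
                      nPeaksPerChrom = 80L, peakLengthBp = 2000L,
                      readsPerChrom = 50000L, readLengthBp = 36L,
                      enrichmentFold = 10, gcBlockBp = 100000L,
                      gcRange = c(0.3, 0.7), motifProb = 0.35,
                      motifPlusProb = 0.5, ctcfPeakProbMotif = 0.9,
                      ctcfPeakProbNoMotif = 0.5, nInteractions = 5000L,
                      mu0 = 10, lambdaKb = 150, beta = 5e-4, gamma = 1,
                      dispersion = 4, seed = 1L) {
    cfg <- as.list(environment())
    stopifnot(cfg$lambdaKb > 0, cfg$dispersion > 0, cfg$mu0 > 0,
              cfg$motifProb >= 0, cfg$motifProb <= 1,
              cfg$enrichmentFold >= 1,
              cfg$gcRange[1] >= 0, cfg$gcRange[2] <= 1)
    class(cfg) <- c("simConfig", "list")
    cfg
}

.chromNames <- function(config) paste0("chr", seq_len(config$nChromosomes))

#' Simulate a genome with isochore-like GC structure
#'
#' Random sequences whose GC fraction varies block-wise: each
#' \code{gcBlockBp} block draws a target GC uniformly from
#' \code{gcRange} and bases are sampled i.i.d. at that composition.
#'
#' @param config a \link{simConfig}.
#' @return list with named \code{DNAStringSet} \code{genome} and a
#'   data.frame \code{blockGc} of per-block GC targets.
#' @export
simulateGenome <- function(config) {
    set.seed(subSeed(config$seed, "genome"))
    chroms <- .chromNames(config)
    L <- config$chromLengthBp
    blocks <- ceiling(L / config$gcBlockBp)
    seqs <- character(length(chroms))
    blockRows <- list()
    for (ci in seq_along(chroms)) {
        gcT <- runif(blocks, config$gcRange[1], config$gcRange[2])
        blockSeq <- vapply(seq_len(blocks), function(b) {
            len <- min(config$gcBlockBp, L - (b - 1L) * config$gcBlockBp)
            paste(sample(c("A", "T", "G", "C"), len, replace = TRUE,
                         prob = c((1 - gcT[b]) / 2, (1 - gcT[b]) / 2,
                                  gcT[b] / 2, gcT[b] / 2)),
                  collapse = "")
        }, "")
        seqs[ci] <- paste(blockSeq, collapse = "")
        blockRows[[ci]] <- data.frame(
            chrom = chroms[ci],
            blockStart0 = (seq_len(blocks) - 1L) * config$gcBlockBp,
            gcTarget = gcT)
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chroms
    list(genome = genome, blockGc = do.call(rbind, blockRows))
}

#' Simulate anchor peaks, ChIP-Seq read tracks, motifs and CTCF peaks
#'
#' Peaks are placed non-overlapping on a jittered grid.  Reads are drawn
#' as uniform background plus in-peak excess such that in-peak density is
#' \code{enrichmentFold} times background on average; RAD21 enrichment
#' varies per peak (gamma-distributed multiplier), while H3K27ac and
#' H3K27me3 enrichment follow a per-peak activity level a and 1 - a
#' respectively, making the two marks anti-correlated across peaks.
#' Motifs are placed inside peaks with the configured presence and strand
#' probabilities; CTCF ChIP peaks co-locate with a configurable subset of
#' motif-bearing (and a few motif-free) peaks.
#'
#' @param config a \link{simConfig}.
#' @param genome result of \link{simulateGenome} (unused beyond length
#'   checks; present so callers can thread one object through).
#' @return list with \code{peaks} (GRanges), \code{tracks} (named list of
#'   \link{ReadTrack}: rad21, h3k27ac, h3k27me3), \code{motifs}
#'   (stranded, scored GRanges), \code{ctcfPeaks} (GRanges) and the
#'   per-peak \code{peakInfo} data.frame.
#' @export
simulatePeaksAndTracks <- function(config, genome = NULL) {
    chroms <- .chromNames(config)
    L <- config$chromLengthBp
    nP <- config$nPeaksPerChrom
    pl <- config$peakLengthBp
    spacing <- L %/% nP
    if (pl >= spacing)
        stop("peaks cannot fit on the chromosome without overlap")

    set.seed(subSeed(config$seed, "peaks"))
    peakList <- list()
    for (ch in chroms) {
        jitter <- floor(runif(nP, 0, spacing - pl))
        start0 <- (seq_len(nP) - 1L) * spacing + jitter
        peakList[[ch]] <- grFromBed(ch, start0, start0 + pl)
    }
    peaks <- suppressWarnings(do.call(c, unname(peakList)))
    peaks$peakId <- seq_along(peaks)

    nPeaksAll <- length(peaks)
    set.seed(subSeed(config$seed, "peak-levels"))
    rad21Mult <- stats::rgamma(nPeaksAll, shape = 4, rate = 4)
    activity <- stats::rbeta(nPeaksAll, 2, 2)
    multipliers <- list(rad21 = rad21Mult,
                        h3k27ac = 2 * activity,
                        h3k27me3 = 2 * (1 - activity))

    tracks <- list()
    for (trk in names(multipliers)) {
        set.seed(subSeed(config$seed, paste0("reads-", trk)))
        grs <- list()
        for (ch in chroms) {
            pIdx <- which(as.character(
                GenomicRanges::seqnames(peaks)) == ch)
            m <- multipliers[[trk]][pIdx]
            ## component weights: whole-chromosome background plus
            ## (fold - 1) x multiplier excess inside each peak
            wts <- c(L, (config$enrichmentFold - 1) * m * pl)
            comp <- sample.int(length(wts), config$readsPerChrom,
                               replace = TRUE, prob = wts)
            pos <- integer(config$readsPerChrom)
            bg <- comp == 1L
            pos[bg] <- floor(runif(sum(bg), 0, L - config$readLengthBp))
            if (any(!bg)) {
                pk <- pIdx[comp[!bg] - 1L]
                pos[!bg] <- bedStart0(peaks)[pk] +
                    floor(runif(sum(!bg), 0, pl - config$readLengthBp))
            }
            grs[[ch]] <- grFromBed(ch, pos, pos + config$readLengthBp)
        }
        tracks[[trk]] <- ReadTrack(suppressWarnings(do.call(c, unname(grs))))
    }

    set.seed(subSeed(config$seed, "motifs"))
    hasMotif <- runif(nPeaksAll) < config$motifProb
    motifStrand <- ifelse(runif(nPeaksAll) < config$motifPlusProb,
                          "+", "-")
    motifWidth <- 19L
    off <- floor(runif(nPeaksAll, 0, pl - motifWidth))
    mi <- which(hasMotif)
    motifs <- grFromBed(
        as.character(GenomicRanges::seqnames(peaks))[mi],
        bedStart0(peaks)[mi] + off[mi],
        bedStart0(peaks)[mi] + off[mi] + motifWidth,
        strand = motifStrand[mi],
        score = round(runif(length(mi), 5, 15), 3))

    set.seed(subSeed(config$seed, "ctcf-peaks"))
    pOcc <- ifelse(hasMotif, config$ctcfPeakProbMotif,
                   config$ctcfPeakProbNoMotif)
    occ <- which(runif(nPeaksAll) < pOcc)
    ctcfHalf <- 250L
    centers <- peakCenter0(peaks)[occ]
    ctcfPeaks <- grFromBed(
        as.character(GenomicRanges::seqnames(peaks))[occ],
        pmax(centers - ctcfHalf, 0L), centers + ctcfHalf)

    peakInfo <- data.frame(
        peakId = seq_len(nPeaksAll),
        chrom = as.character(GenomicRanges::seqnames(peaks)),
        start0 = bedStart0(peaks), end0 = bedEnd0(peaks),
        rad21Mult = rad21Mult, activity = activity,
        hasMotif = hasMotif,
        motifStrand = ifelse(hasMotif, motifStrand, NA_character_),
        ctcfOccupied = seq_len(nPeaksAll) %in% occ)

    list(peaks = peaks, tracks = tracks, motifs = motifs,
         ctcfPeaks = ctcfPeaks, peakInfo = peakInfo)
}

#' Simulate interactions with known ground truth
#'
#' Samples distinct same-chromosome peak pairs and draws each strength
#' from NB(mean mu, dispersion k) with
#' \code{mu = mu0 * exp(-d_kb / lambdaKb) * (1 + beta * meanRad21Rpkm) *
#' (1 + gamma * ctcfFlag)}, where the RAD21 RPKM and the convergence flag
#' are the realized values computed from the simulated tracks and motifs
#' — so a model trained on the extracted features can in principle
#' recover \code{mu}.
#'
#' @param config a \link{simConfig}.
#' @param peaks peak \code{GRanges} from \link{simulatePeaksAndTracks}.
#' @param rad21Rpkm per-peak RAD21 RPKM (parallel to \code{peaks}).
#' @param motifStrand per-peak motif strand (\code{"+"}, \code{"-"} or
#'   \code{NA}), parallel to \code{peaks}.
#' @return list with \code{loops} (a \link{LoopSet}) and \code{truth}
#'   (data.frame with the generative mean \code{mu} and the feature
#'   values used).
#' @export
simulateInteractions <- function(config, peaks, rad21Rpkm, motifStrand) {
    chrom <- as.character(GenomicRanges::seqnames(peaks))
    pairRows <- list()
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        if (length(idx) < 2L) stop("need at least 2 peaks per chromosome")
        cmb <- utils::combn(idx, 2L)
        pairRows[[ch]] <- data.frame(i = cmb[1L, ], j = cmb[2L, ])
    }
    pairs <- do.call(rbind, pairRows)
    set.seed(subSeed(config$seed, "pair-sample"))
    nDraw <- min(config$nInteractions, nrow(pairs))
    pick <- pairs[sample.int(nrow(pairs), nDraw), , drop = FALSE]

    ## order each pair leftmost-first so flag orientation is well defined
    swap <- GenomicRanges::start(peaks)[pick$j] <
        GenomicRanges::start(peaks)[pick$i]
    tmp <- pick$i[swap]; pick$i[swap] <- pick$j[swap]; pick$j[swap] <- tmp

    a1 <- peaks[pick$i]
    a2 <- peaks[pick$j]
    dKb <- genomicDistanceKb(a1, a2)
    radMean <- (rad21Rpkm[pick$i] + rad21Rpkm[pick$j]) / 2
    flag <- ctcfOrientationFlag(motifStrand[pick$i], motifStrand[pick$j])
    mu <- config$mu0 * exp(-dKb / config$lambdaKb) *
        (1 + config$beta * radMean) * (1 + config$gamma * flag)
    set.seed(subSeed(config$seed, "strength-draw"))
    s <- rnbinom(nDraw, size = config$dispersion, mu = mu)

    truth <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(a1)),
        peak1 = pick$i, peak2 = pick$j,
        distanceKb = dKb, rad21Mean = radMean, ctcfFlag = flag,
        mu = mu, strength = s)
    list(loops = LoopSet(a1, a2, s), truth = truth)
}

#' Simulate the complete fixture
#'
#' Runs \link{simulateGenome}, \link{simulatePeaksAndTracks} and
#' \link{simulateInteractions} in sequence, computing the realized
#' per-peak RAD21 RPKM and motif strands that feed the interaction
#' model.
#'
#' @param config a \link{simConfig}.
#' @return list with \code{genome}, \code{blockGc}, \code{peaks},
#'   \code{tracks}, \code{motifs}, \code{ctcfPeaks}, \code{peakInfo},
#'   \code{loops}, \code{truth} and the \code{config} used.
#' @export
simulateDataset <- function(config = simConfig()) {
    gen <- simulateGenome(config)
    pt <- simulatePeaksAndTracks(config, gen$genome)
    counts <- countReadsInPeaks(pt$tracks$rad21, pt$peaks)
    tot <- chromTotals(pt$tracks$rad21)[
        as.character(GenomicRanges::seqnames(pt$peaks))]
    rad21Rpkm <- rpkm(counts, tot, GenomicRanges::width(pt$peaks))
    motifAssign <- assignMotifToPeaks(pt$motifs, pt$peaks)
    sim <- simulateInteractions(config, pt$peaks, rad21Rpkm,
                                motifAssign$strand)
    c(gen, pt, sim, list(config = config))
}
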