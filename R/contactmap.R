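## Binned contact maps from peak-level interactions, plus the smoothing
## and stratification used by the stratum-adjusted correlation.

#' Bin peak-level interactions into a contact map
#'
#' Each anchor is assigned to the bin containing its peak center
#' (\code{floor(center / binSize)}, BED coordinates); the map value of a
#' bin pair is the summed strength of all interactions mapping there.
#' Total map mass (upper triangle + diagonal) therefore equals total
#' input strength exactly.
#'
#' @param loops a \link{LoopSet}, all on one chromosome.
#' @param binSizeBp bin width in bp (> 0).
#' @param chromLengthBp chromosome length in bp; fixes the number of bins.
#' @return A \link{ContactMap}.
#' @export
binInteractions <- function(loops, binSizeBp, chromLengthBp) {
    stopifnot(binSizeBp > 0, chromLengthBp >= binSizeBp)
    chroms <- unique(as.character(GenomicRanges::seqnames(anchorOne(loops))))
    if (length(chroms) > 1)
        stop("all interactions must be on one chromosome")
    chrom <- if (length(chroms)) chroms else NA_character_
    nb <- as.integer(ceiling(chromLengthBp / binSizeBp))
    c1 <- peakCenter0(anchorOne(loops))
    c2 <- peakCenter0(anchorTwo(loops))
    if (length(c1) && any(c(c1, c2) >= chromLengthBp))
        stop("anchor center beyond chromosome length")
    i <- c1 %/% binSizeBp + 1L
    j <- c2 %/% binSizeBp + 1L
    s <- strength(loops)
    off <- i != j
    m <- Matrix::sparseMatrix(i = c(i, j[off]), j = c(j, i[off]),
                              x = c(s, s[off]), dims = c(nb, nb))
    ContactMap(chrom, binSizeBp, m)
}

#' Mean-filter smoothing of a contact map
#'
#' Replaces each entry with the mean over the (2h+1) x (2h+1) window
#' centered on it, truncated at the matrix borders (the mean is over
#' in-bounds cells only), as done before stratum-adjusted correlation to
#' suppress noise.  \code{h = 0} is the identity.
#'
#' @param map a \link{ContactMap}.
#' @param h non-negative integer window half-size.
#' @return A smoothed \code{ContactMap}.
#' @export
smoothMap <- function(map, h) {
    stopifnot(h >= 0)
    h <- as.integer(h)
    if (h == 0L) return(map)
    m <- as.matrix(contactMatrix(map))
    n <- nrow(m)
    if (n == 1L) return(map)
    ## summed-area table: sat[i+1, j+1] = sum(m[1:i, 1:j])
    sat <- matrix(0, n + 1L, n + 1L)
    cs <- apply(m, 2L, cumsum)
    sat[-1L, -1L] <- t(apply(cs, 1L, cumsum))
    idx <- seq_len(n)
    lo <- pmax(idx - h, 1L)
    hi <- pmin(idx + h, n)
    ## window sum over rows lo_i..hi_i, cols lo_j..hi_j via inclusion-
    ## exclusion on the summed-area table
    S <- sat[hi + 1L, hi + 1L, drop = FALSE] -
         sat[lo, hi + 1L, drop = FALSE] -
         sat[hi + 1L, lo, drop = FALSE] +
         sat[lo, lo, drop = FALSE]
    counts <- outer(hi - lo + 1L, hi - lo + 1L)
    ContactMap(map@chrom, binSize(map), S / counts)
}

#' Split a contact map into distance strata
#'
#' Stratum k (k = 0 ... floor(maxDistanceBp / binSize)) is the vector of
#' entries at diagonal offset k, i.e. all bin pairs at genomic distance
#' k bins; strata beyond the maximum distance are excluded.
#'
#' @param map a \link{ContactMap}.
#' @param maxDistanceBp maximum genomic distance to retain (>= bin size).
#' @return list of numeric vectors, one per stratum (offset 0 first).
#' @export
stratify <- function(map, maxDistanceBp) {
    if (maxDistanceBp < binSize(map))
        stop("maxDistanceBp must be at least one bin")
    m <- as.matrix(contactMatrix(map))
    n <- nrow(m)
    kMax <- min(maxDistanceBp %/% binSize(map), n - 1L)
    lapply(0:kMax, function(k) {
        i <- seq_len(n - k)
        m[cbind(i, i + k)]
    })
}

#' Coarsen a contact map to a larger bin size
#'
#' Re-bins by summing blocks; used to check binning consistency (binning
#' at B then coarsening to 2B equals direct binning at 2B).
#'
#' @param map a \link{ContactMap}.
#' @param factor integer coarsening factor (>= 1).
#' @return A \code{ContactMap} at \code{factor * binSize}.
#' @export
coarsenMap <- function(map, factor) {
    stopifnot(factor >= 1, factor == as.integer(factor))
    factor <- as.integer(factor)
    if (factor == 1L) return(map)
    m <- as.matrix(contactMatrix(map))
    n <- nrow(m)
    nb <- as.integer(ceiling(n / factor))
    grp <- (seq_len(n) - 1L) %/% factor + 1L
    agg <- rowsum(t(rowsum(m, grp)), grp)
    agg <- agg[seq_len(nb), seq_len(nb), drop = FALSE]
    dimnames(agg) <- NULL
    ContactMap(map@chrom, binSize(map) * factor, agg)
}
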