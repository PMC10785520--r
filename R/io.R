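## Readers and writers for the plain-text genomics formats the pipeline
## touches: BED3+ (peaks, reads), BED6 (motif hits), BEDPE + strength
## column (interactions, reference loop lists), FASTA (genome), and a
## sparse-triplet text serialization for contact maps.
##
## BED input is 0-based half-open and taken verbatim; ranges are converted
## to the 1-based GRanges convention internally and written back out in
## BED coordinates, so read/write round-trips are exact.

## Split a BED-like file into whitespace-delimited fields, dropping
## comment/track/browser lines but remembering original line numbers for
## error messages.
.readBedLines <- function(path) {
    lines <- readLines(path)
    keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
    list(fields = strsplit(trimws(lines[keep]), "[ \t]+"),
         lineno = which(keep))
}

.parseCoords <- function(fields, lineno, path, startCol = 2L, endCol = 3L) {
    s <- suppressWarnings(as.integer(vapply(fields, `[`, "", startCol)))
    e <- suppressWarnings(as.integer(vapply(fields, `[`, "", endCol)))
    bad <- which(is.na(s) | is.na(e) | e <= s | s < 0L)
    if (length(bad))
        stop(sprintf("%s: malformed interval at line %d (%s)", path,
                     lineno[bad[1]],
                     paste(fields[[bad[1]]], collapse = "\t")))
    list(start0 = s, end0 = e)
}

#' Read peak intervals from a BED file
#'
#' @param path BED3+ file (tab- or space-separated); comment, track and
#'   browser lines are tolerated.
#' @return \code{GRanges} of peaks, in file order.  Malformed lines
#'   (non-integer coordinates, end <= start) raise an error naming the
#'   line number.
#' @export
readPeaks <- function(path) {
    p <- .readBedLines(path)
    if (!length(p$fields))
        return(GenomicRanges::GRanges())
    nc <- vapply(p$fields, length, 1L)
    if (any(nc < 3L))
        stop(sprintf("%s: fewer than 3 columns at line %d", path,
                     p$lineno[which(nc < 3L)[1]]))
    chrom <- vapply(p$fields, `[`, "", 1L)
    co <- .parseCoords(p$fields, p$lineno, path)
    grFromBed(chrom, co$start0, co$end0)
}

#' Read ChIP-Seq reads into a ReadTrack
#'
#' One BED row per sequenced read; duplicates are retained (no
#' deduplication is applied), and the per-chromosome totals are the plain
#' row counts.
#'
#' @inheritParams readPeaks
#' @return A \link{ReadTrack}.
#' @export
readReads <- function(path) {
    ReadTrack(readPeaks(path))
}

#' Read CTCF motif hits from a BED6 file
#'
#' Column 5 is the motif score, column 6 the strand.  Hits with strand
#' \code{"."} (unknown orientation) are discarded with a warning; any
#' other strand symbol is an error, as is a row with fewer than six
#' columns.
#'
#' @inheritParams readPeaks
#' @return \code{GRanges} with \code{score} metadata column and strand
#'   set, in file order.
#' @export
readMotifHits <- function(path) {
    p <- .readBedLines(path)
    if (!length(p$fields))
        return(GenomicRanges::GRanges(score = numeric()))
    nc <- vapply(p$fields, length, 1L)
    if (any(nc < 6L))
        stop(sprintf("%s: BED6 required, fewer than 6 columns at line %d",
                     path, p$lineno[which(nc < 6L)[1]]))
    chrom <- vapply(p$fields, `[`, "", 1L)
    co <- .parseCoords(p$fields, p$lineno, path)
    score <- suppressWarnings(as.numeric(vapply(p$fields, `[`, "", 5L)))
    strand <- vapply(p$fields, `[`, "", 6L)
    badStrand <- !strand %in% c("+", "-", ".")
    if (any(badStrand))
        stop(sprintf("%s: invalid strand '%s' at line %d", path,
                     strand[which(badStrand)[1]],
                     p$lineno[which(badStrand)[1]]))
    unknown <- strand == "."
    if (any(unknown)) {
        warning(sprintf("%s: %d motif hit(s) with unknown strand discarded",
                        path, sum(unknown)))
    }
    keep <- !unknown
    grFromBed(chrom[keep], co$start0[keep], co$end0[keep],
              strand = strand[keep], score = score[keep])
}

#' Read a genome FASTA
#'
#' Sequences are uppercased; the header token before the first whitespace
#' becomes the sequence name.  Duplicate names are an error.
#'
#' @param path FASTA file.
#' @return A named \link[Biostrings]{DNAStringSet}.
#' @export
readGenome <- function(path) {
    seqs <- Biostrings::readDNAStringSet(path)
    nm <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(nm))
        stop(sprintf("%s: duplicate sequence name '%s'", path,
                     nm[duplicated(nm)][1]))
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
    names(seqs) <- nm
    seqs
}

#' Read pairwise anchor interactions (BEDPE + strength column)
#'
#' Columns 1-6 are the two anchors (BED coordinates); \code{strengthColumn}
#' (default 7, configurable because post-processing pipelines differ in
#' their extra columns) holds the integer PET count.  Inter-chromosomal
#' rows are dropped — the models are defined on intra-chromosomal
#' interactions only — and the number dropped is recorded in
#' \code{metadata(x)$interChromDropped} and reported via \code{message()}.
#' Anchors are reordered so that anchor one is the leftmost.
#'
#' @param path BEDPE-like file.
#' @param strengthColumn 1-based index of the strength column.
#' @return A \link{LoopSet}.
#' @export
readInteractions <- function(path, strengthColumn = 7L) {
    p <- .readBedLines(path)
    if (!length(p$fields)) {
        return(LoopSet(GenomicRanges::GRanges(), GenomicRanges::GRanges(),
                       numeric(), metadata = list(interChromDropped = 0L)))
    }
    nc <- vapply(p$fields, length, 1L)
    if (any(nc < strengthColumn))
        stop(sprintf("%s: strength column %d missing at line %d", path,
                     strengthColumn, p$lineno[which(nc < strengthColumn)[1]]))
    chrom1 <- vapply(p$fields, `[`, "", 1L)
    chrom2 <- vapply(p$fields, `[`, "", 4L)
    co1 <- .parseCoords(p$fields, p$lineno, path, 2L, 3L)
    co2 <- .parseCoords(p$fields, p$lineno, path, 5L, 6L)
    s <- suppressWarnings(as.numeric(vapply(p$fields, `[`, "",
                                            strengthColumn)))
    bad <- which(is.na(s) | s < 0)
    if (length(bad))
        stop(sprintf("%s: missing or negative strength at line %d", path,
                     p$lineno[bad[1]]))
    intra <- chrom1 == chrom2
    nDropped <- sum(!intra)
    if (nDropped)
        message(sprintf("%s: dropped %d inter-chromosomal record(s)", path,
                        nDropped))
    a1 <- grFromBed(chrom1[intra], co1$start0[intra], co1$end0[intra])
    a2 <- grFromBed(chrom2[intra], co2$start0[intra], co2$end0[intra])
    LoopSet(a1, a2, s[intra],
            metadata = list(interChromDropped = as.integer(nDropped)))
}

#' Write a LoopSet as BEDPE + strength column
#'
#' Inverse of \link{readInteractions}: seven tab-separated columns in BED
#' coordinates, anchors leftmost-first.
#'
#' @param x a \code{LoopSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeInteractions <- function(x, path) {
    df <- as.data.frame(x)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write peaks / generic ranges as BED
#' @param gr a \code{GRanges}; if a \code{score} column and strand are
#'   present, BED6 is written (name column set to \code{"."}).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(gr, path) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = bedStart0(gr), end = bedEnd0(gr))
    if (!is.null(gr$score)) {
        df$name <- "."
        df$score <- gr$score
        df$strand <- as.character(GenomicRanges::strand(gr))
    }
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Serialize / deserialize a ContactMap as sparse text triplets
#'
#' Tab-separated rows \code{bin_i bin_j value} (0-based bins, upper
#' triangle only) preceded by a header line recording chromosome, bin size
#' and bin count.
#'
#' @param map a \code{ContactMap}.
#' @param path output (input) file.
#' @return \code{path} invisibly (\code{writeContactMap});
#'   a \code{ContactMap} (\code{readContactMap}).
#' @export
writeContactMap <- function(map, path) {
    m <- contactMatrix(map)
    tri <- Matrix::which(Matrix::triu(m != 0), arr.ind = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#chrom=%s\tbin_size=%d\tn_bins=%d", map@chrom,
                       binSize(map), nBins(map)), con)
    if (nrow(tri))
        writeLines(sprintf("%d\t%d\t%.10g", tri[, 1] - 1L, tri[, 2] - 1L,
                           m[tri]), con)
    invisible(path)
}

#' @rdname writeContactMap
#' @export
readContactMap <- function(path) {
    lines <- readLines(path)
    hdr <- lines[1]
    if (!startsWith(hdr, "#chrom="))
        stop(sprintf("%s: missing contact-map header", path))
    kv <- strsplit(strsplit(sub("^#", "", hdr), "\t")[[1]], "=")
    vals <- stats::setNames(vapply(kv, `[`, "", 2L),
                            vapply(kv, `[`, "", 1L))
    n <- as.integer(vals["n_bins"])
    body <- lines[-1]
    if (length(body)) {
        f <- do.call(rbind, strsplit(body, "\t"))
        i <- as.integer(f[, 1]) + 1L
        j <- as.integer(f[, 2]) + 1L
        x <- as.numeric(f[, 3])
        m <- Matrix::sparseMatrix(i = c(i, j[i != j]), j = c(j, i[i != j]),
                                  x = c(x, x[i != j]), dims = c(n, n))
    } else {
        m <- Matrix::sparseMatrix(i = integer(), j = integer(),
                                  x = numeric(), dims = c(n, n))
    }
    ContactMap(vals["chrom"], as.integer(vals["bin_size"]), m)
}

#' Write a feature matrix with its target column
#'
#' Tab-separated table whose header names the schema columns; the final
#' column \code{strength} is the regression target.
#'
#' @param x numeric feature matrix with column names.
#' @param y numeric target vector (may be omitted for prediction-only
#'   feature files).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFeatureMatrix <- function(x, path, y = NULL) {
    df <- as.data.frame(x)
    if (!is.null(y)) df$strength <- y
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
    invisible(path)
}

#' @rdname writeFeatureMatrix
#' @return \code{readFeatureMatrix}: list with matrix \code{x} and,
#'   if present in the file, target \code{y}.
#' @export
readFeatureMatrix <- function(path) {
    df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
    if ("strength" %in% names(df)) {
        y <- df$strength
        df$strength <- NULL
        list(x = as.matrix(df), y = y)
    } else {
        list(x = as.matrix(df), y = NULL)
    }
}
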