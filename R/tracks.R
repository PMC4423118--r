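## Tracks module: signal-track I/O, fragment -> dyad-density conversion,
## normalization, and TSS-window scoring.

#' Read a genomic signal track (bedGraph or fixedStep wiggle)
#'
#' bedGraph intervals are 0-based half-open, wiggle positions 1-based; both
#' are converted to the internal per-bp representation.  Positions not
#' covered by any record are missing (\code{NA}).  Overlapping bedGraph
#' intervals and coordinates beyond the stated chromosome size are hard
#' errors reporting the offending (1-based) record indices.
#'
#' @param path bedGraph or wiggle file.
#' @param format "bedGraph" or "wig".
#' @param chromSizes named integer vector, or path to a two-column TSV.
#' @param scale "linear" or "log2_ratio" (declares the value scale).
#' @param label free-text track label (defaults to the file name).
#' @return An \linkS4class{OccupancyTrack}.
#' @export
readTrack <- function(path, format = c("bedGraph", "wig"), chromSizes,
                      scale = c("linear", "log2_ratio"),
                      label = basename(path)) {
    format <- match.arg(format)
    scale <- match.arg(scale)
    if (is.character(chromSizes) && length(chromSizes) == 1L)
        chromSizes <- readChromSizes(chromSizes)
    gr <- rtracklayer::import(path,
                              format = if (format == "wig") "WIG"
                                       else "bedGraph")
    chrom <- as.character(GenomicRanges::seqnames(gr))
    start0 <- BiocGenerics::start(gr) - 1L   # GRanges 1-based -> internal
    end0 <- BiocGenerics::end(gr)
    sz <- chromSizes[chrom]
    bad <- is.na(sz) | start0 < 0L | end0 > sz
    if (any(bad))
        stopf("track record(s) beyond chrom size: %s",
              paste(which(bad), collapse = ", "))
    if (format == "bedGraph") {
        self <- IRanges::findOverlaps(IRanges::IRanges(start0 + 1L, end0),
                                      drop.self = TRUE)
        perChr <- chrom[S4Vectors::queryHits(self)] ==
            chrom[S4Vectors::subjectHits(self)]
        if (any(perChr))
            stopf("overlapping bedGraph interval(s): %s",
                  paste(unique(S4Vectors::queryHits(self)[perChr]),
                        collapse = ", "))
    }
    signal <- lapply(chromSizes, function(n) rep(NA_real_, n))
    val <- as.numeric(gr$score)
    for (i in seq_along(gr)) {
        signal[[chrom[i]]][(start0[i] + 1L):end0[i]] <- val[i]
    }
    OccupancyTrack(signal, scale = scale, label = label)
}

#' Write an OccupancyTrack as bedGraph
#'
#' Runs of identical consecutive defined values are merged into bedGraph
#' intervals; missing positions are left uncovered.  Values are printed
#' with full precision so that a write/read round trip is bit-identical.
#'
#' @param track an \linkS4class{OccupancyTrack}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeTrack <- function(track, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (chr in names(track@signal)) {
        v <- track@signal[[chr]]
        r <- rle(ifelse(is.na(v), "NA", sprintf("%.17g", v)))
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths   # 0-based starts
        keep <- r$values != "NA"
        if (any(keep))
            writeLines(sprintf("%s\t%d\t%d\t%s", chr, starts[keep],
                               ends[keep], r$values[keep]), con)
    }
    invisible(path)
}

#' Read mono-nucleosome fragments from BED3
#'
#' Fragments are filtered to plausible mono-nucleosome lengths (the
#' standard MNase mono-nucleosome band, 120-180 bp by default) before any
#' downstream use.
#'
#' @param path BED3 file (chrom, start, end; 0-based half-open).
#' @param chromSizes named integer vector, or path to a two-column TSV.
#' @param minLength,maxLength inclusive fragment-length bounds.
#' @return A data.frame with columns \code{chrom}, \code{start},
#'   \code{end}; the number of length-filtered records is kept in
#'   \code{attr(, "filtered")}.
#' @export
readFragments <- function(path, chromSizes, minLength = 120L,
                          maxLength = 180L) {
    if (is.character(chromSizes) && length(chromSizes) == 1L)
        chromSizes <- readChromSizes(chromSizes)
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)[, 1:3]
    names(df) <- c("chrom", "start", "end")
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
    if (any(df$start >= df$end))
        stopf("fragment record(s) with start >= end: %s",
              paste(which(df$start >= df$end), collapse = ", "))
    sz <- chromSizes[df$chrom]
    bad <- is.na(sz) | df$start < 0L | df$end > sz
    if (any(bad))
        stopf("fragment record(s) beyond chrom size: %s",
              paste(which(bad), collapse = ", "))
    len <- df$end - df$start
    keep <- len >= minLength & len <= maxLength
    out <- df[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "filtered") <- sum(!keep)
    out
}

## Discrete Gaussian kernel of bandwidth bw, truncated at +/- 6 bw so that
## the discarded tail mass (< 2e-9) stays well under the 1e-6 mass budget.
gaussKernel <- function(bw) {
    r <- ceiling(6 * bw)
    k <- exp(-((-r:r)^2) / (2 * bw^2))
    k / sum(k)
}

#' Convert fragment midpoints into a smoothed dyad-density track
#'
#' Each fragment contributes unit mass at its midpoint
#' \code{floor((start+end)/2)} (the dyad proxy for mono-nucleosome
#' fragments), then a Gaussian kernel of the stated bandwidth is applied
#' per chromosome.  Total mass is renormalized to the fragment count, so
#' mass lost to chromosome-edge truncation is redistributed and the track
#' sum equals the number of fragments to within 1e-6 relative error.
#'
#' @param fragments data.frame from \code{\link{readFragments}}.
#' @param chromSizes named integer vector of chromosome lengths.
#' @param smoothingBw Gaussian kernel bandwidth in bp; 0 gives the raw
#'   midpoint histogram (integer counts).
#' @return A linear-scale \linkS4class{OccupancyTrack}.
#' @export
midpointOccupancy <- function(fragments, chromSizes, smoothingBw = 20) {
    if (nrow(fragments) == 0L) {
        warnf("empty fragment set: returning all-zero track")
        return(OccupancyTrack(lapply(chromSizes, numeric),
                              scale = "linear", label = "dyad density"))
    }
    mid <- (fragments$start + fragments$end) %/% 2L
    k <- if (smoothingBw > 0) gaussKernel(smoothingBw) else 1
    r <- (length(k) - 1L) %/% 2L
    signal <- lapply(names(chromSizes), function(chr) {
        n <- chromSizes[[chr]]
        m <- mid[fragments$chrom == chr]
        counts <- tabulate(m + 1L, nbins = n)
        if (smoothingBw > 0 && length(m)) {
            padded <- c(numeric(r), counts, numeric(r))
            sm <- stats::filter(padded, k, sides = 2)
            counts <- as.numeric(sm[(r + 1L):(r + n)])
            counts[counts < 0] <- 0
        }
        as.numeric(counts)
    })
    names(signal) <- names(chromSizes)
    total <- sum(vapply(signal, sum, numeric(1)))
    if (total > 0) signal <- lapply(signal, function(v)
        v * (nrow(fragments) / total))
    OccupancyTrack(signal, scale = "linear", label = "dyad density")
}

#' Quantile normalization across replicate vectors
#'
#' After the transform, the sorted values of every column are identical and
#' equal the across-column mean of order statistics; within-column rank
#' order is preserved and ties receive the mean of the tied target values.
#' The transform is idempotent.  Missing values are not supported.
#'
#' @param x numeric matrix (columns = replicates) or a list of equal-length
#'   numeric vectors.
#' @return Object of the same shape as \code{x}, quantile normalized.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantileNormalize <- function(x) {
    wasList <- is.list(x)
    if (wasList) {
        if (length(unique(lengths(x))) != 1L)
            stopf("vectors must have equal length")
        m <- do.call(cbind, x)
    } else m <- as.matrix(x)
    if (ncol(m) < 2L) stopf("need at least two vectors/columns")
    if (anyNA(m)) stopf("missing values are not supported")
    out <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(out) <- dimnames(m)
    if (wasList) {
        res <- lapply(seq_len(ncol(out)), function(j) out[, j])
        names(res) <- names(x)
        res
    } else out
}

#' Genome-wide mean of the defined positions of a track
#'
#' @param track an \linkS4class{OccupancyTrack}.
#' @return A single number.
#' @export
genomeMean <- function(track) {
    s <- sum(vapply(track@signal, function(v) sum(v, na.rm = TRUE),
                    numeric(1)))
    n <- sum(vapply(track@signal, function(v) sum(!is.na(v)), numeric(1)))
    if (n == 0L) stopf("track has no defined positions")
    s / n
}

#' Express a linear track as log2 occupancy relative to the genome average
#'
#' \code{out = log2((v + eps) / (m + eps))} with \code{m} the genome-wide
#' mean over defined positions and pseudocount \code{eps = 0.1 m}, which
#' bounds the log at empty positions (at \code{log2(1/11) = -3.46}) without
#' distorting typical signal.  The genome-wide mean of \code{2^out} is 1 by
#' construction, and the transform is invariant under rescaling the input.
#'
#' @param track a linear-scale \linkS4class{OccupancyTrack}.
#' @return A log2_ratio \linkS4class{OccupancyTrack}.
#' @export
normalizeToGenomeMean <- function(track) {
    if (track@scale != "linear") stopf("track must be linear scale")
    m <- genomeMean(track)
    if (m <= 0) stopf("genome-wide mean must be positive (all-zero track?)")
    eps <- 0.1 * m
    signal <- lapply(track@signal, function(v) log2((v + eps) / (m + eps)))
    OccupancyTrack(signal, scale = "log2_ratio",
                   label = paste0(track@label, " (log2/genome mean)"))
}

#' Score a track in TSS-anchored windows for every gene
#'
#' Cell (g, w) is the mean of the defined track values over window w's
#' genomic footprint, with windows ordered gene-5'-to-3' (column offsets
#' are oriented, so minus-strand genes read their genomic neighborhood in
#' reverse).  A cell is masked if it is neighbor-masked, extends off the
#' chromosome, or more than 50\% of its bases are missing.  Genes on
#' chromosomes absent from the track get fully masked rows with a warning.
#'
#' @param track an \linkS4class{OccupancyTrack}.
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param frame a \linkS4class{PromoterFrame}.
#' @param mask optional neighbor mask from \code{\link{neighborMask}};
#'   computed from \code{annotation} when NULL.
#' @return A \linkS4class{WindowMatrix}.
#' @export
scoreWindows <- function(track, annotation, frame = promoterFrame(),
                         mask = NULL) {
    tx <- annotation@transcripts
    nw <- nWindows(frame)
    w <- frame@window
    if (is.null(mask)) mask <- neighborMask(annotation, frame)
    stopifnot(identical(rownames(mask), tx$id), ncol(mask) == nw)
    scores <- matrix(NA_real_, nrow(tx), nw,
                     dimnames = list(tx$id, windowOffsets(frame)))
    valid <- matrix(FALSE, nrow(tx), nw, dimnames = dimnames(scores))
    missingChrom <- character(0)
    for (chr in unique(tx$chrom)) {
        idx <- which(tx$chrom == chr)
        v <- track@signal[[chr]]
        if (is.null(v)) { missingChrom <- c(missingChrom, chr); next }
        n <- length(v)
        S <- c(0, cumsum(ifelse(is.na(v), 0, v)))
        C <- c(0L, cumsum(!is.na(v)))
        for (i in idx) {
            fp <- windowFootprints(tx$tss[i], tx$strand[i], frame)
            s <- pmin(pmax(fp[, "start"], 0L), n)
            e <- pmin(pmax(fp[, "end"], 0L), n)
            cnt <- ifelse(e > s, C[e + 1L] - C[s + 1L], 0L)
            tot <- ifelse(e > s, S[e + 1L] - S[s + 1L], 0)
            ok <- mask[i, ] & cnt >= w / 2
            scores[i, ok] <- tot[ok] / cnt[ok]
            valid[i, ] <- ok
        }
    }
    if (length(missingChrom))
        warnf("chromosome(s) absent from track, rows fully masked: %s",
              paste(missingChrom, collapse = ", "))
    new("WindowMatrix", scores = scores, mask = valid, frame = frame,
        scale = track@scale, label = track@label)
}

#' Convert linear window scores to log2 relative to the genome mean
#'
#' Applies \code{log2((score + eps)/(m + eps))}, \code{eps = 0.1 m}, to
#' every valid cell of a linear-scale \linkS4class{WindowMatrix}.  Taking
#' the log of the window-mean (rather than window-averaging per-bp logs)
#' avoids the downward Jensen bias of sparse windows at realistic MNase
#' sampling depth.
#'
#' @param x a linear-scale \linkS4class{WindowMatrix}.
#' @param genomeMean the genome-wide mean of the source track
#'   (\code{\link{genomeMean}}); defaults to the mean of the valid cells.
#' @return A log2_ratio \linkS4class{WindowMatrix}.
#' @export
log2RelativeToMean <- function(x, genomeMean = NULL) {
    if (x@scale != "linear") stopf("matrix must be linear scale")
    m <- genomeMean %||% mean(x@scores[x@mask])
    if (!is.finite(m) || m <= 0) stopf("reference mean must be positive")
    eps <- 0.1 * m
    sc <- log2((x@scores + eps) / (m + eps))
    sc[!x@mask] <- NA_real_
    new("WindowMatrix", scores = sc, mask = x@mask, frame = x@frame,
        scale = "log2_ratio",
        label = paste0(x@label, " (log2/genome mean)"))
}

#' Write / read a WindowMatrix as TSV
#'
#' The header holds \code{gene_id} followed by the oriented window start
#' offsets; masked cells are written as \code{NA}.  \code{readWindowMatrix}
#' reconstructs the frame from the header offsets.
#'
#' @param x a \linkS4class{WindowMatrix}.
#' @param path file path.
#' @param scale value scale to declare on reading.
#' @param label track label to attach on reading.
#' @return \code{writeWindowMatrix}: invisibly, \code{path};
#'   \code{readWindowMatrix}: a \linkS4class{WindowMatrix}.
#' @export
writeWindowMatrix <- function(x, path) {
    df <- data.frame(gene_id = rownames(x@scores), x@scores,
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeWindowMatrix
#' @export
readWindowMatrix <- function(path, scale = c("linear", "log2_ratio"),
                             label = basename(path)) {
    scale <- match.arg(scale)
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    off <- as.integer(names(df)[-1L])
    if (anyNA(off) || length(off) < 2L)
        stopf("not a WindowMatrix TSV: %s", path)
    w <- off[2L] - off[1L]
    frame <- promoterFrame(flank = -off[1L], window = w)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$gene_id
    new("WindowMatrix", scores = m, mask = !is.na(m), frame = frame,
        scale = scale, label = label)
}
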