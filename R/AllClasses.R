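#' @import methods
#' @importFrom stats cor lm coef median phyper quantile rnorm runif rpois
#'   rbinom sd setNames splinefun p.adjust pnorm dnorm convolve
#' @importFrom utils read.delim write.table
NULL

## Internal coordinate convention, used everywhere except at parse/write
## boundaries: 0-based, half-open.  The TSS of a minus-strand transcript is
## the 0-based position of its 5'-most base, so tes < tss on that strand and
## the genomic span is [tes, tss + 1).

#' PromoterFrame: the fixed TSS-anchored window layout
#'
#' A \code{PromoterFrame} describes the oriented coordinate frame used for
#' all promoter scoring: \code{2 * flank / window} consecutive windows of
#' \code{window} bp covering oriented offsets \code{[-flank, +flank)}
#' relative to the TSS.  Negative offsets are upstream of transcription on
#' the gene's own strand, so "leftward" means upstream for genes on either
#' genomic strand.
#'
#' @slot flank Integer, bp covered on each side of the TSS (default 800).
#' @slot window Integer, window width in bp (default 50).
#' @export
setClass("PromoterFrame",
    representation(flank = "integer", window = "integer"),
    prototype(flank = 800L, window = 50L))

setValidity("PromoterFrame", function(object) {
    msg <- character(0)
    if (length(object@flank) != 1L || object@flank <= 0L)
        msg <- c(msg, "'flank' must be a single positive integer")
    if (length(object@window) != 1L || object@window <= 0L)
        msg <- c(msg, "'window' must be a single positive integer")
    if (length(msg) == 0L && (2L * object@flank) %% object@window != 0L)
        msg <- c(msg, "2*flank must be a multiple of the window size")
    if (length(msg)) msg else TRUE
})

#' Construct a PromoterFrame
#'
#' @param flank bp covered upstream and downstream of the TSS.
#' @param window window width in bp; must divide \code{2*flank}.
#' @return A \linkS4class{PromoterFrame}.
#' @examples
#' promoterFrame()            # 32 windows of 50 bp spanning [-800, +800)
#' promoterFrame(800, 20)     # sequencing-resolution variant
#' @export
promoterFrame <- function(flank = 800L, window = 50L) {
    new("PromoterFrame", flank = as.integer(flank), window = as.integer(window))
}

#' GenomeAnnotation: a validated set of transcript models
#'
#' Holds one row per transcript with strand-aware TSS/TES in the internal
#' 0-based convention, plus chromosome sizes.  Build with
#' \code{\link{loadAnnotation}} or \code{\link{GenomeAnnotation}}.
#'
#' @slot transcripts data.frame with columns \code{id}, \code{chrom},
#'   \code{strand} ("+"/"-"), \code{tss}, \code{tes}, \code{gene_class}
#'   ("coding", "ncRNA" or "tRNA"), and derived span columns \code{start},
#'   \code{end} (0-based half-open).
#' @slot chromSizes named integer vector of chromosome lengths.
#' @export
setClass("GenomeAnnotation",
    representation(transcripts = "data.frame", chromSizes = "integer"))

setValidity("GenomeAnnotation", function(object) {
    tx <- object@transcripts
    need <- c("id", "chrom", "strand", "tss", "tes", "gene_class",
              "start", "end")
    if (!all(need %in% names(tx)))
        return(paste("transcripts must have columns:",
                     paste(need, collapse = ", ")))
    if (nrow(tx) == 0L) return(TRUE)
    if (anyDuplicated(tx$id)) return("duplicate transcript id")
    if (!all(tx$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
    if (any(!nzchar(tx$chrom))) return("empty chromosome name")
    if (any(tx$tss == tx$tes)) return("tss == tes")
    plus <- tx$strand == "+"
    if (any(plus & tx$tss >= tx$tes) || any(!plus & tx$tes >= tx$tss))
        return("tss/tes order inconsistent with strand")
    sz <- object@chromSizes[tx$chrom]
    if (any(is.na(sz))) return("transcript on chromosome absent from chromSizes")
    if (any(tx$start < 0L) || any(tx$end > sz))
        return("transcript outside [0, chrom_size)")
    if (!all(tx$gene_class %in% c("coding", "ncRNA", "tRNA")))
        return("gene_class must be coding, ncRNA or tRNA")
    TRUE
})

#' Construct a GenomeAnnotation from validated transcript fields
#'
#' @param id,chrom,strand,tss,tes Per-transcript fields in internal 0-based
#'   coordinates (see class docs for the minus-strand convention).
#' @param gene_class "coding", "ncRNA" or "tRNA"; recycled.
#' @param chromSizes named integer vector of chromosome lengths.
#' @return A \linkS4class{GenomeAnnotation} sorted by chromosome and span start.
#' @export
GenomeAnnotation <- function(id, chrom, strand, tss, tes,
                             gene_class = "coding", chromSizes) {
    tx <- data.frame(id = as.character(id), chrom = as.character(chrom),
                     strand = as.character(strand),
                     tss = as.integer(tss), tes = as.integer(tes),
                     gene_class = rep_len(as.character(gene_class),
                                          length(id)),
                     stringsAsFactors = FALSE)
    plus <- tx$strand == "+"
    tx$start <- ifelse(plus, tx$tss, tx$tes)
    tx$end <- ifelse(plus, tx$tes, tx$tss + 1L)
    tx <- tx[order(tx$chrom, tx$start, tx$id), , drop = FALSE]
    rownames(tx) <- NULL
    new("GenomeAnnotation", transcripts = tx,
        chromSizes = setNames(as.integer(chromSizes), names(chromSizes)))
}

#' OccupancyTrack: per-chromosome base-pair signal
#'
#' One numeric vector per chromosome at 1 bp resolution; \code{NA} marks
#' positions with no data.  \code{scale} records whether values are linear
#' occupancy (non-negative) or log2 ratios (may be negative).
#'
#' @slot signal named list of numeric vectors, one per chromosome; the
#'   vector length is the chromosome size.
#' @slot scale "linear" or "log2_ratio".
#' @slot label free-text description of the assay.
#' @export
setClass("OccupancyTrack",
    representation(signal = "list", scale = "character", label = "character"),
    prototype(scale = "linear", label = ""))

setValidity("OccupancyTrack", function(object) {
    if (!object@scale %in% c("linear", "log2_ratio"))
        return("scale must be 'linear' or 'log2_ratio'")
    if (is.null(names(object@signal)) || any(!nzchar(names(object@signal))))
        return("signal list must be named by chromosome")
    if (!all(vapply(object@signal, is.numeric, logical(1))))
        return("signal vectors must be numeric")
    if (object@scale == "linear") {
        neg <- vapply(object@signal,
                      function(v) any(v < 0, na.rm = TRUE), logical(1))
        if (any(neg)) return("linear track has negative values")
    }
    TRUE
})

#' Construct an OccupancyTrack
#'
#' @param signal named list of per-chromosome numeric vectors (NA = no data).
#' @param scale "linear" or "log2_ratio".
#' @param label free-text label.
#' @return An \linkS4class{OccupancyTrack}.
#' @export
OccupancyTrack <- function(signal, scale = c("linear", "log2_ratio"),
                           label = "") {
    scale <- match.arg(scale)
    new("OccupancyTrack", signal = lapply(signal, as.numeric),
        scale = scale, label = label)
}

#' WindowMatrix: genes x TSS-anchored windows
#'
#' Scores of one track in the fixed \linkS4class{PromoterFrame} windows of
#' each gene, with a validity mask.  Masked cells (neighbor-overlapping,
#' off-chromosome, or data-poor windows) carry \code{NA} scores.  Column
#' order is gene-oriented: column 1 is the most upstream window.
#'
#' @slot scores numeric matrix, genes x windows; NA where masked.
#' @slot mask logical matrix, TRUE where the cell is valid.
#' @slot frame the \linkS4class{PromoterFrame} used.
#' @slot scale "linear" or "log2_ratio", inherited from the track.
#' @slot label track label.
#' @export
setClass("WindowMatrix",
    representation(scores = "matrix", mask = "matrix",
                   frame = "PromoterFrame", scale = "character",
                   label = "character"),
    prototype(scale = "linear", label = ""))

setValidity("WindowMatrix", function(object) {
    if (!identical(dim(object@scores), dim(object@mask)))
        return("scores and mask dimensions differ")
    nw <- (2L * object@frame@flank) %/% object@frame@window
    if (ncol(object@scores) != nw)
        return("column count must equal 2*flank/window")
    if (is.null(rownames(object@scores)))
        return("scores must have gene ids as rownames")
    if (!object@scale %in% c("linear", "log2_ratio"))
        return("scale must be 'linear' or 'log2_ratio'")
    if (any(!object@mask & !is.na(object@scores)))
        return("masked cells must carry NA scores")
    TRUE
})

#' RatioMatrix: log2(mutant / wild-type) window scores
#'
#' A \linkS4class{WindowMatrix} whose cells are pseudocounted log2 ratios of
#' two linear-scale window matrices; valid only where both inputs were valid.
#'
#' @slot mutantLabel,wildtypeLabel labels of the two component matrices.
#' @slot epsilon the pseudocount used (0.1 x pooled mean window score).
#' @export
setClass("RatioMatrix", contains = "WindowMatrix",
    representation(mutantLabel = "character", wildtypeLabel = "character",
                   epsilon = "numeric"))

#' ClusterResult: masked k-means clustering of promoter profiles
#'
#' @slot k number of clusters.
#' @slot assignments named integer vector over all matrix rows; NA for genes
#'   set aside as unclustered (fewer than the required fraction of valid
#'   windows).
#' @slot centroids k x windows numeric matrix.
#' @slot inertia sum over clustered genes of mask-scaled squared distance to
#'   the assigned centroid.
#' @slot inertiaTrace per-iteration inertia of the winning run (non-increasing).
#' @slot seed,restarts run metadata.
#' @export
setClass("ClusterResult",
    representation(k = "integer", assignments = "integer",
                   centroids = "matrix", inertia = "numeric",
                   inertiaTrace = "numeric", seed = "integer",
                   restarts = "integer"))

setValidity("ClusterResult", function(object) {
    a <- object@assignments[!is.na(object@assignments)]
    if (length(a) && (min(a) < 1L || max(a) > object@k))
        return("assignments out of 1..k")
    if (nrow(object@centroids) != object@k)
        return("centroids must have k rows")
    if (is.unsorted(rev(object@inertiaTrace)) &&
        any(diff(object@inertiaTrace) > 1e-8 * abs(object@inertiaTrace[1])))
        return("inertia must be non-increasing across iterations")
    TRUE
})
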