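#' Accessors for ndrscope classes
#'
#' Small accessor generics: \code{geneIds} returns the gene identifiers of
#' an object, \code{chromSizes} its chromosome sizes, \code{scores} and
#' \code{validMask} the score and validity matrices of a
#' \linkS4class{WindowMatrix}, \code{windowOffsets} the oriented start
#' offsets of the frame windows, \code{assignments} and \code{centroids}
#' the components of a \linkS4class{ClusterResult}.
#'
#' @param x an ndrscope object.
#' @return The corresponding component; see each method.
#' @name ndrscope-accessors
NULL

#' @rdname ndrscope-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ndrscope-accessors
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' @rdname ndrscope-accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname ndrscope-accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname ndrscope-accessors
#' @export
setGeneric("windowOffsets", function(x) standardGeneric("windowOffsets"))

#' @rdname ndrscope-accessors
#' @export
setGeneric("trackScale", function(x) standardGeneric("trackScale"))

#' @rdname ndrscope-accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname ndrscope-accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname ndrscope-accessors
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' @rdname ndrscope-accessors
#' @export
setMethod("geneIds", "GenomeAnnotation", function(x) x@transcripts$id)

#' @rdname ndrscope-accessors
#' @export
setMethod("geneIds", "WindowMatrix", function(x) rownames(x@scores))

#' @rdname ndrscope-accessors
#' @export
setMethod("geneIds", "ClusterResult", function(x) names(x@assignments))

#' @rdname ndrscope-accessors
#' @export
setMethod("chromSizes", "GenomeAnnotation", function(x) x@chromSizes)

#' @rdname ndrscope-accessors
#' @export
setMethod("chromSizes", "OccupancyTrack",
          function(x) vapply(x@signal, length, integer(1)))

#' @rdname ndrscope-accessors
#' @export
setMethod("scores", "WindowMatrix", function(x) x@scores)

#' @rdname ndrscope-accessors
#' @export
setMethod("validMask", "WindowMatrix", function(x) x@mask)

#' @rdname ndrscope-accessors
#' @export
setMethod("windowOffsets", "PromoterFrame", function(x) {
    seq.int(-x@flank, x@flank - x@window, by = x@window)
})

#' @rdname ndrscope-accessors
#' @export
setMethod("windowOffsets", "WindowMatrix", function(x) windowOffsets(x@frame))

#' @rdname ndrscope-accessors
setMethod("nWindows", "PromoterFrame",
          function(x) (2L * x@flank) %/% x@window)

#' @rdname ndrscope-accessors
#' @export
setMethod("trackScale", "OccupancyTrack", function(x) x@scale)

#' @rdname ndrscope-accessors
#' @export
setMethod("trackScale", "WindowMatrix", function(x) x@scale)

#' @rdname ndrscope-accessors
#' @export
setMethod("assignments", "ClusterResult", function(x) x@assignments)

#' @rdname ndrscope-accessors
#' @export
setMethod("centroids", "ClusterResult", function(x) x@centroids)

setMethod("show", "PromoterFrame", function(object) {
    cat(sprintf("PromoterFrame: %d windows of %d bp over [%+d, %+d)\n",
                nWindows(object), object@window,
                -object@flank, object@flank))
})

setMethod("show", "GenomeAnnotation", function(object) {
    tx <- object@transcripts
    cat(sprintf("GenomeAnnotation: %d transcripts on %d chromosome(s)\n",
                nrow(tx), length(object@chromSizes)))
    if (nrow(tx))
        cat("  classes:",
            paste(sprintf("%s=%d", names(table(tx$gene_class)),
                          table(tx$gene_class)), collapse = " "), "\n")
})

setMethod("show", "OccupancyTrack", function(object) {
    n <- sum(vapply(object@signal, length, integer(1)))
    def <- sum(vapply(object@signal,
                      function(v) sum(!is.na(v)), integer(1)))
    cat(sprintf("OccupancyTrack '%s' (%s): %d chromosome(s), %d bp, %.1f%% defined\n",
                object@label, object@scale, length(object@signal), n,
                100 * def / max(1, n)))
})

setMethod("show", "WindowMatrix", function(object) {
    cat(sprintf("%s '%s' (%s): %d genes x %d windows (%d bp), %.1f%% valid\n",
                class(object), object@label, object@scale,
                nrow(object@scores), ncol(object@scores),
                object@frame@window, 100 * mean(object@mask)))
})

setMethod("show", "ClusterResult", function(object) {
    a <- object@assignments
    cat(sprintf("ClusterResult: k=%d, %d clustered / %d unclustered, inertia=%.4g (seed %d, %d restarts)\n",
                object@k, sum(!is.na(a)), sum(is.na(a)),
                object@inertia, object@seed, object@restarts))
    print(table(cluster = a[!is.na(a)]))
})
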