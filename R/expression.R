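## Expression module: HybMap-style tiled-microarray quantification.
## Probe tables carry sense and antisense probes per gene plus
## non-hybridizing control probes (zebrafish-style) used for scaling.

#' Read a probe-intensity table
#'
#' TSV with header \code{probe_id}, \code{gene_id}, \code{control} (0/1 or
#' TRUE/FALSE), \code{strand} ("sense"/"antisense", "." for controls) and
#' one intensity column per replicate (\code{rep1}, \code{rep2}, ...).
#' Every non-control probe must map to a gene and at least one control
#' probe is required (scaling is impossible otherwise).
#'
#' @param path TSV file.
#' @return data.frame with a \code{"replicates"} attribute naming the
#'   intensity columns.
#' @export
readProbeTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("probe_id", "gene_id", "control", "strand")
    if (!all(need %in% names(df)))
        stopf("probe table must have columns: %s", paste(need, collapse = ", "))
    reps <- grep("^rep[0-9]+$", names(df), value = TRUE)
    if (length(reps) == 0L) stopf("no replicate intensity columns (rep1...)")
    df$control <- as.logical(df$control)
    if (any(!df$control & (is.na(df$gene_id) | !nzchar(df$gene_id))))
        stopf("non-control probe(s) without a gene id")
    if (!any(df$control)) stopf("no control probes: cannot scale")
    if (any(as.matrix(df[reps]) < 0, na.rm = TRUE))
        stopf("negative intensities")
    attr(df, "replicates") <- reps
    df
}

#' Scale probe intensities to the control-probe median
#'
#' Every intensity is divided by that replicate's median control-probe
#' intensity, so the control median after scaling is exactly 1 per
#' replicate.  The operation is idempotent and invariant to rescaling a
#' replicate's raw intensities by any positive constant.
#'
#' @param table probe table from \code{\link{readProbeTable}}.
#' @return The scaled probe table.
#' @export
scaleToControls <- function(table) {
    reps <- attr(table, "replicates") %||%
        grep("^rep[0-9]+$", names(table), value = TRUE)
    ctrl <- table$control
    if (!any(ctrl)) stopf("no control probes: cannot scale")
    for (r in reps) {
        med <- median(table[[r]][ctrl])
        if (!is.finite(med) || med <= 0)
            stopf("control-probe median is not positive in %s", r)
        table[[r]] <- table[[r]] / med
    }
    attr(table, "replicates") <- reps
    table
}

#' Per-gene expression summaries from a scaled probe table
#'
#' Gene level = median over the gene's sense probes within each replicate
#' (robust to single failing probes), then the mean over replicates;
#' antisense likewise from antisense probes.  Genes without any probe are
#' absent from the output and reported in a message.
#'
#' @param table scaled probe table (\code{\link{scaleToControls}}).
#' @param genotype genotype label attached to the summary.
#' @return data.frame with \code{gene_id}, \code{genotype}, \code{sense},
#'   \code{antisense}, and per-replicate sense levels
#'   (\code{sense_rep1}, ...); carries the replicate names as an attribute.
#' @export
geneExpression <- function(table, genotype = "unknown") {
    reps <- attr(table, "replicates") %||%
        grep("^rep[0-9]+$", names(table), value = TRUE)
    gene <- table[!table$control, , drop = FALSE]
    ids <- unique(gene$gene_id)
    perRep <- function(strand) {
        sub <- gene[gene$strand == strand, , drop = FALSE]
        m <- matrix(NA_real_, length(ids), length(reps),
                    dimnames = list(ids, reps))
        if (nrow(sub)) for (r in reps) {
            agg <- tapply(sub[[r]], sub$gene_id, median)
            m[names(agg), r] <- agg
        }
        m
    }
    sense <- perRep("sense")
    anti <- perRep("antisense")
    out <- data.frame(gene_id = ids, genotype = genotype,
                      sense = rowMeans(sense),
                      antisense = rowMeans(anti),
                      stringsAsFactors = FALSE)
    colnames(sense) <- paste0("sense_", reps)
    out <- cbind(out, as.data.frame(sense))
    rownames(out) <- NULL
    dropped <- sum(is.na(out$sense))
    if (dropped > 0)
        message(dropped, " gene(s) without sense probes")
    attr(out, "replicates") <- reps
    out
}

#' Per-gene log2 mutant/wild-type expression ratios
#'
#' Computed as the mean over replicates of the per-replicate log2 ratio of
#' sense levels (replicates paired by index), the reading adopted for
#' "mean mutant/wild-type ratios"; falls back to the ratio of mean levels
#' when the two summaries carry different replicate sets.  Ratios are
#' defined only where the wild-type level is positive.
#'
#' @param mutant,wildtype summaries from \code{\link{geneExpression}}.
#' @return Named numeric vector of log2 ratios over the common genes.
#' @export
expressionRatios <- function(mutant, wildtype) {
    common <- intersect(mutant$gene_id, wildtype$gene_id)
    m <- mutant[match(common, mutant$gene_id), , drop = FALSE]
    w <- wildtype[match(common, wildtype$gene_id), , drop = FALSE]
    repM <- grep("^sense_rep", names(m), value = TRUE)
    repW <- grep("^sense_rep", names(w), value = TRUE)
    if (length(repM) && identical(repM, repW)) {
        lm2 <- as.matrix(m[repM]); lw2 <- as.matrix(w[repW])
        ok <- lw2 > 0 & lm2 > 0
        r <- log2(lm2 / lw2)
        r[!ok] <- NA
        ratios <- rowMeans(r)
        ratios[rowSums(ok) == 0L] <- NA_real_
    } else {
        ratios <- ifelse(w$sense > 0 & m$sense > 0,
                         log2(m$sense / w$sense), NA_real_)
    }
    setNames(ratios, common)
}

#' Class-wise summary of expression ratios
#'
#' Five-number summary (plus n) of per-gene log2 mutant/wild-type ratios
#' within each gene class or cluster; genes lacking either value are
#' skipped and counted.
#'
#' @param mutant,wildtype summaries from \code{\link{geneExpression}}.
#' @param classes named vector mapping gene ids to a class (gene_class or
#'   cluster id).
#' @return data.frame with one row per class: \code{class}, \code{n},
#'   \code{n_skipped}, \code{min}, \code{q1}, \code{median}, \code{q3},
#'   \code{max}.
#' @export
classRatioSummary <- function(mutant, wildtype, classes) {
    ratios <- expressionRatios(mutant, wildtype)
    ids <- names(classes)
    out <- lapply(sort(unique(as.character(classes))), function(cl) {
        members <- ids[classes == cl]
        r <- ratios[intersect(members, names(ratios))]
        skipped <- length(members) - sum(!is.na(r))
        r <- r[!is.na(r)]
        if (length(r) == 0L)
            return(data.frame(class = cl, n = 0L, n_skipped = skipped,
                              min = NA_real_, q1 = NA_real_,
                              median = NA_real_, q3 = NA_real_,
                              max = NA_real_, stringsAsFactors = FALSE))
        q <- quantile(r, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
        data.frame(class = cl, n = length(r), n_skipped = skipped,
                   min = q[1L], q1 = q[2L], median = q[3L], q3 = q[4L],
                   max = q[5L], stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Screen for genes whose repression is suppressed in a double mutant
#'
#' A gene is selected iff it is at least \code{2^downThreshold}-fold down
#' in the single mutant (log2 ratio <= -downThreshold) and the double
#' mutant restores at least \code{restoreFraction} of that effect:
#' \code{(double - single) >= restoreFraction * |single|} in log2 space.
#'
#' @param wt,single,double summaries from \code{\link{geneExpression}} on a
#'   common gene universe.
#' @param downThreshold log2 down-regulation threshold (default 0.585,
#'   i.e., 1.5-fold).
#' @param restoreFraction minimum restored fraction of the single-mutant
#'   effect (default 0.5).
#' @return list: \code{selected} (gene ids) and \code{table} (per-gene
#'   \code{ratio_single}, \code{ratio_double}, \code{selected}).
#' @export
suppressedGeneScreen <- function(wt, single, double,
                                 downThreshold = 0.585,
                                 restoreFraction = 0.5) {
    rS <- expressionRatios(single, wt)
    rD <- expressionRatios(double, wt)
    common <- intersect(names(rS), names(rD))
    rS <- rS[common]; rD <- rD[common]
    sel <- !is.na(rS) & !is.na(rD) & rS <= -downThreshold &
        (rD - rS) >= restoreFraction * abs(rS)
    list(selected = common[sel],
         table = data.frame(gene_id = common, ratio_single = rS,
                            ratio_double = rD, selected = sel,
                            row.names = NULL, stringsAsFactors = FALSE))
}

#' Write an expression summary or ratio table as TSV
#'
#' @param x data.frame (e.g., from \code{\link{geneExpression}} or
#'   \code{\link{classRatioSummary}}).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeExpressionTable <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
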