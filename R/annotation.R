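## Annotation module: transcript models, oriented promoter frames, and
## neighbor-overlap masks.
##
## All arithmetic is done in the internal 0-based half-open convention;
## 1-based formats (GFF3, wiggle) are converted at the parse/write boundary
## only.

#' Read a two-column chromosome-sizes file
#'
#' @param path TSV with chromosome name and length (no header).
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stopf("chrom sizes file must have two columns: %s", path)
    setNames(as.integer(df[[2L]]), as.character(df[[1L]]))
}

#' Write chromosome sizes as TSV
#'
#' @param chromSizes named integer vector.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeChromSizes <- function(chromSizes, path) {
    write.table(data.frame(names(chromSizes), unname(chromSizes)),
                path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

classFromGffType <- function(type) {
    cl <- rep("coding", length(type))
    cl[grepl("ncRNA", type, ignore.case = TRUE)] <- "ncRNA"
    cl[grepl("tRNA", type, ignore.case = TRUE)] <- "tRNA"
    cl
}

gffTypeFromClass <- function(cl) {
    c(coding = "gene", ncRNA = "ncRNA_gene", tRNA = "tRNA_gene")[cl]
}

#' Load transcript models from BED6 or GFF3
#'
#' Records are converted to the internal 0-based half-open convention with
#' strand-aware TSS/TES (the TSS is the 5' end of the transcript on its own
#' strand).  Records violating the transcript-model invariants are rejected
#' with a hard error reporting their (1-based) record indices; unknown
#' strand characters, duplicated ids and transcripts outside the stated
#' chromosome sizes are hard errors.
#'
#' @param path BED6 or GFF3 file.
#' @param format "BED6" or "GFF3".
#' @param chromSizes named integer vector, or path to a two-column TSV.
#' @param geneClass optional gene classes: a named character vector
#'   (id -> class) or a path to a two-column TSV \code{gene_id<TAB>class}.
#'   BED6 has no class field, so records default to "coding" unless given
#'   here; for GFF3 the feature \code{type} column is used
#'   (\code{*tRNA*} -> tRNA, \code{*ncRNA*} -> ncRNA, otherwise coding)
#'   and \code{geneClass} overrides it.
#' @return A \linkS4class{GenomeAnnotation}.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chrI\t100\t400\tg1\t0\t+", bed)
#' ann <- loadAnnotation(bed, "BED6", c(chrI = 1000L))
#' ann@transcripts[, c("tss", "tes")]   # 100, 400
#' @export
loadAnnotation <- function(path, format = c("BED6", "GFF3"), chromSizes,
                           geneClass = NULL) {
    format <- match.arg(format)
    if (is.character(chromSizes) && length(chromSizes) == 1L)
        chromSizes <- readChromSizes(chromSizes)
    if (is.character(geneClass) && length(geneClass) == 1L &&
        file.exists(geneClass)) {
        gc <- read.delim(geneClass, header = FALSE, stringsAsFactors = FALSE)
        geneClass <- setNames(as.character(gc[[2L]]), as.character(gc[[1L]]))
    }
    gr <- rtracklayer::import(path,
                              format = if (format == "BED6") "BED" else "GFF3")
    if (format == "GFF3") {
        ids <- as.character(gr$ID %||% gr$Name)
        cls <- classFromGffType(as.character(gr$type))
    } else {
        ids <- as.character(gr$name)
        cls <- rep("coding", length(gr))
    }
    if (any(is.na(ids)) || any(!nzchar(ids)))
        stopf("records without an id: %s",
              paste(which(is.na(ids) | !nzchar(ids)), collapse = ", "))
    if (!is.null(geneClass)) {
        hit <- ids %in% names(geneClass)
        cls[hit] <- unname(geneClass[ids[hit]])
    }
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(strand == "*"))
        stopf("unknown strand character in record(s): %s",
              paste(which(strand == "*"), collapse = ", "))
    if (anyDuplicated(ids))
        stopf("duplicate transcript id(s): %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
    chrom <- as.character(GenomicRanges::seqnames(gr))
    ## GRanges is 1-based inclusive for both formats after import.
    start0 <- BiocGenerics::start(gr) - 1L
    end0 <- BiocGenerics::end(gr)
    sz <- chromSizes[chrom]
    bad <- is.na(sz) | start0 < 0L | end0 > sz
    if (any(bad))
        stopf("transcript(s) outside chrom_sizes in record(s): %s",
              paste(which(bad), collapse = ", "))
    plus <- strand == "+"
    tss <- ifelse(plus, start0, end0 - 1L)
    tes <- ifelse(plus, end0, start0)
    GenomeAnnotation(id = ids, chrom = chrom, strand = strand,
                     tss = tss, tes = tes, gene_class = cls,
                     chromSizes = chromSizes)
}

#' Write transcript models as BED6 or GFF3
#'
#' Inverse of \code{\link{loadAnnotation}}: internal coordinates are
#' converted back to the 0-based (BED) or 1-based (GFF3) convention at the
#' boundary, so a write/read round trip reproduces the annotation.
#'
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param path output file.
#' @param format "BED6" or "GFF3".
#' @return Invisibly, \code{path}.
#' @export
writeAnnotation <- function(annotation, path, format = c("BED6", "GFF3")) {
    format <- match.arg(format)
    tx <- annotation@transcripts
    if (format == "BED6") {
        df <- data.frame(tx$chrom, tx$start, tx$end, tx$id, 0L, tx$strand)
        write.table(df, path, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    } else {
        lines <- c("##gff-version 3",
                   sprintf("%s\tndrscope\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                           tx$chrom, gffTypeFromClass(tx$gene_class),
                           tx$start + 1L, tx$end, tx$strand, tx$id))
        writeLines(lines, path)
    }
    invisible(path)
}

#' Map genomic positions to oriented TSS offsets and back
#'
#' Oriented offsets are signed bp relative to the TSS with negative values
#' upstream of transcription on the gene's own strand, so that "upstream"
#' (leftward in gene-oriented plots) means the same thing for plus- and
#' minus-strand genes.
#'
#' @param tss 0-based TSS position(s).
#' @param strand "+" or "-" (recycled).
#' @param position genomic position(s) for \code{orientedOffset}; oriented
#'   offset(s) for \code{offsetToGenomic}.
#' @return Signed oriented offset(s), or genomic position(s) for the
#'   inverse.
#' @examples
#' orientedOffset(1000, "+", 1050)   # +50
#' orientedOffset(1000, "-", 1050)   # -50
#' offsetToGenomic(1000, "-", -50)   # 1050
#' @export
orientedOffset <- function(tss, strand, position) {
    sgn <- ifelse(strand == "+", 1L, -1L)
    (position - tss) * sgn
}

#' @rdname orientedOffset
#' @export
offsetToGenomic <- function(tss, strand, offset) {
    sgn <- ifelse(strand == "+", 1L, -1L)
    tss + offset * sgn
}

## Genomic footprint [start, end) of each frame window of one gene.
## Window i covers oriented offsets [-flank + i*w, -flank + (i+1)*w); on the
## minus strand offset d maps to genomic tss - d, so the footprint is
## [tss - o - w + 1, tss - o + 1).
windowFootprints <- function(tss, strand, frame) {
    off <- windowOffsets(frame)
    w <- frame@window
    if (strand == "+") {
        cbind(start = tss + off, end = tss + off + w)
    } else {
        cbind(start = tss - off - w + 1L, end = tss - off + 1L)
    }
}

#' Neighbor-overlap window mask
#'
#' A window of gene g is invalid iff its genomic footprint overlaps, by at
#' least 1 bp, the transcript span (TSS to TES) of any transcript other
#' than g, or extends past either chromosome end.  Windows overlapping
#' neighboring genes are thereby excluded from all downstream scoring.
#'
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param frame a \linkS4class{PromoterFrame}.
#' @return Logical matrix, genes x windows, TRUE = valid; rownames are gene
#'   ids, colnames the oriented window start offsets.
#' @export
neighborMask <- function(annotation, frame = promoterFrame()) {
    tx <- annotation@transcripts
    nw <- nWindows(frame)
    mask <- matrix(TRUE, nrow(tx), nw,
                   dimnames = list(tx$id, windowOffsets(frame)))
    if (nrow(tx) == 0L) return(mask)
    for (chr in unique(tx$chrom)) {
        idx <- which(tx$chrom == chr)
        size <- annotation@chromSizes[[chr]]
        fp <- lapply(idx, function(i)
            windowFootprints(tx$tss[i], tx$strand[i], frame))
        starts <- unlist(lapply(fp, function(m) m[, "start"]))
        ends <- unlist(lapply(fp, function(m) m[, "end"]))
        gene <- rep(idx, each = nw)
        win <- rep(seq_len(nw), times = length(idx))
        ## off-chromosome windows
        off <- starts < 0L | ends > size
        ## windows overlapping any *other* transcript span; IRanges is
        ## 1-based inclusive, so [start, end) becomes start+1 .. end
        winR <- IRanges::IRanges(start = starts + 1L, end = ends)
        spanR <- IRanges::IRanges(start = tx$start[idx] + 1L,
                                  end = tx$end[idx])
        hits <- IRanges::findOverlaps(winR, spanR, minoverlap = 1L)
        qh <- S4Vectors::queryHits(hits)
        keep <- gene[qh] != idx[S4Vectors::subjectHits(hits)]
        bad <- off
        bad[unique(qh[keep])] <- TRUE
        mask[cbind(gene[bad], win[bad])] <- FALSE
    }
    mask
}

#' Write a window validity mask as TSV
#'
#' Long-format TSV with columns \code{gene_id}, \code{window_index}
#' (1-based), \code{offset} (oriented window start) and \code{valid}.
#'
#' @param mask logical matrix from \code{\link{neighborMask}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeMask <- function(mask, path) {
    df <- data.frame(gene_id = rep(rownames(mask), ncol(mask)),
                     window_index = rep(seq_len(ncol(mask)),
                                        each = nrow(mask)),
                     offset = rep(as.integer(colnames(mask)),
                                  each = nrow(mask)),
                     valid = as.vector(mask))
    df <- df[order(df$gene_id, df$window_index), ]
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
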