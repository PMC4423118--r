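## Enrichment module: FDR-based promoter occupancy calling, IUPAC motif
## scanning, permutation enrichment and gene-set intersection tests.

IUPAC_REGEX <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupacToRegex <- function(pattern) {
    chars <- strsplit(toupper(pattern), "")[[1L]]
    bad <- !chars %in% names(IUPAC_REGEX)
    if (any(bad))
        stopf("pattern '%s' contains non-IUPAC character(s): %s",
              pattern, paste(unique(chars[bad]), collapse = ""))
    paste(IUPAC_REGEX[chars], collapse = "")
}

## Greedy leftmost non-overlapping match count of an IUPAC pattern on one
## strand of `seq`.  An N in the sequence never matches (the regex classes
## only contain ACGT).
countMatchesOneStrand <- function(seq, pattern) {
    m <- gregexpr(iupacToRegex(pattern), seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
}

revComp <- function(seq) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## Scan one sequence for one motif; mode "presence" -> 0/1,
## "count" -> greedy non-overlapping matches (summed over strands when
## bothStrands).
scanOne <- function(seq, pattern, bothStrands, mode) {
    n <- countMatchesOneStrand(seq, pattern)
    if (bothStrands) n <- n + countMatchesOneStrand(revComp(seq), pattern)
    if (mode == "presence") as.integer(n > 0L) else n
}

#' Default promoter sequence-element set
#'
#' Standard budding-yeast consensi: TATA box (TATAWAWR), Reb1 site
#' (TTACCCG), Rsc3 site (CGCGC), and poly(A) tracts (runs of >= 5
#' consecutive A on either strand, counted).  All are scanned on both
#' strands; the first three are scored as presence/absence, poly(A) as a
#' count of non-overlapping matches.
#'
#' @return data.frame with columns \code{name}, \code{pattern},
#'   \code{both_strands}, \code{count_mode}.
#' @export
defaultMotifs <- function() {
    data.frame(name = c("TATA", "Reb1", "Rsc3", "polyA"),
               pattern = c("TATAWAWR", "TTACCCG", "CGCGC", "AAAAA"),
               both_strands = TRUE,
               count_mode = c("presence", "presence", "presence", "count"),
               stringsAsFactors = FALSE)
}

#' Read / write a motif set as YAML
#'
#' The YAML maps motif names to \code{pattern}, \code{both_strands} and
#' \code{count_mode} fields.
#'
#' @param path YAML file.
#' @param motifs motif data.frame as from \code{\link{defaultMotifs}}.
#' @return \code{readMotifs}: a motif data.frame; \code{writeMotifs}:
#'   invisibly, \code{path}.
#' @export
readMotifs <- function(path) {
    y <- yaml::read_yaml(path)
    data.frame(name = names(y),
               pattern = vapply(y, function(m) m$pattern, character(1)),
               both_strands = vapply(y, function(m)
                   isTRUE(m$both_strands), logical(1)),
               count_mode = vapply(y, function(m)
                   m$count_mode %||% "presence", character(1)),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname readMotifs
#' @export
writeMotifs <- function(motifs, path) {
    y <- lapply(seq_len(nrow(motifs)), function(i)
        list(pattern = motifs$pattern[i],
             both_strands = motifs$both_strands[i],
             count_mode = motifs$count_mode[i]))
    names(y) <- motifs$name
    yaml::write_yaml(y, path)
    invisible(path)
}

#' Scan promoter sequences for sequence elements
#'
#' Exact IUPAC matching: presence motifs give 0/1 for at least one match
#' (both strands when flagged); count motifs give the number of greedy
#' non-overlapping matches.  \code{N} never matches.  Sequences shorter
#' than the requested region are scored on the available span and flagged.
#'
#' @param sequences a named \code{Biostrings::DNAStringSet} (or named
#'   character vector) of promoter sequences, oriented 5'->3' on the gene
#'   strand.
#' @param motifs motif data.frame as from \code{\link{defaultMotifs}}.
#' @param region oriented offsets scanned, relative to the TSS; NULL scans
#'   the whole sequence.
#' @param seqStart oriented offset of the first sequence base (default
#'   -500), used to cut \code{region} out of the sequences.
#' @return data.frame with \code{gene_id}, one column per motif, and
#'   \code{truncated}.
#' @export
scanMotifs <- function(sequences, motifs = defaultMotifs(), region = NULL,
                       seqStart = -500) {
    seqs <- setNames(toupper(as.character(sequences)), names(sequences))
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
        stopf("sequences must be named by gene id")
    truncated <- rep(FALSE, length(seqs))
    if (!is.null(region)) {
        from <- region[1L] - seqStart + 1L
        to <- region[2L] - seqStart
        if (from < 1L) stopf("region starts before the sequences do")
        truncated <- nchar(seqs) < to
        seqs <- substr(seqs, from, pmin(to, nchar(seqs)))
    }
    out <- data.frame(gene_id = names(seqs), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(motifs))) {
        out[[motifs$name[i]]] <- vapply(seqs, scanOne, integer(1),
                                        pattern = motifs$pattern[i],
                                        bothStrands = motifs$both_strands[i],
                                        mode = motifs$count_mode[i],
                                        USE.NAMES = FALSE)
    }
    out$truncated <- truncated
    rownames(out) <- NULL
    out
}

## Per-gene null TSS scores from B circular per-chromosome shifts of a
## track: the score of gene g under shift delta equals the mean over g's
## *valid* TSS-zone windows, each translated by -delta (mod chromosome
## length), computed from doubled prefix sums.  Evaluating the same
## valid-window footprint as the observed score matters: a gene with few
## valid windows has a noisier score, and a null built on the full
## interval would understate that variance.
shiftNullScores <- function(track, annotation, halfWidth, B, seed,
                            windowMatrix = NULL) {
    tx <- annotation@transcripts
    frame <- if (is.null(windowMatrix)) promoterFrame(halfWidth,
                                                     2L * halfWidth)
             else windowMatrix@frame
    off <- windowOffsets(frame)
    w <- frame@window
    zone <- off + w > -halfWidth & off < halfWidth
    null <- matrix(NA_real_, nrow(tx), B, dimnames = list(tx$id, NULL))
    withSeed(seed, {
        for (chr in unique(tx$chrom)) {
            v <- track@signal[[chr]]
            if (is.null(v)) next
            L <- length(v)
            v2 <- c(v, v)
            S <- c(0, cumsum(ifelse(is.na(v2), 0, v2)))
            C <- c(0L, cumsum(!is.na(v2)))
            idx <- which(tx$chrom == chr)
            ## genomic starts of each gene's valid zone windows
            gene <- integer(0); starts <- integer(0)
            for (i in idx) {
                fp <- windowFootprints(tx$tss[i], tx$strand[i], frame)
                keep <- zone
                if (!is.null(windowMatrix))
                    keep <- keep & windowMatrix@mask[tx$id[i], ]
                if (!any(keep)) next
                gene <- c(gene, rep(i, sum(keep)))
                starts <- c(starts, fp[keep, "start"])
            }
            if (length(gene) == 0L) next
            shifts <- sample.int(L, B, replace = TRUE) - 1L
            for (b in seq_len(B)) {
                s <- (starts - shifts[b]) %% L
                cnt <- C[s + w + 1L] - C[s + 1L]
                wmean <- ifelse(cnt >= w / 2,
                                (S[s + w + 1L] - S[s + 1L]) / cnt, NA_real_)
                ok <- !is.na(wmean)
                if (!any(ok)) next
                tot <- rowsum(wmean[ok], gene[ok])
                n <- rowsum(rep(1, sum(ok)), gene[ok])
                null[as.integer(rownames(tot)), b] <- tot / n
            }
        }
    })
    null
}

#' Call remodeler-enriched promoters at a target FDR
#'
#' Per-gene empirical p-values are computed against a null score
#' distribution built from \code{B} circular per-chromosome shifts of a
#' track: the matched input/control track under the "control_track" model
#' (preferred -- the null is then free of true promoter enrichment), or
#' the chip track itself under "circular_shift" (conservative when many
#' promoters are truly enriched, since shifted windows can land on them).
#' Benjamini-Hochberg correction is applied and genes with q <= fdr are
#' returned; calls at a stricter fdr are always a subset of calls at a
#' looser one.
#'
#' @param chipScores per-gene TSS scores of the chip track, as from
#'   \code{\link{tssScore}} on a log2-enrichment \linkS4class{WindowMatrix}.
#' @param annotation the \linkS4class{GenomeAnnotation} the scores refer to.
#' @param nullTrack the track shifted to build the null: the control/input
#'   track ("control_track") or the chip track ("circular_shift").
#' @param nullModel which null the track represents (metadata).
#' @param halfWidth TSS zone half-width in bp (must match the scores).
#' @param B number of circular shifts (>= 1000 recommended; < 100 is an
#'   error, the null is too unstable).
#' @param fdr target false discovery rate.
#' @param seed RNG seed for the shifts.
#' @param windowMatrix the \linkS4class{WindowMatrix} the scores came
#'   from; when given, each gene's null is evaluated over the same
#'   valid-window footprint as its observed score (recommended -- genes
#'   with partially masked zones have noisier scores, which a
#'   full-interval null would understate).
#' @return list with \code{calls} (gene ids with q <= fdr), \code{p},
#'   \code{q} (named vectors), \code{nullModel}, \code{B}, \code{fdr}.
#' @export
callEnrichedPromoters <- function(chipScores, annotation, nullTrack,
                                  nullModel = c("control_track",
                                                "circular_shift"),
                                  halfWidth = 250, B = 1000L, fdr = 0.01,
                                  seed = 1L, windowMatrix = NULL) {
    nullModel <- match.arg(nullModel)
    if (B < 100L) stopf("B = %d shifts give an unstable null; use >= 100", B)
    ids <- geneIds(annotation)
    obs <- chipScores[ids]
    null <- shiftNullScores(nullTrack, annotation, halfWidth, as.integer(B),
                            seed, windowMatrix)
    p <- rep(NA_real_, length(ids))
    names(p) <- ids
    for (i in seq_along(ids)) {
        if (is.na(obs[i])) next
        ni <- null[i, ]
        ni <- ni[!is.na(ni)]
        if (length(ni) == 0L) next
        p[i] <- (1 + sum(ni >= obs[i])) / (length(ni) + 1)
    }
    q <- p
    ok <- !is.na(p)
    q[ok] <- p.adjust(p[ok], method = "BH")
    list(calls = ids[ok & q <= fdr], p = p, q = q,
         nullModel = nullModel, B = as.integer(B), fdr = fdr)
}

#' Permutation test of a per-gene statistic in a gene category
#'
#' The observed value is the mean statistic over the category; the null is
#' the mean over random same-size draws from the background without
#' replacement.  The one-sided empirical p-value uses the plus-one rule
#' \code{p = (1 + #(null at least as extreme)) / (n_permutations + 1)}, so
#' it is never 0.  By default the tested tail follows the sign of
#' (observed - null mean); fix \code{alternative} to "greater" or "less"
#' when a calibrated one-sided p-value is needed (with "auto", null
#' p-values fold onto (0, 0.5] because the smaller tail is reported).
#' Deterministic given \code{seed}.
#'
#' @param statistic named per-gene numeric vector (e.g., motif presence or
#'   counts).
#' @param category gene ids forming the tested category (subset of the
#'   background).
#' @param background gene universe (defaults to all genes in
#'   \code{statistic}).
#' @param nPermutations number of random draws (>= 1000 recommended).
#' @param seed RNG seed.
#' @param name label stored in the result.
#' @return One-row data.frame (an enrichment record): \code{category},
#'   \code{observed}, \code{null_mean}, \code{null_sd},
#'   \code{n_permutations}, \code{p}, \code{direction}.
#' @export
#' @param alternative "auto" (tail by observed direction), "greater"
#'   (enrichment) or "less" (depletion).
permutationEnrichment <- function(statistic, category,
                                  background = names(statistic),
                                  nPermutations = 10000L, seed = 1L,
                                  name = "category",
                                  alternative = c("auto", "greater",
                                                  "less")) {
    alternative <- match.arg(alternative)
    if (length(category) == 0L) stopf("empty category")
    if (!all(category %in% background))
        stopf("category must be a subset of the background")
    if (nPermutations < 100L) stopf("need >= 100 permutations")
    stat <- statistic[background]
    if (anyNA(stat)) stopf("statistic undefined for some background genes")
    observed <- mean(statistic[category])
    k <- length(category)
    nulls <- withSeed(seed, {
        vapply(seq_len(nPermutations), function(b)
            mean(stat[sample.int(length(stat), k)]), numeric(1))
    })
    enriched <- switch(alternative,
                       auto = observed >= mean(nulls),
                       greater = TRUE,
                       less = FALSE)
    extreme <- if (enriched) sum(nulls >= observed) else
        sum(nulls <= observed)
    data.frame(category = name, observed = observed,
               null_mean = mean(nulls), null_sd = sd(nulls),
               n_permutations = as.integer(nPermutations),
               p = (1 + extreme) / (nPermutations + 1),
               direction = if (enriched) "enriched" else "depleted",
               stringsAsFactors = FALSE)
}

#' Gene-set intersection test
#'
#' Tests whether the overlap of two gene sets within a universe is larger
#' (or smaller) than expected: hypergeometric tail probability, optionally
#' cross-checked by a label-shuffling permutation p-value (random same-size
#' draws of the second set).
#'
#' @param setA,setB gene id vectors, both subsets of \code{universe}.
#' @param universe gene universe.
#' @param method "hypergeometric", "permutation" or "both".
#' @param alternative "auto" picks the tail from the sign of
#'   (observed - expected); or force "enrichment" / "depletion".
#' @param nPermutations,seed permutation settings.
#' @return One-row data.frame: \code{observed}, \code{expected},
#'   \code{direction}, \code{p_hypergeometric}, \code{p_permutation},
#'   \code{n_permutations}.
#' @export
geneSetIntersectionTest <- function(setA, setB, universe,
                                    method = c("hypergeometric",
                                               "permutation", "both"),
                                    alternative = c("auto", "enrichment",
                                                    "depletion"),
                                    nPermutations = 10000L, seed = 1L) {
    method <- match.arg(method)
    alternative <- match.arg(alternative)
    if (length(universe) == 0L) stopf("empty universe")
    setA <- unique(setA); setB <- unique(setB)
    if (!all(setA %in% universe) || !all(setB %in% universe))
        stopf("both sets must be subsets of the universe")
    U <- length(universe); a <- length(setA); b <- length(setB)
    observed <- length(intersect(setA, setB))
    expected <- a * b / U
    if (alternative == "auto")
        alternative <- if (observed >= expected) "enrichment" else "depletion"
    pHyper <- if (alternative == "enrichment")
        phyper(observed - 1, a, U - a, b, lower.tail = FALSE)
    else phyper(observed, a, U - a, b, lower.tail = TRUE)
    pPerm <- NA_real_
    if (method %in% c("permutation", "both")) {
        if (nPermutations < 100L) stopf("need >= 100 permutations")
        inA <- universe %in% setA
        nulls <- withSeed(seed, {
            vapply(seq_len(nPermutations), function(i)
                sum(inA[sample.int(U, b)]), numeric(1))
        })
        extreme <- if (alternative == "enrichment") sum(nulls >= observed)
        else sum(nulls <= observed)
        pPerm <- (1 + extreme) / (nPermutations + 1)
    }
    data.frame(observed = observed, expected = expected,
               direction = if (alternative == "enrichment") "enriched"
                           else "depleted",
               p_hypergeometric = pHyper, p_permutation = pPerm,
               n_permutations = if (is.na(pPerm)) NA_integer_
                                else as.integer(nPermutations),
               stringsAsFactors = FALSE)
}
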