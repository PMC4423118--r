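## Independent brute-force oracles and small fixture builders.  These stay
## deliberately naive (per-base loops, exhaustive enumeration) so they share
## no code path with the implementations they check.

## Random annotation on a handful of chromosomes.
randomAnnotation <- function(n, nChrom = 2L, chromSize = 30000L,
                             minLen = 300L, maxLen = 2500L) {
    chrom <- sort(sample(sprintf("c%d", seq_len(nChrom)), n, replace = TRUE))
    start <- integer(n)
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        start[idx] <- sort(sample.int(chromSize - maxLen - 1L, length(idx)))
    }
    len <- sample(minLen:maxLen, n, replace = TRUE)
    end <- pmin(start + len, chromSize)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    GenomeAnnotation(sprintf("g%03d", seq_len(n)), chrom, strand,
                     tss = ifelse(strand == "+", start, end - 1L),
                     tes = ifelse(strand == "+", end, start),
                     chromSizes = setNames(rep(chromSize, nChrom),
                                           sprintf("c%d", seq_len(nChrom))))
}

randomTrack <- function(chromSizes, density = 0.9) {
    sig <- lapply(chromSizes, function(nn) {
        v <- rnorm(nn)
        v[runif(nn) > density] <- NA
        v
    })
    OccupancyTrack(sig, scale = "log2_ratio", label = "random")
}

## Per-base recomputation of one gene's window means and validity.
naiveGeneRow <- function(track, tx, frame, maskRow) {
    off <- windowOffsets(frame)
    w <- frame@window
    v <- track@signal[[tx$chrom]]
    out <- rep(NA_real_, length(off))
    ok <- rep(FALSE, length(off))
    for (j in seq_along(off)) {
        vals <- rep(NA_real_, w)
        for (d in 0:(w - 1L)) {
            p <- offsetToGenomic(tx$tss, tx$strand, off[j] + d)
            if (p >= 0L && p < length(v)) vals[d + 1L] <- v[p + 1L]
        }
        cnt <- sum(!is.na(vals))
        if (maskRow[j] && cnt >= w / 2) {
            out[j] <- mean(vals, na.rm = TRUE)
            ok[j] <- TRUE
        }
    }
    list(scores = out, valid = ok)
}

## All-pairs interval-overlap recomputation of the neighbor mask.
naiveNeighborMask <- function(annotation, frame) {
    tx <- annotation@transcripts
    off <- windowOffsets(frame)
    w <- frame@window
    mask <- matrix(TRUE, nrow(tx), length(off),
                   dimnames = list(tx$id, off))
    for (i in seq_len(nrow(tx))) {
        size <- annotation@chromSizes[[tx$chrom[i]]]
        for (j in seq_along(off)) {
            ps <- vapply(off[j] + 0:(w - 1L), function(d)
                offsetToGenomic(tx$tss[i], tx$strand[i], d), numeric(1))
            ws <- min(ps); we <- max(ps) + 1L
            if (ws < 0L || we > size) { mask[i, j] <- FALSE; next }
            for (k in seq_len(nrow(tx))) {
                if (k == i || tx$chrom[k] != tx$chrom[i]) next
                if (max(ws, tx$start[k]) < min(we, tx$end[k])) {
                    mask[i, j] <- FALSE
                    break
                }
            }
        }
    }
    mask
}

## Order-statistic quantile normalization (no ties expected).
naiveQuantileNormalize <- function(m) {
    target <- rowMeans(apply(m, 2L, sort))
    out <- m
    for (j in seq_len(ncol(m))) out[order(m[, j]), j] <- target
    out
}

## Position-by-position greedy IUPAC scanner (regex-free).
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

naiveCountOneStrand <- function(seq, pattern) {
    s <- strsplit(seq, "")[[1L]]
    p <- strsplit(pattern, "")[[1L]]
    n <- 0L; i <- 1L
    while (i <= length(s) - length(p) + 1L) {
        hit <- TRUE
        for (j in seq_along(p)) {
            if (!s[i + j - 1L] %in% IUPAC_SETS[[p[j]]]) { hit <- FALSE; break }
        }
        if (hit) { n <- n + 1L; i <- i + length(p) } else i <- i + 1L
    }
    n
}

naiveRevComp <- function(seq) {
    map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(map[strsplit(seq, "")[[1L]]]), collapse = "")
}

naiveScan <- function(seq, pattern, bothStrands, mode) {
    n <- naiveCountOneStrand(seq, pattern)
    if (bothStrands) n <- n + naiveCountOneStrand(naiveRevComp(seq), pattern)
    if (mode == "presence") as.integer(n > 0L) else n
}

## Exhaustive two-block partition optimum for 1-D k-means (6 points).
minTwoBlockInertia <- function(x) {
    stopifnot(length(x) == 6L)
    best <- Inf
    for (m in 1:31) {
        lab <- as.integer(intToBits(m))[1:6]
        a <- x[lab == 1L]; b <- x[lab == 0L]
        if (!length(a) || !length(b)) next
        best <- min(best, sum((a - mean(a))^2) + sum((b - mean(b))^2))
    }
    best
}

## WindowMatrix straight from a score matrix (fully valid mask).
matrixAsWindowMatrix <- function(X, frame = promoterFrame(),
                                 scale = "log2_ratio") {
    colnames(X) <- windowOffsets(frame)
    if (is.null(rownames(X))) rownames(X) <- sprintf("g%03d", seq_len(nrow(X)))
    new("WindowMatrix", scores = X,
        mask = matrix(!is.na(X), nrow(X), ncol(X), dimnames = dimnames(X)),
        frame = frame, scale = scale, label = "test")
}

## Minimal probe table.
makeProbeTable <- function(genes, senseLevels, nCtrl = 20L, ctrlLevel = 10,
                           noiseSD = 0, nReps = 3L, antisenseLevels = NULL) {
    rows <- list()
    for (i in seq_along(genes)) {
        for (str in c("sense", "antisense")) {
            lev <- if (str == "sense") senseLevels[i]
                   else (antisenseLevels[i] %||% senseLevels[i] / 8)
            m <- matrix(lev * 2^rnorm(3L * nReps, 0, noiseSD), nrow = 3L)
            colnames(m) <- paste0("rep", seq_len(nReps))
            rows[[length(rows) + 1L]] <-
                data.frame(probe_id = sprintf("%s_%s_%d", genes[i], str, 1:3),
                           gene_id = genes[i], control = FALSE,
                           strand = str, m)
        }
    }
    cm <- matrix(ctrlLevel * 2^rnorm(nCtrl * nReps, 0, noiseSD), nrow = nCtrl)
    colnames(cm) <- paste0("rep", seq_len(nReps))
    rows[[length(rows) + 1L]] <-
        data.frame(probe_id = sprintf("ctrl_%02d", seq_len(nCtrl)),
                   gene_id = "", control = TRUE, strand = ".", cm)
    tab <- do.call(rbind, rows)
    attr(tab, "replicates") <- paste0("rep", seq_len(nReps))
    tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
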