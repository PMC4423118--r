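## Profiles module: mutant/wild-type ratio matrices, masked k-means promoter
## clustering, aggregate cluster profiles, per-gene TSS scores and assay
## correlation.

#' Build a log2(mutant / wild-type) ratio matrix
#'
#' Cells are \code{log2((m + eps)/(w + eps))} on linear window scores, with
#' pseudocount \code{eps} = 0.1 x the mean valid window score pooled over
#' both matrices (a symmetric choice, so that swapping the arguments negates
#' every valid cell exactly).  A cell is valid only where both inputs are
#' valid.
#'
#' @param mutant,wildtype linear-scale \linkS4class{WindowMatrix} objects on
#'   the same gene list and frame.
#' @return A \linkS4class{RatioMatrix} (scale "log2_ratio").
#' @export
ratioMatrix <- function(mutant, wildtype) {
    if (!identical(rownames(mutant@scores), rownames(wildtype@scores)))
        stopf("mutant and wildtype gene lists differ")
    if (mutant@frame@flank != wildtype@frame@flank ||
        mutant@frame@window != wildtype@frame@window)
        stopf("mutant and wildtype frames differ")
    if (mutant@scale != "linear" || wildtype@scale != "linear")
        stopf("ratio matrices are computed from linear-scale window scores")
    mask <- mutant@mask & wildtype@mask
    pooled <- c(mutant@scores[mutant@mask], wildtype@scores[wildtype@mask])
    eps <- 0.1 * mean(pooled)
    if (!is.finite(eps) || eps <= 0)
        stopf("cannot derive pseudocount: no positive valid scores")
    sc <- log2((mutant@scores + eps) / (wildtype@scores + eps))
    sc[!mask] <- NA_real_
    new("RatioMatrix", scores = sc, mask = mask, frame = mutant@frame,
        scale = "log2_ratio",
        label = sprintf("log2(%s / %s)", mutant@label, wildtype@label),
        mutantLabel = mutant@label, wildtypeLabel = wildtype@label,
        epsilon = eps)
}

## Masked squared-Euclidean distances of every profile to every centroid,
## scaled per gene by (total windows / valid windows).  X0 is the score
## matrix with NA as 0, V the 0/1 validity matrix.
maskedDistances <- function(X0, V, centroids, scaleFac) {
    xx <- rowSums(V * X0^2)
    d <- xx - 2 * (X0 * V) %*% t(centroids) + V %*% t(centroids^2)
    d[d < 0] <- 0
    d * scaleFac
}

## One k-means run: k-means++ seeding then Lloyd iterations under the
## masked distance.  Returns assignments, centroids and the inertia trace.
kmeansOnce <- function(X0, V, k, colFallback, maxIter = 100L) {
    n <- nrow(X0)
    vfrac <- rowSums(V)
    scaleFac <- ncol(X0) / vfrac
    ## impute column means into invalid cells for seeding only
    Ximp <- X0 * V + rep(colFallback, each = n) * (1 - V)
    centers <- matrix(NA_real_, k, ncol(X0))
    first <- sample.int(n, 1L)
    centers[1L, ] <- Ximp[first, ]
    if (k > 1L) for (j in 2:k) {
        d <- maskedDistances(X0, V, centers[seq_len(j - 1L), , drop = FALSE],
                             scaleFac)
        dmin <- apply(d, 1L, min)
        if (sum(dmin) <= 0) idx <- sample.int(n, 1L)
        else idx <- sample.int(n, 1L, prob = dmin)
        centers[j, ] <- Ximp[idx, ]
    }
    assign <- rep(0L, n)
    trace <- numeric(0)
    for (iter in seq_len(maxIter)) {
        d <- maskedDistances(X0, V, centers, scaleFac)
        newAssign <- max.col(-d, ties.method = "first")
        inertia <- sum(d[cbind(seq_len(n), newAssign)])
        trace <- c(trace, inertia)
        if (identical(newAssign, assign)) break
        assign <- newAssign
        for (c in seq_len(k)) {
            members <- assign == c
            if (!any(members)) {
                ## re-seed empty cluster at the worst-fit profile
                worst <- which.max(d[cbind(seq_len(n), assign)])
                centers[c, ] <- Ximp[worst, ]
                next
            }
            cnt <- colSums(V[members, , drop = FALSE])
            tot <- colSums((X0 * V)[members, , drop = FALSE])
            cw <- ifelse(cnt > 0, tot / cnt, colFallback)
            centers[c, ] <- cw
        }
    }
    list(assign = assign, centers = centers,
         inertia = trace[length(trace)], trace = trace)
}

#' Masked-distance k-means clustering of promoter profiles
#'
#' Lloyd's algorithm with k-means++ seeding over the masked squared
#' Euclidean distance: the distance between a profile and a centroid is
#' computed over the profile's valid windows only and scaled by
#' (total windows / valid windows), so neighbor-masked promoters are
#' neither imputed nor favored.  Genes with fewer than
#' \code{minValidFrac} valid windows are set aside as unclustered
#' (assignment \code{NA}) but remain in the result.  The best of
#' \code{restarts} runs by inertia is returned (ties broken by the lowest
#' run index); results are deterministic given \code{seed}.  Cluster ids
#' are relabeled by descending mean centroid gain in the NDR zone
#' \code{[-150, +50)}, so cluster 1 always has the strongest NDR fill-in.
#'
#' @param x a \linkS4class{RatioMatrix} or \linkS4class{WindowMatrix}.
#' @param k number of clusters (default 6).
#' @param seed RNG seed recorded in the result.
#' @param restarts number of independent runs (default 20).
#' @param minValidFrac minimum fraction of valid windows to cluster a gene.
#' @return A \linkS4class{ClusterResult}.
#' @export
kmeansProfiles <- function(x, k = 6L, seed = 1L, restarts = 20L,
                           minValidFrac = 0.5) {
    ## canonical gene order: the run (incl. the seeded k-means++ draws) is
    ## then invariant under permutations of the input rows
    ord <- order(rownames(x@scores))
    X <- x@scores[ord, , drop = FALSE]
    V <- x@mask[ord, , drop = FALSE] * 1
    retained <- rowSums(V) >= minValidFrac * ncol(X) & rowSums(V) > 0
    if (k > sum(retained))
        stopf("k = %d exceeds the %d genes with enough valid windows",
              k, sum(retained))
    Xr <- X[retained, , drop = FALSE]
    Vr <- V[retained, , drop = FALSE]
    X0 <- ifelse(is.na(Xr), 0, Xr)
    cnt <- colSums(Vr)
    colFallback <- ifelse(cnt > 0, colSums(X0 * Vr) / cnt, 0)
    best <- NULL
    for (run in seq_len(restarts)) {
        res <- withSeed(childSeed(seed, run),
                        kmeansOnce(X0, Vr, as.integer(k), colFallback))
        if (is.null(best) || res$inertia < best$inertia) best <- res
    }
    ## semantic relabeling: cluster 1 = strongest mean gain over the NDR zone
    off <- windowOffsets(x)
    w <- x@frame@window
    ndrZone <- off + w > -150 & off < 50
    gain <- rowMeans(best$centers[, ndrZone, drop = FALSE])
    relabel <- order(order(gain, decreasing = TRUE))
    assign <- rep(NA_integer_, nrow(X))
    assign[retained] <- relabel[best$assign]
    assign <- setNames(assign, rownames(X))[rownames(x@scores)]
    centers <- best$centers[order(gain, decreasing = TRUE), , drop = FALSE]
    dimnames(centers) <- list(seq_len(k), colnames(X))
    new("ClusterResult", k = as.integer(k),
        assignments = assign,
        centroids = centers, inertia = best$inertia,
        inertiaTrace = best$trace, seed = as.integer(seed),
        restarts = as.integer(restarts))
}

#' Per-cluster mean profiles with bootstrap confidence bands
#'
#' For each cluster and window, the mean over valid cells of member genes,
#' with a percentile confidence band from bootstrap resampling of member
#' genes.  Windows with fewer than \code{minGenes} contributing genes are
#' flagged.
#'
#' @param x a \linkS4class{WindowMatrix} (typically log2 occupancy).
#' @param clusters a \linkS4class{ClusterResult} on the same genes.
#' @param nBoot number of bootstrap resamples (>= 1000 recommended).
#' @param conf confidence level of the band.
#' @param seed RNG seed for the resampling.
#' @param minGenes flag threshold for thinly supported windows.
#' @return data.frame with columns \code{cluster}, \code{offset},
#'   \code{mean}, \code{lower}, \code{upper}, \code{n_genes},
#'   \code{flagged}.
#' @export
clusterMeanProfiles <- function(x, clusters, nBoot = 1000L, conf = 0.95,
                                seed = 1L, minGenes = 10L) {
    if (!identical(geneIds(x), geneIds(clusters)))
        stopf("matrix and clustering cover different genes")
    a <- clusters@assignments
    off <- windowOffsets(x)
    alpha <- (1 - conf) / 2
    out <- lapply(seq_len(clusters@k), function(cl) {
        rows <- which(!is.na(a) & a == cl)
        if (length(rows) == 0L) stopf("cluster %d is empty", cl)
        Xc <- x@scores[rows, , drop = FALSE]
        Vc <- x@mask[rows, , drop = FALSE]
        X0 <- ifelse(is.na(Xc), 0, Xc)
        nGenes <- colSums(Vc)
        m <- ifelse(nGenes > 0, colSums(X0 * Vc) / nGenes, NA_real_)
        boots <- withSeed(childSeed(seed, cl), {
            vapply(seq_len(nBoot), function(b) {
                idx <- sample.int(length(rows), replace = TRUE)
                cnt <- colSums(Vc[idx, , drop = FALSE])
                ifelse(cnt > 0,
                       colSums((X0 * Vc)[idx, , drop = FALSE]) / cnt,
                       NA_real_)
            }, numeric(ncol(Xc)))
        })
        lo <- apply(boots, 1L, quantile, probs = alpha, na.rm = TRUE)
        hi <- apply(boots, 1L, quantile, probs = 1 - alpha, na.rm = TRUE)
        data.frame(cluster = cl, offset = off, mean = m, lower = lo,
                   upper = hi, n_genes = nGenes,
                   flagged = nGenes < minGenes, row.names = NULL)
    })
    do.call(rbind, out)
}

#' Per-gene TSS occupancy score
#'
#' The chosen statistic over the valid windows whose oriented span
#' intersects \code{[-halfWidth, +halfWidth)}.  Genes with no valid window
#' in range get \code{NA}.
#'
#' @param x a \linkS4class{WindowMatrix}.
#' @param statistic "mean" or "max".
#' @param halfWidth half-width of the TSS zone in bp (default 250; the
#'   zone must lie within the frame).
#' @return Named numeric vector over genes.
#' @export
tssScore <- function(x, statistic = c("mean", "max"), halfWidth = 250) {
    statistic <- match.arg(statistic)
    if (halfWidth > x@frame@flank)
        stopf("halfWidth (%g) exceeds the frame flank (%d)",
              halfWidth, x@frame@flank)
    off <- windowOffsets(x)
    w <- x@frame@window
    zone <- off + w > -halfWidth & off < halfWidth
    sub <- x@scores[, zone, drop = FALSE]
    fun <- if (statistic == "mean") meanOrNA else
        function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    setNames(apply(sub, 1L, fun), rownames(sub))
}

#' Correlate two per-gene score vectors
#'
#' Pearson correlation and least-squares line on the genes defined in both
#' inputs (matched by name when named).
#'
#' @param scoresA,scoresB named numeric vectors of per-gene scores.
#' @return A list with \code{r}, \code{n}, \code{slope}, \code{intercept};
#'   \code{r} is \code{NA} when either input has zero variance.
#' @export
correlateAssays <- function(scoresA, scoresB) {
    if (!is.null(names(scoresA)) && !is.null(names(scoresB))) {
        common <- intersect(names(scoresA), names(scoresB))
        a <- scoresA[common]; b <- scoresB[common]
    } else {
        if (length(scoresA) != length(scoresB))
            stopf("unnamed score vectors must have equal length")
        a <- scoresA; b <- scoresB
    }
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    n <- length(a)
    if (n < 3L) stopf("need at least 3 genes defined in both score sets")
    if (sd(a) == 0 || sd(b) == 0)
        return(list(r = NA_real_, n = n, slope = NA_real_,
                    intercept = NA_real_))
    fit <- lm(b ~ a)
    list(r = cor(a, b), n = n,
         slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]))
}
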