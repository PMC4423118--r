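## Architecture module: promoter chromatin geometry.  All positions are
## oriented bp offsets relative to the TSS (negative = upstream of
## transcription), so "leftward" shifts toward the NDR are strand-correct.

#' Detect the nucleosome-depleted region of one promoter profile
#'
#' The NDR is the longest contiguous run of valid windows whose log2
#' occupancy (relative to the genome mean) falls below \code{theta},
#' overlapping the search zone and spanning at least \code{minRun}
#' windows.  Because an NDR is by definition a depleted region
#' \emph{flanked by positioned nucleosomes} (the -1 and +1), a candidate
#' run is eligible only when the nearest valid window on each side of the
#' full depleted stretch is occupied (>= \code{theta}); depleted stretches
#' running off the profile edge are promoter-distal low-coverage ground,
#' not NDRs.  Ties between equally long eligible runs are broken by the
#' midpoint closest to the TSS.  Depth is measured from the genome-mean
#' reference (0) down to the minimum window value of the run.
#'
#' @param profile numeric vector of window values in log2
#'   relative-to-genome-mean scale (NA = masked).
#' @param offsets oriented window start offsets (bp), as from
#'   \code{\link{windowOffsets}}.
#' @param searchZone oriented interval searched, default \code{c(-350, 50)}.
#' @param theta depletion threshold in log2 units (default -0.5).
#' @param minRun minimum run length, in windows, to call an NDR.
#' @return A one-row data.frame: \code{present}, \code{ndr_start},
#'   \code{ndr_end} (oriented bp), \code{depth} (log2 units, positive),
#'   \code{unevaluable} (TRUE when every window in the zone is masked).
#' @export
detectNDR <- function(profile, offsets, searchZone = c(-350, 50),
                      theta = -0.5, minRun = 2L) {
    stopifnot(length(profile) == length(offsets))
    w <- diff(offsets[1:2])
    inZone <- offsets >= searchZone[1L] & offsets + w <= searchZone[2L]
    absent <- data.frame(present = FALSE, ndr_start = NA_real_,
                         ndr_end = NA_real_, depth = NA_real_,
                         unevaluable = FALSE)
    if (!any(inZone)) { absent$unevaluable <- TRUE; return(absent) }
    if (all(is.na(profile[inZone]))) {
        absent$unevaluable <- TRUE
        return(absent)
    }
    ## runs of consecutive *valid* windows below theta, restricted to the
    ## search zone (masked windows and the zone boundary break contiguity)
    low <- !is.na(profile) & profile < theta & inZone
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ## the nearest valid window beyond each end of the run must be
    ## occupied: depletion continuing past the flank is promoter-distal
    ## vacuum, not a -1/+1-bounded NDR
    flankedBy <- function(i, dir) {
        j <- i + dir
        while (j >= 1L && j <= length(profile)) {
            if (!is.na(profile[j])) return(profile[j] >= theta)
            j <- j + dir
        }
        FALSE   # depletion runs off the profile edge: not an NDR flank
    }
    cand <- which(r$values & r$lengths >= minRun)
    if (length(cand)) {
        flanked <- vapply(cand, function(k)
            flankedBy(starts[k], -1L) && flankedBy(ends[k], +1L),
            logical(1))
        cand <- cand[flanked]
    }
    if (length(cand) == 0L) return(absent)
    lens <- r$lengths[cand]
    cand <- cand[lens == max(lens)]
    mid <- (offsets[starts[cand]] + offsets[ends[cand]] + w) / 2
    pick <- cand[which.min(abs(mid))]
    i1 <- starts[pick]; i2 <- ends[pick]
    data.frame(present = TRUE, ndr_start = offsets[i1],
               ndr_end = offsets[i2] + w,
               depth = -min(profile[i1:i2]), unevaluable = FALSE)
}

## Cubic spline through the valid windows (at their centers), evaluated on
## a `res`-bp grid over [zoneStart, zoneEnd).  Returns NULL when fewer than
## 4 valid support points exist.
interpProfile <- function(profile, offsets, zoneStart, zoneEnd, res = 10) {
    w <- diff(offsets[1:2])
    centers <- offsets + w / 2
    ok <- !is.na(profile)
    if (sum(ok) < 4L) return(NULL)
    f <- splinefun(centers[ok], profile[ok], method = "natural")
    grid <- seq(zoneStart, zoneEnd - res, by = res)
    if (length(grid) < 2L) return(NULL)
    list(grid = grid, value = f(grid))
}

## Sub-window peak position on the interpolated profile.  The +1 is the
## *first* nucleosome downstream of the NDR, so the first substantial
## interior local maximum of the spline is taken: the global argmax would
## lock onto the +2 whenever sampling noise makes it marginally taller,
## while small spline ripples near the NDR edge must not capture the
## peak either -- a candidate must reach within `minRelHeight` of the
## zone's dynamic range above its minimum.  NA when no interior local
## maximum qualifies.
peakPosition <- function(profile, offsets, zoneStart, zoneEnd, res = 10,
                         minRelHeight = 0.7) {
    ip <- interpProfile(profile, offsets, zoneStart, zoneEnd, res)
    if (is.null(ip)) return(NA_real_)
    v <- ip$value
    n <- length(v)
    isMax <- which(v[2:(n - 1L)] > v[1:(n - 2L)] &
                   v[2:(n - 1L)] >= v[3:n]) + 1L
    if (length(isMax) == 0L) return(NA_real_)
    floorV <- min(v) + minRelHeight * (max(v) - min(v))
    isMax <- isMax[v[isMax] >= floorV]
    if (length(isMax) == 0L) return(NA_real_)
    ip$grid[isMax[1L]]
}

#' +1 nucleosome position shift between two genotypes
#'
#' The +1 nucleosome is located as the argmax of a cubic-interpolated
#' profile on a \code{res}-bp grid inside the search zone, restricted
#' downstream of the detected NDR end so the \code{-1} peak cannot be
#' picked up.  The shift is \code{mut - wt} in oriented bp, so negative
#' values are upstream ("leftward", toward the NDR).
#'
#' @param wtProfile,mutProfile window vectors in log2 occupancy scale.
#' @param offsets oriented window start offsets (bp).
#' @param searchZone oriented interval searched, default \code{c(0, 300)}.
#' @param ndrEnd oriented end of the wild-type NDR (bp); when given and
#'   larger than \code{searchZone[1]}, the search starts there.
#' @param res interpolation grid step in bp (default 10).
#' @return A one-row data.frame: \code{plus_one_wt}, \code{plus_one_mut}
#'   (oriented bp), \code{shift_bp}, \code{defined} (FALSE when either
#'   profile has no interior maximum in the zone).
#' @export
plusOneShift <- function(wtProfile, mutProfile, offsets,
                         searchZone = c(0, 300), ndrEnd = NA, res = 10) {
    z1 <- if (!is.na(ndrEnd)) max(searchZone[1L], ndrEnd) else searchZone[1L]
    z2 <- searchZone[2L]
    wtPos <- peakPosition(wtProfile, offsets, z1, z2, res)
    mutPos <- peakPosition(mutProfile, offsets, z1, z2, res)
    defined <- !is.na(wtPos) && !is.na(mutPos)
    data.frame(plus_one_wt = wtPos, plus_one_mut = mutPos,
               shift_bp = if (defined) mutPos - wtPos else NA_real_,
               defined = defined)
}

## Window set for the fill-in contrast: the detected NDR extended to the
## surrounding run of below-genome-mean (value < 0) valid windows.  The
## detection threshold theta sits in the noisy flank of the NDR, so the
## raw detected interval gains/loses marginal windows on sampling noise,
## and conditioning the window set on the wild-type noise biases
## (mut - wt); windows are instead in or out according to values ~2 sigma
## away from the 0 boundary, making the evaluated set stable and equal to
## its infinite-data limit.
fillWindows <- function(profile, offsets, ndr) {
    if (!isTRUE(ndr$present)) return(ndr)
    w <- diff(offsets[1:2])
    i1 <- match(ndr$ndr_start, offsets)
    i2 <- match(ndr$ndr_end - w, offsets)
    while (i1 > 1L && !is.na(profile[i1 - 1L]) && profile[i1 - 1L] < 0)
        i1 <- i1 - 1L
    while (i2 < length(profile) && !is.na(profile[i2 + 1L]) &&
           profile[i2 + 1L] < 0)
        i2 <- i2 + 1L
    ndr$ndr_start <- offsets[i1]
    ndr$ndr_end <- offsets[i2] + w
    ndr
}

#' NDR fill-in score
#'
#' The log2 ratio of mutant to wild-type occupancy aggregated over the
#' NDR windows: \code{log2(mean(2^mut) / mean(2^wt))}.  Positive values
#' mean the mutant gained occupancy over the NDR (fill-in).  Aggregating
#' the linear occupancies before taking the log keeps the score unbiased
#' in the sparsely covered NDR, where averaging per-window logs is pulled
#' down by sampling noise; a uniform log2 offset of the mutant over the
#' NDR windows is still recovered exactly.  Undefined when the NDR is
#' absent.
#'
#' @param wtProfile,mutProfile window vectors in log2 occupancy scale.
#' @param offsets oriented window start offsets (bp).
#' @param ndr one-row data.frame from \code{\link{detectNDR}} (or the
#'   contrast-NDR used by \code{\link{architectureReport}}).
#' @return A single number (log2 units), or NA.
#' @export
fillInScore <- function(wtProfile, mutProfile, offsets, ndr) {
    if (!isTRUE(ndr$present)) return(NA_real_)
    w <- diff(offsets[1:2])
    inNdr <- offsets >= ndr$ndr_start & offsets + w <= ndr$ndr_end
    ok <- inNdr & !is.na(wtProfile) & !is.na(mutProfile)
    if (!any(ok)) return(NA_real_)
    log2(mean(2^mutProfile[ok]) / mean(2^wtProfile[ok]))
}

## Mean linear relative occupancy over the fill window set.
ndrOccupancy <- function(profile, offsets, ndr) {
    if (!isTRUE(ndr$present)) return(NA_real_)
    w <- diff(offsets[1:2])
    inNdr <- offsets >= ndr$ndr_start & offsets + w <= ndr$ndr_end
    v <- profile[inNdr]
    if (all(is.na(v))) NA_real_ else mean(2^v, na.rm = TRUE)
}

#' Cohort-level composite NDR fill-in
#'
#' The log2 ratio of mutant to wild-type NDR occupancy aggregated over a
#' gene cohort, read the way composite (metagene) profiles are read:
#' \code{log2(sum(occ_mut) / sum(occ_wt))} over genes with a detected
#' NDR.  Aggregating across genes before the log makes this the centered
#' cohort estimate of the planted fill even at MNase sampling depths
#' where per-gene log scores are noisy.
#'
#' @param report data.frame from \code{\link{architectureReport}}.
#' @param genotype "mut" (single mutant) or "dbl" (double mutant).
#' @return A single number (log2 units).
#' @export
compositeFillIn <- function(report, genotype = c("mut", "dbl")) {
    genotype <- match.arg(genotype)
    col <- if (genotype == "mut") "ndr_occ_mut" else "ndr_occ_dbl"
    ok <- !is.na(report$ndr_occ_wt) & !is.na(report[[col]])
    if (!any(ok)) return(NA_real_)
    log2(sum(report[[col]][ok]) / sum(report$ndr_occ_wt[ok]))
}

#' Double-mutant suppression index
#'
#' \code{1 - effectDouble/effectSingle} per gene: 0 means the double mutant
#' reproduces the single-mutant effect (no suppression), 1 means full
#' restoration of the wild type.  Genes whose single-mutant effect is below
#' \code{floor} in magnitude are skipped (NA) and counted, since the ratio
#' is unstable there.  The index is invariant under a common rescaling of
#' both effects, and is reported separately per metric (fill-in in log2
#' units, floor 0.3; shift in bp, floor 20).
#'
#' @param effectSingle,effectDouble per-gene effect vectors on a common
#'   metric.
#' @param floor minimum \code{|effectSingle|} for a defined index.
#' @return Named list: \code{index} (per-gene numeric, NA where skipped)
#'   and \code{n_skipped}.
#' @export
suppressionIndex <- function(effectSingle, effectDouble, floor = 0.3) {
    stopifnot(length(effectSingle) == length(effectDouble))
    ok <- !is.na(effectSingle) & !is.na(effectDouble) &
        abs(effectSingle) >= floor
    idx <- rep(NA_real_, length(effectSingle))
    idx[ok] <- 1 - effectDouble[ok] / effectSingle[ok]
    names(idx) <- names(effectSingle)
    list(index = idx, n_skipped = sum(!ok))
}

#' Classify a promoter as open (structured) or closed (unstructured)
#'
#' The structure score is the NDR depth (0 when absent) plus the phasing
#' amplitude: the maximum autocorrelation of the mean-subtracted profile
#' over the phasing zone at nucleosome-repeat lags (140-220 bp), floored at
#' 0.  A promoter is open iff an NDR is present and the structure score
#' reaches \code{tau}.  Undefined when more than half of the phasing-zone
#' windows are masked.
#'
#' @param wtProfile window vector in log2 occupancy scale.
#' @param offsets oriented window start offsets (bp).
#' @param ndr one-row data.frame from \code{\link{detectNDR}}.
#' @param phasingZone oriented interval over gene bodies, default
#'   \code{c(50, 750)}.
#' @param lagRange nucleosome-repeat lag range in bp, default
#'   \code{c(140, 220)}.
#' @param tau open/closed threshold on the structure score (default 0.8).
#' @return A one-row data.frame: \code{promoter_class} ("open", "closed" or
#'   NA), \code{structure_score}, \code{phasing_amplitude}.
#' @export
classifyPromoter <- function(wtProfile, offsets, ndr,
                             phasingZone = c(50, 750),
                             lagRange = c(140, 220), tau = 0.8) {
    w <- diff(offsets[1:2])
    inZone <- offsets >= phasingZone[1L] & offsets + w <= phasingZone[2L]
    v <- wtProfile[inZone]
    if (mean(is.na(v)) > 0.5)
        return(data.frame(promoter_class = NA_character_,
                          structure_score = NA_real_,
                          phasing_amplitude = NA_real_))
    lags <- seq_len(length(v) - 2L)
    lags <- lags[lags * w >= lagRange[1L] & lags * w <= lagRange[2L]]
    amp <- 0
    if (length(lags) > 0L) {
        x <- v - mean(v, na.rm = TRUE)
        denom <- sum(x^2, na.rm = TRUE)
        if (denom > 0) {
            r <- vapply(lags, function(k) {
                a <- x[seq_len(length(x) - k)]
                b <- x[seq_len(length(x) - k) + k]
                sum(a * b, na.rm = TRUE) / denom
            }, numeric(1))
            amp <- max(0, r)
        }
    }
    depth <- if (isTRUE(ndr$present)) ndr$depth else 0
    score <- depth + amp
    cls <- if (isTRUE(ndr$present) && score >= tau) "open" else "closed"
    data.frame(promoter_class = cls, structure_score = score,
               phasing_amplitude = amp)
}

#' Per-gene promoter architecture report
#'
#' Runs NDR detection, +1 localization/shift, fill-in scoring, open/closed
#' classification and (when a double-mutant matrix is given) per-metric
#' suppression indices over a whole cohort.  All input matrices must be on
#' the same genes and frame, in log2 relative-to-genome-mean scale (see
#' \code{\link{log2RelativeToMean}}).
#'
#' @param wt,mut log2-scale \linkS4class{WindowMatrix} objects (wild type
#'   and single mutant).
#' @param dbl optional log2-scale \linkS4class{WindowMatrix} of the double
#'   mutant.
#' @param searchZone,theta,minRun passed to \code{\link{detectNDR}}.
#' @param shiftZone passed to \code{\link{plusOneShift}}.
#' @param phasingZone,tau passed to \code{\link{classifyPromoter}}.
#' @param fillFloor,shiftFloor suppression floors for the fill-in (log2)
#'   and shift (bp) metrics.
#' @return data.frame with one row per gene: NDR geometry, +1 positions,
#'   \code{shift_bp}, \code{fill_in}, \code{promoter_class},
#'   \code{structure_score}, and when \code{dbl} is given,
#'   \code{fill_in_dbl}, \code{shift_bp_dbl}, \code{suppression_fill},
#'   \code{suppression_shift}.
#' @export
architectureReport <- function(wt, mut, dbl = NULL,
                               searchZone = c(-350, 50), theta = -0.5,
                               minRun = 2L, shiftZone = c(0, 300),
                               phasingZone = c(50, 750), tau = 0.8,
                               fillFloor = 0.3, shiftFloor = 20) {
    stopifnot(identical(geneIds(wt), geneIds(mut)))
    if (!is.null(dbl)) stopifnot(identical(geneIds(wt), geneIds(dbl)))
    off <- windowOffsets(wt)
    rows <- lapply(seq_along(geneIds(wt)), function(i) {
        wtP <- wt@scores[i, ]
        mutP <- mut@scores[i, ]
        ndr <- detectNDR(wtP, off, searchZone, theta, minRun)
        ps <- plusOneShift(wtP, mutP, off, shiftZone,
                           ndrEnd = if (ndr$present) ndr$ndr_end else NA)
        cls <- classifyPromoter(wtP, off, ndr, phasingZone, tau = tau)
        ndrF <- fillWindows(wtP, off, ndr)
        out <- cbind(data.frame(gene_id = geneIds(wt)[i]), ndr, ps,
                     fill_in = fillInScore(wtP, mutP, off, ndrF), cls)
        out$ndr_occ_wt <- ndrOccupancy(wtP, off, ndrF)
        out$ndr_occ_mut <- ndrOccupancy(mutP, off, ndrF)
        if (!is.null(dbl)) {
            dblP <- dbl@scores[i, ]
            psd <- plusOneShift(wtP, dblP, off, shiftZone,
                                ndrEnd = if (ndr$present) ndr$ndr_end else NA)
            out$fill_in_dbl <- fillInScore(wtP, dblP, off, ndrF)
            out$shift_bp_dbl <- psd$shift_bp
            out$ndr_occ_dbl <- ndrOccupancy(dblP, off, ndrF)
        }
        out
    })
    rep <- do.call(rbind, rows)
    if (!is.null(dbl)) {
        rep$suppression_fill <-
            suppressionIndex(rep$fill_in, rep$fill_in_dbl, fillFloor)$index
        rep$suppression_shift <-
            suppressionIndex(rep$shift_bp, rep$shift_bp_dbl, shiftFloor)$index
    }
    rep
}
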