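off50 <- windowOffsets(promoterFrame())

## A stereotyped open-promoter profile: occupied ground, a -1 and +1 peak,
## an NDR trough between them and phased decaying peaks downstream.
protoProfile <- function(ndrDepth = -2, ndrWindows = c(-150, -100),
                         base = 0.4) {
    v <- rep(base, length(off50))
    names(v) <- off50
    v[as.character(c(-250, -200))] <- 1.6            # -1 nucleosome
    v[as.character(ndrWindows)] <- ndrDepth
    v[as.character(c(50, 100))] <- 1.8               # +1 nucleosome
    v[as.character(c(250, 300))] <- 1.2
    v[as.character(c(450, 500))] <- 0.9
    v[as.character(c(650, 700))] <- 0.7
    unname(v)
}

test_that("NDR detection: flat profiles give none, constructed troughs are exact", {
    flat <- rep(0, 32)
    expect_false(detectNDR(flat, off50)$present)
    prof <- rep(0, 32)
    prof[off50 >= -250 & off50 < -100] <- -1.2
    ndr <- detectNDR(prof, off50)
    expect_true(ndr$present)
    expect_equal(ndr$ndr_start, -250)
    expect_equal(ndr$ndr_end, -100)
    expect_equal(ndr$depth, 1.2)
    masked <- rep(NA_real_, 32)
    out <- detectNDR(masked, off50)
    expect_false(out$present)
    expect_true(out$unevaluable)
})

test_that("NDR detection requires occupied flanks and enough depleted windows", {
    ## depletion running off the upstream edge is not an NDR
    vac <- rep(0.5, 32)
    vac[off50 < -250] <- -3
    expect_false(detectNDR(vac, off50)$present)
    ## a single depleted window is below the minimum run
    single <- rep(0.5, 32)
    single[off50 == -100] <- -2
    expect_false(detectNDR(single, off50)$present)
    ## a masked window inside the depleted stretch breaks contiguity and
    ## leaves both fragments without an established depleted flank
    split <- rep(0.5, 32)
    split[off50 >= -200 & off50 < -50] <- -2
    split[off50 == -150] <- NA
    expect_false(detectNDR(split, off50)$present)
    ## a masked window outside the trough is skipped when flank-checking
    okNA <- rep(0.5, 32)
    okNA[off50 >= -150 & off50 < -50] <- -2
    okNA[off50 == -250] <- NA
    ndr <- detectNDR(okNA, off50)
    expect_true(ndr$present)
    expect_equal(c(ndr$ndr_start, ndr$ndr_end), c(-150, -50))
    ## the flanked trough wins over a deeper unflanked stretch
    both <- protoProfile()
    both[off50 < -300] <- -3.4
    ndr2 <- detectNDR(both, off50)
    expect_true(ndr2$present)
    expect_equal(ndr2$ndr_start, -150)
})

test_that("+1 shift: zero for identical profiles, exact for window translations", {
    wt <- protoProfile()
    ps <- plusOneShift(wt, wt, off50, ndrEnd = -50)
    expect_true(ps$defined)
    expect_equal(ps$shift_bp, 0)
    ## translate the mutant one window upstream: -50 bp
    mut <- c(wt[-1], 0.4)
    ps2 <- plusOneShift(wt, mut, off50, ndrEnd = -50)
    expect_equal(ps2$shift_bp, -50)
    ## joint integer-window translation of both profiles leaves the shift
    ## unchanged (equivariance)
    wtT <- c(0.4, wt[-length(wt)])
    mutT <- c(0.4, mut[-length(mut)])
    psT <- plusOneShift(wtT, mutT, off50, ndrEnd = -50)
    expect_equal(psT$shift_bp, ps2$shift_bp)
    ## no interior maximum in the zone -> undefined, flagged
    mono <- seq(0, 3.1, by = 0.1)
    psU <- plusOneShift(mono, mono, off50)
    expect_false(psU$defined)
})

test_that("fill-in score averages the NDR gain and is antisymmetric", {
    wt <- protoProfile()
    ndr <- detectNDR(wt, off50)
    expect_true(ndr$present)
    expect_equal(fillInScore(wt, wt, off50, ndr), 0)
    mut <- wt
    mut[off50 >= ndr$ndr_start & off50 + 50 <= ndr$ndr_end] <-
        mut[off50 >= ndr$ndr_start & off50 + 50 <= ndr$ndr_end] + 0.8
    expect_equal(fillInScore(wt, mut, off50, ndr), 0.8)
    expect_equal(fillInScore(mut, wt, off50, ndr),
                 -fillInScore(wt, mut, off50, ndr))
    absent <- detectNDR(rep(0, 32), off50)
    expect_true(is.na(fillInScore(wt, mut, off50, absent)))
})

test_that("suppression index: fixed points, floor, and rescaling invariance", {
    s <- c(a = 1, b = 1, c = 0.1, d = -0.8)
    expect_equal(unname(suppressionIndex(s, s, floor = 0.3)$index[1]), 0)
    full <- suppressionIndex(s, c(0, 0, 0, 0), floor = 0.3)
    expect_equal(unname(full$index[c(1, 2, 4)]), c(1, 1, 1))
    expect_true(is.na(full$index[3]))   # below the floor
    expect_equal(full$n_skipped, 1L)
    half <- suppressionIndex(s, s / 2, floor = 0.3)
    scaled <- suppressionIndex(10 * s, 10 * s / 2, floor = 0.3)
    expect_equal(half$index[c(1, 2, 4)], scaled$index[c(1, 2, 4)])
})

test_that("promoter classification separates structured from flat profiles", {
    ## deep NDR + 165 bp phasing: far above tau
    phased <- protoProfile(ndrDepth = -1.5)
    ndr <- detectNDR(phased, off50)
    cls <- classifyPromoter(phased, off50, ndr)
    expect_equal(cls$promoter_class, "open")
    expect_gt(cls$structure_score, 1.5)
    ## flat noisy profile: closed
    set.seed(31)
    flat <- rnorm(32, 0, 0.1)
    cls2 <- classifyPromoter(flat, off50, detectNDR(flat, off50))
    expect_equal(cls2$promoter_class, "closed")
    ## mostly-masked phasing zone: class undefined
    gappy <- phased
    gappy[off50 >= 50] <- NA
    cls3 <- classifyPromoter(gappy, off50, ndr)
    expect_true(is.na(cls3$promoter_class))
})

test_that("cohort report combines metrics and mirrors the expected sign conventions", {
    set.seed(32)
    n <- 12L
    wtX <- t(replicate(n, protoProfile() + rnorm(32, 0, 0.05)))
    mutX <- t(vapply(seq_len(n), function(i) {
        v <- protoProfile() + rnorm(32, 0, 0.05)
        v[off50 >= -150 & off50 < -50] <- v[off50 >= -150 & off50 < -50] + 1
        c(v[off50 < 0], v[off50 >= 0][-1], 0.4)   # -50 bp downstream shift
    }, numeric(32)))
    dblX <- t(replicate(n, protoProfile() + rnorm(32, 0, 0.05)))
    wt <- matrixAsWindowMatrix(wtX)
    mut <- matrixAsWindowMatrix(mutX)
    dbl <- matrixAsWindowMatrix(dblX)
    rownames(mut@scores) <- rownames(dbl@scores) <- rownames(wt@scores)
    rep <- architectureReport(wt, mut, dbl)
    expect_equal(nrow(rep), n)
    expect_true(all(rep$present))
    expect_gt(mean(rep$fill_in), 0)         # NDR fills in the mutant
    expect_lt(mean(rep$shift_bp), 0)        # +1 moves upstream
    expect_true(all(rep$promoter_class == "open"))
    ## double mutant == wild type: full suppression on both metrics
    expect_equal(median(rep$suppression_shift, na.rm = TRUE), 1,
                 tolerance = 0.2)
    expect_equal(median(rep$suppression_fill, na.rm = TRUE), 1,
                 tolerance = 0.2)
})
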