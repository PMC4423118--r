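test_that("bedGraph and fixedStep wiggle parse to the internal convention", {
    b <- withr::local_tempfile(fileext = ".bedgraph")
    writeLines("chrI\t0\t100\t2.0", b)
    tr <- readTrack(b, "bedGraph", c(chrI = 200L))
    expect_equal(unique(tr@signal$chrI[1:100]), 2)
    expect_true(all(is.na(tr@signal$chrI[101:200])))

    w <- withr::local_tempfile(fileext = ".wig")
    writeLines(c("fixedStep chrom=chrI start=1 step=1", "1", "2", "3"), w)
    tw <- readTrack(w, "wig", c(chrI = 10L))
    expect_equal(tw@signal$chrI[1:3], c(1, 2, 3))
    expect_true(all(is.na(tw@signal$chrI[4:10])))

    writeLines(c("chrI\t0\t100\t1.0", "chrI\t50\t150\t2.0"), b)
    expect_error(readTrack(b, "bedGraph", c(chrI = 200L)), "overlapping")
    writeLines("chrI\t0\t300\t1.0", b)
    expect_error(readTrack(b, "bedGraph", c(chrI = 200L)), "beyond chrom size")
})

test_that("track write -> read round trip is bit-identical", {
    set.seed(8)
    v <- rep(NA_real_, 400)
    v[31:350] <- rnorm(320)
    t1 <- OccupancyTrack(list(cA = v, cB = rep(1.25, 80)),
                         scale = "log2_ratio")
    f <- withr::local_tempfile()
    writeTrack(t1, f)
    t2 <- readTrack(f, "bedGraph", c(cA = 400L, cB = 80L),
                    scale = "log2_ratio")
    expect_identical(t1@signal, t2@signal)
})

test_that("fragment reading enforces the mono-nucleosome length filter", {
    f <- withr::local_tempfile(fileext = ".bed")
    writeLines(c("c1\t100\t247", "c1\t500\t580", "c1\t900\t1100"), f)
    fr <- readFragments(f, c(c1 = 2000L))
    expect_equal(nrow(fr), 1L)           # 80 and 200 bp are filtered out
    expect_equal(attr(fr, "filtered"), 2L)
    writeLines("c1\t300\t200", f)
    expect_error(readFragments(f, c(c1 = 2000L)), "start >= end")
})

test_that("midpoint occupancy: unit mass at the midpoint, linearity, mass conservation", {
    sizes <- c(c1 = 1000L)
    one <- data.frame(chrom = "c1", start = 100L, end = 247L)
    tr <- midpointOccupancy(one, sizes, smoothingBw = 0)
    expect_equal(tr@signal$c1[174], 1)   # midpoint floor((100+247)/2) = 173
    expect_equal(sum(tr@signal$c1), 1)
    two <- rbind(one, one)
    tr2 <- midpointOccupancy(two, sizes, smoothingBw = 0)
    expect_equal(tr2@signal$c1, 2 * tr@signal$c1)

    set.seed(2)
    n <- 10000L
    st <- sample.int(8000L, n, replace = TRUE)
    frag <- data.frame(chrom = "c1", start = st, end = st + 147L)
    sm <- midpointOccupancy(frag, c(c1 = 9000L), smoothingBw = 20)
    expect_lt(abs(sum(sm@signal$c1) - n), 1e-2)
    ## bw = 0 is exactly the midpoint histogram
    h <- midpointOccupancy(frag, c(c1 = 9000L), smoothingBw = 0)
    mids <- (frag$start + frag$end) %/% 2L
    expect_identical(h@signal$c1, as.numeric(tabulate(mids + 1L, 9000L)))
    expect_warning(midpointOccupancy(frag[0, ], sizes), "empty")
})

test_that("quantile normalization matches the order-statistic definition", {
    expect_equal(quantileNormalize(cbind(c(1, 2, 3), c(4, 5, 6))),
                 cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
    m <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
    expect_equal(quantileNormalize(m), m)     # identical columns: fixed point
    set.seed(4)
    for (rep in 1:5) {
        x <- matrix(rnorm(60), ncol = 3L)
        qn <- quantileNormalize(x)
        expect_equal(qn, naiveQuantileNormalize(x))
        sorted <- apply(qn, 2L, sort)
        expect_equal(sorted[, 1], sorted[, 2])
        expect_equal(sorted[, 1], sorted[, 3])
        expect_equal(quantileNormalize(qn), qn)   # idempotent
    }
    expect_error(quantileNormalize(list(1:3, 1:4)), "equal length")
    expect_error(quantileNormalize(cbind(c(1, NA), c(2, 3))), "missing")
})

test_that("genome-mean normalization is centered, bounded and scale-invariant", {
    flat <- OccupancyTrack(list(c1 = rep(3, 500)), scale = "linear")
    expect_equal(unique(normalizeToGenomeMean(flat)@signal$c1), 0)
    set.seed(6)
    v <- rexp(2000)
    tr <- OccupancyTrack(list(c1 = v), scale = "linear")
    out <- normalizeToGenomeMean(tr)
    expect_equal(mean(2^out@signal$c1), 1, tolerance = 1e-10)
    ## a small region at 2x the track mean reads close to +1 (epsilon
    ## distortion bounded by log2(2.1/1.1), about 0.067)
    tr2 <- OccupancyTrack(list(c1 = c(rep(1, 10000), rep(2, 10))),
                          scale = "linear")
    hi <- normalizeToGenomeMean(tr2)@signal$c1[10005]
    expect_lt(abs(hi - 1), 0.07)
    dbl <- OccupancyTrack(list(c1 = 2 * v), scale = "linear")
    expect_lt(max(abs(normalizeToGenomeMean(dbl)@signal$c1 -
                      out@signal$c1)), 1e-9)
    zero <- OccupancyTrack(list(c1 = rep(0, 10)), scale = "linear")
    expect_error(normalizeToGenomeMean(zero), "mean")
})

test_that("window scoring matches a per-base brute force on random inputs", {
    set.seed(9)
    fr <- promoterFrame()
    for (rep in 1:2) {
        ann <- randomAnnotation(25L, nChrom = 2L, chromSize = 30000L)
        trk <- randomTrack(chromSizes(ann))
        mask <- neighborMask(ann, fr)
        wm <- scoreWindows(trk, ann, fr, mask)
        for (i in seq_len(25L)) {
            tx <- ann@transcripts[i, ]
            ref <- naiveGeneRow(trk, tx, fr, mask[tx$id, ])
            expect_equal(unname(scores(wm)[tx$id, ]), ref$scores,
                         tolerance = 1e-9)
            expect_identical(unname(validMask(wm)[tx$id, ]), ref$valid)
        }
    }
})

test_that("window scoring is linear in the track and constant-faithful", {
    set.seed(10)
    ann <- randomAnnotation(10L, nChrom = 1L, chromSize = 20000L)
    const <- OccupancyTrack(list(c1 = rep(2.5, 20000)), scale = "linear")
    wm <- scoreWindows(const, ann)
    expect_true(all(scores(wm)[validMask(wm)] == 2.5))
    x <- randomTrack(chromSizes(ann), density = 1)
    y <- randomTrack(chromSizes(ann), density = 1)
    mix <- OccupancyTrack(list(c1 = 3 * x@signal$c1 - 2 * y@signal$c1),
                          scale = "log2_ratio")
    sMix <- scores(scoreWindows(mix, ann))
    sLin <- 3 * scores(scoreWindows(x, ann)) - 2 * scores(scoreWindows(y, ann))
    expect_equal(sMix, sLin, tolerance = 1e-9)
})

test_that("minus-strand genes read their genomic neighborhood in gene orientation", {
    ## signal covering oriented offsets [-100, -50) of a minus-strand gene
    sig <- rep(0, 2000)
    tssP <- 1000L
    for (d in -100:-51) sig[offsetToGenomic(tssP, "-", d) + 1L] <- 1
    trk <- OccupancyTrack(list(c1 = sig), scale = "linear")
    ann <- GenomeAnnotation("g1", "c1", "-", tss = tssP, tes = 200L,
                            chromSizes = c(c1 = 2000L))
    wm <- scoreWindows(trk, ann, promoterFrame())
    hit <- which(scores(wm)[1, ] == 1)
    expect_identical(colnames(scores(wm))[hit], "-100")
    ## oriented row equals the reversed genomic-order window means
    set.seed(12)
    v <- rnorm(2000)
    trk2 <- OccupancyTrack(list(c1 = v), scale = "log2_ratio")
    wm2 <- scoreWindows(trk2, ann, promoterFrame())
    genomic <- vapply(seq(0, 31), function(j) {
        lo <- tssP - 800L + 1L + j * 50L     # minus-strand grid is +1 shifted
        mean(v[(lo + 1L):(lo + 50L)])
    }, numeric(1))
    expect_equal(unname(scores(wm2)[1, ]), rev(genomic), tolerance = 1e-12)
})

test_that("genes on chromosomes missing from the track are masked with a warning", {
    ann <- GenomeAnnotation(c("a", "b"), c("c1", "c2"), "+",
                            tss = c(2000L, 2000L), tes = c(3000L, 3000L),
                            chromSizes = c(c1 = 9000L, c2 = 9000L))
    trk <- OccupancyTrack(list(c1 = rep(1, 9000)), scale = "linear")
    expect_warning(wm <- scoreWindows(trk, ann), "absent from track")
    expect_true(all(!validMask(wm)["b", ]))
    expect_true(any(validMask(wm)["a", ]))
})

test_that("WindowMatrix TSV round trip preserves scores, frame and mask", {
    set.seed(13)
    X <- matrix(rnorm(60), 5, 12)
    X[1, 2] <- NA
    wm <- matrixAsWindowMatrix(X, promoterFrame(300L, 50L))
    wm@mask[1, 2] <- FALSE
    f <- withr::local_tempfile()
    writeWindowMatrix(wm, f)
    back <- readWindowMatrix(f, scale = "log2_ratio")
    expect_equal(scores(back), scores(wm))
    expect_identical(validMask(back), validMask(wm))
    expect_equal(windowOffsets(back), windowOffsets(wm))
})
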