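linearMatrix <- function(X, frame = promoterFrame()) {
    matrixAsWindowMatrix(X, frame, scale = "linear")
}

test_that("ratio matrices are zero for identical inputs and exactly antisymmetric", {
    set.seed(21)
    X <- matrix(1 + rexp(96), 3, 32)
    a <- linearMatrix(X)
    b <- linearMatrix(X * 2)
    same <- ratioMatrix(a, a)
    expect_true(all(abs(scores(same)[validMask(same)]) < 1e-12))
    dbl <- ratioMatrix(b, a)
    expect_true(all(abs(scores(dbl)[validMask(dbl)] - 1) < 0.3))
    expect_gt(mean(scores(dbl)[validMask(dbl)]), 0.8)
    fwd <- ratioMatrix(b, a)
    rev <- ratioMatrix(a, b)
    expect_equal(scores(fwd), -scores(rev), tolerance = 1e-12)
    small <- linearMatrix(X[, 1:16, drop = FALSE], promoterFrame(400L, 50L))
    expect_error(ratioMatrix(a, small), "frames differ")
})

test_that("k = 1 clustering returns the column-wise mean of valid cells", {
    set.seed(22)
    X <- matrix(rnorm(64), 8, 8)
    X[1, 3] <- NA
    wm <- matrixAsWindowMatrix(X, promoterFrame(200L, 50L))
    cl <- kmeansProfiles(wm, k = 1L, seed = 1L, restarts = 3L)
    expect_true(all(assignments(cl) == 1L))
    expect_equal(unname(centroids(cl)[1, ]), colMeans(X, na.rm = TRUE),
                 tolerance = 1e-12)
})

test_that("planted two-archetype profiles are recovered perfectly (ARI = 1)", {
    set.seed(23)
    A <- sin(seq(0, 3 * pi, length.out = 32))
    noise <- 0.2                       # separation >> 3x noise SD
    X <- rbind(t(replicate(20, A + rnorm(32, 0, noise))),
               t(replicate(20, -A + rnorm(32, 0, noise))))
    wm <- matrixAsWindowMatrix(X)
    cl <- kmeansProfiles(wm, k = 2L, seed = 1L)
    expect_equal(adjustedRandIndex(assignments(cl), rep(1:2, each = 20)), 1)
})

test_that("attained inertia matches the exhaustive two-block optimum in 1-D", {
    set.seed(24)
    fr1 <- promoterFrame(25L, 50L)
    for (rep in 1:20) {
        x <- rnorm(6)
        wm <- matrixAsWindowMatrix(matrix(x, ncol = 1), fr1)
        cl <- kmeansProfiles(wm, k = 2L, seed = rep, restarts = 50L,
                             minValidFrac = 0)
        expect_equal(cl@inertia, minTwoBlockInertia(x), tolerance = 1e-9)
    }
})

test_that("clustering is deterministic, label-permutation-equivariant, and monotone in inertia", {
    set.seed(25)
    X <- matrix(rnorm(40 * 32), 40, 32) +
        rep(c(0, 3), each = 20)[row(matrix(0, 40, 32))]
    wm <- matrixAsWindowMatrix(X)
    c1 <- kmeansProfiles(wm, k = 3L, seed = 7L)
    c2 <- kmeansProfiles(wm, k = 3L, seed = 7L)
    expect_identical(assignments(c1), assignments(c2))
    expect_identical(centroids(c1), centroids(c2))
    expect_true(all(diff(c1@inertiaTrace) <= 1e-8))
    perm <- sample.int(40L)
    rownames(X) <- sprintf("g%03d", seq_len(40L))
    wm <- matrixAsWindowMatrix(X)
    c1 <- kmeansProfiles(wm, k = 3L, seed = 7L)
    wmP <- matrixAsWindowMatrix(X[perm, ])
    cP <- kmeansProfiles(wmP, k = 3L, seed = 7L)
    ## permuting rows permutes the assignments identically
    ids <- geneIds(wm)
    expect_identical(assignments(cP)[ids], assignments(c1)[ids])
    expect_identical(centroids(cP), centroids(c1))
    expect_error(kmeansProfiles(wm, k = 50L), "exceeds")
})

test_that("genes with mostly masked windows are set aside as unclustered", {
    set.seed(26)
    X <- matrix(rnorm(10 * 32), 10, 32)
    wm <- matrixAsWindowMatrix(X)
    wm@scores[1, 1:20] <- NA
    wm@mask[1, 1:20] <- FALSE
    cl <- kmeansProfiles(wm, k = 2L, seed = 1L)
    expect_true(is.na(assignments(cl)[1]))
    expect_true(all(!is.na(assignments(cl)[-1])))
})

test_that("cluster mean profiles: degenerate bands, weighted-mean identity, support flags", {
    row <- sin(seq(-1, 1, length.out = 32))
    X <- matrix(rep(row, each = 6), 6, 32)
    wm <- matrixAsWindowMatrix(X)
    cl <- kmeansProfiles(wm, k = 1L, seed = 1L, restarts = 2L)
    prof <- clusterMeanProfiles(wm, cl, nBoot = 200L, seed = 1L)
    expect_equal(prof$mean, row)
    expect_equal(prof$lower, prof$upper)        # identical rows: no spread
    expect_true(all(prof$flagged))              # 6 < 10 supporting genes
    set.seed(27)
    X2 <- matrix(rnorm(30 * 32), 30, 32) + rep(c(-2, 2), each = 15)
    wm2 <- matrixAsWindowMatrix(X2)
    cl2 <- kmeansProfiles(wm2, k = 2L, seed = 1L)
    prof2 <- clusterMeanProfiles(wm2, cl2, nBoot = 100L, seed = 1L)
    sizes <- table(assignments(cl2))
    pooled <- vapply(seq_len(32), function(j) {
        sum(vapply(1:2, function(c)
            sizes[[c]] * prof2$mean[prof2$cluster == c][j], numeric(1))) /
            sum(sizes)
    }, numeric(1))
    expect_equal(pooled, colMeans(X2), tolerance = 1e-12)
})

test_that("TSS scores honor the zone, the statistic and the validity mask", {
    X <- matrix(4, 3, 32)
    wm <- matrixAsWindowMatrix(X)
    expect_equal(unname(tssScore(wm, "mean")), rep(4, 3))
    X2 <- matrix(NA_real_, 1, 32)
    X2[1, 16] <- 7                      # offset [-50, 0): inside the zone
    wm2 <- matrixAsWindowMatrix(X2)
    expect_equal(unname(tssScore(wm2, "max")), 7)
    expect_error(tssScore(wm, halfWidth = 900), "flank")
    set.seed(28)
    ann <- randomAnnotation(50L)
    trk <- randomTrack(chromSizes(ann))
    wm3 <- scoreWindows(trk, ann)
    sc <- tssScore(wm3, "mean", 250)
    off <- windowOffsets(wm3)
    zone <- off + 50 > -250 & off < 250
    for (g in geneIds(wm3)) {
        vals <- scores(wm3)[g, zone]
        ref <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
        expect_equal(unname(sc[g]), ref, tolerance = 1e-12)
    }
})

test_that("assay correlation recovers exact and sampled relationships", {
    a <- setNames(c(1, 2, 3, 4, 5), letters[1:5])
    expect_equal(correlateAssays(a, a)$r, 1)
    flip <- correlateAssays(a, -a + 3)
    expect_equal(flip$r, -1)
    expect_equal(flip$slope, -1)
    expect_equal(flip$intercept, 3)
    set.seed(29)
    n <- 2000L
    x <- rnorm(n)
    y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
    r <- correlateAssays(setNames(x, seq_len(n)), setNames(y, seq_len(n)))
    expect_lt(abs(r$r - 0.6), 0.04)
    const <- setNames(rep(1, 5), letters[1:5])
    expect_true(is.na(correlateAssays(a, const)$r))
    expect_error(correlateAssays(a[1:2], a[1:2]), "at least 3")
})
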