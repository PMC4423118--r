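## Small cohorts keep these generator tests fast; the full default cohort is
## exercised by the acceptance suite.

smallConfig <- function(...) {
    syntheticConfig(nGenes = 40L, genesPerChrom = 20L,
                    fragmentsPerGene = 150L, nControlProbes = 30L, ...)
}

dirDigest <- function(dir) {
    files <- sort(list.files(dir, full.names = TRUE))
    setNames(tools::md5sum(files), basename(files))
}

## Cohort-mean fill-in of rscd vs wt measured through the standard chain.
measureFill <- function(dir, truth) {
    sizes <- readChromSizes(file.path(dir, "chrom.sizes"))
    ann <- loadAnnotation(file.path(dir, "genes.bed"), "BED6", sizes)
    mask <- neighborMask(ann)
    lg <- lapply(c(wt = "wt", rscd = "rscd"), function(gt) {
        trk <- midpointOccupancy(
            readFragments(file.path(dir, sprintf("fragments_%s.bed", gt)),
                          sizes), sizes, 20)
        log2RelativeToMean(scoreWindows(trk, ann, promoterFrame(), mask),
                           genomeMean(trk))
    })
    rep <- architectureReport(lg$wt, lg$rscd)
    mean(rep$fill_in[rep$gene_id %in%
                     truth$genes$gene_id[truth$genes$architecture == "open"]],
         na.rm = TRUE)
}

test_that("generation is deterministic and emits exactly the promised fragments", {
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    cfg <- smallConfig(seed = 5L)
    t1 <- generateCohort(cfg, d1)
    t2 <- generateCohort(cfg, d2)
    expect_identical(unname(dirDigest(d1)), unname(dirDigest(d2)))
    for (gt in c("wt", "rscd", "isw1d", "rscd_isw1d")) {
        nf <- nrow(read.delim(file.path(d1, sprintf("fragments_%s.bed", gt)),
                              header = FALSE))
        expect_equal(nf, cfg$nGenes * cfg$fragmentsPerGene)
    }
    ## the loader cross-checks truth against the emitted files
    expect_silent(truth <- readGroundTruth(d1))
    expect_equal(nrow(truth$genes), cfg$nGenes)
})

test_that("null genotype effects leave the rscd fragment distribution at wild type", {
    d <- withr::local_tempdir()
    truth <- generateCohort(smallConfig(seed = 6L, fillFraction = 0,
                                        shiftBp = 0), d)
    sizes <- readChromSizes(file.path(d, "chrom.sizes"))
    wt <- readFragments(file.path(d, "fragments_wt.bed"), sizes)
    mu <- readFragments(file.path(d, "fragments_rscd.bed"), sizes)
    tg <- truth$genes
    ps <- vapply(seq_len(nrow(tg)), function(i) {
        near <- function(fr) {
            mid <- (fr$start + fr$end) %/% 2L
            sel <- fr$chrom == tg$chrom[i] &
                abs(mid - tg$tss[i]) < 1100
            orientedOffset(tg$tss[i], tg$strand[i], mid[sel])
        }
        suppressWarnings(stats::ks.test(near(wt), near(mu))$p.value)
    }, numeric(1))
    expect_gt(median(ps), 0.2)
})

test_that("full suppression restores the double mutant to wild-type parameters", {
    cfg <- smallConfig(suppression = 1)
    for (arch in c("open", "closed")) {
        wt <- ndrscope:::dyadComponents(cfg, arch, 30, "wt")
        dbl <- ndrscope:::dyadComponents(cfg, arch, 30, "rscd_isw1d")
        expect_equal(wt, dbl)
    }
})

test_that("planted motif content equals a fresh scan of the emitted FASTA exactly", {
    d <- withr::local_tempdir()
    truth <- generateCohort(smallConfig(seed = 7L), d)
    seqs <- Biostrings::readDNAStringSet(file.path(d, "promoters.fa"))
    tab <- scanMotifs(seqs)
    tg <- truth$genes[match(tab$gene_id, truth$genes$gene_id), ]
    expect_identical(tab$TATA, as.integer(tg$TATA > 0))
    expect_identical(tab$Reb1, as.integer(tg$Reb1 > 0))
    expect_identical(tab$Rsc3, as.integer(tg$Rsc3 > 0))
    expect_identical(tab$polyA, as.integer(tg$polyA))
})

test_that("the composite wild-type open-promoter profile matches the dyad model", {
    d <- withr::local_tempdir()
    truth <- generateCohort(smallConfig(seed = 8L, fractionOpen = 1), d)
    sizes <- readChromSizes(file.path(d, "chrom.sizes"))
    ann <- loadAnnotation(file.path(d, "genes.bed"), "BED6", sizes)
    trk <- midpointOccupancy(readFragments(file.path(d, "fragments_wt.bed"),
                                           sizes), sizes, 20)
    lg <- log2RelativeToMean(scoreWindows(trk, ann, promoterFrame(),
                                          neighborMask(ann)),
                             genomeMean(trk))
    comp <- colMeans(scores(lg), na.rm = TRUE)
    off <- windowOffsets(lg)
    prom <- off >= -300 & off < 300
    ## minimum of the promoter-proximal composite falls inside the NDR zone
    minOff <- off[prom][which.min(comp[prom])]
    expect_gte(minOff + 50, -180)
    expect_lte(minOff, -20)
    ## first downstream peak sits at the +1 (mu = +60), within 15 bp
    ps <- plusOneShift(comp, comp, off, ndrEnd = minOff + 50)
    expect_lt(abs(ps$plus_one_wt - 60), 15.01)
})

test_that("cohort-mean fill-in increases strictly with the planted fill fraction", {
    fills <- c(0, 0.3, 0.6, 0.9)
    measured <- vapply(fills, function(f) {
        d <- withr::local_tempdir()
        truth <- generateCohort(smallConfig(seed = 9L, fillFraction = f), d)
        measureFill(d, truth)
    }, numeric(1))
    expect_true(all(diff(measured) > 0))
})

test_that("zero-effect configs recover near-zero effects downstream", {
    d <- withr::local_tempdir()
    ## a larger, deeper cohort: the null check pits cohort effect
    ## estimates against a 0.05 log2 band, which needs both many open
    ## promoters and decent per-gene coverage to resolve
    truth <- generateCohort(syntheticConfig(seed = 10L, nGenes = 200L,
                                            genesPerChrom = 25L,
                                            fragmentsPerGene = 800L,
                                            nControlProbes = 30L,
                                            fillFraction = 0, shiftBp = 0,
                                            isw1BodyShift = 0), d)
    sizes <- readChromSizes(file.path(d, "chrom.sizes"))
    ann <- loadAnnotation(file.path(d, "genes.bed"), "BED6", sizes)
    mask <- neighborMask(ann)
    lg <- lapply(c(wt = "wt", rscd = "rscd"), function(gt) {
        trk <- midpointOccupancy(
            readFragments(file.path(d, sprintf("fragments_%s.bed", gt)),
                          sizes), sizes, 20)
        log2RelativeToMean(scoreWindows(trk, ann, promoterFrame(), mask),
                           genomeMean(trk))
    })
    rep <- architectureReport(lg$wt, lg$rscd)
    openIds <- truth$genes$gene_id[truth$genes$architecture == "open"]
    rep <- rep[rep$gene_id %in% openIds, ]
    ## cohort-level fill estimate (composite, as metagene profiles are
    ## read) centered at 0
    expect_lt(abs(compositeFillIn(rep)), 0.05)
    expect_lt(abs(median(rep$shift_bp, na.rm = TRUE)), 5)
})

test_that("truth reports demand matching gene universes", {
    d <- withr::local_tempdir()
    truth <- generateCohort(smallConfig(seed = 12L), d)
    fake <- data.frame(gene_id = "nope", present = TRUE, shift_bp = 0,
                       fill_in = 0, promoter_class = "open")
    expect_error(truthReport(truth, architecture = fake), "universe")
})
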