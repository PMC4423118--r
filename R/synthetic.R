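## Synthetic-cohort generator: annotations, promoter sequences, per-genotype
## mono-nucleosome fragments, remodeler ChIP tracks and probe intensities,
## with recorded ground truth for every downstream metric.
##
## Nucleosome signal is simulated at the fragment level (not as idealized
## profiles) so the full tracks -> profiles -> architecture chain is
## exercised, including MNase-style sampling noise.  Open (structured)
## promoters carry the canonical -1 / NDR / +1 architecture with phased,
## decaying downstream nucleosomes; closed (unstructured) promoters carry
## the same components translated by a per-gene random phase and a mostly
## filled NDR, so they lack consensus structure relative to the TSS.

#' Build a validated synthetic-cohort configuration
#'
#' All values have defaults describing the cohort the package validates
#' itself on: 300 genes, 200 mono-nucleosome fragments per gene and
#' genotype, 165 bp nucleosome repeat, 147 +/- 10 bp fragment lengths,
#' a -40 bp RSC-loss +1 shift with 0.6 NDR fill fraction, 50% suppression
#' in the double mutant, ChIP enrichment doubled at closed promoters, and
#' an almost-twofold expression knockdown of coding/ncRNA (not tRNA)
#' genes.  Override any subset via \code{...}.
#'
#' @param ... named overrides of the defaults (see
#'   \code{str(syntheticConfig())}).
#' @return A validated list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(...) {
    cfg <- list(
        seed = 1L,
        nGenes = 300L,
        genesPerChrom = 30L,
        fractionOpen = 0.5,
        classFractions = c(coding = 0.755, ncRNA = 0.088, tRNA = 0.157),
        geneLengthRange = c(800L, 2000L),
        ## intergenic spacing: a mixture that keeps most promoters free of
        ## neighbors (>= 2*flank) but guarantees the neighbor-masking path
        ## is exercised by the short-spacing component
        fractionLongSpacing = 0.75,
        spacingLongMean = 2200, spacingLongSD = 300, spacingLongMin = 1600,
        spacingShortRange = c(400, 1400),
        ## fragments
        fragmentsPerGene = 200L,
        fragLenMean = 147, fragLenSD = 10, fragLenRange = c(120L, 180L),
        ## dyad mixture model (oriented bp)
        minusOneMu = -220, plusOneMu = 60, dyadSD = 20,
        period = 165, nPhased = 4L, sigmaStep = 5, weightDecay = 0.8,
        ndrZone = c(-180, -20),
        ndrBaselineOpen = 0.05, ndrBaselineClosed = 0.6,
        ## genotype effects
        fillFraction = 0.6, shiftBp = -40, isw1BodyShift = -10,
        suppression = 0.5,
        ## ChIP (log2 enrichment over input)
        chipEffect = 1, chipClosedMultiplier = 2, chipEnrichedFraction = 1,
        chipNoiseSD = 0.25, chipBinSize = 25L, chipBumpHalfWidth = 200L,
        ## promoter sequences / motif planting rates per architecture
        promoterRegion = c(-500L, 50L),
        motifRatesOpen = c(TATA = 0.1, Reb1 = 0.6, Rsc3 = 0.6),
        motifRatesClosed = c(TATA = 0.7, Reb1 = 0.1, Rsc3 = 0.1),
        polyAMeanOpen = 2, polyAMeanClosed = 0.3,
        ## expression (HybMap-style)
        nReplicates = 3L, probesPerGene = 3L, nControlProbes = 502L,
        exprNoiseSD = 0.15,
        exprEffectsSingle = c(coding = -1, ncRNA = -1, tRNA = 0),
        exprEffectsIsw1 = c(coding = -0.25, ncRNA = -0.25, tRNA = 0),
        nRestored = 15L, exprRestoreFraction = 0.8,
        ## analysis defaults mirrored by the truth computation
        smoothingBw = 20)
    over <- list(...)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
        stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    probs <- c(cfg$fractionOpen, cfg$fractionLongSpacing,
               cfg$fillFraction, cfg$suppression, cfg$chipEnrichedFraction,
               cfg$exprRestoreFraction, cfg$motifRatesOpen,
               cfg$motifRatesClosed, cfg$classFractions)
    if (any(probs < 0 | probs > 1))
        stopf("all probabilities/fractions must lie in [0, 1]")
    if (cfg$nGenes < 1L || cfg$fragmentsPerGene < 1L)
        stopf("nGenes and fragmentsPerGene must be positive")
    if (cfg$spacingLongMin < 2L * 800L)
        stopf("long spacing must be >= 2*flank so unmasked promoters exist")
    if (cfg$fragLenRange[1L] > cfg$fragLenMean ||
        cfg$fragLenRange[2L] < cfg$fragLenMean)
        stopf("fragment length range must bracket the mean")
    class(cfg) <- "SyntheticConfig"
    cfg
}

## Dyad mixture components of one gene/genotype in oriented bp:
## data.frame(mu, sigma, weight, uniform, z1, z2).  `phase` translates the
## whole architecture (closed promoters); genotype effects follow the
## planted parameter model.
dyadComponents <- function(cfg, architecture, phase, genotype) {
    kk <- seq_len(cfg$nPhased)
    mu <- c(cfg$minusOneMu, cfg$plusOneMu, cfg$plusOneMu + cfg$period * kk)
    sigma <- c(cfg$dyadSD, cfg$dyadSD, cfg$dyadSD + cfg$sigmaStep * kk)
    weight <- c(1, 1, cfg$weightDecay^kk)
    baseline <- if (architecture == "open") cfg$ndrBaselineOpen
                else cfg$ndrBaselineClosed
    shift <- 0
    if (architecture == "open") {
        if (genotype == "rscd")
            baseline <- baseline + cfg$fillFraction * (1 - baseline)
        if (genotype == "rscd_isw1d")
            baseline <- baseline +
                cfg$fillFraction * (1 - cfg$suppression) * (1 - baseline)
    }
    if (genotype == "rscd") shift <- cfg$shiftBp
    if (genotype == "rscd_isw1d") shift <- cfg$shiftBp * (1 - cfg$suppression)
    ## +1 and everything downstream shifts with RSC loss
    mu[-1L] <- mu[-1L] + shift
    ## ISW1 loss nudges gene-body nucleosomes (downstream of the +1) only
    if (genotype == "isw1d") mu[-(1:2)] <- mu[-(1:2)] + cfg$isw1BodyShift
    comp <- data.frame(mu = mu + phase, sigma = sigma, weight = weight,
                       uniform = FALSE, z1 = NA_real_, z2 = NA_real_)
    ndr <- data.frame(mu = NA_real_, sigma = NA_real_, weight = baseline,
                      uniform = TRUE, z1 = cfg$ndrZone[1L] + phase,
                      z2 = cfg$ndrZone[2L] + phase)
    rbind(comp, ndr)
}

## Sample n oriented dyad offsets from a component table.
sampleDyads <- function(comp, n) {
    pick <- sample.int(nrow(comp), n, replace = TRUE,
                       prob = comp$weight)
    d <- numeric(n)
    g <- !comp$uniform[pick]
    d[g] <- rnorm(sum(g), comp$mu[pick[g]], comp$sigma[pick[g]])
    d[!g] <- runif(sum(!g), comp$z1[pick[!g]], comp$z2[pick[!g]])
    round(d)
}

## Expected window profile of one gene/genotype in the infinite-fragment
## limit of the analysis pipeline: expected smoothed dyad density averaged
## over each frame window, then log2 relative to the analytic genome mean.
## Used to compute planted metric values (the closed-form limit oracle).
expectedWindowProfile <- function(cfg, architecture, phase, genotype,
                                  frame, genomeMeanDensity) {
    comp <- dyadComponents(cfg, architecture, phase, genotype)
    off <- windowOffsets(frame)
    w <- frame@window
    a <- off; b <- off + w
    mass <- numeric(length(off))
    bw <- cfg$smoothingBw
    for (i in seq_len(nrow(comp))) {
        if (comp$uniform[i]) {
            s <- max(bw, 1e-9)
            G <- function(t) t * pnorm(t / s) + s * dnorm(t / s)
            H <- function(x) G(x - comp$z1[i]) - G(x - comp$z2[i])
            mass <- mass + comp$weight[i] * (H(b) - H(a)) /
                (comp$z2[i] - comp$z1[i])
        } else {
            s <- sqrt(comp$sigma[i]^2 + bw^2)
            mass <- mass + comp$weight[i] *
                (pnorm((b - comp$mu[i]) / s) - pnorm((a - comp$mu[i]) / s))
        }
    }
    mass <- mass / sum(comp$weight)
    density <- cfg$fragmentsPerGene * mass / w   # expected per-bp density
    eps <- 0.1 * genomeMeanDensity
    log2((density + eps) / (genomeMeanDensity + eps))
}

## ---- sequence generation -------------------------------------------------

## Remove every match of the motif set (both strands) from a background
## sequence by point mutation, so planted counts are exact.
scrubSequence <- function(chars, motifs, maxIter = 50L) {
    bases <- c("A", "C", "G", "T")
    for (iter in seq_len(maxIter)) {
        seq <- paste(chars, collapse = "")
        hit <- FALSE
        for (i in seq_len(nrow(motifs))) {
            rx <- iupacToRegex(motifs$pattern[i])
            for (s in c(seq, revComp(seq))) {
                m <- gregexpr(rx, s, perl = TRUE)[[1L]]
                if (m[1L] == -1L) next
                hit <- TRUE
                len <- attr(m, "match.length")
                pos <- if (s == seq) as.integer(m) + len %/% 2L
                       else nchar(seq) - (as.integer(m) + len %/% 2L) + 1L
                for (p in pos)
                    chars[p] <- sample(setdiff(bases, chars[p]), 1L)
                seq <- paste(chars, collapse = "")
            }
        }
        if (!hit) return(chars)
    }
    chars
}

## Realize one concrete instance of a motif pattern, fixed choices that do
## not collide with the other motifs in the default set.
motifInstance <- function(name) {
    switch(name,
           TATA = "TATATAAG", Reb1 = "TTACCCG", Rsc3 = "CGCGC",
           polyA = "CAAAAAC",   # guard bases isolate the A-run
           stopf("no planting rule for motif '%s'", name))
}

## Plant instances at random non-overlapping positions (1 bp guard).
plantInstances <- function(chars, instances) {
    occupied <- rep(FALSE, length(chars))
    for (ins in instances) {
        insChars <- strsplit(ins, "")[[1L]]
        li <- length(insChars)
        spots <- which(!occupied)
        placed <- FALSE
        for (try in seq_len(200L)) {
            p <- sample.int(length(chars) - li + 1L, 1L)
            span <- max(1L, p - 1L):min(length(chars), p + li)
            if (any(occupied[span])) next
            chars[p:(p + li - 1L)] <- insChars
            occupied[span] <- TRUE
            placed <- TRUE
            break
        }
        if (!placed) return(NULL)
    }
    chars
}

## Generate one promoter sequence with exactly the intended motif content;
## verified by re-scanning, retried on collisions.
generatePromoterSequence <- function(len, want, motifs, maxTries = 50L) {
    for (try in seq_len(maxTries)) {
        chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        chars <- scrubSequence(chars, motifs)
        instances <- c(
            if (want[["TATA"]] > 0) rep(motifInstance("TATA"), 1L),
            if (want[["Reb1"]] > 0) rep(motifInstance("Reb1"), 1L),
            if (want[["Rsc3"]] > 0) rep(motifInstance("Rsc3"), 1L),
            rep(motifInstance("polyA"), want[["polyA"]]))
        planted <- if (length(instances))
            plantInstances(chars, sample(instances)) else chars
        if (is.null(planted)) next
        seq <- paste(planted, collapse = "")
        got <- vapply(seq_len(nrow(motifs)), function(i)
            scanOne(seq, motifs$pattern[i], motifs$both_strands[i],
                    motifs$count_mode[i]), numeric(1))
        names(got) <- motifs$name
        target <- c(TATA = as.numeric(want[["TATA"]] > 0),
                    Reb1 = as.numeric(want[["Reb1"]] > 0),
                    Rsc3 = as.numeric(want[["Rsc3"]] > 0),
                    polyA = want[["polyA"]])
        if (all(got[names(target)] == target)) return(seq)
    }
    stopf("could not realize the requested motif content in %d tries",
          maxTries)
}

## ---- cohort generation ---------------------------------------------------

#' Generate a synthetic chromatin cohort with planted ground truth
#'
#' Emits, under \code{outDir}: \code{genes.bed} (BED6) +
#' \code{chrom.sizes} + \code{gene_classes.tsv}; \code{promoters.fa}
#' (FASTA over the oriented promoter region, motifs planted at the
#' configured per-architecture rates); per-genotype mono-nucleosome
#' fragment files \code{fragments_<genotype>.bed} for wt, rscd, isw1d and
#' rscd_isw1d sampled from the dyad mixture model; \code{chip.bedgraph}
#' and \code{input.bedgraph} (log2 enrichment, closed promoters boosted);
#' per-genotype probe tables \code{probes_<genotype>.tsv} (wt, rsc2,
#' isw1, rsc2_isw1 with non-hybridizing control probes); and
#' \code{truth.json} with the per-gene ground truth, including the
#' planted metric values in the infinite-fragment limit of the analysis
#' pipeline (closed-form expected profiles).  Byte-identical outputs for
#' a given config (the seed lives in the config).
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param outDir output directory (created).
#' @return Invisibly, the ground-truth list (also written as JSON).
#' @export
generateCohort <- function(config = syntheticConfig(), outDir) {
    stopifnot(inherits(config, "SyntheticConfig"))
    cfg <- config
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    withSeed(cfg$seed, generateCohortImpl(cfg, outDir))
}

generateCohortImpl <- function(cfg, outDir) {
    n <- cfg$nGenes
    nChrom <- ceiling(n / cfg$genesPerChrom)
    chromOf <- rep(sprintf("chr%02d", seq_len(nChrom)),
                   each = cfg$genesPerChrom)[seq_len(n)]
    margin <- 1500L
    ## chromosome layout
    strand <- sample(c("+", "-"), n, replace = TRUE)
    geneLen <- round(runif(n, cfg$geneLengthRange[1L], cfg$geneLengthRange[2L]))
    start <- integer(n); end <- integer(n)
    sizes <- integer(nChrom); names(sizes) <- sprintf("chr%02d", seq_len(nChrom))
    for (chr in names(sizes)) {
        idx <- which(chromOf == chr)
        cursor <- margin
        for (i in idx) {
            start[i] <- cursor
            end[i] <- cursor + geneLen[i]
            gap <- if (runif(1) < cfg$fractionLongSpacing)
                max(cfg$spacingLongMin,
                    round(rnorm(1, cfg$spacingLongMean, cfg$spacingLongSD)))
            else round(runif(1, cfg$spacingShortRange[1L],
                             cfg$spacingShortRange[2L]))
            cursor <- end[i] + gap
        }
        sizes[chr] <- cursor + margin
    }
    ids <- sprintf("gene%03d", seq_len(n))
    tss <- ifelse(strand == "+", start, end - 1L)
    tes <- ifelse(strand == "+", end, start)
    geneClass <- sample(names(cfg$classFractions), n, replace = TRUE,
                        prob = cfg$classFractions)
    architecture <- ifelse(runif(n) < cfg$fractionOpen, "open", "closed")
    phase <- ifelse(architecture == "closed",
                    runif(n, 0, cfg$period), 0)
    ann <- GenomeAnnotation(ids, chromOf, strand, tss, tes, geneClass, sizes)
    ord <- match(geneIds(ann), ids)   # annotation is span-sorted

    writeAnnotation(ann, file.path(outDir, "genes.bed"), "BED6")
    writeChromSizes(sizes, file.path(outDir, "chrom.sizes"))
    write.table(data.frame(ids, geneClass)[ord, ],
                file.path(outDir, "gene_classes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)

    ## ---- fragments per genotype ----
    genotypes <- c("wt", "rscd", "isw1d", "rscd_isw1d")
    for (gt in genotypes) {
        rows <- vector("list", n)
        for (i in seq_len(n)) {
            comp <- dyadComponents(cfg, architecture[i], phase[i], gt)
            d <- sampleDyads(comp, cfg$fragmentsPerGene)
            mid <- offsetToGenomic(tss[i], strand[i], d)
            len <- pmin(cfg$fragLenRange[2L],
                        pmax(cfg$fragLenRange[1L],
                             round(rnorm(cfg$fragmentsPerGene,
                                         cfg$fragLenMean, cfg$fragLenSD))))
            ## keep fragments on the chromosome
            mid <- pmin(pmax(mid, 91L), sizes[[chromOf[i]]] - 91L)
            fs <- as.integer(mid - len %/% 2L)
            rows[[i]] <- data.frame(chrom = chromOf[i], start = fs,
                                    end = fs + len)
        }
        frag <- do.call(rbind, rows)
        write.table(frag, file.path(outDir,
                                    sprintf("fragments_%s.bed", gt)),
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    }

    ## ---- promoter sequences with planted motifs ----
    motifs <- defaultMotifs()
    seqLen <- cfg$promoterRegion[2L] - cfg$promoterRegion[1L]
    wantTata <- wantReb1 <- wantRsc3 <- integer(n); wantPolyA <- integer(n)
    seqs <- character(n)
    for (i in seq_len(n)) {
        rates <- if (architecture[i] == "open") cfg$motifRatesOpen
                 else cfg$motifRatesClosed
        polyAMean <- if (architecture[i] == "open") cfg$polyAMeanOpen
                     else cfg$polyAMeanClosed
        wantTata[i] <- rbinom(1L, 1L, rates[["TATA"]])
        wantReb1[i] <- rbinom(1L, 1L, rates[["Reb1"]])
        wantRsc3[i] <- rbinom(1L, 1L, rates[["Rsc3"]])
        wantPolyA[i] <- rpois(1L, polyAMean)
        seqs[i] <- generatePromoterSequence(
            seqLen,
            list(TATA = wantTata[i], Reb1 = wantReb1[i],
                 Rsc3 = wantRsc3[i], polyA = wantPolyA[i]), motifs)
    }
    dss <- Biostrings::DNAStringSet(setNames(seqs, ids)[ord])
    Biostrings::writeXStringSet(dss, file.path(outDir, "promoters.fa"))

    ## ---- ChIP and input tracks ----
    enriched <- runif(n) < cfg$chipEnrichedFraction
    chipEffect <- ifelse(enriched,
                         cfg$chipEffect *
                             ifelse(architecture == "closed",
                                    cfg$chipClosedMultiplier, 1), 0)
    binNoise <- function(size) {
        nb <- ceiling(size / cfg$chipBinSize)
        rep(rnorm(nb, 0, cfg$chipNoiseSD), each = cfg$chipBinSize)[seq_len(size)]
    }
    mkTrack <- function(withBumps) {
        sig <- lapply(names(sizes), function(chr) {
            v <- binNoise(sizes[[chr]])
            if (withBumps) for (i in which(chromOf == chr & enriched)) {
                lo <- offsetToGenomic(tss[i], strand[i],
                                      -cfg$chipBumpHalfWidth)
                hi <- offsetToGenomic(tss[i], strand[i],
                                      cfg$chipBumpHalfWidth)
                rng <- (min(lo, hi) + 1L):max(lo, hi)
                v[rng] <- v[rng] + chipEffect[i]
            }
            v
        })
        names(sig) <- names(sizes)
        OccupancyTrack(sig, scale = "log2_ratio",
                       label = if (withBumps) "chip" else "input")
    }
    writeTrack(mkTrack(TRUE), file.path(outDir, "chip.bedgraph"))
    writeTrack(mkTrack(FALSE), file.path(outDir, "input.bedgraph"))

    ## ---- probe tables ----
    exprGenotypes <- c(wt = "wt", rsc2 = "rsc2", isw1 = "isw1",
                       dbl = "rsc2_isw1")
    baseLevel <- rnorm(n, 8, 1)
    restored <- rep(FALSE, n)
    coding <- which(geneClass == "coding")
    restored[sample(coding, min(cfg$nRestored, length(coding)))] <- TRUE
    effS <- cfg$exprEffectsSingle[geneClass]
    effI <- cfg$exprEffectsIsw1[geneClass]
    effD <- ifelse(restored, effS * (1 - cfg$exprRestoreFraction), effS)
    effects <- list(wt = rep(0, n), rsc2 = effS, isw1 = effI, dbl = effD)
    reps <- paste0("rep", seq_len(cfg$nReplicates))
    for (gtKey in names(exprGenotypes)) {
        eff <- effects[[gtKey]]
        ## per-replicate array gain, shared by gene and control probes of
        ## one hybridization; the control-probe scaling removes it
        gain <- rnorm(cfg$nReplicates, 0, 0.5)
        probeRows <- vector("list", n + 1L)
        for (i in seq_len(n)) {
            pid <- sprintf("%s_p%d", ids[i], seq_len(2L * cfg$probesPerGene))
            pstrand <- rep(c("sense", "antisense"), each = cfg$probesPerGene)
            level <- ifelse(pstrand == "sense", baseLevel[i] + eff[i],
                            baseLevel[i] - 3)
            m <- matrix(2^(level + rep(gain, each = length(pid)) +
                               rnorm(length(pid) * cfg$nReplicates,
                                     0, cfg$exprNoiseSD)),
                        nrow = length(pid))
            colnames(m) <- reps
            probeRows[[i]] <- data.frame(probe_id = pid, gene_id = ids[i],
                                         control = 0L, strand = pstrand, m)
        }
        cm <- sapply(seq_len(cfg$nReplicates), function(r)
            2^(4 + gain[r] + rnorm(cfg$nControlProbes, 0, 0.2)))
        colnames(cm) <- reps
        probeRows[[n + 1L]] <-
            data.frame(probe_id = sprintf("zf_ctrl_%03d",
                                          seq_len(cfg$nControlProbes)),
                       gene_id = "", control = 1L, strand = ".", cm)
        tab <- do.call(rbind, probeRows)
        write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                    file.path(outDir, sprintf("probes_%s.tsv",
                                              exprGenotypes[[gtKey]])),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }

    ## ---- ground truth, incl. analytic planted metric values ----
    frame <- promoterFrame()
    genomeMeanDensity <- (n * cfg$fragmentsPerGene) / sum(sizes)
    off <- windowOffsets(frame)
    planted <- lapply(seq_len(n), function(i) {
        prof <- lapply(genotypes, function(gt)
            expectedWindowProfile(cfg, architecture[i], phase[i], gt,
                                  frame, genomeMeanDensity))
        names(prof) <- genotypes
        ndr <- detectNDR(prof$wt, off)
        ## fill truth mirrors the estimator: same extended window set
        ndrF <- fillWindows(prof$wt, off, ndr)
        fillS <- fillInScore(prof$wt, prof$rscd, off, ndrF)
        fillD <- fillInScore(prof$wt, prof$rscd_isw1d, off, ndrF)
        shS <- plusOneShift(prof$wt, prof$rscd, off,
                            ndrEnd = if (ndr$present) ndr$ndr_end else NA)
        shD <- plusOneShift(prof$wt, prof$rscd_isw1d, off,
                            ndrEnd = if (ndr$present) ndr$ndr_end else NA)
        data.frame(fill_rscd = fillS, fill_dbl = fillD,
                   shift_rscd = shS$shift_bp, shift_dbl = shD$shift_bp,
                   ndr_present = ndr$present,
                   ndr_start = ndr$ndr_start, ndr_end = ndr$ndr_end)
    })
    planted <- do.call(rbind, planted)
    suppFill <- ifelse(!is.na(planted$fill_rscd) & planted$fill_rscd != 0,
                       1 - planted$fill_dbl / planted$fill_rscd, NA_real_)
    suppShift <- ifelse(!is.na(planted$shift_rscd) & planted$shift_rscd != 0,
                        1 - planted$shift_dbl / planted$shift_rscd, NA_real_)
    genes <- data.frame(
        gene_id = ids, chrom = chromOf, strand = strand, tss = tss,
        tes = tes, gene_class = geneClass, architecture = architecture,
        phase = round(phase, 3),
        planted_ndr_start = ifelse(architecture == "open",
                                   cfg$ndrZone[1L], NA_real_) + phase * 0,
        planted_ndr_end = ifelse(architecture == "open",
                                 cfg$ndrZone[2L], NA_real_),
        plus_one_wt = cfg$plusOneMu + phase,
        plus_one_rscd = cfg$plusOneMu + phase + cfg$shiftBp,
        plus_one_isw1d = cfg$plusOneMu + phase,
        plus_one_dbl = cfg$plusOneMu + phase +
            cfg$shiftBp * (1 - cfg$suppression),
        planted_shift_rscd = cfg$shiftBp,
        planted_shift_dbl = cfg$shiftBp * (1 - cfg$suppression),
        limit_fill_rscd = planted$fill_rscd,
        limit_fill_dbl = planted$fill_dbl,
        limit_shift_rscd = planted$shift_rscd,
        limit_shift_dbl = planted$shift_dbl,
        limit_suppression_fill = suppFill,
        limit_suppression_shift = suppShift,
        limit_ndr_present = planted$ndr_present,
        limit_ndr_start = planted$ndr_start,
        limit_ndr_end = planted$ndr_end,
        chip_enriched = enriched, chip_effect = chipEffect,
        expr_effect_rsc2 = unname(effS), expr_effect_isw1 = unname(effI),
        expr_effect_dbl = unname(effD), restored = restored,
        TATA = wantTata, Reb1 = wantReb1, Rsc3 = wantRsc3,
        polyA = wantPolyA, stringsAsFactors = FALSE)
    truth <- list(config = unclass(cfg), genes = genes[ord, ])
    jsonlite::write_json(truth, file.path(outDir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    invisible(truth)
}

#' Read the ground truth of a generated cohort
#'
#' Reloads \code{truth.json} and, when \code{checkDir} is TRUE, verifies
#' its consistency with the emitted files (gene universe of the BED
#' annotation, and exact per-genotype fragment counts).
#'
#' @param dir cohort directory from \code{\link{generateCohort}}.
#' @param checkDir verify truth/file consistency (default TRUE).
#' @return list with \code{config} and \code{genes} (data.frame).
#' @export
readGroundTruth <- function(dir, checkDir = TRUE) {
    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
    ## columns containing JSON nulls (NA metric values) come back as lists
    truth$genes[] <- lapply(truth$genes, function(col) {
        if (is.list(col))
            vapply(col, function(x) if (is.null(x)) NA_real_
                   else as.numeric(x), numeric(1))
        else col
    })
    class(truth$config) <- "SyntheticConfig"
    if (checkDir) {
        sizes <- readChromSizes(file.path(dir, "chrom.sizes"))
        ann <- loadAnnotation(file.path(dir, "genes.bed"), "BED6", sizes)
        if (!identical(sort(geneIds(ann)), sort(truth$genes$gene_id)))
            stopf("truth.json and genes.bed disagree on the gene universe")
        nExp <- nrow(truth$genes) * truth$config$fragmentsPerGene
        for (gt in c("wt", "rscd", "isw1d", "rscd_isw1d")) {
            nf <- length(readLines(file.path(dir, sprintf("fragments_%s.bed",
                                                          gt))))
            if (nf != nExp)
                stopf("fragment count mismatch for %s: %d != %d", gt, nf, nExp)
        }
    }
    truth
}

#' Recovery metrics of a pipeline run against the planted ground truth
#'
#' Compares pipeline outputs with the generator's ground truth and returns
#' one row per metric: bias and RMSE of the +1 shift and NDR fill-in
#' (against the planted infinite-fragment-limit values), open/closed
#' classification accuracy, adjusted Rand index of the clustering against
#' planted architecture classes, precision/recall of enriched-promoter
#' calls, and recall/false count of the suppressed-gene screen.
#'
#' @param truth ground truth from \code{\link{readGroundTruth}} or
#'   \code{\link{generateCohort}}.
#' @param architecture optional data.frame from
#'   \code{\link{architectureReport}}.
#' @param clusters optional \linkS4class{ClusterResult}.
#' @param chipCalls optional result of \code{\link{callEnrichedPromoters}}.
#' @param screen optional result of \code{\link{suppressedGeneScreen}}.
#' @return data.frame with columns \code{metric}, \code{value}, \code{n}.
#' @export
truthReport <- function(truth, architecture = NULL, clusters = NULL,
                        chipCalls = NULL, screen = NULL) {
    tg <- truth$genes
    out <- list()
    add <- function(metric, value, n)
        out[[length(out) + 1L]] <<- data.frame(metric = metric,
                                               value = value, n = n)
    if (!is.null(architecture)) {
        if (!all(architecture$gene_id %in% tg$gene_id))
            stopf("architecture report and truth cover different universes")
        m <- merge(architecture, tg, by = "gene_id")
        open <- m[m$architecture == "open", ]
        dShift <- open$shift_bp - open$limit_shift_rscd
        add("shift_bias_bp", mean(dShift, na.rm = TRUE), sum(!is.na(dShift)))
        add("shift_rmse_bp", sqrt(mean(dShift^2, na.rm = TRUE)),
            sum(!is.na(dShift)))
        dFill <- open$fill_in - open$limit_fill_rscd
        add("fill_bias_log2", mean(dFill, na.rm = TRUE), sum(!is.na(dFill)))
        add("fill_rmse_log2", sqrt(mean(dFill^2, na.rm = TRUE)),
            sum(!is.na(dFill)))
        okCls <- !is.na(m$promoter_class)
        add("class_accuracy",
            mean(m$promoter_class[okCls] == m$architecture[okCls]),
            sum(okCls))
        if ("suppression_shift" %in% names(m)) {
            add("suppression_shift_median",
                median(open$suppression_shift, na.rm = TRUE),
                sum(!is.na(open$suppression_shift)))
            add("suppression_fill_median",
                median(open$suppression_fill, na.rm = TRUE),
                sum(!is.na(open$suppression_fill)))
        }
    }
    if (!is.null(clusters)) {
        a <- assignments(clusters)
        cls <- setNames(tg$architecture, tg$gene_id)[names(a)]
        add("cluster_ari", adjustedRandIndex(a, cls), sum(!is.na(a)))
    }
    if (!is.null(chipCalls)) {
        called <- tg$gene_id %in% chipCalls$calls
        truthFlag <- tg$chip_enriched
        add("chip_precision",
            if (sum(called)) mean(truthFlag[called]) else NA_real_,
            sum(called))
        add("chip_recall",
            if (sum(truthFlag)) mean(called[truthFlag]) else NA_real_,
            sum(truthFlag))
    }
    if (!is.null(screen)) {
        hits <- tg$gene_id %in% screen$selected
        add("screen_recall",
            if (sum(tg$restored)) mean(hits[tg$restored]) else NA_real_,
            sum(tg$restored))
        add("screen_false_selections", sum(hits & !tg$restored),
            sum(!tg$restored))
    }
    do.call(rbind, out)
}
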