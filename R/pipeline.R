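## End-to-end driver over a generated (or equivalently formatted) cohort
## directory: score -> cluster -> architecture -> enrichment -> expression.
## Every output is a plain TSV; with a fixed seed two runs are
## byte-identical.

#' Run the full promoter-chromatin pipeline on a cohort directory
#'
#' Expects the file layout written by \code{\link{generateCohort}}:
#' \code{genes.bed}, \code{chrom.sizes}, \code{gene_classes.tsv},
#' \code{fragments_<genotype>.bed} (wt, rscd, rscd_isw1d at least),
#' \code{chip.bedgraph} + \code{input.bedgraph}, \code{promoters.fa} and
#' \code{probes_*.tsv}.  Writes, under \code{outDir}: per-genotype log2
#' occupancy window matrices, the rscd/wt log2 ratio matrix, k-means
#' cluster assignments and centroids, per-cluster mean profiles, the
#' per-gene architecture report, FDR-based enriched-promoter calls,
#' motif-enrichment tests (open vs closed promoters), the class-wise
#' expression ratio summary and the suppressed-gene screen.
#'
#' @param dir cohort directory.
#' @param outDir output directory for the TSVs (created).
#' @param seed seed for every stochastic step (k-means restarts, shifts,
#'   permutations, bootstrap).
#' @param k number of promoter clusters.
#' @param smoothingBw dyad-density smoothing bandwidth in bp.
#' @param frame the \linkS4class{PromoterFrame} used for scoring.
#' @param fdr FDR for enriched-promoter calling.
#' @param nPermutations permutations for the motif-enrichment tests.
#' @param chipB circular shifts for the enrichment null.
#' @return Invisibly, a list with the in-memory results (annotation,
#'   matrices, clusters, architecture, chip calls, motif enrichment,
#'   expression summaries).
#' @export
runPipeline <- function(dir, outDir, seed = 1L, k = 6L, smoothingBw = 20,
                        frame = promoterFrame(), fdr = 0.01,
                        nPermutations = 10000L, chipB = 1000L) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    sizes <- readChromSizes(file.path(dir, "chrom.sizes"))
    ann <- loadAnnotation(file.path(dir, "genes.bed"), "BED6", sizes,
                          geneClass = file.path(dir, "gene_classes.tsv"))
    mask <- neighborMask(ann, frame)

    ## nucleosome occupancy per genotype
    genotypes <- c("wt", "rscd", "rscd_isw1d")
    linear <- list(); log2m <- list()
    for (gt in genotypes) {
        frag <- readFragments(file.path(dir, sprintf("fragments_%s.bed", gt)),
                              sizes)
        track <- midpointOccupancy(frag, sizes, smoothingBw)
        wm <- scoreWindows(track, ann, frame, mask)
        wm@label <- gt
        linear[[gt]] <- wm
        log2m[[gt]] <- log2RelativeToMean(wm, genomeMean(track))
        writeWindowMatrix(log2m[[gt]],
                          file.path(outDir, sprintf("matrix_%s.tsv", gt)))
    }

    ## promoter response clustering on the rscd/wt ratio profiles
    ratio <- ratioMatrix(linear$rscd, linear$wt)
    writeWindowMatrix(ratio, file.path(outDir, "ratio_rscd.tsv"))
    clusters <- kmeansProfiles(ratio, k = k, seed = seed)
    write.table(data.frame(gene_id = geneIds(clusters),
                           cluster = assignments(clusters)),
                file.path(outDir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cent <- data.frame(cluster = seq_len(clusters@k), centroids(clusters),
                       check.names = FALSE)
    write.table(cent, file.path(outDir, "centroids.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    profiles <- clusterMeanProfiles(log2m$wt, clusters, seed = seed)
    write.table(profiles, file.path(outDir, "cluster_profiles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    ## per-gene promoter architecture
    arch <- architectureReport(log2m$wt, log2m$rscd, log2m$rscd_isw1d)
    write.table(arch, file.path(outDir, "architecture.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    ## remodeler ChIP enrichment calling (control-track null)
    chip <- readTrack(file.path(dir, "chip.bedgraph"), "bedGraph", sizes,
                      scale = "log2_ratio", label = "chip")
    input <- readTrack(file.path(dir, "input.bedgraph"), "bedGraph", sizes,
                       scale = "log2_ratio", label = "input")
    chipWm <- scoreWindows(chip, ann, frame, mask)
    chipScores <- tssScore(chipWm, "mean")
    calls <- callEnrichedPromoters(chipScores, ann, input, "control_track",
                                   B = chipB, fdr = fdr, seed = seed,
                                   windowMatrix = chipWm)
    write.table(data.frame(gene_id = names(calls$p), score = chipScores,
                           p = calls$p, q = calls$q,
                           called = names(calls$p) %in% calls$calls),
                file.path(outDir, "enriched_promoters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    ## sequence-element enrichment in open vs closed promoters
    seqs <- Biostrings::readDNAStringSet(file.path(dir, "promoters.fa"))
    motifTable <- scanMotifs(seqs)
    openGenes <- arch$gene_id[!is.na(arch$promoter_class) &
                              arch$promoter_class == "open"]
    closedGenes <- arch$gene_id[!is.na(arch$promoter_class) &
                                arch$promoter_class == "closed"]
    motifs <- defaultMotifs()
    enr <- do.call(rbind, lapply(seq_len(nrow(motifs)), function(i) {
        stat <- setNames(motifTable[[motifs$name[i]]], motifTable$gene_id)
        rbind(cbind(motif = motifs$name[i],
                    permutationEnrichment(stat, openGenes,
                                          motifTable$gene_id,
                                          nPermutations,
                                          childSeed(seed, i),
                                          name = "open")),
              cbind(motif = motifs$name[i],
                    permutationEnrichment(stat, closedGenes,
                                          motifTable$gene_id,
                                          nPermutations,
                                          childSeed(seed, 100 + i),
                                          name = "closed")))
    }))
    write.table(enr, file.path(outDir, "motif_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    ## HybMap-style expression
    expr <- lapply(c(wt = "wt", single = "rsc2", double = "rsc2_isw1"),
                   function(gt) {
        tab <- scaleToControls(readProbeTable(
            file.path(dir, sprintf("probes_%s.tsv", gt))))
        geneExpression(tab, gt)
    })
    tx <- ann@transcripts
    classes <- setNames(tx$gene_class, tx$id)
    classSummary <- classRatioSummary(expr$single, expr$wt, classes)
    write.table(classSummary, file.path(outDir,
                                        "expression_class_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    screen <- suppressedGeneScreen(expr$wt, expr$single, expr$double)
    write.table(screen$table, file.path(outDir, "suppressed_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    invisible(list(annotation = ann, mask = mask, linear = linear,
                   log2 = log2m, ratio = ratio, clusters = clusters,
                   clusterProfiles = profiles, architecture = arch,
                   chipScores = chipScores, chipCalls = calls,
                   motifTable = motifTable, motifEnrichment = enr,
                   expression = expr, classSummary = classSummary,
                   screen = screen))
}
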