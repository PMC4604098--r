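#' Configuration for an end-to-end synthetic pipeline run
#'
#' Collects the analysis constants of the cross-stress workflow (fold
#' cutoffs 2 and 1.5, Pearson threshold 0.7, elim cutoff 0.01, the
#' P1BS pattern GNATATNC, 3000 bp upstream windows, 1000 bp proximal
#' cutoff) together with the synthetic-generation sizes. Defaults are
#' desk-scale versions of a two-contrast root study: two contrasts with
#' three biological replicates each, a shared gene universe, a planted
#' overlapping DEG set with a realistic mix of the four regulatory
#' types, co-expression modules planted at expected within-module r =
#' 0.9 over 200 arrays, a small GO universe with one over-represented
#' term, and promoters with planted P1BS instances.
#'
#' @param seed master integer seed; every stage derives its own
#'   documented sub-seed from it.
#' @param nGenes size of the shared gene universe.
#' @param nDegPerContrast planted DEGs per contrast (including the
#'   shared ones).
#' @param nOverlap planted DEGs shared by both contrasts.
#' @param typeWeights expected proportions of the four regulatory types
#'   among shared DEGs (down/down, up/up, Pi-up Fe-down, Fe-up
#'   Pi-down); default scaled from a 223:169:97:90 mix.
#' @param nReps replicates per condition.
#' @param noiseCv replicate coefficient of variation.
#' @param zeroControlFraction fraction of planted DEGs with all-zero
#'   controls.
#' @param foldCutoffs fold cutoffs applied downstream; first element is
#'   the main filter.
#' @param nArrays compendium arrays.
#' @param moduleSizes sizes of planted co-expression modules (drawn
#'   from the overlap genes).
#' @param latentWeight,noiseSd compendium module strength (weight 3,
#'   sd 1 gives expected within-module r = 0.9).
#' @param corThreshold network correlation threshold.
#' @param goTerms,goDepth,goCutoff GO universe size, depth and elim
#'   cutoff.
#' @param enrichmentOdds planted GO enrichment odds.
#' @param motifPattern degenerate motif scanned in promoters.
#' @param upstreamLength promoter length (bp).
#' @param withinDistance proximal-promoter cutoff (bp).
#' @param nPlantedMotifGenes promoters that receive a planted motif
#'   instance.
#' @return a named list of class \code{fepiConfig}.
#' @export
pipelineConfig <- function(seed = 1L,
                           nGenes = 1500L,
                           nDegPerContrast = 300L,
                           nOverlap = 120L,
                           typeWeights = c(223, 169, 97, 90) / 579,
                           nReps = 3L,
                           noiseCv = 0.1,
                           zeroControlFraction = 0.03,
                           foldCutoffs = c(2, 1.5),
                           nArrays = 200L,
                           moduleSizes = c(10L, 6L),
                           latentWeight = 3,
                           noiseSd = 1,
                           corThreshold = 0.7,
                           goTerms = 40L,
                           goDepth = 5L,
                           goCutoff = 0.01,
                           enrichmentOdds = 10,
                           motifPattern = "GNATATNC",
                           upstreamLength = 3000L,
                           withinDistance = 1000L,
                           nPlantedMotifGenes = 12L) {
    cfg <- as.list(environment())
    if (any(cfg$foldCutoffs <= 1))
        stop("fold cutoffs must be greater than 1")
    if (cfg$corThreshold <= 0 || cfg$corThreshold > 1)
        stop("corThreshold must be in (0, 1]")
    compileIupac(cfg$motifPattern)
    if (cfg$nOverlap > cfg$nDegPerContrast)
        stop("nOverlap cannot exceed nDegPerContrast")
    structure(cfg, class = "fepiConfig")
}

# Draw a fold magnitude >= 1 (log-half-normal) and orient it.
orientedFolds <- function(n, up, sdlog = 0.7) {
    mag <- exp(abs(stats::rnorm(n, sd = sdlog)))
    ifelse(up, mag, 1 / mag)
}

#' Run the cross-stress analysis pipeline end to end on synthetic data
#'
#' Generates the four synthetic input classes under one master seed and
#' executes the full workflow in order: DEG-list overlap, fold-change
#' computation with the undetermined-control convention, fold-cutoff
#' filtering, four-type classification, hierarchical clustering of the
#' filtered genes, co-expression network and module detection over a
#' planted compendium, GO elim enrichment over a planted ontology, and
#' P1BS promoter scanning of the type-4 subset. Every stage artifact is
#' written under \code{outDir} and a machine-readable JSON report with
#' all counts is produced. The report contains no timestamps and all
#' randomness derives from the config seed, so re-running with the same
#' config reproduces it byte for byte.
#'
#' @param config a [pipelineConfig()] list.
#' @param outDir output directory (created if needed).
#' @return the report, invisibly, as a named list (also written to
#'   \code{<outDir>/report.json}).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile()) {
    stopifnot(inherits(config, "fepiConfig"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    logStage <- function(...) message("[FePiOverlap] ", ...)
    genes <- sprintf("g%05d", seq_len(config$nGenes))

    ## ---- planted design: shared DEGs with a type mix ----
    design <- withSeed(subSeed(config$seed, 11L), {
        shared <- sample(genes, config$nOverlap)
        type <- sample(1:4, config$nOverlap, replace = TRUE,
                       prob = config$typeWeights)
        feUp <- type %in% c(2L, 4L)
        piUp <- type %in% c(2L, 3L)
        extraFe <- sample(setdiff(genes, shared),
                          config$nDegPerContrast - config$nOverlap)
        extraPi <- sample(setdiff(genes, c(shared, extraFe)),
                          config$nDegPerContrast - config$nOverlap)
        list(shared = shared, type = type,
             feDeg = c(shared, extraFe), piDeg = c(shared, extraPi),
             feFold = c(orientedFolds(config$nOverlap, feUp),
                        orientedFolds(length(extraFe),
                                      stats::runif(length(extraFe)) < 0.5)),
             piFold = c(orientedFolds(config$nOverlap, piUp),
                        orientedFolds(length(extraPi),
                                      stats::runif(length(extraPi)) < 0.5)))
    })

    logStage("generating contrast experiments")
    fe <- genContrastExperiment(config$nGenes, length(design$feDeg),
                                nReps = config$nReps,
                                noiseCv = config$noiseCv,
                                zeroControlFraction =
                                    config$zeroControlFraction,
                                seed = subSeed(config$seed, 1L),
                                degGenes = design$feDeg,
                                folds = design$feFold)
    pi <- genContrastExperiment(config$nGenes, length(design$piDeg),
                                nReps = config$nReps,
                                noiseCv = config$noiseCv,
                                zeroControlFraction =
                                    config$zeroControlFraction,
                                seed = subSeed(config$seed, 2L),
                                degGenes = design$piDeg,
                                folds = design$piFold)
    writeContrastTable(fe$treatment, fe$control,
                       file.path(outDir, "fe_contrast.tsv"))
    writeContrastTable(pi$treatment, pi$control,
                       file.path(outDir, "pi_contrast.tsv"))

    logStage("overlap and fold changes")
    overlap <- overlapGenes(design$feDeg, design$piDeg)
    feFc <- foldChangeTable(fe$treatment, fe$control)
    piFc <- foldChangeTable(pi$treatment, pi$control)
    ot <- makeOverlapTable(feFc, piFc, overlap)
    writeOverlapTable(ot, file.path(outDir, "overlap_foldchanges.tsv"))

    mainCutoff <- config$foldCutoffs[1]
    filtered <- filterByFold(ot, mainCutoff)
    cls <- classifyTypes(ot, cutoffs = config$foldCutoffs)
    utils::write.table(cls$assignment,
                       file.path(outDir, "type_assignment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    logStage("clustering ", length(filtered), " filtered genes")
    clusterInfo <- NULL
    if (length(filtered) >= 2L &&
        sum(rowSums(is.finite(log2FoldMatrix(filtered))) > 0L) >= 2L) {
        m <- log2FoldMatrix(filtered)
        hc <- hierarchicalCluster(m)
        clusterNewick(hc, file.path(outDir, "cluster.nwk"))
        writeOrderedMatrix(m, hc, file.path(outDir, "cluster_matrix.tsv"))
        clusterInfo <- list(genes = nrow(m) - length(hc$excluded),
                            excluded = length(hc$excluded))
    }

    logStage("co-expression network")
    nMod <- length(config$moduleSizes)
    modGenes <- withSeed(subSeed(config$seed, 12L),
                         sample(overlap, sum(config$moduleSizes)))
    comp <- genCompendium(length(overlap), nArrays = config$nArrays,
                          modules = lapply(config$moduleSizes, function(s)
                              c(s, config$latentWeight)),
                          noiseSd = config$noiseSd,
                          seed = subSeed(config$seed, 3L),
                          geneIds = c(modGenes,
                                      setdiff(overlap, modGenes)))
    writeCompendium(comp$matrix, file.path(outDir, "compendium.tsv"))
    corr <- pearsonMatrix(comp$matrix, overlap)
    net <- buildNetwork(corr, threshold = config$corThreshold)
    mods <- findModules(net)
    netStats <- networkStats(net, mods)
    exportNetwork(net, file.path(outDir, "network.sif"), "sif",
                  modules = mods)
    exportNetwork(net, file.path(outDir, "network.graphml"), "graphml",
                  modules = mods)
    writeModuleTable(mods, file.path(outDir, "modules.tsv"))

    logStage("GO enrichment")
    study <- geneIds(filtered)
    go <- genGoUniverse(nTerms = config$goTerms,
                        maxDepth = config$goDepth,
                        universeSize = length(overlap),
                        plantedTerm = "GO:0000005",
                        studySize = length(study),
                        enrichmentOdds = config$enrichmentOdds,
                        seed = subSeed(config$seed, 4L),
                        universeGenes = overlap,
                        studyGenes = study)
    writeObo(go$obo, file.path(outDir, "ontology.obo"))
    writeAnnotations(go$annotations, file.path(outDir, "annotations.tsv"))
    dag <- parseObo(go$obo)
    direct <- split(go$annotations$term, go$annotations$gene)
    prop <- propagateAnnotations(dag, direct)
    enr <- elimEnrich(dag, prop, study = go$study,
                      universe = go$universe, cutoff = config$goCutoff)
    utils::write.table(enr, file.path(outDir, "go_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    logStage("promoter motif scan")
    type4 <- subsetByType(ot, 4L)
    motifCutoff <- config$foldCutoffs[min(2L, length(config$foldCutoffs))]
    scanSet <- geneIds(filterByFold(type4, motifCutoff))
    if (!length(scanSet)) scanSet <- geneIds(type4)
    if (!length(scanSet)) {
        msum <- summarizeHits(data.frame(gene = character(0),
                                         start = integer(0),
                                         end = integer(0),
                                         matched = character(0)))
        plantGenes <- character(0)
    } else {
    plantGenes <- utils::head(sort(scanSet), config$nPlantedMotifGenes)
    m <- nchar(config$motifPattern)
    plantSpec <- withSeed(subSeed(config$seed, 13L), {
        sets <- compileIupac(config$motifPattern)
        lapply(setNames(plantGenes, plantGenes), function(g) {
            data.frame(distance = sample(config$upstreamLength - m, 1L),
                       motif = paste(vapply(sets, sample, character(1),
                                            size = 1L), collapse = ""))
        })
    })
    prom <- genPromoters(length(scanSet),
                         length = config$upstreamLength,
                         plantSpec = plantSpec,
                         forbidBackgroundHits = TRUE,
                         pattern = config$motifPattern,
                         seed = subSeed(config$seed, 5L),
                         geneIds = sort(scanSet))
    writePromoters(prom$promoters, file.path(outDir, "promoters.fasta"),
                   upstreamLength = prom$upstreamLength)
    hits <- scanPromoterSet(prom$promoters, config$motifPattern)
    writeMotifHits(hits, file.path(outDir, "motif_hits.tsv"))
    msum <- summarizeHits(hits, within = config$withinDistance)
    }

    report <- list(
        seed = config$seed,
        nGenes = config$nGenes,
        overlap = length(overlap),
        filtered = length(filtered),
        foldCutoff = mainCutoff,
        typeCounts = as.list(cls$counts),
        clustering = clusterInfo,
        network = list(nodes = netStats$nodes, edges = netStats$edges,
                       modules = netStats$modules,
                       moduleSizes = netStats$moduleSizes,
                       unconnected = netStats$unconnected),
        go = list(terms = nrow(dagTerms(dag)),
                  significant = sum(enr$p_elim < config$goCutoff),
                  topTerm = if (nrow(enr)) enr$term[1] else NA_character_,
                  plantedTerm = go$truth$plantedTerm),
        motif = list(promoters = length(scanSet),
                     totalHits = msum$totalHits,
                     genesWithHit = msum$genesWithHit,
                     genesWithin = msum$genesWithin,
                     distinctPatterns = msum$distinctPatterns),
        truth = list(sharedDeg = length(design$shared),
                     plantedModules = length(config$moduleSizes),
                     plantedModuleSizes = as.integer(config$moduleSizes),
                     plantedMotifGenes = length(plantGenes)))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
}
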