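test_that("contrast generator is deterministic and rejects bad sizes", {
    a <- genContrastExperiment(200, 20, seed = 42)
    b <- genContrastExperiment(200, 20, seed = 42)
    expect_identical(a, b)
    c <- genContrastExperiment(200, 20, seed = 43)
    expect_false(identical(a$treatment, c$treatment))
    expect_true(all(a$treatment >= 0) && all(a$control >= 0))
    expect_error(genContrastExperiment(0, 0), "positive integer")
    expect_error(genContrastExperiment(10, 2, nReps = 0), "positive integer")
    expect_error(genContrastExperiment(10, 20), "nDeg")
})

test_that("noiseless planting reproduces folds and baselines exactly", {
    x <- genContrastExperiment(1, 1, nReps = 3, noiseCv = 0,
                               zeroControlFraction = 0, folds = 4,
                               baselines = 10, seed = 1)
    expect_equal(unname(x$control[1, ]), c(10, 10, 10))
    expect_equal(unname(x$treatment[1, ]), c(40, 40, 40))
    # planted folds recovered exactly across many genes at zero noise
    y <- genContrastExperiment(50, 10, noiseCv = 0,
                               zeroControlFraction = 0, seed = 9)
    fc <- foldChangeTable(y$treatment, y$control)
    planted <- y$truth$degGenes
    expect_equal(fc$mean[match(names(planted), fc$gene)],
                 unname(planted))
    others <- setdiff(fc$gene, names(planted))
    expect_true(all(fc$mean[match(others, fc$gene)] == 1))
})

test_that("zero-control planting exercises the undetermined convention", {
    x <- genContrastExperiment(100, 3, zeroControlFraction = 1, seed = 5)
    z <- x$truth$zeroControlGenes
    expect_length(z, 3L)
    expect_true(all(x$control[z, ] == 0))
    expect_true(all(x$treatment[z, ] > 0))
    fc <- foldChangeTable(x$treatment, x$control)
    expect_true(all(fc$flag[match(z, fc$gene)] == "undetermined"))
})

test_that("compendium modules hit their closed-form correlation", {
    # noiseless latent factor: perfect within-module correlation
    x0 <- genCompendium(10, nArrays = 20, modules = list(c(3, 2)),
                        noiseSd = 0, seed = 1)
    r0 <- cor(t(x0$matrix[1:3, ]))
    expect_equal(unname(r0[upper.tri(r0)]), rep(1, 3))
    # zero latent weight: no induced correlation
    x1 <- genCompendium(10, nArrays = 500, modules = list(c(4, 0)),
                        noiseSd = 1, seed = 2)
    r1 <- cor(t(x1$matrix[1:4, ]))
    expect_lt(max(abs(r1[upper.tri(r1)])), 0.15)
    # latent weight 3, noise 1: expected r = 9/10, empirical mean
    # within +/- 0.05 over 200 arrays
    x2 <- genCompendium(20, nArrays = 200, modules = list(c(8, 3)),
                        noiseSd = 1, seed = 3)
    expect_equal(x2$truth$expectedR, 0.9)
    r2 <- cor(t(x2$matrix[1:8, ]))
    expect_lt(abs(mean(r2[upper.tri(r2)]) - 0.9), 0.05)
    expect_error(genCompendium(10, modules = list(c(1, 3))), "at least 2")
    expect_error(genCompendium(4, modules = list(c(10, 3))), "sum")
    expect_identical(genCompendium(20, 30, seed = 7),
                     genCompendium(20, 30, seed = 7))
})

test_that("GO universe generator plants a recoverable enrichment", {
    g <- genGoUniverse(nTerms = 25, maxDepth = 4, universeSize = 200,
                       plantedTerm = "GO:0000005", studySize = 30,
                       enrichmentOdds = 10, seed = 1)
    dag <- parseObo(g$obo)
    expect_equal(nrow(dagTerms(dag)), 25L)
    expect_true("GO:0000005" %in% dagTerms(dag)$id)
    # single root, acyclic (parseObo would reject a cycle)
    expect_equal(sum(lengths(dagParents(dag)) == 0L), 1L)
    expect_error(genGoUniverse(enrichmentOdds = 0), "positive")
    expect_error(genGoUniverse(nTerms = 3, plantedTerm = "GO:0000009"),
                 "does not exist")

    # null odds: study overlap behaves hypergeometrically
    ov <- vapply(1:40, function(s) {
        gg <- genGoUniverse(nTerms = 10, universeSize = 100,
                            plantedTerm = "GO:0000005", studySize = 20,
                            enrichmentOdds = 1, seed = s,
                            carrierFraction = 0.3)
        length(intersect(gg$study, gg$truth$carriers))
    }, numeric(1))
    # expected mean = 20 * 30 / 100 = 6; SE of the mean ~ 0.25
    expect_lt(abs(mean(ov) - 6), 1)

    # odds 10: classic Fisher p for the planted term < 0.01 in >= 90%
    # of seeds (brute-force hypergeometric oracle)
    sig <- vapply(1:50, function(s) {
        gg <- genGoUniverse(nTerms = 10, universeSize = 500,
                            plantedTerm = "GO:0000005", studySize = 50,
                            enrichmentOdds = 10, seed = s)
        k <- length(intersect(gg$study, gg$truth$carriers))
        bruteHyperTail(500, length(gg$truth$carriers), 50, k) < 0.01
    }, logical(1))
    expect_gte(mean(sig), 0.9)
})

test_that("single-term ontology maps every annotation to the root", {
    g <- genGoUniverse(nTerms = 1, universeSize = 20,
                       plantedTerm = "GO:0000001", studySize = 5,
                       seed = 3)
    expect_true(all(g$annotations$term == "GO:0000001"))
    expect_equal(nrow(dagTerms(parseObo(g$obo))), 1L)
})

test_that("promoter generator plants motifs at exact distances", {
    spec <- list(gene_a = data.frame(distance = 153, motif = "GTATATGC"))
    p <- genPromoters(1, length = 3000, plantSpec = spec,
                      forbidBackgroundHits = TRUE, seed = 11,
                      geneIds = "gene_a")
    hits <- scanPromoterSet(p$promoters, "GNATATNC")
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$start, 153L)
    expect_equal(hits$end, 160L)
    expect_equal(hits$matched, "GTATATGC")
    # empty plant spec with background forbidden: zero hits
    q <- genPromoters(5, length = 500, forbidBackgroundHits = TRUE,
                      seed = 2)
    expect_equal(nrow(scanPromoterSet(q$promoters, "GNATATNC")), 0L)
    expect_true(all(strsplit(paste(as.character(q$promoters),
                                   collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "T")))
    # rejected plants
    expect_error(genPromoters(1, plantSpec = list(g00001 = data.frame(
        distance = 10, motif = "AAAAAAAA"))), "conform")
    expect_error(genPromoters(1, length = 100, plantSpec = list(
        g00001 = data.frame(distance = c(10, 12),
                            motif = c("GTATATGC", "GTATATGC")))),
        "overlap")
    expect_identical(genPromoters(3, length = 300, seed = 8),
                     genPromoters(3, length = 300, seed = 8))
})

test_that("forbid-background scan output equals planted truth exactly", {
    set.seed(99)
    genes <- sprintf("p%02d", 1:50)
    spec <- lapply(setNames(genes, genes), function(g) {
        d <- sort(sample(1:990, 2))
        while (diff(d) < 8) d <- sort(sample(1:990, 2))
        data.frame(distance = d,
                   motif = c("GTATATGC", "GAATATCC"))
    })
    p <- genPromoters(50, length = 1000, plantSpec = spec,
                      forbidBackgroundHits = TRUE, seed = 21,
                      geneIds = genes)
    hits <- scanPromoterSet(p$promoters, "GNATATNC")
    expect_equal(nrow(hits), 100L)
    got <- hits[order(hits$gene, hits$start), c("gene", "start", "matched")]
    want <- p$truth[order(p$truth$gene, p$truth$distance), ]
    expect_equal(got$gene, want$gene)
    expect_equal(got$start, want$distance)
    expect_equal(got$matched, want$motif)
})

test_that("synthetic IO round-trips through the plain-text formats", {
    x <- genContrastExperiment(20, 5, seed = 4)
    f <- tempfile(fileext = ".tsv")
    writeContrastTable(x$treatment, x$control, f)
    back <- readContrastTable(f)
    expect_equal(back$treatment, x$treatment, tolerance = 1e-6)
    expect_equal(back$control, x$control, tolerance = 1e-6)

    comp <- genCompendium(10, 12, modules = list(c(3, 2)), seed = 5)
    g <- tempfile(fileext = ".tsv")
    writeCompendium(comp$matrix, g)
    expect_equal(readCompendium(g), comp$matrix, tolerance = 1e-6)

    p <- genPromoters(3, length = 50, seed = 6)
    h <- tempfile(fileext = ".fasta")
    writePromoters(p$promoters, h, upstreamLength = 50)
    back <- readPromoters(h)
    expect_equal(as.character(back), as.character(p$promoters))
})
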