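test_that("fold change is the mean and SD of paired replicate ratios", {
    expect_equal(computeFoldChange(c(5, 5, 5), c(5, 5, 5)),
                 list(mean = 1, sd = 0, n = 3L, flag = "ok"))
    expect_equal(computeFoldChange(c(4, 6, 8), c(2, 2, 2)),
                 list(mean = 3, sd = 1, n = 3L, flag = "ok"))
    # identity invariant for random all-positive vectors
    for (s in 1:20) {
        set.seed(s)
        x <- runif(sample(2:6, 1), 0.1, 100)
        r <- computeFoldChange(x, x)
        expect_equal(r$mean, 1)
        expect_equal(r$sd, 0)
    }
})

test_that("zero-control conventions: undetermined, silent, pair-drop", {
    u <- computeFoldChange(c(7, 9, 5), c(0, 0, 0))
    expect_true(is.na(u$mean))
    expect_identical(u$flag, "undetermined")
    s <- computeFoldChange(c(0, 0), c(0, 0))
    expect_identical(s$flag, "silent")
    # partial zero controls: pair dropped, n decremented, finite stats
    p <- computeFoldChange(c(4, 6, 8), c(2, 0, 2))
    expect_identical(p$flag, "ok")
    expect_equal(p$n, 2L)
    expect_equal(p$mean, mean(c(2, 4)))
    # single usable pair: SD absent
    p1 <- computeFoldChange(c(4, 6), c(2, 0))
    expect_equal(p1$n, 1L)
    expect_true(is.na(p1$sd))
    expect_error(computeFoldChange(c(1, 2), c(1, 2, 3)), "same number")
    expect_error(computeFoldChange(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("overlapGenes is a sorted, symmetric, idempotent intersection", {
    expect_equal(overlapGenes(c("A", "B", "C"), c("B", "C", "D")),
                 c("B", "C"))
    expect_equal(overlapGenes("A", "B"), character(0))
    expect_equal(overlapGenes(c("C", "A"), c("A", "C")), c("A", "C"))
    for (s in 1:10) {
        set.seed(s)
        a <- sample(sprintf("g%02d", 1:30), 12)
        b <- sample(sprintf("g%02d", 1:30), 15)
        ab <- overlapGenes(a, b)
        expect_identical(ab, overlapGenes(b, a))
        expect_identical(ab, overlapGenes(ab, ab))
        expect_true(all(ab %in% a) && all(ab %in% b))
    }
})

test_that("fold filter keeps either-contrast changes and undetermined", {
    ot <- makeToyOverlap(c("a", "b", "c", "d"),
                         feMean = c(2.5, 1.2, NA, 1.0),
                         piMean = c(1.0, 0.9, 0.77, 0.4))
    kept <- geneIds(filterByFold(ot, 2))
    expect_true("a" %in% kept)        # 2.5-fold up in Fe
    expect_false("b" %in% kept)       # (1.2, 0.9): no twofold change
    expect_true("c" %in% kept)        # undetermined counts as up
    expect_true("d" %in% kept)        # 0.4 <= 1/2 in Pi
    expect_error(filterByFold(ot, 1), "greater than 1")
    # monotone: raising the cutoff never adds genes
    set.seed(3)
    big <- makeToyOverlap(sprintf("g%03d", 1:200),
                          feMean = exp(rnorm(200)),
                          piMean = exp(rnorm(200)))
    cuts <- c(1.2, 1.5, 2, 3, 5)
    kept <- lapply(cuts, function(co) geneIds(filterByFold(big, co)))
    for (i in seq_along(cuts)[-1])
        expect_true(all(kept[[i]] %in% kept[[i - 1]]))
})

test_that("four-type classification follows the direction pairs", {
    ot <- makeToyOverlap(
        c("At3G12900", "At1G73220", "At3G52720", "down", "tie", "und"),
        feMean = c(612.44, 17.38, 0.40, 0.5, 1.0, NA),
        piMean = c(0.06, 196.69, 5.56, 0.8, 2.0, 0.77))
    cls <- classifyTypes(ot)
    a <- setNames(cls$assignment$type, cls$assignment$gene)
    expect_equal(a[["At3G12900"]], 4L)  # Fe up, Pi down
    expect_equal(a[["At1G73220"]], 2L)  # up under both
    expect_equal(a[["At3G52720"]], 3L)  # Pi up, Fe down
    expect_equal(a[["down"]], 1L)
    expect_true(is.na(a[["tie"]]))      # exact fold 1: unclassified
    expect_equal(a[["und"]], 4L)        # undetermined counts as up
    expect_equal(unname(cls$counts["unclassified"]), 1L)
})

test_that("types partition the table and swap with the contrasts", {
    set.seed(11)
    n <- 150
    fe <- exp(rnorm(n)); pi <- exp(rnorm(n))
    fe[sample(n, 5)] <- NA
    ot <- makeToyOverlap(sprintf("g%03d", 1:n), fe, pi)
    cls <- classifyTypes(ot)
    expect_equal(sum(cls$counts), n)  # partition incl. unclassified
    # swapping the two contrasts maps type 3 <-> 4, fixes 1 and 2
    swapped <- makeToyOverlap(sprintf("g%03d", 1:n), pi, fe)
    cls2 <- classifyTypes(swapped)
    expect_equal(unname(cls2$counts[c("type1", "type2")]),
                 unname(cls$counts[c("type1", "type2")]))
    expect_equal(unname(cls2$counts["type3"]), unname(cls$counts["type4"]))
    expect_equal(unname(cls2$counts["type4"]), unname(cls$counts["type3"]))
    # sub-counts: 'both' never exceeds 'either'
    expect_true(all(cls$subCounts$both <= cls$subCounts$either))
})

test_that("printed cross-stress table round-trips with its conventions", {
    ot <- readOverlapTable(table1Path())
    expect_equal(length(ot), 110L)
    rec <- overlapRecords(ot)
    expect_true(all(is.na(rec$fe_mean[rec$fe_flag == "undetermined"])))
    # every printed row passes the twofold either-contrast filter
    expect_equal(length(filterByFold(ot, 2)), 110L)
    # undetermined-Fe gene with Pi fold 0.77 is retained
    expect_true("AT4G09110" %in% geneIds(filterByFold(ot, 2)))
    # write/read round-trip preserves the "-" rendering
    f <- tempfile(fileext = ".tsv")
    writeOverlapTable(ot, f)
    back <- readOverlapTable(f)
    expect_equal(overlapRecords(back)$fe_mean, rec$fe_mean,
                 tolerance = 1e-6)
    expect_identical(overlapRecords(back)$fe_flag, rec$fe_flag)
})

test_that("delta-Ct relative expression and its t test behave", {
    # target equals the reference mean in both groups -> 1.0
    r <- qpcrRelativeExpression(
        target = list(treatment = c(20, 20, 20), control = c(21, 21, 21)),
        ref1 = list(treatment = c(19, 19, 19), control = c(20, 20, 20)),
        ref2 = list(treatment = c(21, 21, 21), control = c(22, 22, 22)))
    expect_equal(r$relativeExpression, 1)
    # dCt control 2, treatment 1 -> 2^(2-1) = 2
    r2 <- qpcrRelativeExpression(
        target = list(treatment = c(21, 21), control = c(22, 22)),
        ref1 = list(treatment = c(20, 20), control = c(20, 20)),
        ref2 = list(treatment = c(20, 20), control = c(20, 20)))
    expect_equal(r2$relativeExpression, 2)
    # reference around 20 cycles, target around 34 -> dCt around 14
    r3 <- qpcrRelativeExpression(
        target = list(treatment = c(34, 34.2, 33.8),
                      control = c(34.1, 34, 33.9)),
        ref1 = list(treatment = c(20, 20.1, 19.9),
                    control = c(20, 20, 20)),
        ref2 = list(treatment = c(20.1, 19.9, 20),
                    control = c(20, 20.1, 19.9)))
    expect_lt(abs(mean(r3$dCtTreatment) - 14), 0.5)
    expect_true(r3$pValue >= 0 && r3$pValue <= 1)
    # fewer than two replicates: p undefined and flagged
    expect_warning(
        r4 <- qpcrRelativeExpression(
            target = list(treatment = 21, control = c(22, 22)),
            ref1 = list(treatment = 20, control = c(20, 20)),
            ref2 = list(treatment = 20, control = c(20, 20))),
        "fewer than 2")
    expect_true(is.na(r4$pValue))
    expect_error(qpcrRelativeExpression(
        target = list(treatment = c(-1, 2), control = c(1, 1)),
        ref1 = list(treatment = c(1, 1), control = c(1, 1)),
        ref2 = list(treatment = c(1, 1), control = c(1, 1))),
        "positive")
})
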