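oboLines <- function(...) {
    # tiny OBO builder: each argument is c(id, parents...)
    stanzas <- lapply(list(...), function(v) {
        c("[Term]", paste0("id: ", v[1]), paste0("name: term ", v[1]),
          "namespace: biological_process",
          if (length(v) > 1) paste0("is_a: ", v[-1]), "")
    })
    c("format-version: 1.2", "", unlist(stanzas))
}

test_that("OBO parsing resolves the DAG and rejects broken input", {
    one <- parseObo(oboLines("a"))
    expect_equal(nrow(dagTerms(one)), 1L)
    expect_error(parseObo(oboLines(c("a", "b"), c("b", "a"))), "cycle")
    expect_error(parseObo(oboLines(c("a", "zzz"))), "dangling")
    # diamond: d is_a b, d is_a c, b is_a a, c is_a a
    dia <- parseObo(oboLines("a", c("b", "a"), c("c", "a"),
                             c("d", "b", "c")))
    expect_equal(nrow(dagTerms(dia)), 4L)
    expect_equal(termAncestors(dia, "d"), c("a", "b", "c"))
    # obsolete terms are skipped
    obs <- parseObo(c(oboLines("a"),
                      "[Term]", "id: old", "name: gone",
                      "is_obsolete: true", ""))
    expect_equal(dagTerms(obs)$id, "a")
    # part_of treated as parentage by default, ignorable on request
    po <- c(oboLines("a"), "[Term]", "id: b", "name: term b",
            "relationship: part_of a ! comment", "")
    expect_equal(termAncestors(parseObo(po), "b"), "a")
    expect_length(termAncestors(parseObo(po, partOfAsIsA = FALSE), "b"),
                  0L)
})

test_that("annotation propagation closes over ancestry, idempotently", {
    chain <- parseObo(oboLines("a", c("b", "a"), c("c", "b")))
    direct <- list(g1 = "c", g2 = "a", g3 = "b")
    prop <- propagateAnnotations(chain, direct)
    expect_equal(prop$g1, c("a", "b", "c"))  # leaf of a 3-level chain
    expect_equal(prop$g2, "a")               # root-only: unchanged
    expect_equal(prop$g3, c("a", "b"))
    expect_identical(propagateAnnotations(chain, prop), prop)
    expect_error(propagateAnnotations(chain, list(g1 = "nope")),
                 "unknown term")
})

test_that("the per-term test equals the enumerated hypergeometric tail", {
    expect_equal(fisherTerm(20, 5, 5, 4), 76 / 15504)
    expect_equal(fisherTerm(50, 10, 8, 0), 1)       # P(X >= 0) = 1
    expect_equal(fisherTerm(12, 7, 12, 7), 1)       # exhaustive study
    expect_error(fisherTerm(10, 5, 5, 6), "inconsistent")
    expect_error(fisherTerm(10, 11, 5, 2), "inconsistent")
    # oracle sweep over all consistent tables with universe <= 12, plus
    # spot checks up to 30
    for (N in c(5, 9, 12)) for (K in 0:N) for (n in 0:N)
        for (k in max(0, K + n - N):min(K, n))
            expect_equal(fisherTerm(N, K, n, k),
                         bruteHyperTail(N, K, n, k))
    set.seed(4)
    for (i in 1:50) {
        N <- sample(13:30, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
        k <- sample(max(0, K + n - N):min(K, n), 1)
        expect_equal(fisherTerm(N, K, n, k), bruteHyperTail(N, K, n, k))
    }
})

test_that("elim with cutoff 0 reduces to classic, term for term", {
    g <- genGoUniverse(nTerms = 30, universeSize = 150, studySize = 25,
                       plantedTerm = "GO:0000005", seed = 8)
    dag <- parseObo(g$obo)
    prop <- propagateAnnotations(dag, split(g$annotations$term,
                                            g$annotations$gene))
    res <- elimEnrich(dag, prop, g$study, g$universe, cutoff = 0)
    expect_equal(res$p_elim, res$p_classic)
    # output ordering and column sanity
    expect_true(!is.unsorted(res$p_elim))
    expect_true(all(res$significant <= res$annotated))
    expect_true(all(res$p_classic >= 0 & res$p_classic <= 1))
})

test_that("elim prunes a significant child's genes from its ancestors", {
    dag <- parseObo(oboLines("root", c("child", "root")))
    genes <- sprintf("x%02d", 1:20)
    inRoot <- genes[1:15]
    inChild <- genes[1:10]
    direct <- c(setNames(as.list(rep("root", 5)), inRoot[11:15]),
                setNames(as.list(rep("child", 10)), inChild))
    prop <- propagateAnnotations(dag, direct)
    study <- inChild
    res <- elimEnrich(dag, prop, study, genes, cutoff = 0.01)
    child <- res[res$term == "child", ]
    root <- res[res$term == "root", ]
    # child tested on full sets, matches the brute-force oracle
    expect_equal(child$p_classic, bruteHyperTail(20, 10, 10, 10))
    expect_equal(child$p_elim, child$p_classic)  # leaf: elim = classic
    expect_lt(child$p_elim, 0.01)
    # ancestor tested on pruned sets: no study gene left
    expect_equal(root$p_classic, bruteHyperTail(20, 15, 10, 10))
    expect_equal(root$p_elim, 1)
})

test_that("a flat ontology leaves every non-root p unchanged", {
    dag <- parseObo(oboLines("root", c("t1", "root"), c("t2", "root"),
                             c("t3", "root")))
    set.seed(6)
    genes <- sprintf("x%02d", 1:40)
    direct <- lapply(setNames(genes, genes), function(g)
        sample(c("t1", "t2", "t3"), sample(1:2, 1)))
    prop <- propagateAnnotations(dag, direct)
    study <- genes[1:12]
    res <- elimEnrich(dag, prop, study, genes, cutoff = 0.05)
    nonroot <- res[res$term != "root", ]
    expect_equal(nonroot$p_elim, nonroot$p_classic)
    expect_error(elimEnrich(dag, prop, c(study, "alien"), genes),
                 "absent from universe")
})

test_that("the planted term wins the elim ranking in most seeds", {
    top <- vapply(1:100, function(s) {
        g <- genGoUniverse(nTerms = 25, universeSize = 200,
                           studySize = 30, plantedTerm = "GO:0000005",
                           enrichmentOdds = 10, seed = s)
        dag <- parseObo(g$obo)
        prop <- propagateAnnotations(dag, split(g$annotations$term,
                                                g$annotations$gene))
        res <- elimEnrich(dag, prop, g$study, g$universe)
        res$term[which.min(res$p_elim)] == "GO:0000005"
    }, logical(1))
    expect_gte(mean(top), 0.9)
})
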