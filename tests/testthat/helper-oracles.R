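# Independent oracles used to cross-check the implementation.

# Upper-tail hypergeometric by direct enumeration of the tail.
bruteHyperTail <- function(N, K, n, k) {
    kk <- k:min(K, n)
    sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Connected components by breadth-first reachability over an edge list.
bruteComponents <- function(nodes, edges) {
    adj <- setNames(vector("list", length(nodes)), nodes)
    for (i in seq_len(nrow(edges))) {
        a <- edges$gene_a[i]; b <- edges$gene_b[i]
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
    }
    seen <- character(0)
    comps <- list()
    for (s in nodes) {
        if (s %in% seen) next
        queue <- s; comp <- character(0)
        while (length(queue)) {
            v <- queue[[1]]; queue <- queue[-1]
            if (v %in% comp) next
            comp <- c(comp, v)
            queue <- c(queue, setdiff(adj[[v]], comp))
        }
        comps[[length(comps) + 1L]] <- sort(comp)
        seen <- c(seen, comp)
    }
    comps[order(-lengths(comps),
                vapply(comps, `[`, character(1), 1L))]
}

# Canonical form of a partition (list of sets) for set equality checks.
canonicalPartition <- function(p) {
    p <- unname(lapply(p, sort))
    p[order(vapply(p, `[`, character(1), 1L))]
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# A tiny overlap table built directly from fold means (NA = undetermined
# zero-control fold).
makeToyOverlap <- function(genes, feMean, piMean) {
    rec <- data.frame(gene = genes,
                      fe_mean = feMean, fe_sd = ifelse(is.na(feMean), NA, 0.1),
                      fe_flag = ifelse(is.na(feMean), "undetermined", "ok"),
                      fe_n = 3L,
                      pi_mean = piMean, pi_sd = ifelse(is.na(piMean), NA, 0.1),
                      pi_flag = ifelse(is.na(piMean), "undetermined", "ok"),
                      pi_n = 3L,
                      stringsAsFactors = FALSE)
    new("OverlapTable", records = rec)
}

table3Path <- function() {
    system.file("extdata", "table3_p1bs_hits.tsv",
                package = "FePiOverlap", mustWork = TRUE)
}

table1Path <- function() {
    system.file("extdata", "table1_printed_foldchanges.tsv",
                package = "FePiOverlap", mustWork = TRUE)
}
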