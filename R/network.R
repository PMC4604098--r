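#' Pairwise Pearson correlation over an expression compendium
#'
#' Correlates the array profiles of the requested genes. Genes with a
#' zero-variance profile have no defined correlation; they are excluded
#' with a warning and reported in the \code{"excluded"} attribute of the
#' result.
#'
#' @param compendium numeric matrix, genes x arrays, rownames = gene
#'   ids; at least 3 arrays.
#' @param genes gene ids to correlate; default all rows.
#' @return symmetric correlation matrix (diagonal 1) with attribute
#'   \code{excluded} (character).
#' @export
pearsonMatrix <- function(compendium, genes = rownames(compendium)) {
    stopifnot(is.matrix(compendium), !is.null(rownames(compendium)))
    if (ncol(compendium) < 3L)
        stop("the compendium must have at least 3 arrays")
    genes <- unique(as.character(genes))
    miss <- setdiff(genes, rownames(compendium))
    if (length(miss))
        stop("genes absent from the compendium: ",
             paste(utils::head(miss, 5), collapse = ", "))
    sub <- compendium[genes, , drop = FALSE]
    v <- apply(sub, 1L, stats::var)
    excluded <- rownames(sub)[v == 0]
    if (length(excluded)) {
        warning(length(excluded),
                " zero-variance profile(s) excluded from correlation")
        sub <- sub[v > 0, , drop = FALSE]
    }
    r <- stats::cor(t(sub))
    diag(r) <- 1
    attr(r, "excluded") <- excluded
    r
}

#' Build the thresholded co-expression network
#'
#' Draws an undirected edge between genes i and j (i != j) whenever
#' their correlation is at least the threshold; by default the signed
#' correlation is used, so only positive co-expression forms edges
#' (\code{absolute = TRUE} thresholds |r| instead). Genes left without
#' any edge are reported as unconnected rather than silently dropped.
#'
#' @param corr symmetric correlation matrix as from [pearsonMatrix()].
#' @param threshold correlation cutoff in (0, 1]; default 0.7.
#' @param absolute threshold on |r| instead of signed r; default
#'   \code{FALSE}.
#' @return a [CoexpressionNetwork-class].
#' @export
buildNetwork <- function(corr, threshold = 0.7, absolute = FALSE) {
    stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        threshold <= 0 || threshold > 1)
        stop("threshold must be in (0, 1]")
    ids <- rownames(corr)
    val <- if (absolute) abs(corr) else corr
    hit <- which(upper.tri(val) & val >= threshold, arr.ind = TRUE)
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
    if (nrow(hit)) {
        a <- ids[hit[, 1L]]
        b <- ids[hit[, 2L]]
        swap <- a > b
        tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
        edges <- data.frame(gene_a = a, gene_b = b,
                            r = corr[hit], stringsAsFactors = FALSE)
        edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
        rownames(edges) <- NULL
    }
    nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
    new("CoexpressionNetwork", edges = edges, nodes = nodes,
        threshold = threshold, unconnected = sort(setdiff(ids, nodes)))
}

# igraph view of a CoexpressionNetwork (internal)
asIgraph <- function(net) {
    igraph::graph_from_data_frame(net@edges[, c("gene_a", "gene_b")],
                                  directed = FALSE,
                                  vertices = net@nodes)
}

#' Partition a co-expression network into modules
#'
#' A module is a maximal group of genes mutually reachable through
#' network edges, i.e. a connected component: a cluster with no edge to
#' any other cluster.
#'
#' @param net a [CoexpressionNetwork-class].
#' @return list of character vectors (each sorted), ordered by
#'   decreasing size then by first gene id; empty list for an empty
#'   network.
#' @export
findModules <- function(net) {
    stopifnot(is(net, "CoexpressionNetwork"))
    if (!length(net@nodes)) return(list())
    comp <- igraph::components(asIgraph(net))
    mods <- split(names(comp$membership), comp$membership)
    mods <- lapply(mods, function(g) sort(unname(g)))
    ord <- order(-lengths(mods),
                 vapply(mods, `[`, character(1), 1L))
    unname(mods[ord])
}

#' Summary statistics of a network and its module partition
#'
#' @param net a [CoexpressionNetwork-class].
#' @param modules result of [findModules()]; recomputed when missing.
#' @return list with \code{nodes}, \code{edges}, \code{modules},
#'   \code{moduleSizes} (decreasing), \code{unconnected}.
#' @export
networkStats <- function(net, modules = findModules(net)) {
    stopifnot(is(net, "CoexpressionNetwork"))
    list(nodes = length(net@nodes),
         edges = nrow(net@edges),
         modules = length(modules),
         moduleSizes = as.integer(lengths(modules)),
         unconnected = length(net@unconnected))
}

#' Export a network for external viewers
#'
#' Supported formats: \code{"sif"} (Cytoscape simple interaction lines
#' \code{geneA cx geneB}, lexicographic order), \code{"graphml"}
#' (carries the correlation weight and module index as attributes) and
#' \code{"tsv"} (edge list gene_a, gene_b, r).
#'
#' @param net a [CoexpressionNetwork-class].
#' @param path output file.
#' @param format one of \code{"sif"}, \code{"graphml"}, \code{"tsv"}.
#' @param modules module partition for GraphML attributes; recomputed
#'   when missing.
#' @return \code{path}, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("sif", "graphml", "tsv"),
                          modules = findModules(net)) {
    stopifnot(is(net, "CoexpressionNetwork"))
    format <- match.arg(format)
    e <- net@edges
    if (format == "sif") {
        writeLines(if (nrow(e)) paste(e$gene_a, "cx", e$gene_b)
                   else character(0), path)
    } else if (format == "tsv") {
        utils::write.table(e, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        g <- asIgraph(net)
        igraph::E(g)$r <- e$r
        memb <- integer(length(net@nodes))
        names(memb) <- net@nodes
        for (i in seq_along(modules)) memb[modules[[i]]] <- i
        igraph::V(g)$module <- memb[igraph::V(g)$name]
        igraph::write_graph(g, path, format = "graphml")
    }
    invisible(path)
}

#' Write the gene-to-module assignment as TSV
#'
#' @param modules result of [findModules()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeModuleTable <- function(modules, path) {
    out <- data.frame(
        gene = unlist(modules, use.names = FALSE),
        module_index = rep(seq_along(modules), lengths(modules)),
        stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
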