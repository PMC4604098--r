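#' @import methods
NULL

#' Paired fold-change table for two stress contrasts
#'
#' Holds, for a set of genes, the mean and standard deviation of the
#' replicate-wise treatment/control abundance ratios under each of two
#' contrasts (iron deficiency, phosphate starvation). A fold change is
#' \emph{undetermined} ("-") when every control replicate had zero reads
#' while at least one treatment replicate was positive; it is stored as
#' \code{NA} in the mean/sd columns with the flag column set to
#' \code{"undetermined"} (or \code{"silent"} when both conditions were
#' all-zero).
#'
#' @slot records a \code{data.frame} with columns \code{gene},
#'   \code{fe_mean}, \code{fe_sd}, \code{fe_flag}, \code{fe_n},
#'   \code{pi_mean}, \code{pi_sd}, \code{pi_flag}, \code{pi_n}.
#'
#' @seealso [makeOverlapTable()], [filterByFold()], [classifyTypes()]
#' @exportClass OverlapTable
setClass("OverlapTable", representation(records = "data.frame"))

setValidity("OverlapTable", function(object) {
    rec <- object@records
    need <- c("gene", "fe_mean", "fe_sd", "fe_flag", "fe_n",
              "pi_mean", "pi_sd", "pi_flag", "pi_n")
    if (!all(need %in% names(rec)))
        return(paste("missing columns:",
                     paste(setdiff(need, names(rec)), collapse = ", ")))
    if (anyDuplicated(rec$gene))
        return("duplicate gene ids")
    for (ctr in c("fe", "pi")) {
        m <- rec[[paste0(ctr, "_mean")]]
        fl <- rec[[paste0(ctr, "_flag")]]
        if (any(!is.na(m) & m <= 0))
            return("determined mean folds must be positive")
        if (any(is.na(m) & fl == "ok"))
            return("NA mean fold must carry an undetermined/silent flag")
        if (any(!is.na(m) & fl != "ok"))
            return("determined mean fold must carry flag 'ok'")
    }
    TRUE
})

#' Thresholded co-expression network
#'
#' An undirected graph over genes in which an edge joins two genes whose
#' Pearson correlation across an expression compendium reaches the
#' construction threshold. Nodes are the genes with at least one
#' surviving edge; input genes that lost all their edges are retained
#' separately for auditing.
#'
#' @slot edges \code{data.frame} with columns \code{gene_a},
#'   \code{gene_b}, \code{r} (one row per unordered pair,
#'   \code{gene_a < gene_b} lexicographically).
#' @slot nodes character, genes incident to at least one edge.
#' @slot threshold numeric, the correlation cutoff used.
#' @slot unconnected character, input genes with no surviving edge.
#'
#' @seealso [buildNetwork()], [findModules()], [networkStats()]
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork",
         representation(edges = "data.frame", nodes = "character",
                        threshold = "numeric", unconnected = "character"))

setValidity("CoexpressionNetwork", function(object) {
    e <- object@edges
    if (!all(c("gene_a", "gene_b", "r") %in% names(e)))
        return("edges must have columns gene_a, gene_b, r")
    if (nrow(e)) {
        if (any(e$gene_a == e$gene_b)) return("self-loops are not allowed")
        if (any(e$gene_a > e$gene_b))
            return("edges must be stored with gene_a < gene_b")
        if (anyDuplicated(paste(e$gene_a, e$gene_b)))
            return("duplicate edges")
        if (any(abs(e$r) < object@threshold - 1e-12))
            return("edge weight below construction threshold")
    }
    if (!setequal(object@nodes, unique(c(e$gene_a, e$gene_b))))
        return("nodes must be exactly the edge endpoints")
    if (length(intersect(object@nodes, object@unconnected)))
        return("a gene cannot be both connected and unconnected")
    TRUE
})

#' Gene ontology directed acyclic graph
#'
#' A rooted DAG of ontology terms with \code{is_a} (and optionally
#' \code{part_of}) parent links, as parsed from an OBO 1.2 stream.
#'
#' @slot terms \code{data.frame} with columns \code{id}, \code{name},
#'   \code{namespace}.
#' @slot parents named list mapping each term id to the character vector
#'   of its direct parent ids (empty for roots).
#'
#' @seealso [parseObo()], [termAncestors()], [elimEnrich()]
#' @exportClass GoDag
setClass("GoDag",
         representation(terms = "data.frame", parents = "list"))

setValidity("GoDag", function(object) {
    tm <- object@terms
    if (!all(c("id", "name", "namespace") %in% names(tm)))
        return("terms must have columns id, name, namespace")
    if (anyDuplicated(tm$id)) return("duplicate term ids")
    if (!setequal(names(object@parents), tm$id))
        return("parents list must be keyed by every term id")
    ref <- unlist(object@parents, use.names = FALSE)
    if (length(ref) && !all(ref %in% tm$id))
        return("dangling parent reference")
    TRUE
})

#' @describeIn OverlapTable number of genes in the table
#' @param x,object an \code{OverlapTable}
#' @export
setMethod("length", "OverlapTable", function(x) nrow(x@records))

setMethod("show", "OverlapTable", function(object) {
    rec <- object@records
    cat("OverlapTable with", nrow(rec), "genes (two contrasts: Fe, Pi)\n")
    und <- sum(rec$fe_flag != "ok") + sum(rec$pi_flag != "ok")
    cat("  undetermined fold changes:", und, "\n")
    if (nrow(rec)) {
        cat("  head:\n")
        print(utils::head(rec[, c("gene", "fe_mean", "fe_sd",
                                  "pi_mean", "pi_sd")], 3L))
    }
})

setMethod("show", "CoexpressionNetwork", function(object) {
    cat("CoexpressionNetwork: ", length(object@nodes), " nodes, ",
        nrow(object@edges), " edges (r >= ", object@threshold, ")\n",
        sep = "")
    if (length(object@unconnected))
        cat("  unconnected input genes:", length(object@unconnected), "\n")
})

setMethod("show", "GoDag", function(object) {
    nroot <- sum(lengths(object@parents) == 0L)
    cat("GoDag with", nrow(object@terms), "terms,", nroot, "root(s)\n")
})

#' Accessors for the core classes
#'
#' \code{overlapRecords} returns the underlying per-gene fold-change
#' data.frame; \code{geneIds} the gene identifiers; \code{networkNodes},
#' \code{networkEdges} and \code{networkThreshold} the graph pieces;
#' \code{dagTerms} and \code{dagParents} the ontology pieces.
#'
#' @param x an object of the documented class
#' @return the slot contents, as described above
#' @name accessors
NULL

#' @rdname accessors
#' @export
overlapRecords <- function(x) {
    stopifnot(is(x, "OverlapTable"))
    x@records
}

#' @rdname accessors
#' @export
geneIds <- function(x) {
    if (is(x, "OverlapTable")) return(x@records$gene)
    if (is(x, "CoexpressionNetwork")) return(x@nodes)
    stop("no gene ids for class ", class(x))
}

#' @rdname accessors
#' @export
networkNodes <- function(x) {
    stopifnot(is(x, "CoexpressionNetwork"))
    x@nodes
}

#' @rdname accessors
#' @export
networkEdges <- function(x) {
    stopifnot(is(x, "CoexpressionNetwork"))
    x@edges
}

#' @rdname accessors
#' @export
networkThreshold <- function(x) {
    stopifnot(is(x, "CoexpressionNetwork"))
    x@threshold
}

#' @rdname accessors
#' @export
unconnectedGenes <- function(x) {
    stopifnot(is(x, "CoexpressionNetwork"))
    x@unconnected
}

#' @rdname accessors
#' @export
dagTerms <- function(x) {
    stopifnot(is(x, "GoDag"))
    x@terms
}

#' @rdname accessors
#' @export
dagParents <- function(x) {
    stopifnot(is(x, "GoDag"))
    x@parents
}
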