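#' Log2 fold-change matrix of an overlap table
#'
#' Returns the genes x contrasts matrix of log2(mean fold); cells whose
#' fold is undetermined (zero-control) or silent are \code{NA}, matching
#' the "grey = missing" convention of cross-stress heatmaps.
#'
#' @param x an [OverlapTable-class].
#' @return numeric matrix with rownames = gene ids and columns
#'   \code{fe}, \code{pi}.
#' @export
log2FoldMatrix <- function(x) {
    stopifnot(is(x, "OverlapTable"))
    rec <- x@records
    m <- cbind(fe = log2(rec$fe_mean), pi = log2(rec$pi_mean))
    rownames(m) <- rec$gene
    m
}

# Pairwise-complete distances over the rows of `m`. For the correlation
# distance, pairs of profiles sharing fewer than 2 finite cells get the
# maximum distance (2); for Euclidean, distances are scaled up by the
# ratio of total to shared columns (the classic pairwise-complete
# convention) and pairs with no shared cell get the largest observed
# distance.
profileDist <- function(m, distance = c("correlation", "euclidean")) {
    distance <- match.arg(distance)
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    if (distance == "correlation") {
        for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
            ok <- is.finite(m[i, ]) & is.finite(m[j, ])
            dij <- if (sum(ok) < 2L) 2 else {
                r <- suppressWarnings(stats::cor(m[i, ok], m[j, ok]))
                if (is.na(r)) 2 else 1 - r
            }
            d[i, j] <- d[j, i] <- dij
        }
    } else {
        p <- ncol(m)
        for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
            ok <- is.finite(m[i, ]) & is.finite(m[j, ])
            dij <- if (!sum(ok)) NA_real_
                   else sqrt(sum((m[i, ok] - m[j, ok])^2) * p / sum(ok))
            d[i, j] <- d[j, i] <- dij
        }
        if (anyNA(d)) d[is.na(d)] <- max(d, na.rm = TRUE)
    }
    stats::as.dist(d)
}

#' Hierarchical clustering of log2 fold-change profiles
#'
#' Agglomeratively clusters genes on their log2 fold-change profiles
#' across the two contrasts. The default distance is 1 - Pearson
#' correlation (grouping by profile shape, the standard
#' expression-heatmap choice); Euclidean distance is available. Missing
#' cells (undetermined folds) are handled pairwise-complete. Genes whose
#' profile is entirely missing are excluded and reported. Input genes
#' are sorted lexicographically before clustering so that ties in merge
#' distance resolve identically regardless of input order.
#'
#' @param m numeric matrix as from [log2FoldMatrix()].
#' @param distance \code{"correlation"} (default) or
#'   \code{"euclidean"}.
#' @param linkage agglomeration method for [stats::hclust()]; default
#'   \code{"average"}.
#' @return list with \code{hclust} (the tree), \code{leafOrder}
#'   (character, depth-first leaf order), \code{excluded} (genes with
#'   all-missing profiles), \code{distance}, \code{linkage}.
#' @export
hierarchicalCluster <- function(m, distance = c("correlation", "euclidean"),
                                linkage = "average") {
    distance <- match.arg(distance)
    stopifnot(is.matrix(m), !is.null(rownames(m)))
    excluded <- rownames(m)[rowSums(is.finite(m)) == 0L]
    keep <- setdiff(rownames(m), excluded)
    if (length(keep) < 2L)
        stop("need at least 2 genes with a non-missing profile")
    m <- m[sort(keep), , drop = FALSE]
    hc <- stats::hclust(profileDist(m, distance), method = linkage)
    list(hclust = hc,
         leafOrder = hc$labels[hc$order],
         excluded = excluded,
         distance = distance,
         linkage = linkage)
}

#' Export a clustering as a Newick tree
#'
#' Branch lengths derive from the merge heights of the agglomeration.
#'
#' @param clustering result of [hierarchicalCluster()].
#' @param path optional output file; when \code{NULL} the Newick string
#'   is returned.
#' @return the Newick string (invisibly when written to a file).
#' @export
clusterNewick <- function(clustering, path = NULL) {
    phy <- ape::as.phylo(clustering$hclust)
    txt <- ape::write.tree(phy)
    if (is.null(path)) return(txt)
    writeLines(txt, path)
    invisible(txt)
}

#' Write the clustered matrix in leaf order
#'
#' @param m matrix as passed to [hierarchicalCluster()].
#' @param clustering result of [hierarchicalCluster()].
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeOrderedMatrix <- function(m, clustering, path) {
    ord <- m[clustering$leafOrder, , drop = FALSE]
    out <- data.frame(gene = rownames(ord), ord, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
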