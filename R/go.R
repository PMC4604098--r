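#' Parse a minimal OBO 1.2 ontology
#'
#' Reads \code{[Term]} stanzas with \code{id}, \code{name},
#' \code{namespace}, \code{is_a} and (optionally) \code{relationship:
#' part_of} lines. Obsolete terms are skipped. The parsed graph must be
#' acyclic with every parent reference resolvable.
#'
#' @param x path to an OBO file, or a character vector of OBO lines.
#' @param partOfAsIsA treat \code{part_of} relationships as parent
#'   links, like \code{is_a} (default \code{TRUE}; the usual true-path
#'   closure).
#' @return a [GoDag-class].
#' @export
parseObo <- function(x, partOfAsIsA = TRUE) {
    lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
    lines <- trimws(lines)
    stanzaStarts <- which(lines == "[Term]")
    if (!length(stanzaStarts)) stop("no [Term] stanzas found")
    bounds <- c(stanzaStarts, length(lines) + 1L)
    ids <- character(0); nms <- character(0); nss <- character(0)
    parents <- list()
    for (k in seq_along(stanzaStarts)) {
        chunk <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
        field <- function(tag) {
            v <- grep(paste0("^", tag, ":"), chunk, value = TRUE)
            trimws(sub(paste0("^", tag, ":"), "", v))
        }
        if (length(grep("^is_obsolete: *true", chunk))) next
        id <- field("id")[1]
        if (is.na(id)) stop("[Term] stanza without id")
        nm <- field("name")[1]
        ns <- field("namespace")[1]
        par <- sub(" *!.*$", "", field("is_a"))
        if (partOfAsIsA) {
            rel <- field("relationship")
            po <- grep("^part_of ", rel, value = TRUE)
            par <- c(par, sub(" *!.*$", "", sub("^part_of +", "", po)))
        }
        ids <- c(ids, id)
        nms <- c(nms, if (is.na(nm)) id else nm)
        nss <- c(nss, if (is.na(ns)) "default" else ns)
        parents[[id]] <- unique(par[nzchar(par)])
    }
    if (anyDuplicated(ids)) stop("duplicate term ids in OBO input")
    dangling <- setdiff(unlist(parents, use.names = FALSE), ids)
    if (length(dangling))
        stop("dangling parent reference(s): ",
             paste(utils::head(dangling, 5), collapse = ", "))
    dag <- new("GoDag",
               terms = data.frame(id = ids, name = nms, namespace = nss,
                                  stringsAsFactors = FALSE),
               parents = parents[ids])
    lv <- try(dagLevels(dag), silent = TRUE)
    if (inherits(lv, "try-error"))
        stop("ontology graph contains a cycle")
    dag
}

# Longest-path-to-root level of every term; errors on a cycle. Roots are
# level 0. Computed by iterating level = 1 + max(parent levels).
dagLevels <- function(dag) {
    par <- dag@parents
    lv <- setNames(rep(NA_integer_, length(par)), names(par))
    lv[lengths(par) == 0L] <- 0L
    repeat {
        todo <- names(lv)[is.na(lv)]
        if (!length(todo)) break
        progressed <- FALSE
        for (t in todo) {
            pl <- lv[par[[t]]]
            if (!anyNA(pl)) {
                lv[t] <- 1L + max(pl)
                progressed <- TRUE
            }
        }
        if (!progressed)
            stop("cycle detected involving term(s): ",
                 paste(utils::head(names(lv)[is.na(lv)], 5),
                       collapse = ", "))
    }
    lv
}

#' Ancestors of a term
#'
#' @param dag a [GoDag-class].
#' @param term term id.
#' @return character vector of strict ancestors (term itself excluded).
#' @export
termAncestors <- function(dag, term) {
    stopifnot(is(dag, "GoDag"))
    if (!term %in% names(dag@parents)) stop("unknown term: ", term)
    seen <- character(0)
    queue <- dag@parents[[term]]
    while (length(queue)) {
        t <- queue[[1L]]; queue <- queue[-1L]
        if (t %in% seen) next
        seen <- c(seen, t)
        queue <- c(queue, dag@parents[[t]])
    }
    sort(seen)
}

#' Propagate direct annotations up the ontology (true-path rule)
#'
#' A gene directly annotated to a term is implicitly annotated to every
#' ancestor of that term; this closure is a prerequisite of any GO
#' over-representation test. The operation is idempotent.
#'
#' @param dag a [GoDag-class].
#' @param direct named list: gene id -> character vector of directly
#'   annotated term ids.
#' @return named list of the same shape with each gene's term set
#'   closed under ancestry (sorted).
#' @export
propagateAnnotations <- function(dag, direct) {
    stopifnot(is(dag, "GoDag"), is.list(direct))
    allTerms <- unique(unlist(direct, use.names = FALSE))
    unknown <- setdiff(allTerms, names(dag@parents))
    if (length(unknown))
        stop("unknown term id(s): ",
             paste(utils::head(unknown, 5), collapse = ", "))
    anc <- lapply(setNames(allTerms, allTerms),
                  function(t) c(t, termAncestors(dag, t)))
    lapply(direct, function(ts)
        sort(unique(unlist(anc[ts], use.names = FALSE))))
}

#' One-sided hypergeometric over-representation test for a term
#'
#' Probability of observing at least the given study overlap when
#' drawing the study set from the universe without replacement (the
#' per-node test of classic and elim GO enrichment).
#'
#' @param universeSize genes in the universe.
#' @param termInUniverse universe genes annotated to the term.
#' @param studySize genes in the study set.
#' @param termInStudy study genes annotated to the term.
#' @return upper-tail probability P(X >= termInStudy).
#' @examples
#' fisherTerm(20, 5, 5, 4)  # 76/15504
#' @export
fisherTerm <- function(universeSize, termInUniverse, studySize,
                       termInStudy) {
    for (v in c(universeSize, termInUniverse, studySize, termInStudy))
        if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
            v != floor(v))
            stop("counts must be non-negative integers")
    if (termInUniverse > universeSize || studySize > universeSize ||
        termInStudy > min(termInUniverse, studySize))
        stop("inconsistent counts")
    stats::phyper(termInStudy - 1L, termInUniverse,
                  universeSize - termInUniverse, studySize,
                  lower.tail = FALSE)
}

#' GO over-representation with the elim decorrelation algorithm
#'
#' Tests every term carrying at least one universe annotation, walking
#' the ontology from its most specific terms upward (terms ordered by
#' decreasing longest-path-to-root level, ties broken by term id). Each
#' term is tested with the one-sided hypergeometric test on its
#' \emph{current} gene sets; when a term's elim p-value falls below the
#' significance cutoff, the genes currently annotated to it are removed
#' from the annotation sets of all of its strict ancestors before those
#' are tested. This suppresses the trivial re-discovery of a specific
#' signal at every general ancestor. The classic p-value (computed on
#' the unpruned sets) is reported alongside; for leaf terms the two are
#' always equal.
#'
#' @param dag a [GoDag-class].
#' @param annotations propagated annotations, as from
#'   [propagateAnnotations()]: named list gene -> term ids.
#' @param study character vector of study gene ids; must be a subset of
#'   \code{universe}.
#' @param universe character vector of universe gene ids.
#' @param cutoff elim significance (and conventional reporting)
#'   threshold on the raw p-value; default 0.01. \code{cutoff = 0}
#'   disables pruning, making elim identical to classic.
#' @return \code{data.frame} with columns \code{term}, \code{name},
#'   \code{annotated} (universe count), \code{significant} (study
#'   count, unpruned), \code{p_classic}, \code{p_elim}, sorted by
#'   \code{p_elim} then term id. No multiple-testing correction is
#'   applied (raw p-values are the convention for elim reports).
#' @export
elimEnrich <- function(dag, annotations, study, universe, cutoff = 0.01) {
    stopifnot(is(dag, "GoDag"), is.list(annotations))
    study <- unique(as.character(study))
    universe <- unique(as.character(universe))
    bad <- setdiff(study, universe)
    if (length(bad))
        stop("study gene(s) absent from universe: ",
             paste(utils::head(bad, 5), collapse = ", "))
    ann <- annotations[intersect(names(annotations), universe)]
    # term -> universe genes annotated to it (propagated)
    term2genes <- split(rep(names(ann), lengths(ann)),
                        unlist(ann, use.names = FALSE))
    term2genes <- lapply(term2genes, unique)
    terms <- intersect(names(dag@parents), names(term2genes))
    if (!length(terms))
        return(data.frame(term = character(0), name = character(0),
                          annotated = integer(0), significant = integer(0),
                          p_classic = numeric(0), p_elim = numeric(0),
                          stringsAsFactors = FALSE))
    lv <- dagLevels(dag)[terms]
    ord <- terms[order(-lv, terms)]
    N <- length(universe)
    n <- length(study)
    current <- term2genes[ord]
    pClassic <- pElim <- setNames(numeric(length(ord)), ord)
    annUniv <- annStudy <- setNames(integer(length(ord)), ord)
    for (t in ord) {
        full <- term2genes[[t]]
        annUniv[t] <- length(full)
        annStudy[t] <- length(intersect(full, study))
        pClassic[t] <- fisherTerm(N, annUniv[t], n, annStudy[t])
        cur <- current[[t]]
        kUniv <- length(cur)
        kStudy <- length(intersect(cur, study))
        pElim[t] <- fisherTerm(N, kUniv, n, kStudy)
        if (cutoff > 0 && pElim[t] < cutoff && length(cur)) {
            for (a in intersect(termAncestors(dag, t), ord))
                current[[a]] <- setdiff(current[[a]], cur)
        }
    }
    nameOf <- setNames(dag@terms$name, dag@terms$id)
    res <- data.frame(term = ord, name = unname(nameOf[ord]),
                      annotated = unname(annUniv),
                      significant = unname(annStudy),
                      p_classic = unname(pClassic),
                      p_elim = unname(pElim),
                      stringsAsFactors = FALSE)
    res <- res[order(res$p_elim, res$term), , drop = FALSE]
    rownames(res) <- NULL
    res
}
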