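#' Synthetic two-condition abundance experiment with planted fold changes
#'
#' Generates treatment and control replicate tables (RPKM-like,
#' non-negative) for one stress contrast, with a known subset of
#' differentially expressed genes whose true fold factors are recorded.
#' Baseline abundances are log-normal; replicate noise is multiplicative
#' log-normal with unit mean and the requested coefficient of variation,
#' so the expected treatment/control ratio of a planted gene equals its
#' planted fold exactly and non-planted genes are balanced. A stated
#' fraction of the planted genes is emitted with all-zero control
#' replicates and strictly positive treatment replicates, to exercise
#' the "-" (undetermined fold) convention of cross-stress tables.
#'
#' Fold factors are drawn log-normally (symmetric in log space, so up-
#' and down-regulation are exchangeable, with the heavy right tail real
#' fold tables show).
#'
#' @param nGenes number of genes.
#' @param nDeg number of planted differentially expressed genes.
#' @param foldSampler either a list with \code{meanlog}, \code{sdlog}
#'   for the log-normal fold distribution (default \code{meanlog = 0,
#'   sdlog = 0.7}) or a function \code{n -> positive folds}.
#' @param nReps replicates per condition; default 3 (the usual
#'   biological-triplicate design).
#' @param noiseCv replicate coefficient of variation; default 0.1.
#' @param zeroControlFraction fraction of planted genes with all-zero
#'   controls; default 0.03.
#' @param seed integer seed; the same seed and parameters reproduce the
#'   output bit for bit.
#' @param degGenes optional explicit gene ids to plant (must be among
#'   the generated ids); overrides the default choice.
#' @param folds optional explicit fold factors, recycled along
#'   \code{degGenes}; overrides \code{foldSampler}.
#' @param baselines optional explicit control-level baselines (recycled
#'   to \code{nGenes}); overrides the log-normal draw.
#' @return list with \code{treatment} and \code{control} (gene x
#'   replicate matrices, columns \code{trt_1..}/\code{ctrl_1..}) and
#'   \code{truth} (list: \code{degGenes} named numeric of planted
#'   folds, \code{zeroControlGenes} character).
#' @export
genContrastExperiment <- function(nGenes, nDeg,
                                  foldSampler = list(meanlog = 0,
                                                     sdlog = 0.7),
                                  nReps = 3L, noiseCv = 0.1,
                                  zeroControlFraction = 0.03,
                                  seed = 1L, degGenes = NULL,
                                  folds = NULL, baselines = NULL) {
    stopifnotCount(nGenes, "nGenes")
    stopifnotCount(nReps, "nReps")
    if (!is.numeric(nDeg) || nDeg < 0 || nDeg > nGenes)
        stop("nDeg must lie in [0, nGenes]")
    if (noiseCv < 0) stop("noiseCv must be non-negative")
    stopifnotFraction(zeroControlFraction, "zeroControlFraction")
    withSeed(seed, {
        genes <- sprintf("g%05d", seq_len(nGenes))
        deg <- if (is.null(degGenes)) sample(genes, nDeg)
               else as.character(degGenes)
        if (!all(deg %in% genes))
            stop("degGenes must be among the generated gene ids")
        fold <- if (!is.null(folds)) rep_len(folds, length(deg))
                else if (is.function(foldSampler)) foldSampler(length(deg))
                else stats::rlnorm(length(deg),
                                   meanlog = foldSampler$meanlog,
                                   sdlog = foldSampler$sdlog)
        if (any(fold <= 0)) stop("planted folds must be positive")
        names(fold) <- deg
        baseline <- if (is.null(baselines))
            stats::rlnorm(nGenes, meanlog = log(10), sdlog = 1)
        else rep_len(as.numeric(baselines), nGenes)
        if (any(baseline < 0)) stop("baselines must be non-negative")
        names(baseline) <- genes
        foldVec <- setNames(rep(1, nGenes), genes)
        foldVec[deg] <- fold
        s2 <- log(1 + noiseCv^2)
        noise <- function(n) {
            if (noiseCv == 0) rep(1, n)
            else stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
        }
        control <- matrix(baseline * noise(nGenes * nReps),
                          nrow = nGenes, ncol = nReps,
                          dimnames = list(genes,
                                          paste0("ctrl_", seq_len(nReps))))
        treatment <- matrix(baseline * foldVec * noise(nGenes * nReps),
                            nrow = nGenes, ncol = nReps,
                            dimnames = list(genes,
                                            paste0("trt_",
                                                   seq_len(nReps))))
        nZero <- round(zeroControlFraction * length(deg))
        zeroGenes <- if (nZero > 0) deg[seq_len(nZero)] else character(0)
        control[zeroGenes, ] <- 0
        # zero-control genes must still be expressed under treatment
        treatment[zeroGenes, ][treatment[zeroGenes, ] <= 0] <- 1
        list(treatment = treatment, control = control,
             truth = list(degGenes = fold,
                          zeroControlGenes = zeroGenes))
    })
}

#' Synthetic expression compendium with planted co-expression modules
#'
#' Emulates a normalized genes x arrays microarray compendium. Genes of
#' one planted module share a latent standard-normal array profile
#' scaled by \code{latentWeight}, plus independent Gaussian noise, so
#' the expected within-module Pearson correlation is
#' \code{latentWeight^2 / (latentWeight^2 + noiseSd^2)} - callers can
#' place it above or below a network threshold by choosing the weight.
#' Background genes are pure independent noise (expected correlation
#' 0).
#'
#' @param nGenes number of genes (module sizes must sum to at most
#'   this).
#' @param nArrays number of arrays, at least 3; default 300 (a
#'   root-compendium-sized collection).
#' @param modules list of planted modules, each \code{c(size,
#'   latentWeight)} or \code{list(size =, latentWeight =)}; sizes must
#'   be >= 2. Default: two modules of 10 and 6 genes at weight 3.
#' @param noiseSd per-gene noise standard deviation; default 1 (weight
#'   3 then gives expected within-module r = 0.9).
#' @param seed integer seed.
#' @param geneIds optional explicit gene ids of length \code{nGenes};
#'   module members are the leading ids, in order.
#' @return list with \code{matrix} (genes x arrays) and \code{truth}
#'   (list: \code{moduleMembership} named integer, \code{NA} for
#'   background; \code{expectedR} numeric per module).
#' @export
genCompendium <- function(nGenes, nArrays = 300L,
                          modules = list(c(10, 3), c(6, 3)),
                          noiseSd = 1, seed = 1L, geneIds = NULL) {
    stopifnotCount(nGenes, "nGenes")
    if (nArrays < 3L) stop("nArrays must be at least 3")
    if (noiseSd < 0) stop("noiseSd must be positive or zero")
    sizes <- vapply(modules, function(m)
        as.numeric(if (is.list(m)) m$size else m[[1]]), numeric(1))
    weights <- vapply(modules, function(m)
        as.numeric(if (is.list(m)) m$latentWeight else m[[2]]), numeric(1))
    if (any(sizes < 2)) stop("module sizes must be at least 2")
    if (sum(sizes) > nGenes)
        stop("module sizes must sum to at most nGenes")
    genes <- if (is.null(geneIds)) sprintf("g%05d", seq_len(nGenes))
             else as.character(geneIds)
    if (length(genes) != nGenes || anyDuplicated(genes))
        stop("geneIds must be nGenes unique ids")
    withSeed(seed, {
        mat <- matrix(stats::rnorm(nGenes * nArrays), nGenes, nArrays,
                      dimnames = list(genes,
                                      sprintf("array_%03d",
                                              seq_len(nArrays))))
        membership <- setNames(rep(NA_integer_, nGenes), genes)
        offset <- 0L
        for (k in seq_along(sizes)) {
            idx <- offset + seq_len(sizes[k])
            latent <- stats::rnorm(nArrays)
            mat[idx, ] <- weights[k] * matrix(latent, sizes[k], nArrays,
                                              byrow = TRUE) +
                noiseSd * matrix(stats::rnorm(sizes[k] * nArrays),
                                 sizes[k], nArrays)
            membership[idx] <- k
            offset <- offset + as.integer(sizes[k])
        }
        list(matrix = mat,
             truth = list(moduleMembership = membership,
                          expectedR = weights^2 /
                              (weights^2 + noiseSd^2)))
    })
}

#' Synthetic gene ontology universe with one planted enriched term
#'
#' Builds a random rooted DAG (single root, acyclic, bounded depth),
#' direct (unpropagated) gene annotations, and a study gene list
#' enriched for one planted term at a stated odds factor: study genes
#' are drawn from the universe by weighted sampling without
#' replacement, weighting genes that carry the planted term by
#' \code{enrichmentOdds} (odds 1 reduces to the hypergeometric null).
#'
#' @param nTerms number of terms including the root.
#' @param maxDepth maximum longest-path depth of any term.
#' @param universeSize number of universe genes.
#' @param plantedTerm term id to over-represent; must exist in the
#'   generated DAG (ids are \code{GO:0000001 ..}, root first).
#' @param studySize study list size.
#' @param enrichmentOdds positive odds factor; default 10.
#' @param seed integer seed.
#' @param carrierFraction fraction of universe genes directly annotated
#'   to the planted term; default 0.2.
#' @param universeGenes optional explicit universe gene ids.
#' @param studyGenes optional explicit study list; when given, the
#'   study is not sampled - instead the planted term's carriers are
#'   sampled with weight \code{enrichmentOdds} on study members, which
#'   plants the same enrichment around a study fixed by upstream
#'   stages.
#' @return list with \code{obo} (character lines, OBO 1.2),
#'   \code{annotations} (data.frame gene, term; direct only),
#'   \code{study} (character), \code{universe} (character) and
#'   \code{truth} (list: plantedTerm, carriers).
#' @export
genGoUniverse <- function(nTerms = 40L, maxDepth = 5L,
                          universeSize = 500L,
                          plantedTerm = "GO:0000005",
                          studySize = 50L, enrichmentOdds = 10,
                          seed = 1L, carrierFraction = 0.2,
                          universeGenes = NULL, studyGenes = NULL) {
    stopifnotCount(nTerms, "nTerms")
    stopifnotCount(maxDepth, "maxDepth")
    stopifnotCount(universeSize, "universeSize")
    if (!is.numeric(enrichmentOdds) || enrichmentOdds <= 0)
        stop("enrichmentOdds must be positive")
    ids <- sprintf("GO:%07d", seq_len(nTerms))
    if (!plantedTerm %in% ids)
        stop("plantedTerm ", plantedTerm,
             " does not exist in the generated DAG")
    withSeed(seed, {
        level <- setNames(integer(nTerms), ids)
        parents <- setNames(vector("list", nTerms), ids)
        for (i in seq_len(nTerms)[-1]) {
            eligible <- ids[seq_len(i - 1L)][level[seq_len(i - 1L)] <
                                             maxDepth]
            # the planted term stays childless (a specific term), so its
            # propagated annotation set is exactly its direct carriers
            # plus direct background - a clean, recoverable ground truth
            if (plantedTerm != ids[1L])
                eligible <- setdiff(eligible, plantedTerm)
            np <- min(length(eligible), sample(1:2, 1L))
            parents[[ids[i]]] <- sort(sample(eligible, np))
            level[ids[i]] <- 1L + max(level[parents[[ids[i]]]])
        }
        obo <- c("format-version: 1.2", "")
        for (i in seq_len(nTerms)) {
            obo <- c(obo, "[Term]",
                     paste0("id: ", ids[i]),
                     paste0("name: synthetic term ", i),
                     "namespace: biological_process",
                     if (i > 1L) paste0("is_a: ", parents[[ids[i]]],
                                        " ! synthetic parent"),
                     "")
        }
        universe <- if (is.null(universeGenes))
            sprintf("u%05d", seq_len(universeSize))
        else as.character(universeGenes)
        if (length(universe) != universeSize)
            universeSize <- length(universe)
        if (studySize > universeSize)
            stop("studySize must not exceed universeSize")
        # background direct annotations: 1-2 random terms per gene
        nAnn <- 1L + (stats::runif(universeSize) < 0.5)
        annGene <- rep(universe, nAnn)
        annTerm <- sample(ids, sum(nAnn), replace = TRUE)
        if (is.null(studyGenes)) {
            carriers <- sample(universe,
                               round(carrierFraction * universeSize))
            w <- ifelse(universe %in% carriers, enrichmentOdds, 1)
            study <- sort(sample(universe, studySize, prob = w))
        } else {
            study <- sort(unique(as.character(studyGenes)))
            if (!all(study %in% universe))
                stop("studyGenes must be a subset of the universe")
            w <- ifelse(universe %in% study, enrichmentOdds, 1)
            carriers <- sample(universe,
                               round(carrierFraction * universeSize),
                               prob = w)
        }
        annGene <- c(annGene, carriers)
        annTerm <- c(annTerm, rep(plantedTerm, length(carriers)))
        ann <- unique(data.frame(gene = annGene, term = annTerm,
                                 stringsAsFactors = FALSE))
        ann <- ann[order(ann$gene, ann$term), , drop = FALSE]
        rownames(ann) <- NULL
        list(obo = obo, annotations = ann, study = study,
             universe = universe,
             truth = list(plantedTerm = plantedTerm,
                          carriers = sort(carriers)))
    })
}

#' Synthetic upstream promoter sequences with planted motifs
#'
#' Generates fixed-length upstream sequences (default 3000 bp, the
#' conventional window upstream of the translation start) and plants
#' concrete motif instances so that the match base nearest the
#' translation start sits at exactly the stated upstream distance. With
#' \code{forbidBackgroundHits}, background occurrences of the
#' degenerate pattern are removed by targeted resampling, so a scan
#' recovers exactly the planted truth.
#'
#' @param nGenes number of promoters.
#' @param length upstream length L in bp; default 3000.
#' @param plantSpec named list (gene id -> data.frame with columns
#'   \code{distance}, \code{motif}) of planted instances; distances
#'   must lie in \code{[1, L - nchar(motif) + 1]} and instances within
#'   one gene must not overlap. Gene ids outside the generated set are
#'   rejected. Default: none.
#' @param gc background GC content; default 0.36 (Arabidopsis
#'   promoter-like).
#' @param forbidBackgroundHits guarantee no occurrence of
#'   \code{pattern} other than the planted ones; default \code{FALSE}.
#' @param pattern degenerate IUPAC pattern defining the motif family
#'   (default the P1BS element \code{"GNATATNC"}); planted motifs must
#'   conform to it when it is non-\code{NULL}.
#' @param seed integer seed.
#' @param geneIds optional explicit gene ids (length \code{nGenes}).
#' @return list with \code{promoters}
#'   (\code{Biostrings::DNAStringSet}, names = gene ids),
#'   \code{upstreamLength} and \code{truth} (data.frame gene, distance,
#'   motif).
#' @export
genPromoters <- function(nGenes, length = 3000L, plantSpec = list(),
                         gc = 0.36, forbidBackgroundHits = FALSE,
                         pattern = "GNATATNC", seed = 1L,
                         geneIds = NULL) {
    stopifnotCount(nGenes, "nGenes")
    stopifnotCount(length, "length")
    stopifnotFraction(gc, "gc")
    genes <- if (is.null(geneIds)) sprintf("g%05d", seq_len(nGenes))
             else as.character(geneIds)
    if (length(genes) != nGenes || anyDuplicated(genes))
        stop("geneIds must be nGenes unique ids")
    patSets <- if (!is.null(pattern)) compileIupac(pattern) else NULL
    plantSpec <- lapply(plantSpec, function(df) {
        df <- as.data.frame(df)
        stopifnot(all(c("distance", "motif") %in% names(df)))
        df$motif <- toupper(as.character(df$motif))
        df$distance <- as.integer(df$distance)
        df
    })
    if (length(plantSpec)) {
        if (is.null(names(plantSpec)) || !all(names(plantSpec) %in% genes))
            stop("plantSpec must be named by generated gene ids")
        for (g in names(plantSpec)) {
            df <- plantSpec[[g]]
            m <- nchar(df$motif)
            if (any(df$distance < 1L | df$distance > length - m + 1L))
                stop("planted distance out of range for gene ", g)
            if (!is.null(patSets)) {
                for (mm in df$motif) {
                    ch <- strsplit(mm, "")[[1]]
                    if (base::length(ch) != base::length(patSets) ||
                        !all(mapply(`%in%`, ch, patSets)))
                        stop("planted motif ", mm,
                             " does not conform to pattern ", pattern)
                }
            }
            # window occupied by a plant at distance d: string
            # positions [L - m + 2 - d, L + 1 - d]
            lo <- length - m + 2L - df$distance
            hi <- length + 1L - df$distance
            o <- order(lo)
            if (any(lo[o][-1] <= hi[o][-base::length(hi)]))
                stop("planted motifs overlap within gene ", g)
        }
    }
    withSeed(seed, {
        probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                   T = (1 - gc) / 2)
        seqs <- vapply(genes, function(g) {
            paste(sample(names(probs), length, replace = TRUE,
                         prob = probs), collapse = "")
        }, character(1))
        plantedStarts <- setNames(vector("list", nGenes), genes)
        for (g in names(plantSpec)) {
            df <- plantSpec[[g]]
            ch <- strsplit(seqs[[g]], "")[[1]]
            starts <- integer(0)
            for (i in seq_len(nrow(df))) {
                m <- nchar(df$motif[i])
                s <- length - m + 2L - df$distance[i]
                ch[s:(s + m - 1L)] <- strsplit(df$motif[i], "")[[1]]
                starts <- c(starts, s)
            }
            seqs[[g]] <- paste(ch, collapse = "")
            plantedStarts[[g]] <- starts
        }
        if (forbidBackgroundHits) {
            if (is.null(patSets))
                stop("forbidBackgroundHits requires a pattern")
            m <- base::length(patSets)
            for (g in genes) {
                ch <- strsplit(seqs[[g]], "")[[1]]
                protected <- unlist(lapply(plantedStarts[[g]], function(s)
                    s:(s + m - 1L)))
                for (iter in seq_len(200L)) {
                    hits <- setdiff(matchStarts(ch, patSets),
                                    plantedStarts[[g]])
                    if (!base::length(hits)) break
                    for (s in hits) {
                        win <- s:(s + m - 1L)
                        free <- setdiff(win, protected)
                        # prefer an informative pattern position (one
                        # excluding at least one base)
                        free <- free[order(lengths(patSets[free - s + 1L]))]
                        fixed <- FALSE
                        for (q in free) {
                            allowed <- patSets[[q - s + 1L]]
                            if (base::length(allowed) == 4L) next
                            ch[q] <- sample(setdiff(c("A", "C", "G", "T"),
                                                    allowed), 1L)
                            fixed <- TRUE
                            break
                        }
                        if (!fixed && base::length(free))
                            ch[free[1L]] <- sample(c("A", "C", "G", "T"),
                                                   1L)
                    }
                }
                if (base::length(setdiff(matchStarts(ch, patSets),
                                         plantedStarts[[g]])))
                    stop("could not clear background hits for gene ", g)
                seqs[[g]] <- paste(ch, collapse = "")
            }
        }
        truth <- if (base::length(plantSpec))
            do.call(rbind, lapply(names(plantSpec), function(g)
                data.frame(gene = g,
                           distance = plantSpec[[g]]$distance,
                           motif = plantSpec[[g]]$motif,
                           stringsAsFactors = FALSE)))
        else data.frame(gene = character(0), distance = integer(0),
                        motif = character(0), stringsAsFactors = FALSE)
        truth <- truth[order(truth$gene, truth$distance), , drop = FALSE]
        rownames(truth) <- NULL
        list(promoters = Biostrings::DNAStringSet(seqs),
             upstreamLength = as.integer(length),
             truth = truth)
    })
}

#' Read and write the synthetic-data file formats
#'
#' Plain-text interchange used by the pipeline: abundance tables are
#' TSV with a \code{gene} column followed by \code{ctrl_*} then
#' \code{trt_*} replicate columns; compendia are genes x arrays TSV;
#' annotations are two-column TSV; promoters are FASTA whose record
#' descriptions carry \code{upstream_length=L}.
#'
#' @param treatment,control,compendium gene-by-replicate or
#'   gene-by-array numeric matrices.
#' @param annotations data.frame with columns \code{gene}, \code{term}.
#' @param promoters named \code{DNAStringSet}.
#' @param upstreamLength promoter length recorded in the FASTA
#'   descriptions.
#' @param obo character vector of OBO lines.
#' @param path file path.
#' @return writers return \code{path} invisibly; readers return the
#'   parsed object (for \code{readContrastTable}, a list with
#'   \code{treatment} and \code{control}).
#' @name synthetic-io
NULL

#' @rdname synthetic-io
#' @export
writeContrastTable <- function(treatment, control, path) {
    stopifnot(identical(rownames(treatment), rownames(control)))
    out <- data.frame(gene = rownames(control), control, treatment,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname synthetic-io
#' @export
readContrastTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot("gene" %in% names(tab))
    ctrl <- as.matrix(tab[grep("^ctrl_", names(tab))])
    trt <- as.matrix(tab[grep("^trt_", names(tab))])
    rownames(ctrl) <- rownames(trt) <- tab$gene
    list(treatment = trt, control = ctrl)
}

#' @rdname synthetic-io
#' @export
writeCompendium <- function(compendium, path) {
    out <- data.frame(gene = rownames(compendium), compendium,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname synthetic-io
#' @export
readCompendium <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    m
}

#' @rdname synthetic-io
#' @export
writeAnnotations <- function(annotations, path) {
    utils::write.table(annotations[, c("gene", "term")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}

#' @rdname synthetic-io
#' @export
readAnnotations <- function(path) {
    tab <- utils::read.delim(path, header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("gene", "term"))
    tab
}

#' @rdname synthetic-io
#' @export
writePromoters <- function(promoters, path, upstreamLength = NULL) {
    x <- promoters
    if (!is.null(upstreamLength))
        names(x) <- paste0(names(x), " upstream_length=", upstreamLength)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' @rdname synthetic-io
#' @export
readPromoters <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    names(x) <- sub(" .*$", "", names(x))
    x
}

#' @rdname synthetic-io
#' @export
writeObo <- function(obo, path) {
    writeLines(obo, path)
    invisible(path)
}
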