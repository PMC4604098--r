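#' Replicate-wise fold change with the undetermined-control convention
#'
#' Computes the fold change of a gene between treatment and control as
#' the mean and sample standard deviation of the per-replicate
#' abundance ratios (replicate i of the treatment is paired with
#' replicate i of the control). Three special cases are handled the way
#' published cross-stress tables report them:
#' \itemize{
#'   \item every control replicate is zero while at least one treatment
#'     replicate is positive: the fold cannot be computed and is
#'     reported as \emph{undetermined} (rendered "-" in tables);
#'   \item both conditions are all-zero: undetermined as well, but
#'     flagged \code{"silent"} to distinguish a gene that is simply not
#'     expressed;
#'   \item some, but not all, control replicates are zero: the affected
#'     replicate pairs are dropped and \code{n} reduced, keeping the
#'     mean and SD finite.
#' }
#'
#' @param treatment,control numeric vectors of equal length with the
#'   non-negative per-replicate abundances (RPKM-like units).
#' @return a list with elements \code{mean} (positive number or
#'   \code{NA}), \code{sd} (\code{NA} when undetermined or when only one
#'   usable replicate pair remains), \code{n} (replicate pairs used) and
#'   \code{flag} (\code{"ok"}, \code{"undetermined"} or
#'   \code{"silent"}).
#' @examples
#' computeFoldChange(c(4, 6, 8), c(2, 2, 2))   # mean 3, sd 1
#' computeFoldChange(c(7, 9, 5), c(0, 0, 0))   # undetermined
#' @export
computeFoldChange <- function(treatment, control) {
    if (length(treatment) != length(control))
        stop("treatment and control must have the same number of replicates")
    if (length(treatment) < 1L)
        stop("at least one replicate is required")
    if (any(is.na(treatment)) || any(is.na(control)))
        stop("abundances must not be NA")
    if (any(treatment < 0) || any(control < 0))
        stop("abundances must be non-negative")
    if (all(control == 0)) {
        flag <- if (any(treatment > 0)) "undetermined" else "silent"
        return(list(mean = NA_real_, sd = NA_real_, n = length(treatment),
                    flag = flag))
    }
    keep <- control > 0
    r <- treatment[keep] / control[keep]
    n <- sum(keep)
    list(mean = mean(r),
         sd = if (n > 1L) stats::sd(r) else NA_real_,
         n = n,
         flag = "ok")
}

#' Fold-change table for a whole contrast
#'
#' Applies [computeFoldChange()] to every gene of a treatment/control
#' abundance pair.
#'
#' @param treatment,control numeric matrices (genes x replicates) with
#'   identical rownames and the same number of columns.
#' @return a \code{data.frame} with columns \code{gene}, \code{mean},
#'   \code{sd}, \code{n}, \code{flag}.
#' @export
foldChangeTable <- function(treatment, control) {
    stopifnot(is.matrix(treatment), is.matrix(control),
              identical(rownames(treatment), rownames(control)),
              ncol(treatment) == ncol(control))
    if (is.null(rownames(treatment)))
        stop("abundance matrices must carry gene ids as rownames")
    rows <- lapply(rownames(treatment), function(g)
        computeFoldChange(treatment[g, ], control[g, ]))
    data.frame(gene = rownames(treatment),
               mean = vapply(rows, `[[`, numeric(1), "mean"),
               sd = vapply(rows, `[[`, numeric(1), "sd"),
               n = vapply(rows, `[[`, integer(1), "n"),
               flag = vapply(rows, `[[`, character(1), "flag"),
               stringsAsFactors = FALSE)
}

#' Intersect two differentially-expressed gene lists
#'
#' @param listA,listB character vectors of gene ids (duplicates are
#'   ignored).
#' @return the sorted intersection; symmetric in its arguments.
#' @examples
#' overlapGenes(c("A", "B", "C"), c("B", "C", "D"))
#' @export
overlapGenes <- function(listA, listB) {
    sort(intersect(unique(as.character(listA)),
                   unique(as.character(listB))))
}

#' Assemble the two-contrast overlap table
#'
#' Joins the per-contrast fold-change tables for the genes responding to
#' both stresses into an [OverlapTable-class].
#'
#' @param feTable,piTable data.frames as returned by
#'   [foldChangeTable()] for the iron-deficiency and
#'   phosphate-starvation contrasts.
#' @param genes gene ids to keep (typically the overlap of the two DEG
#'   lists); every id must be present in both tables.
#' @return an \code{OverlapTable}.
#' @export
makeOverlapTable <- function(feTable, piTable, genes) {
    genes <- sort(unique(as.character(genes)))
    miss <- setdiff(genes, intersect(feTable$gene, piTable$gene))
    if (length(miss))
        stop("genes absent from a contrast table: ",
             paste(utils::head(miss, 5), collapse = ", "))
    fe <- feTable[match(genes, feTable$gene), ]
    pi <- piTable[match(genes, piTable$gene), ]
    rec <- data.frame(gene = genes,
                      fe_mean = fe$mean, fe_sd = fe$sd, fe_flag = fe$flag,
                      fe_n = fe$n,
                      pi_mean = pi$mean, pi_sd = pi$sd, pi_flag = pi$flag,
                      pi_n = pi$n,
                      stringsAsFactors = FALSE)
    new("OverlapTable", records = rec)
}

#' Read an overlap fold-change table from TSV
#'
#' Reads a tab-separated table with columns \code{gene}, \code{fe_mean},
#' \code{fe_sd}, \code{pi_mean}, \code{pi_sd} in which undetermined fold
#' changes are written as \code{"-"} (the convention of printed
#' cross-stress tables).
#'
#' @param path file path.
#' @param nReps replicate count to record (the file format does not
#'   carry it); default 3.
#' @return an [OverlapTable-class].
#' @export
readOverlapTable <- function(path, nReps = 3L) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    need <- c("gene", "fe_mean", "fe_sd", "pi_mean", "pi_sd")
    if (!all(need %in% names(tab)))
        stop("expected columns: ", paste(need, collapse = ", "))
    num <- function(x) suppressWarnings(as.numeric(ifelse(x == "-", NA, x)))
    rec <- data.frame(gene = tab$gene,
                      fe_mean = num(tab$fe_mean), fe_sd = num(tab$fe_sd),
                      fe_flag = ifelse(tab$fe_mean == "-", "undetermined",
                                       "ok"),
                      fe_n = as.integer(nReps),
                      pi_mean = num(tab$pi_mean), pi_sd = num(tab$pi_sd),
                      pi_flag = ifelse(tab$pi_mean == "-", "undetermined",
                                       "ok"),
                      pi_n = as.integer(nReps),
                      stringsAsFactors = FALSE)
    new("OverlapTable", records = rec)
}

#' Write an overlap table as TSV ("-" for undetermined)
#'
#' @param x an [OverlapTable-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeOverlapTable <- function(x, path) {
    stopifnot(is(x, "OverlapTable"))
    rec <- x@records
    fmt <- function(v) ifelse(is.na(v), "-", format(v, trim = TRUE,
                                                    scientific = FALSE))
    out <- data.frame(gene = rec$gene,
                      fe_mean = fmt(rec$fe_mean), fe_sd = fmt(rec$fe_sd),
                      pi_mean = fmt(rec$pi_mean), pi_sd = fmt(rec$pi_sd),
                      flags = paste0(ifelse(rec$fe_flag == "ok", "", "fe:"),
                                     ifelse(rec$fe_flag == "ok", "",
                                            rec$fe_flag),
                                     ifelse(rec$pi_flag == "ok", "", ";pi:"),
                                     ifelse(rec$pi_flag == "ok", "",
                                            rec$pi_flag)),
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

# Effective fold used by the filter/classifier: undetermined counts as
# up-regulated (Inf); silent genes carry no direction (NA).
effectiveFold <- function(mean, flag) {
    ifelse(flag == "undetermined", Inf,
           ifelse(flag == "silent", NA_real_, mean))
}

#' Keep genes changed beyond a fold cutoff in either contrast
#'
#' A gene passes when, in at least one of the two contrasts, its mean
#' fold is \code{>= cutoff} (up) or \code{<= 1/cutoff} (down). An
#' undetermined fold (zero control, positive treatment) passes any
#' up-regulation cutoff.
#'
#' @param x an [OverlapTable-class].
#' @param cutoff fold cutoff, must be > 1 (default 2, the conventional
#'   twofold filter).
#' @return the filtered \code{OverlapTable}.
#' @export
filterByFold <- function(x, cutoff = 2) {
    stopifnot(is(x, "OverlapTable"))
    if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 1)
        stop("cutoff must be a single number greater than 1")
    rec <- x@records
    fe <- effectiveFold(rec$fe_mean, rec$fe_flag)
    pi <- effectiveFold(rec$pi_mean, rec$pi_flag)
    pass1 <- !is.na(fe) & (fe >= cutoff | fe <= 1 / cutoff)
    pass2 <- !is.na(pi) & (pi >= cutoff | pi <= 1 / cutoff)
    new("OverlapTable", records = rec[pass1 | pass2, , drop = FALSE])
}

#' Classify overlap genes into the four cross-stress regulatory types
#'
#' Partitions genes by the direction of their response under the two
#' stresses: type 1 = down under both Fe and Pi deficiency; type 2 = up
#' under both; type 3 = up under Pi deficiency but down under Fe
#' deficiency; type 4 = up under Fe deficiency but down under Pi
#' starvation. An undetermined fold counts as up-regulated. A mean fold
#' of exactly 1 carries no direction and the gene is left UNCLASSIFIED
#' (excluded from the four counts).
#'
#' For each requested cutoff the per-type sub-counts report how many
#' genes of that type are changed beyond the cutoff, under two readings:
#' \code{either} (beyond the cutoff in at least one contrast) and
#' \code{both} (in both contrasts). The change magnitude in a contrast
#' is \code{max(fold, 1/fold)}, infinite for undetermined folds.
#'
#' @param x an [OverlapTable-class].
#' @param cutoffs numeric vector of fold cutoffs (> 1) for the
#'   sub-counts; default \code{c(2, 1.5)}.
#' @return a list with \code{assignment} (data.frame gene, type where
#'   type is 1:4 or NA for UNCLASSIFIED), \code{counts} (named integer
#'   vector type1..type4, unclassified) and \code{subCounts} (data.frame
#'   type, cutoff, either, both).
#' @export
classifyTypes <- function(x, cutoffs = c(2, 1.5)) {
    stopifnot(is(x, "OverlapTable"))
    if (any(cutoffs <= 1)) stop("cutoffs must be greater than 1")
    rec <- x@records
    fe <- effectiveFold(rec$fe_mean, rec$fe_flag)
    pi <- effectiveFold(rec$pi_mean, rec$pi_flag)
    type <- rep(NA_integer_, nrow(rec))
    det <- !is.na(fe) & !is.na(pi) & fe != 1 & pi != 1
    type[det & fe < 1 & pi < 1] <- 1L
    type[det & fe > 1 & pi > 1] <- 2L
    type[det & fe < 1 & pi > 1] <- 3L
    type[det & fe > 1 & pi < 1] <- 4L
    counts <- c(type1 = sum(type == 1L, na.rm = TRUE),
                type2 = sum(type == 2L, na.rm = TRUE),
                type3 = sum(type == 3L, na.rm = TRUE),
                type4 = sum(type == 4L, na.rm = TRUE),
                unclassified = sum(is.na(type)))
    magFe <- pmax(fe, 1 / fe)
    magPi <- pmax(pi, 1 / pi)
    sub <- do.call(rbind, lapply(sort(unique(cutoffs)), function(co) {
        do.call(rbind, lapply(1:4, function(tp) {
            idx <- which(type == tp)
            data.frame(type = tp, cutoff = co,
                       either = sum(magFe[idx] >= co | magPi[idx] >= co),
                       both = sum(magFe[idx] >= co & magPi[idx] >= co))
        }))
    }))
    list(assignment = data.frame(gene = rec$gene, type = type,
                                 stringsAsFactors = FALSE),
         counts = counts,
         subCounts = sub)
}

#' Subset an overlap table to one regulatory type
#'
#' @param x an [OverlapTable-class].
#' @param type integer in 1:4 (see [classifyTypes()]).
#' @return the subset \code{OverlapTable}.
#' @export
subsetByType <- function(x, type) {
    stopifnot(type %in% 1:4)
    cls <- classifyTypes(x)
    keep <- cls$assignment$gene[!is.na(cls$assignment$type) &
                                cls$assignment$type == type]
    new("OverlapTable",
        records = x@records[x@records$gene %in% keep, , drop = FALSE])
}

#' Relative expression from qPCR threshold cycles (delta-Ct)
#'
#' Per replicate, the delta threshold cycle is the target gene's Ct
#' minus the mean Ct of the two reference genes. Relative expression of
#' treatment versus control is \code{2^(mean dCt_control - mean
#' dCt_treatment)} and the p-value comes from a two-sample, two-tailed
#' Student t test on the replicate delta-Ct values.
#'
#' @param target,ref1,ref2 each a list with numeric vectors
#'   \code{treatment} and \code{control} of per-replicate Ct values
#'   (cycles); replicate i of the target is paired with replicate i of
#'   each reference within a condition.
#' @return list with \code{relativeExpression}, \code{pValue}
#'   (\code{NA} with a warning when either group has fewer than 2
#'   replicates), \code{dCtTreatment}, \code{dCtControl}.
#' @export
qpcrRelativeExpression <- function(target, ref1, ref2) {
    grab <- function(lst, grp) {
        v <- lst[[grp]]
        if (is.null(v) || !is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
            stop("Ct values must be finite positive numerics for ", grp)
        v
    }
    dct <- function(grp) {
        tg <- grab(target, grp); r1 <- grab(ref1, grp); r2 <- grab(ref2, grp)
        if (length(r1) != length(tg) || length(r2) != length(tg))
            stop("replicate counts must agree within a condition")
        tg - (r1 + r2) / 2
    }
    dTrt <- dct("treatment")
    dCtl <- dct("control")
    rel <- 2^(mean(dCtl) - mean(dTrt))
    p <- if (length(dTrt) < 2L || length(dCtl) < 2L) {
        warning("fewer than 2 replicates per group; p-value undefined")
        NA_real_
    } else if (stats::sd(dTrt) == 0 && stats::sd(dCtl) == 0) {
        if (mean(dTrt) == mean(dCtl)) 1 else 0
    } else {
        stats::t.test(dTrt, dCtl, var.equal = TRUE)$p.value
    }
    list(relativeExpression = rel, pValue = p,
         dCtTreatment = dTrt, dCtControl = dCtl)
}
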