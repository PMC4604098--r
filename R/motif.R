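IUPAC_SETS <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Compile an IUPAC degenerate pattern into position-wise base sets
#'
#' @param pattern uppercase IUPAC string (e.g. the P1BS element
#'   \code{"GNATATNC"}).
#' @return list of character vectors, one allowed-base set per
#'   position.
#' @examples
#' compileIupac("GNATATNC")[[2]]  # A C G T
#' @export
compileIupac <- function(pattern) {
    if (!is.character(pattern) || length(pattern) != 1L ||
        !nzchar(pattern))
        stop("pattern must be a non-empty character string")
    chars <- strsplit(pattern, "")[[1]]
    bad <- setdiff(chars, names(IUPAC_SETS))
    if (length(bad))
        stop("invalid IUPAC character(s): ",
             paste(unique(bad), collapse = ", "))
    unname(IUPAC_SETS[chars])
}

# TRUE where the window starting at each position of `chars` matches the
# compiled sets. An 'N' (or any non-ACGT letter) in the sequence never
# matches any pattern position.
matchStarts <- function(chars, sets) {
    m <- length(sets)
    L <- length(chars)
    if (m > L) return(integer(0))
    ok <- rep(TRUE, L - m + 1L)
    for (p in seq_len(m)) {
        ok <- ok & chars[seq_len(L - m + 1L) + p - 1L] %in% sets[[p]]
    }
    which(ok)
}

#' Scan one upstream promoter sequence for a degenerate motif
#'
#' Slides the pattern over every window of the forward strand and
#' reports matches in upstream coordinates: position 1 is the base
#' immediately 5' of the translation start, so the last base of the
#' sequence string is position 1 and the first is position L. For a
#' window starting at string position s, the reported near distance is
#' \code{L - s - m + 2} (the match base closest to the translation
#' start) and the far distance \code{L - s + 1}. Overlapping matches
#' are all reported; a sequence letter \code{N} (masked base) never
#' matches.
#'
#' Note the P1BS element GNATATNC equals its own reverse complement at
#' the degenerate level, so a forward-strand scan already captures both
#' orientations.
#'
#' @param sequence promoter as a character string or
#'   \code{Biostrings::DNAString}; the string runs 5' to 3' with its
#'   last base adjacent to the translation start.
#' @param pattern IUPAC pattern string.
#' @param gene gene id to stamp on the hits.
#' @return \code{data.frame} with columns \code{gene}, \code{start}
#'   (near distance, bp), \code{end} (far distance), \code{matched}
#'   (concrete subsequence, 5'-3'), sorted by \code{start}. Empty (with
#'   a warning) when the pattern is longer than the sequence.
#' @examples
#' scanPromoter("AAGTATATGCAA", "GNATATNC", gene = "g1")  # start 3, end 10
#' @export
scanPromoter <- function(sequence, pattern, gene = "promoter") {
    seqChar <- toupper(as.character(sequence))
    sets <- compileIupac(pattern)
    m <- length(sets)
    L <- nchar(seqChar)
    empty <- data.frame(gene = character(0), start = integer(0),
                        end = integer(0), matched = character(0),
                        stringsAsFactors = FALSE)
    if (m > L) {
        warning("pattern longer than sequence; no scan performed")
        return(empty)
    }
    chars <- strsplit(seqChar, "")[[1]]
    s <- matchStarts(chars, sets)
    if (!length(s)) return(empty)
    hits <- data.frame(
        gene = gene,
        start = L - s - m + 2L,
        end = L - s + 1L,
        matched = vapply(s, function(i)
            paste(chars[i:(i + m - 1L)], collapse = ""), character(1)),
        stringsAsFactors = FALSE)
    hits <- hits[order(hits$start), , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

#' Scan a set of promoters for a degenerate motif
#'
#' @param promoters a named character vector or
#'   \code{Biostrings::DNAStringSet}; names are gene ids and must be
#'   unique.
#' @param pattern IUPAC pattern string.
#' @return hits \code{data.frame} (see [scanPromoter()]) ordered by
#'   gene id then near distance.
#' @export
scanPromoterSet <- function(promoters, pattern) {
    seqs <- vapply(as.list(promoters), function(x) as.character(x),
                   character(1))
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
        stop("promoters must be named by gene id")
    if (anyDuplicated(names(seqs)))
        stop("duplicate gene id(s) in promoter set")
    out <- lapply(sort(names(seqs)), function(g)
        scanPromoter(seqs[[g]], pattern, gene = g))
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(gene = character(0), start = integer(0),
                          end = integer(0), matched = character(0),
                          stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
}

#' Summarize motif hits the way promoter-survey tables report them
#'
#' Duplicate identical hit records are deliberately counted as distinct
#' records (input fidelity: published hit tables can list a position
#' twice, and their totals count both).
#'
#' @param hits \code{data.frame} with columns \code{gene},
#'   \code{start}, \code{end}, \code{matched}.
#' @param within distance cutoff in bp for the proximal-promoter count;
#'   default 1000.
#' @return list with \code{totalHits}, \code{genesWithHit},
#'   \code{genesWithin} (genes having a hit whose near distance is <=
#'   \code{within}), \code{distinctPatterns}, \code{patternCounts}
#'   (data.frame matched, count, sorted by decreasing count then
#'   pattern).
#' @export
summarizeHits <- function(hits, within = 1000) {
    stopifnot(all(c("gene", "start", "matched") %in% names(hits)))
    if (!nrow(hits))
        return(list(totalHits = 0L, genesWithHit = 0L, genesWithin = 0L,
                    distinctPatterns = 0L,
                    patternCounts = data.frame(matched = character(0),
                                               count = integer(0))))
    pc <- as.data.frame(table(hits$matched), stringsAsFactors = FALSE)
    names(pc) <- c("matched", "count")
    pc <- pc[order(-pc$count, pc$matched), , drop = FALSE]
    rownames(pc) <- NULL
    list(totalHits = nrow(hits),
         genesWithHit = length(unique(hits$gene)),
         genesWithin = length(unique(hits$gene[hits$start <= within])),
         distinctPatterns = nrow(pc),
         patternCounts = pc)
}

#' Read a motif hit table from TSV
#'
#' @param path TSV with columns \code{gene}, \code{start}, \code{end},
#'   \code{matched}.
#' @return the hits \code{data.frame}.
#' @export
readMotifHits <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene", "start", "end", "matched") %in% names(tab)))
    tab
}

#' Write a motif hit table as TSV
#'
#' @param hits hits \code{data.frame}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMotifHits <- function(hits, path) {
    utils::write.table(hits, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
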