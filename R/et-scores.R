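# Evolutionary-trace (ET) real-value scores: parsing of server-style
# "ranks" text files and aggregation over residue sets.  Score
# orientation is kept exactly as in the input (the server convention puts
# low variation near the tree root); no rescaling is applied.

#' Read an evolutionary-trace ranks file
#'
#' The dialect is comment lines starting with \code{\%} or \code{#}
#' followed by whitespace-delimited rows carrying a residue number, a
#' residue type and the real-value ET score (rvet).  Column positions are
#' configurable.  Duplicate residue rows keep the last occurrence, with a
#' warning.
#'
#' @param path ranks-style text file.
#' @param chainId chain the scores describe.
#' @param columns named integer vector giving the 1-based positions of
#'   \code{resno} and \code{rvet} (default \code{c(resno = 1, rvet = 3)}).
#' @param structure optional \code{\linkS4class{ChainStructure}} used to
#'   compute coverage (fraction of chain residues scored).
#' @return an \code{\linkS4class{EtScoreTable}}.
#' @export
readEtFile <- function(path, chainId = "A",
                       columns = c(resno = 1, rvet = 3),
                       structure = NULL) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !grepl("^[%#]", lines)]
    if (!length(lines)) stop("empty ET file: ", path)
    fields <- strsplit(lines, "[[:space:]]+")
    resno <- suppressWarnings(as.integer(
        vapply(fields, `[`, "", columns[["resno"]])))
    rvet <- suppressWarnings(as.numeric(
        vapply(fields, `[`, "", columns[["rvet"]])))
    ok <- !is.na(resno) & is.finite(rvet)
    if (!any(ok)) stop("empty ET file: no parseable rows in ", path)
    resno <- resno[ok]; rvet <- rvet[ok]
    if (anyDuplicated(resno)) {
        warning("duplicate residue rows in ", path, "; last occurrence wins")
        keep <- !duplicated(resno, fromLast = TRUE)
        resno <- resno[keep]; rvet <- rvet[keep]
    }
    scores <- setNames(rvet, resKey(resno))
    coverage <- NA_real_
    if (!is.null(structure)) {
        keys <- unique(resKey(structure@atoms$resno,
                              structure@atoms$icode))
        coverage <- mean(keys %in% names(scores))
    }
    new("EtScoreTable", chainId = chainId, scores = scores,
        coverage = coverage)
}

#' Aggregate rvet scores over a residue set
#'
#' Mean and median over the residues present in the table; residues
#' without a score are skipped (never zero-filled).  When no residue is
#' scored the aggregate is missing (\code{NA}), which propagates through
#' the survey records.
#'
#' @param table an \code{\linkS4class{EtScoreTable}} (or NULL: all
#'   missing).
#' @param residues character vector of residue keys
#'   (\code{"<resno>:<icode>"}).
#' @return list with \code{mean}, \code{median}, \code{n_scored}.
#' @export
aggregateRvet <- function(table, residues) {
    if (!length(residues)) stop("empty residue list")
    if (is.null(table))
        return(list(mean = NA_real_, median = NA_real_, n_scored = 0L))
    stopifnot(is(table, "EtScoreTable"))
    hit <- table@scores[unique(residues)]
    hit <- hit[!is.na(hit)]
    if (!length(hit))
        return(list(mean = NA_real_, median = NA_real_, n_scored = 0L))
    list(mean = mean(hit), median = median(hit),
         n_scored = length(hit))
}
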