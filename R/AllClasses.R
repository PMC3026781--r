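#' @import methods
NULL

#' RNA secondary structure of a folded window
#'
#' Result of folding a sequence with the maximum-weighted nested-pairing
#' dynamic program (\code{\link{foldRNA}}). Pairing is stored as a partner
#' vector: \code{basePairs(x)[i]} is the 1-based partner of position \code{i},
#' or \code{NA} if unpaired. Structures are strictly nested (no pseudoknots)
#' and every hairpin loop spans at least the minimum loop length.
#'
#' @slot sequence folded sequence (DNA alphabet, T for U)
#' @slot pairs integer partner vector (NA = unpaired)
#' @slot score total pair weight of the structure (GC=3, AU=2, GU=1 by
#'   default); acts as a negative pseudo-energy, higher = more stable
#' @slot dotBracket Vienna-style dot-bracket string
#' @slot windowStart 1-based genomic start of the folded window (NA when the
#'   sequence was folded outside genomic context)
#'
#' @exportClass FoldResult
setClass("FoldResult",
         representation(sequence = "character",
                        pairs = "integer",
                        score = "numeric",
                        dotBracket = "character",
                        windowStart = "integer"),
         prototype(windowStart = NA_integer_))

setValidity("FoldResult", function(object) {
    n <- nchar(object@sequence)
    p <- object@pairs
    if (length(p) != n)
        return("pairs length must equal sequence length")
    idx <- which(!is.na(p))
    if (any(p[idx] < 1L | p[idx] > n))
        return("pair partner out of range")
    if (any(p[p[idx]] != idx))
        return("pairs vector is not an involution")
    if (nchar(object@dotBracket) != n)
        return("dot-bracket length must equal sequence length")
    TRUE
})

#' Structural criteria report for a candidate hairpin
#'
#' Outcome of evaluating the novel-miRNA structural criteria on a folded
#' window: (a) the mature span sits in a stem-loop unit with exactly one
#' terminal loop; (b) more than \code{minMaturePaired} mature nucleotides are
#' base-paired; (c) the terminal loop has fewer than \code{loopMax}
#' nucleotides; (d) every internal loop has fewer than \code{internalMax}
#' nucleotides (summed over both sides); (e) every bulge has fewer than
#' \code{bulgeMax} nucleotides. The conservation verdict (best 15-nt stem
#' window mean at or above the cutoff) is attached by
#' \code{\link{stemConservation}}.
#'
#' @slot a,b,c,d,e logical criterion verdicts
#' @slot nTerminalLoops number of terminal loops in the mature span's
#'   stem-loop unit
#' @slot maturePaired number of paired mature-span nucleotides
#' @slot terminalLoopSize size of the unit's terminal loop (NA if none)
#' @slot maxInternalLoop largest internal loop in the unit (0 if none)
#' @slot maxBulge largest bulge in the unit (0 if none)
#' @slot stemPositions window positions participating in the unit's stem
#' @slot conserved conservation verdict (NA until tested)
#' @slot bestWindowMean best 15-nt stem-window conservation mean
#' @slot conservationFlag "ok", "stem-too-short" or "not-tested"
#'
#' @exportClass CriteriaReport
setClass("CriteriaReport",
         representation(a = "logical", b = "logical", c = "logical",
                        d = "logical", e = "logical",
                        nTerminalLoops = "integer",
                        maturePaired = "integer",
                        terminalLoopSize = "integer",
                        maxInternalLoop = "integer",
                        maxBulge = "integer",
                        stemPositions = "integer",
                        conserved = "logical",
                        bestWindowMean = "numeric",
                        conservationFlag = "character"),
         prototype(conserved = NA, bestWindowMean = NA_real_,
                   conservationFlag = "not-tested"))

#' @describeIn FoldResult structure score (total pair weight)
#' @param x a \code{FoldResult}
#' @export
foldScore <- function(x) x@score

#' @describeIn FoldResult partner vector of the structure
#' @export
basePairs <- function(x) x@pairs

#' @describeIn FoldResult Vienna-style dot-bracket string
#' @export
dotBracket <- function(x) x@dotBracket

setMethod("show", "FoldResult", function(object) {
    cat("FoldResult (", nchar(object@sequence), " nt, score ",
        object@score, ")\n", sep = "")
    cat(object@sequence, "\n", object@dotBracket, "\n", sep = "")
})

setMethod("show", "CriteriaReport", function(object) {
    verdict <- criteriaPass(object)
    cat("CriteriaReport: ",
        paste0(c("a", "b", "c", "d", "e"),
               ifelse(c(object@a, object@b, object@c, object@d, object@e),
                      "+", "-"), collapse = " "),
        if (!is.na(object@conserved))
            paste0(" | conserved", if (object@conserved) "+" else "-"),
        " | ", if (verdict) "PASS" else "fail", "\n", sep = "")
    cat("  terminal loops: ", object@nTerminalLoops,
        ", mature paired: ", object@maturePaired,
        ", loop size: ", object@terminalLoopSize,
        ", max internal loop: ", object@maxInternalLoop,
        ", max bulge: ", object@maxBulge, "\n", sep = "")
})

#' Overall structural pass of a criteria report
#'
#' @param report a \code{CriteriaReport}
#' @param requireConserved if TRUE the conservation verdict must also hold
#' @return logical
#' @export
criteriaPass <- function(report, requireConserved = FALSE) {
    ok <- report@a && report@b && report@c && report@d && report@e
    if (requireConserved)
        ok <- ok && isTRUE(report@conserved)
    ok
}
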