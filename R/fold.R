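## Maximum-weighted nested-pairing folder (Nussinov-style dynamic program).
## Pair weights reflect base-pair stability ranks (GC > AU > GU wobble); the
## score is a pseudo-energy surrogate: the criteria downstream operate on
## pairing topology, not on free energies.

.baseCode <- c(A = 1L, C = 2L, G = 3L, T = 4L, U = 4L)

.encodeSeq <- function(seq) {
    chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
    code <- .baseCode[chars]
    if (anyNA(code))
        stop("invalid base '", chars[which(is.na(code))[1L]],
             "' at position ", which(is.na(code))[1L])
    unname(code)
}

.pairWeightMatrix <- function(weights = c(GC = 3, AU = 2, GU = 1)) {
    w <- matrix(0, 4L, 4L)
    w[3L, 2L] <- w[2L, 3L] <- weights[["GC"]]
    w[1L, 4L] <- w[4L, 1L] <- weights[["AU"]]
    w[3L, 4L] <- w[4L, 3L] <- weights[["GU"]]
    w
}

#' Fold a sequence by maximum-weighted nested pairing
#'
#' Computes the maximum-score nested secondary structure of a DNA/RNA
#' sequence under pair weights GC=3, AU=2, GU=1 (T read as U) with a minimum
#' hairpin loop of \code{minLoop} unpaired nucleotides, by the classic
#' O(n^3) nested-pairing dynamic program. The traceback is deterministic:
#' among optimal structures it pairs the smallest available 5' position
#' first, with its largest admissible partner.
#'
#' @param seq character, sequence over A/C/G/T (T for U); length 1 to 200
#' @param minLoop minimum number of unpaired nucleotides in a hairpin loop
#' @param weights named numeric vector with elements GC, AU, GU
#' @return a \code{\linkS4class{FoldResult}}
#' @examples
#' foldRNA("GGGAAACCC")   # three GC pairs, score 9
#' @export
foldRNA <- function(seq, minLoop = 3L, weights = c(GC = 3, AU = 2, GU = 1)) {
    stopifnot(is.character(seq), length(seq) == 1L)
    n <- nchar(seq)
    if (n < 1L || n > 200L)
        stop("sequence length must be in [1, 200]")
    code <- .encodeSeq(seq)
    w4 <- .pairWeightMatrix(weights)
    WW <- w4[code, code, drop = FALSE]   # n x n pair weights

    ## Dm[i, j + 1] = best score of region [i, j]; Dm[i, i] = empty region 0.
    Dm <- matrix(0, n + 1L, n + 1L)
    if (n >= minLoop + 2L) {
        for (L in (minLoop + 1L):(n - 1L)) {
            for (i in seq_len(n - L)) {
                j <- i + L
                ks <- i:(j - minLoop - 1L)
                ## pair (k, j): best of [i, k-1] + w(k,j) + best of [k+1, j-1];
                ## w = 0 entries are dominated by the unpaired-j option.
                cand <- Dm[i, ks] + WW[ks, j] + Dm[ks + 1L, j]
                Dm[i, j + 1L] <- max(Dm[i, j], cand)
            }
        }
    }

    pairs <- rep(NA_integer_, n)
    if (n >= minLoop + 2L && Dm[1L, n + 1L] > 0) {
        stack <- list(c(1L, n))
        while (length(stack)) {
            ij <- stack[[length(stack)]]
            stack[[length(stack)]] <- NULL
            i <- ij[1L]; j <- ij[2L]
            while (j - i > minLoop) {
                target <- Dm[i, j + 1L]
                if (target <= 0) break
                ms <- (i + minLoop + 1L):j
                vals <- WW[i, ms] + Dm[i + 1L, ms] + Dm[ms + 1L, j + 1L]
                ok <- ms[WW[i, ms] > 0 & abs(vals - target) < 1e-9]
                if (length(ok)) {
                    m <- max(ok)         # largest partner for smallest i
                    pairs[i] <- m
                    pairs[m] <- i
                    if (m < j)
                        stack[[length(stack) + 1L]] <- c(m + 1L, j)
                    j <- m - 1L
                    i <- i + 1L
                } else {
                    i <- i + 1L          # i optimally unpaired
                }
            }
        }
    }

    new("FoldResult",
        sequence = toupper(seq),
        pairs = pairs,
        score = Dm[1L, n + 1L],
        dotBracket = renderDotBracket(pairs))
}

#' Render a partner vector as a dot-bracket string
#'
#' @param pairs integer partner vector (NA = unpaired)
#' @return character dot-bracket string
#' @export
renderDotBracket <- function(pairs) {
    out <- rep(".", length(pairs))
    idx <- which(!is.na(pairs))
    out[idx[pairs[idx] > idx]] <- "("
    out[idx[pairs[idx] < idx]] <- ")"
    paste(out, collapse = "")
}

#' Parse a dot-bracket string into a partner vector
#'
#' @param db character dot-bracket string over ".", "(", ")"
#' @return integer partner vector
#' @export
parseDotBracket <- function(db) {
    chars <- strsplit(db, "", fixed = TRUE)[[1L]]
    pairs <- rep(NA_integer_, length(chars))
    stack <- integer(0)
    for (i in seq_along(chars)) {
        if (chars[i] == "(") {
            stack <- c(stack, i)
        } else if (chars[i] == ")") {
            if (!length(stack)) stop("unbalanced dot-bracket at position ", i)
            j <- stack[length(stack)]
            stack <- stack[-length(stack)]
            pairs[i] <- j
            pairs[j] <- i
        } else if (chars[i] != ".") {
            stop("invalid dot-bracket character '", chars[i], "'")
        }
    }
    if (length(stack)) stop("unbalanced dot-bracket: unclosed '('")
    pairs
}

#' Build a FoldResult from an explicit pairing
#'
#' Convenience constructor for hand-specified structures (e.g. boundary-case
#' fixtures); validates nesting and the minimum loop constraint.
#'
#' @param seq sequence
#' @param pairs integer partner vector or dot-bracket string
#' @param weights pair weights used to score the structure
#' @return a \code{\linkS4class{FoldResult}}
#' @export
foldFromPairs <- function(seq, pairs, weights = c(GC = 3, AU = 2, GU = 1)) {
    if (is.character(pairs))
        pairs <- parseDotBracket(pairs)
    pairs <- as.integer(pairs)
    code <- .encodeSeq(seq)
    w4 <- .pairWeightMatrix(weights)
    opening <- which(!is.na(pairs) & pairs > seq_along(pairs))
    sc <- sum(w4[cbind(code[opening], code[pairs[opening]])])
    new("FoldResult", sequence = toupper(seq), pairs = pairs,
        score = sc, dotBracket = renderDotBracket(pairs))
}
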