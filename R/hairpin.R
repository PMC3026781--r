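## Hairpin assessment: structure decomposition, novel-miRNA criteria (a)-(e),
## 110-nt window scanning over +/-88 nt genomic context, and the 15-nt
## stem-conservation window test.

## Pair tree of a nested structure: opening positions, closing partners,
## parent/children links (indices into the opening vector).
.pairTree <- function(pairs) {
    n <- length(pairs)
    open <- which(!is.na(pairs) & pairs > seq_len(n))
    close <- pairs[open]
    np <- length(open)
    parent <- rep(NA_integer_, np)
    children <- vector("list", np)
    id <- match(seq_len(n), open)
    stack <- integer(0)
    for (pos in seq_len(n)) {
        if (is.na(pairs[pos])) next
        if (pairs[pos] > pos) {
            k <- id[pos]
            if (length(stack)) {
                top <- stack[length(stack)]
                parent[k] <- top
                children[[top]] <- c(children[[top]], k)
            }
            stack <- c(stack, k)
        } else {
            stack <- stack[-length(stack)]
        }
    }
    list(open = open, close = close, parent = parent, children = children)
}

.descendants <- function(tree, k) {
    out <- integer(0)
    todo <- k
    while (length(todo)) {
        cur <- todo[1L]
        todo <- todo[-1L]
        out <- c(out, cur)
        todo <- c(todo, tree$children[[cur]])
    }
    out
}

#' Decompose a structure into stems, loops, bulges and internal loops
#'
#' Walks the pair tree of a \code{FoldResult} and classifies every helix
#' interruption in standard nomenclature: a hairpin (terminal) loop closes a
#' pair with no nested pairs; between a pair and its single nested child,
#' zero unpaired nucleotides is a stack, unpaired nucleotides on exactly one
#' side form a bulge, and on both sides an internal loop (size = total
#' unpaired nucleotides over both sides); two or more children form a
#' multiloop.
#'
#' @param fold a \code{\linkS4class{FoldResult}} (or partner vector)
#' @return a data.frame with one row per structural element: \code{type}
#'   ("hairpin-loop", "stack", "bulge", "internal-loop", "multiloop"),
#'   \code{open}, \code{close} (positions of the outer pair) and \code{size}
#'   (unpaired nucleotides in the element)
#' @export
structureElements <- function(fold) {
    pairs <- if (is(fold, "FoldResult")) fold@pairs else as.integer(fold)
    tree <- .pairTree(pairs)
    np <- length(tree$open)
    if (np == 0L)
        return(data.frame(type = character(0), open = integer(0),
                          close = integer(0), size = integer(0)))
    type <- character(np)
    size <- integer(np)
    for (k in seq_len(np)) {
        ch <- tree$children[[k]]
        if (length(ch) == 0L) {
            type[k] <- "hairpin-loop"
            size[k] <- tree$close[k] - tree$open[k] - 1L
        } else if (length(ch) == 1L) {
            left <- tree$open[ch] - tree$open[k] - 1L
            right <- tree$close[k] - tree$close[ch] - 1L
            if (left == 0L && right == 0L) {
                type[k] <- "stack"; size[k] <- 0L
            } else if (left == 0L || right == 0L) {
                type[k] <- "bulge"; size[k] <- left + right
            } else {
                type[k] <- "internal-loop"; size[k] <- left + right
            }
        } else {
            type[k] <- "multiloop"
            inner <- sum(tree$close[ch] - tree$open[ch] + 1L)
            size[k] <- tree$close[k] - tree$open[k] - 1L - inner
        }
    }
    data.frame(type = type, open = tree$open, close = tree$close, size = size)
}

## Stem-loop unit containing the mature span: subtree of the innermost pair
## enclosing the mature midpoint, extended outward through single-child
## ancestors (the rest of the mature's stem). With a max-pairing folder the
## flanking context pairs liberally, so the literal connected component would
## pick up spurious flank hairpins; anchoring at the mature midpoint keeps the
## criteria focused on the stem that actually carries the cloned sequence.
.matureUnit <- function(pairs, matureStart, matureEnd) {
    tree <- .pairTree(pairs)
    mid <- (matureStart + matureEnd) %/% 2L
    enclosing <- which(tree$open <= mid & tree$close >= mid)
    if (!length(enclosing))
        return(list(tree = tree, anchor = NA_integer_, unit = integer(0),
                    subtree = integer(0)))
    anchor <- enclosing[which.max(tree$open[enclosing])]
    subtree <- .descendants(tree, anchor)
    chain <- integer(0)
    cur <- anchor
    while (!is.na(tree$parent[cur]) &&
           length(tree$children[[tree$parent[cur]]]) == 1L) {
        cur <- tree$parent[cur]
        chain <- c(chain, cur)
    }
    list(tree = tree, anchor = anchor, unit = c(chain, subtree),
         subtree = subtree)
}

#' Evaluate the structural novel-miRNA criteria on a folded window
#'
#' Applies the five structural criteria to the stem-loop unit containing the
#' mature span: (a) the unit has exactly one terminal loop; (b) more than
#' \code{minMaturePaired} mature nucleotides are base-paired (anywhere in the
#' fold); (c) the terminal loop contains fewer than \code{loopMax}
#' nucleotides; (d) every internal loop contains fewer than
#' \code{internalMax} nucleotides (summed over both sides); (e) every bulge
#' contains fewer than \code{bulgeMax} nucleotides.
#'
#' @param fold a \code{\linkS4class{FoldResult}}
#' @param matureStart,matureEnd 1-based mature span within the window
#' @param minMaturePaired criterion (b) bound: paired mature nt must exceed it
#' @param loopMax criterion (c) bound: terminal loop must be smaller
#' @param internalMax criterion (d) bound: internal loops must be smaller
#' @param bulgeMax criterion (e) bound: bulges must be smaller
#' @return a \code{\linkS4class{CriteriaReport}} (conservation untested)
#' @export
evaluateCriteria <- function(fold, matureStart, matureEnd,
                             minMaturePaired = 16L, loopMax = 20L,
                             internalMax = 10L, bulgeMax = 5L) {
    pairs <- fold@pairs
    n <- length(pairs)
    stopifnot(matureStart >= 1L, matureEnd <= n, matureStart <= matureEnd)
    u <- .matureUnit(pairs, matureStart, matureEnd)
    tree <- u$tree

    maturePaired <- sum(!is.na(pairs[matureStart:matureEnd]))
    b <- maturePaired > minMaturePaired

    if (is.na(u$anchor)) {
        return(new("CriteriaReport", a = FALSE, b = b, c = FALSE,
                   d = TRUE, e = TRUE, nTerminalLoops = 0L,
                   maturePaired = as.integer(maturePaired),
                   terminalLoopSize = NA_integer_,
                   maxInternalLoop = 0L, maxBulge = 0L,
                   stemPositions = integer(0)))
    }

    hairpinIdx <- u$subtree[vapply(u$subtree, function(k)
        length(tree$children[[k]]) == 0L, logical(1))]
    nLoops <- length(hairpinIdx)
    a <- nLoops == 1L
    loopSizes <- tree$close[hairpinIdx] - tree$open[hairpinIdx] - 1L
    tls <- if (nLoops) max(loopSizes) else NA_integer_
    c_ <- nLoops > 0L && all(loopSizes < loopMax)

    maxInternal <- 0L
    maxBulge <- 0L
    for (k in u$unit) {
        ch <- tree$children[[k]]
        if (length(ch) != 1L) next
        left <- tree$open[ch] - tree$open[k] - 1L
        right <- tree$close[k] - tree$close[ch] - 1L
        if (left > 0L && right > 0L)
            maxInternal <- max(maxInternal, left + right)
        else if (left + right > 0L)
            maxBulge <- max(maxBulge, left + right)
    }
    d <- maxInternal < internalMax
    e <- maxBulge < bulgeMax

    stem <- sort(c(tree$open[u$unit], tree$close[u$unit]))

    new("CriteriaReport", a = a, b = b, c = c_, d = d, e = e,
        nTerminalLoops = as.integer(nLoops),
        maturePaired = as.integer(maturePaired),
        terminalLoopSize = as.integer(tls),
        maxInternalLoop = as.integer(maxInternal),
        maxBulge = as.integer(maxBulge),
        stemPositions = as.integer(stem))
}

#' Best conservation mean over 15-nt stem windows
#'
#' Enumerates every contiguous window of \code{window} positions lying
#' entirely within consecutive stem (paired) positions and returns the
#' maximum mean conservation score, or \code{NA} if no stem run is long
#' enough.
#'
#' @param positions sorted window positions that are part of the stem
#' @param track numeric conservation scores indexed by window position
#' @param window window length in nucleotides
#' @return best window mean (NA if no admissible window)
#' @export
bestStemWindowMean <- function(positions, track, window = 15L) {
    if (!length(positions)) return(NA_real_)
    runs <- split(positions, cumsum(c(1L, diff(positions) != 1L)))
    best <- NA_real_
    for (run in runs) {
        if (length(run) < window) next
        vals <- track[run]
        cs <- cumsum(c(0, vals))
        means <- (cs[(window + 1L):length(cs)] -
                  cs[1L:(length(cs) - window)]) / window
        best <- max(best, means, na.rm = TRUE)
    }
    best
}

#' Test stem conservation of a candidate hairpin
#'
#' A hairpin is conserved when the mean conservation score over any
#' contiguous \code{window}-nt stretch of its stem is at least
#' \code{cutoff}. Stem positions are taken from the criteria report; runs
#' shorter than \code{window} (e.g. interrupted by bulges) admit no window
#' and are flagged \code{"stem-too-short"}.
#'
#' @param report a \code{\linkS4class{CriteriaReport}} from
#'   \code{\link{evaluateCriteria}}
#' @param track numeric conservation scores indexed by window position
#' @param window conservation window length (nt)
#' @param cutoff minimum admissible window mean
#' @return the report with \code{conserved}, \code{bestWindowMean} and
#'   \code{conservationFlag} filled in
#' @export
stemConservation <- function(report, track, window = 15L, cutoff = 0.8) {
    positions <- report@stemPositions
    runs <- if (length(positions))
        split(positions, cumsum(c(1L, diff(positions) != 1L)))
    else list()
    hasRun <- any(vapply(runs, length, integer(1)) >= window)
    best <- bestStemWindowMean(positions, track, window)
    report@bestWindowMean <- best
    if (!hasRun) {
        report@conserved <- FALSE
        report@conservationFlag <- "stem-too-short"
    } else {
        report@conserved <- !is.na(best) && best >= cutoff
        report@conservationFlag <- "ok"
    }
    report
}

#' Scan candidate windows over a locus and keep the best fold
#'
#' Extends the mature locus by \code{context} nucleotides of genomic
#' sequence on each side (truncated at genome edges), slides windows of
#' \code{windowSize} nucleotides in steps of \code{step} across the extended
#' region, keeps only windows fully containing the mature span, folds each
#' with \code{\link{foldRNA}}, and returns the window with the maximal score
#' (ties: leftmost window start). Minus-strand loci are folded on the
#' reverse complement with coordinates and conservation track reversed
#' accordingly.
#'
#' @param genome a \code{DNAString}, \code{DNAStringSet} of length 1, or
#'   character genome sequence
#' @param start,end 1-based inclusive mature locus on the plus strand
#' @param strand "+" or "-"
#' @param track optional numeric per-base conservation track (genome length)
#' @param context nucleotides of flanking sequence added on each side
#' @param windowSize window length in nucleotides
#' @param step window step in nucleotides
#' @param ... passed to \code{\link{foldRNA}}
#' @return a list with elements \code{fold} (best \code{FoldResult}),
#'   \code{windowStart} (genomic, plus strand), \code{matureSpan} (1-based
#'   span of the mature inside the folded window, in fold orientation),
#'   \code{trackWindow} (conservation values in fold orientation, or NULL),
#'   \code{nWindows} and \code{truncated}
#' @export
windowScan <- function(genome, start, end, strand = "+", track = NULL,
                       context = 88L, windowSize = 110L, step = 5L, ...) {
    gseq <- .asGenomeString(genome)
    glen <- Biostrings::nchar(gseq)
    start <- as.integer(start)
    end <- as.integer(end)
    context <- as.integer(context)
    windowSize <- as.integer(windowSize)
    step <- as.integer(step)
    stopifnot(start >= 1L, end <= glen, start <= end)
    matureLen <- end - start + 1L
    if (matureLen > windowSize)
        stop("locus (", matureLen, " nt) longer than the ", windowSize,
             "-nt window")
    regionStart <- max(1L, start - context)
    regionEnd <- min(glen, end + context)
    truncated <- (regionStart > start - context) || (regionEnd < end + context)

    if (regionEnd - regionStart + 1L <= windowSize) {
        starts <- regionStart
        windowEnds <- regionEnd
    } else {
        lo <- max(regionStart, end - windowSize + 1L)
        hi <- min(start, regionEnd - windowSize + 1L)
        starts <- seq.int(lo, hi, by = step)
        windowEnds <- starts + windowSize - 1L
    }

    best <- NULL
    bestStart <- NA_integer_
    bestEnd <- NA_integer_
    for (k in seq_along(starts)) {
        ws <- starts[k]; we <- windowEnds[k]
        wseq <- as.character(Biostrings::subseq(gseq, ws, we))
        if (strand == "-")
            wseq <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(wseq)))
        f <- foldRNA(wseq, ...)
        if (is.null(best) || f@score > best@score) {
            best <- f
            bestStart <- ws
            bestEnd <- we
        }
    }
    best@windowStart <- bestStart

    if (strand == "+") {
        matureSpan <- c(start - bestStart + 1L, end - bestStart + 1L)
        trackWindow <- if (!is.null(track)) track[bestStart:bestEnd] else NULL
    } else {
        matureSpan <- c(bestEnd - end + 1L, bestEnd - start + 1L)
        trackWindow <- if (!is.null(track)) rev(track[bestStart:bestEnd]) else NULL
    }

    list(fold = best, windowStart = bestStart,
         matureSpan = matureSpan, trackWindow = trackWindow,
         nWindows = length(starts), truncated = truncated)
}

.asGenomeString <- function(genome) {
    if (is(genome, "DNAString")) return(genome)
    if (is(genome, "DNAStringSet")) {
        stopifnot(length(genome) == 1L)
        return(genome[[1L]])
    }
    Biostrings::DNAString(genome)
}

#' Assess a candidate locus: window scan, criteria and conservation
#'
#' Folds every admissible window over the locus (same enumeration as
#' \code{\link{windowScan}}), evaluates the structural criteria -- and,
#' when a track is supplied, stem conservation -- on each window's
#' configuration, and accepts the locus when some window passes. With a
#' pair-count folding score, genuinely hairpin-bearing windows are not
#' always the top-scoring ones (pairing in random flanks scores freely),
#' so the assessment asks whether any window folds into a qualifying
#' stem-loop; the best-scoring passing window is reported (ties:
#' leftmost), or the best-scoring window overall when none passes.
#'
#' @inheritParams windowScan
#' @param windowSizes window sizes scanned, largest first; the smaller,
#'   precursor-scale subwindows matter because a pair-count score has no
#'   loop or stacking penalty, so over a full 110-nt window diffuse
#'   pairing of random flanks can mask a genuine compact hairpin
#' @param minMaturePaired,loopMax,internalMax,bulgeMax criterion bounds
#' @param consWindow,consCutoff conservation window length and cutoff
#' @param requireConserved demand the conservation verdict for a pass
#'   (novel candidates); ignored when no track is supplied
#' @return list with \code{fold} (reported window's \code{FoldResult}),
#'   \code{windowStart}, \code{matureSpan}, \code{nWindows},
#'   \code{truncated}, \code{pass} and \code{report} (a
#'   \code{\linkS4class{CriteriaReport}})
#' @export
assessHairpin <- function(genome, start, end, strand = "+", track = NULL,
                          context = 88L, windowSizes = c(110L, 85L, 65L),
                          step = 5L,
                          minMaturePaired = 16L, loopMax = 20L,
                          internalMax = 10L, bulgeMax = 5L,
                          consWindow = 15L, consCutoff = 0.8,
                          requireConserved = FALSE) {
    gseq <- .asGenomeString(genome)
    glen <- Biostrings::nchar(gseq)
    start <- as.integer(start)
    end <- as.integer(end)
    geoms <- lapply(as.integer(windowSizes), function(wsz)
        .scanGeometry(glen, start, end, as.integer(context), wsz,
                      as.integer(step)))
    geom <- list(starts = unlist(lapply(geoms, `[[`, "starts")),
                 ends = unlist(lapply(geoms, `[[`, "ends")),
                 truncated = geoms[[1L]]$truncated)
    needCons <- requireConserved && !is.null(track)

    best <- NULL        # best-scoring window overall
    bestPass <- NULL    # best-scoring passing window
    for (k in seq_along(geom$starts)) {
        w <- .foldWindow(gseq, geom$starts[k], geom$ends[k], start, end,
                         strand, track)
        report <- evaluateCriteria(w$fold, w$matureSpan[1L],
                                   w$matureSpan[2L],
                                   minMaturePaired = minMaturePaired,
                                   loopMax = loopMax,
                                   internalMax = internalMax,
                                   bulgeMax = bulgeMax)
        if (!is.null(w$trackWindow))
            report <- stemConservation(report, w$trackWindow,
                                       window = consWindow,
                                       cutoff = consCutoff)
        w$report <- report
        w$pass <- criteriaPass(report, requireConserved = needCons)
        if (is.null(best) || w$fold@score > best$fold@score) best <- w
        if (w$pass && (is.null(bestPass) ||
                       w$fold@score > bestPass$fold@score)) bestPass <- w
    }
    chosen <- if (!is.null(bestPass)) bestPass else best
    list(fold = chosen$fold, windowStart = chosen$windowStart,
         matureSpan = chosen$matureSpan, nWindows = length(geom$starts),
         truncated = geom$truncated, pass = chosen$pass,
         report = chosen$report)
}

## admissible window starts over the extended region
.scanGeometry <- function(glen, start, end, context, windowSize, step) {
    matureLen <- end - start + 1L
    if (matureLen > windowSize)
        stop("locus (", matureLen, " nt) longer than the ", windowSize,
             "-nt window")
    regionStart <- max(1L, start - context)
    regionEnd <- min(glen, end + context)
    truncated <- (regionStart > start - context) ||
        (regionEnd < end + context)
    if (regionEnd - regionStart + 1L <= windowSize) {
        starts <- regionStart
        ends <- regionEnd
    } else {
        lo <- max(regionStart, end - windowSize + 1L)
        hi <- min(start, regionEnd - windowSize + 1L)
        starts <- seq.int(lo, hi, by = step)
        ends <- starts + windowSize - 1L
    }
    list(starts = starts, ends = ends, truncated = truncated)
}

## fold one window, mapping mature span and track into fold orientation
.foldWindow <- function(gseq, ws, we, start, end, strand, track, ...) {
    wseq <- as.character(Biostrings::subseq(gseq, ws, we))
    if (strand == "-")
        wseq <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(wseq)))
    f <- foldRNA(wseq, ...)
    f@windowStart <- as.integer(ws)
    if (strand == "+") {
        matureSpan <- c(start - ws + 1L, end - ws + 1L)
        trackWindow <- if (!is.null(track)) track[ws:we] else NULL
    } else {
        matureSpan <- c(we - end + 1L, we - start + 1L)
        trackWindow <- if (!is.null(track)) rev(track[ws:we]) else NULL
    }
    list(fold = f, windowStart = ws, matureSpan = matureSpan,
         trackWindow = trackWindow)
}
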