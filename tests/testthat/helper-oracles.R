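## Independent oracles and fixture builders shared across the suite.

## Exhaustive folding oracle: recursive enumeration of nested pair sets
## (no memoisation, top-down), feasible for sequences up to ~12 nt.
enumFoldScore <- function(seq, minLoop = 3L) {
    chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
    pw <- function(a, b) {
        key <- paste0(sort(c(a, b)), collapse = "")
        switch(key, "CG" = 3, "AT" = 2, "GT" = 1, 0)
    }
    n <- length(chars)
    best <- function(i, j) {
        if (j - i < minLoop + 1L) return(0)
        b <- best(i + 1L, j)
        for (m in (i + minLoop + 1L):j) {
            w <- pw(chars[i], chars[m])
            if (w > 0)
                b <- max(b, w + best(i + 1L, m - 1L) + best(m + 1L, j))
        }
        b
    }
    if (n < minLoop + 2L) 0 else best(1L, n)
}

randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcompChr <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## Hand-built stem-loop pairing fixtures. Builds a FoldResult whose
## structure is specified explicitly: outer stem of `outer` pairs, an
## optional defect (gapLeft/gapRight unpaired nt), an inner stem of
## `inner` pairs, and a terminal loop of `loop` nt. The mature span is the
## 5' side: positions 1 .. (outer + gapLeft + inner).
stemFixture <- function(outer = 11L, inner = 11L, loop = 4L,
                        gapLeft = 0L, gapRight = 0L) {
    n <- 2L * (outer + inner) + gapLeft + gapRight + loop
    pairs <- rep(NA_integer_, n)
    seq <- rep("A", n)
    for (i in seq_len(outer)) {
        j <- n + 1L - i
        pairs[i] <- j; pairs[j] <- i
        seq[i] <- "G"; seq[j] <- "C"
    }
    for (t in seq_len(inner)) {
        i <- outer + gapLeft + t
        j <- n - outer - gapRight - t + 1L
        pairs[i] <- j; pairs[j] <- i
        seq[i] <- "G"; seq[j] <- "C"
    }
    foldFromPairs(paste(seq, collapse = ""), pairs)
}

## Fixture with a branched interior: a stem of `stem` pairs whose closing
## pair contains two hairpins (multiloop) -- i.e. no stem-loop
## configuration for a mature lying on the stem.
branchedFixture <- function(stem = 22L) {
    hp <- function(offset, arm = 2L, loop = 5L) {
        idx <- list()
        for (t in seq_len(arm))
            idx[[t]] <- c(offset + t, offset + 2L * arm + loop - t + 1L)
        idx
    }
    innerLen <- 2L * (2L * 2L + 5L) + 2L
    n <- 2L * stem + innerLen
    pairs <- rep(NA_integer_, n)
    seq <- rep("A", n)
    for (i in seq_len(stem)) {
        j <- n + 1L - i
        pairs[i] <- j; pairs[j] <- i
        seq[i] <- "G"; seq[j] <- "C"
    }
    for (p in c(hp(stem), hp(stem + 9L + 1L))) {
        pairs[p[1L]] <- p[2L]; pairs[p[2L]] <- p[1L]
        seq[p[1L]] <- "G"; seq[p[2L]] <- "C"
    }
    foldFromPairs(paste(seq, collapse = ""), pairs)
}

## Brute-force conservation oracle: any 15-nt genomic window fully inside
## stem positions with mean >= cutoff?
bruteConserved <- function(positions, track, window = 15L, cutoff = 0.8) {
    pos <- sort(positions)
    n <- length(track)
    for (s in seq_len(max(n - window + 1L, 0L))) {
        win <- s:(s + window - 1L)
        if (all(win %in% pos) && mean(track[win]) >= cutoff)
            return(TRUE)
    }
    FALSE
}

## Mann-Whitney statistic scaled to [0,1]: AUC oracle.
mannWhitneyAUC <- function(values, labels) {
    xp <- values[labels]
    xn <- values[!labels]
    u <- 0
    for (a in xp) u <- u + sum(a > xn) + 0.5 * sum(a == xn)
    u / (length(xp) * length(xn))
}

## Exhaustive two-sided Fisher oracle: sum of hypergeometric probabilities
## not exceeding that of the observed table (fixed margins).
bruteFisherP <- function(a, b, c_, d) {
    m <- a + c_          # in-term total
    n <- b + d
    k <- a + b           # target size
    ks <- max(0L, k - n):min(k, m)
    probs <- stats::dhyper(ks, m, n, k)
    pObs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

## Adjusted Rand index between two label vectors.
adjustedRand <- function(a, b) {
    tab <- table(a, b)
    sumij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2))
    bj <- sum(choose(colSums(tab), 2))
    nC2 <- choose(sum(tab), 2)
    expected <- ai * bj / nC2
    (sumij - expected) / ((ai + bj) / 2 - expected)
}

## Small synthetic study shared by discovery/annotation tests (cached per
## session to keep the suite fast).
smallStudy <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            cfg <- simConfig(seed = 11L, n_pairs = 2L, library_size = 800L)
            truth <- generateReference(cfg)
            reads <- simulateReads(truth)
            annot <- classifyReads(reads$reads, truth$dbs,
                                   genome = truth$genome)
            cache <<- list(cfg = cfg, truth = truth, reads = reads,
                           annot = annot)
        }
        cache
    }
})
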