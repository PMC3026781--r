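## Expression analytics: prevalence filtering, hierarchical clustering of
## samples with a high-risk flag, the SAM permutation d statistic with a
## zero-false-positive delta, paired t tests and Fisher 2x2 enrichment.

#' Drop miRNAs expressed in fewer than a fraction of samples
#'
#' A row is retained when it is nonzero in at least \code{threshold} of
#' the samples (a row at exactly the threshold is kept: the filter drops
#' "fewer than" 25\% by default).
#'
#' @param mat numeric matrix (miRNA x sample)
#' @param threshold minimum fraction of samples with nonzero expression
#' @return the filtered matrix
#' @export
prevalenceFilter <- function(mat, threshold = 0.25) {
    frac <- rowMeans(mat > 0)
    mat[frac >= threshold, , drop = FALSE]
}

#' Hierarchical clustering of samples with a high-risk cluster flag
#'
#' Samples are clustered by average-linkage agglomeration on the distance
#' 1 - Pearson correlation of log2(normalized + 1) profiles (pairs with
#' undefined correlation get distance 1, with a warning). The tree is cut
#' into \code{k} flat clusters; any cluster whose members are all tumours
#' and whose mean normalized marker expression exceeds
#' \code{markerThreshold} is flagged high-risk.
#'
#' @param normalized normalized expression matrix (miRNA x sample)
#' @param k number of flat clusters
#' @param groups named vector of sample groups ("HCC" marks tumours);
#'   optional, required for the high-risk flag
#' @param marker row name of the marker miRNA (e.g. the miR-21 equivalent)
#' @param markerThreshold normalized marker expression a high-risk cluster
#'   must exceed on average
#' @param log2 transform to log2(x + 1) before correlating (clone counts
#'   are heavy-tailed); disable for a scale-free correlation distance
#' @return list of class \code{ClusteringResult}: \code{hclust}, flat
#'   \code{labels}, \code{composition} (per-cluster tumour/normal counts
#'   and marker means), \code{highRisk} (flag per cluster),
#'   \code{highRiskSamples}
#' @export
clusterSamples <- function(normalized, k = 3L, groups = NULL,
                           marker = NULL, markerThreshold = 250,
                           log2 = TRUE) {
    stopifnot(ncol(normalized) >= 2L)
    x <- if (log2) base::log2(normalized + 1) else normalized
    cc <- suppressWarnings(stats::cor(x))
    if (any(is.na(cc))) {
        warning("undefined correlations set to distance 1")
        cc[is.na(cc)] <- 0
    }
    d <- stats::as.dist(1 - cc)
    hc <- stats::hclust(d, method = "average")
    k <- min(k, ncol(normalized))
    labels <- stats::cutree(hc, k = k)

    comp <- data.frame(cluster = seq_len(k))
    comp$n <- as.integer(table(factor(labels, seq_len(k))))
    if (!is.null(groups)) {
        g <- groups[colnames(normalized)]
        comp$n_tumour <- vapply(seq_len(k), function(i)
            sum(g[labels == i] == "HCC"), integer(1))
    }
    if (!is.null(marker) && marker %in% rownames(normalized)) {
        comp$marker_mean <- vapply(seq_len(k), function(i)
            mean(normalized[marker, labels == i]), numeric(1))
    } else {
        comp$marker_mean <- NA_real_
    }
    highRisk <- rep(FALSE, k)
    if (!is.null(groups) && !is.null(marker) &&
        marker %in% rownames(normalized)) {
        highRisk <- comp$n_tumour == comp$n & comp$n > 0L &
            !is.na(comp$marker_mean) & comp$marker_mean > markerThreshold
    }
    out <- list(hclust = hc, labels = labels, composition = comp,
                highRisk = highRisk,
                highRiskSamples = colnames(normalized)[
                    labels %in% which(highRisk)])
    class(out) <- "ClusteringResult"
    out
}

.samStat <- function(x, idx1, idx2, s0) {
    n1 <- length(idx1); n2 <- length(idx2)
    m1 <- rowMeans(x[, idx1, drop = FALSE])
    m2 <- rowMeans(x[, idx2, drop = FALSE])
    v1 <- rowSums((x[, idx1, drop = FALSE] - m1)^2)
    v2 <- rowSums((x[, idx2, drop = FALSE] - m2)^2)
    pooled <- (v1 + v2) / (n1 + n2 - 2)
    si <- sqrt(pooled * (1 / n1 + 1 / n2))
    list(d = (m1 - m2) / (si + s0), s = si)
}

.samStatPaired <- function(diffs, signs, s0) {
    n <- ncol(diffs)
    d <- diffs %*% signs / n
    dm <- as.vector(d)
    v <- (rowSums(diffs^2) - n * dm^2) / (n - 1)
    si <- sqrt(pmax(v, 0) / n)
    list(d = dm / (si + s0), s = si)
}

## balanced permutations: each permuted "tumour" group draws half its
## members from each true group, so planted signal is maximally diluted
.balancedPerms <- function(n1, n2, nPerm) {
    h1 <- n1 %/% 2L
    lapply(seq_len(nPerm), function(b) {
        a <- sample(seq_len(n1), h1)
        b2 <- sample(seq_len(n2), n1 - h1)
        c(a, n1 + b2)
    })
}

#' SAM permutation test with a zero-false-positive delta
#'
#' Computes the SAM statistic d_i = (mean difference) / (s_i + s0) on
#' log2(normalized + 1), with s0 the 5th percentile of the per-gene
#' standard errors (or the coefficient-of-variation minimizing grid
#' value). The null distribution comes from balanced permutations of the
#' group labels (balanced sign flips of pair differences in the paired
#' design; all sign patterns when there are at most 2^12). The reported
#' delta is the smallest for which the estimated number of false positives
#' -- the mean (default) or median across permutations of permuted
#' statistics beyond the delta cut points -- is zero, and the significant
#' set is read off at that delta.
#'
#' @param normalized normalized expression matrix (miRNA x sample)
#' @param groups vector of "HCC"/"ANL" labels per column
#' @param paired use the paired (sign-flip) design
#' @param pairIds pair identifiers per column (required when paired)
#' @param nPerm number of permutations (all sign flips when feasible)
#' @param s0Method "percentile" (5th percentile of s_i) or "grid"
#' @param fpMethod "mean" or "median" across permutations
#' @param seed RNG seed for the permutation draw
#' @return list of class \code{SamResult}: \code{d}, \code{s}, \code{s0},
#'   \code{dbar} (expected order statistics), \code{delta},
#'   \code{significant} (row names), \code{up}, \code{down},
#'   \code{deltaTable} (delta / called / estimated FP), \code{nPerm}
#' @export
samTest <- function(normalized, groups, paired = FALSE, pairIds = NULL,
                    nPerm = 1000L, s0Method = c("percentile", "grid"),
                    fpMethod = c("mean", "median"), seed = 1L) {
    s0Method <- match.arg(s0Method)
    fpMethod <- match.arg(fpMethod)
    x <- log2(normalized + 1)
    gTum <- which(groups == "HCC")
    gNor <- which(groups == "ANL")
    if (length(gTum) < 2L || length(gNor) < 2L)
        stop("each group needs at least 2 samples")

    withSeed(seed, {
        if (paired) {
            if (is.null(pairIds)) stop("paired design requires pairIds")
            ord <- match(pairIds[gTum], pairIds[gNor])
            if (anyNA(ord)) stop("unpaired samples: ",
                                 paste(pairIds[gTum][is.na(ord)],
                                       collapse = ", "))
            diffs <- x[, gTum, drop = FALSE] - x[, gNor[ord], drop = FALSE]
            n <- ncol(diffs)
            base <- .samStatPaired(diffs, rep(1, n), 0)
        } else {
            base <- .samStat(x, gTum, gNor, 0)
        }
        s0 <- if (s0Method == "percentile")
            stats::quantile(base$s, 0.05, names = FALSE)
        else .samS0Grid(base)

        if (paired) {
            n <- ncol(diffs)
            half <- n %/% 2L
            ## balanced sign flips (exactly half the pairs flipped) so the
            ## identity and near-identity patterns -- which retain the
            ## signal -- never enter the null; enumerate all of them when
            ## feasible
            if (choose(n, half) <= 4096L) {
                signs <- t(apply(utils::combn(n, half), 2L, function(ix) {
                    s <- rep(1, n); s[ix] <- -1; s
                }))
            } else {
                signs <- t(vapply(seq_len(nPerm), function(b) {
                    s <- rep(1, n)
                    s[sample(n, half)] <- -1
                    s
                }, numeric(n)))
            }
            d <- .samStatPaired(diffs, rep(1, n), s0)$d
            perm <- apply(signs, 1L, function(s)
                .samStatPaired(diffs, s, s0)$d)
        } else {
            d <- .samStat(x, gTum, gNor, s0)$d
            perms <- .balancedPerms(length(gTum), length(gNor), nPerm)
            cols <- c(gTum, gNor)
            perm <- vapply(perms, function(p) {
                .samStat(x[, cols, drop = FALSE], p,
                         setdiff(seq_along(cols), p), s0)$d
            }, numeric(length(d)))
        }

        ord <- order(d)
        dSort <- d[ord]
        permSort <- apply(perm, 2L, sort)
        dbar <- rowMeans(permSort)

        res <- .samDelta(dSort, dbar, perm, fpMethod)
        sig <- ord[res$sigIdx]
        names(d) <- rownames(normalized)
        list(d = d, s = base$s, s0 = s0, dbar = dbar,
             delta = res$delta,
             significant = rownames(normalized)[sig],
             up = rownames(normalized)[sig[d[sig] > 0]],
             down = rownames(normalized)[sig[d[sig] < 0]],
             deltaTable = res$table, nPerm = ncol(perm)) -> out
        class(out) <- "SamResult"
        out
    })
}

## grid s0: percentile of s minimizing the coefficient of variation of the
## mad of d across s-quantile bins (Tusher-style tuning)
.samS0Grid <- function(base) {
    qs <- stats::quantile(base$s, seq(0, 1, 0.05), names = FALSE)
    cvs <- vapply(qs, function(s0c) {
        dd <- (base$d * base$s) / (base$s + s0c)   # base$d computed at s0=0
        bins <- cut(base$s, stats::quantile(base$s, seq(0, 1, 0.1)),
                    include.lowest = TRUE)
        mads <- tapply(dd, bins, stats::mad)
        stats::sd(mads, na.rm = TRUE) / mean(mads, na.rm = TRUE)
    }, numeric(1))
    qs[which.min(cvs)]
}

## delta sweep: for each candidate delta find the first order statistics
## whose deviation from the permutation expectation exceeds delta; count
## permuted statistics beyond those cut points
.samDelta <- function(dSort, dbar, perm, fpMethod) {
    m <- length(dSort)
    dev <- dSort - dbar
    zero <- which(dbar >= 0)[1L]
    if (is.na(zero)) zero <- m
    deltas <- sort(unique(c(0, abs(dev))))
    permVec <- as.vector(perm)
    nPerm <- ncol(perm)
    evalDelta <- function(delta) {
        upIdx <- which(seq_len(m) >= zero & dev >= delta)
        loIdx <- which(seq_len(m) < zero & dev <= -delta)
        cutUp <- if (length(upIdx)) dSort[min(upIdx)] else Inf
        cutLo <- if (length(loIdx)) dSort[max(loIdx)] else -Inf
        nSig <- sum(dSort >= cutUp) + sum(dSort <= cutLo)
        exceed <- matrix(permVec >= cutUp | permVec <= cutLo,
                         nrow = m)
        fpPerPerm <- colSums(exceed)
        fp <- if (fpMethod == "mean") mean(fpPerPerm)
              else stats::median(fpPerPerm)
        list(nSig = nSig, fp = fp, cutUp = cutUp, cutLo = cutLo,
             sigIdx = c(which(dSort <= cutLo), which(dSort >= cutUp)))
    }
    tab <- data.frame(delta = deltas, called = NA_integer_, fp = NA_real_)
    chosen <- NULL
    for (i in seq_along(deltas)) {
        ev <- evalDelta(deltas[i])
        tab$called[i] <- ev$nSig
        tab$fp[i] <- ev$fp
        if (is.null(chosen) && ev$fp == 0) {
            chosen <- ev
            chosen$delta <- deltas[i]
        }
    }
    if (is.null(chosen))
        chosen <- list(delta = Inf, sigIdx = integer(0))
    list(delta = chosen$delta, sigIdx = chosen$sigIdx, table = tab)
}

#' Paired t tests per miRNA
#'
#' Two-tailed paired Student t on log2(normalized + 1) pair differences.
#' Rows with zero-variance differences are flagged: t = 0 and p = 1 when
#' the mean difference is also zero, otherwise p is undefined (NA).
#'
#' @param normalized normalized expression matrix
#' @param groups "HCC"/"ANL" labels per column
#' @param pairIds pair identifiers per column
#' @return data.frame: mirna, t, p, mean_diff, flagged
#' @export
pairedTTest <- function(normalized, groups, pairIds) {
    x <- log2(normalized + 1)
    gTum <- which(groups == "HCC")
    gNor <- which(groups == "ANL")
    ord <- match(pairIds[gTum], pairIds[gNor])
    if (anyNA(ord))
        stop("unpaired samples: ",
             paste(pairIds[gTum][is.na(ord)], collapse = ", "))
    diffs <- x[, gTum, drop = FALSE] - x[, gNor[ord], drop = FALSE]
    n <- ncol(diffs)
    md <- rowMeans(diffs)
    sd_ <- apply(diffs, 1L, stats::sd)
    t <- md / (sd_ / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1L)
    ## zero variance up to floating-point noise from the log transform
    flagged <- sd_ <= 1e-10 * pmax(abs(md), 1)
    t[flagged & md == 0] <- 0
    p[flagged & md == 0] <- 1
    p[flagged & md != 0] <- NA_real_
    t[flagged & md != 0] <- NA_real_
    ids <- rownames(normalized)
    if (is.null(ids)) ids <- sprintf("row%04d", seq_len(nrow(normalized)))
    data.frame(mirna = ids, t = t, p = p,
               mean_diff = md, flagged = flagged,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Fisher 2x2 enrichment of a gene set against annotation terms
#'
#' For each term, a two-sided Fisher exact test on the 2x2 table
#' (in target x in term) over the universe; the output is ranked by
#' ascending p.
#'
#' @param target character vector of selected genes (subset of universe)
#' @param universe character vector of all genes
#' @param terms named list of character vectors (term -> genes)
#' @return data.frame: term, n_target_term, n_target, n_term, n_universe,
#'   odds_ratio, p -- sorted by p
#' @export
fisherEnrichment <- function(target, universe, terms) {
    if (!length(target)) stop("empty target set")
    if (!all(target %in% universe))
        stop("target must be a subset of the universe")
    rows <- lapply(names(terms), function(tm) {
        tg <- intersect(terms[[tm]], universe)
        a <- length(intersect(target, tg))
        b <- length(setdiff(target, tg))
        c_ <- length(setdiff(tg, target))
        d <- length(universe) - a - b - c_
        ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2L))
        data.frame(term = tm, n_target_term = a,
                   n_target = length(target), n_term = length(tg),
                   n_universe = length(universe),
                   odds_ratio = unname(ft$estimate), p = ft$p.value,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$p, out$term), , drop = FALSE]
    rownames(out) <- NULL
    out
}
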