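## RNA modification profiling: per-position substitutions of clone reads
## against their mature reference, clone-count modified fractions per
## tissue group, and modified/nonmodified expression splitting.

.EDIT_OFFSETS <- c(0L, -1L, 1L, -2L, 2L)   # deterministic tie order

.editClass <- function(from, to) {
    ## inosine reads as G, so A>G is reported as A-to-I; U is displayed for T
    ifelse(from == "A" & to == "G", "A-to-I",
           paste0(chartr("T", "U", from), "-to-", chartr("T", "U", to)))
}

#' Align a clone read to its mature reference
#'
#' Best ungapped 5'-anchored alignment with a read-start offset in
#' [-2, +2] relative to the reference 5' end (+1). Substitutions are
#' called at reference positions +1..+18, ignoring bases beyond the
#' shorter 3' extent of read and reference (the 3'-variable region).
#' Reads with more than \code{maxSubs} substitutions in that window are
#' excluded as probable artifacts, as are reads with no offset achieving
#' identity above \code{threshold}.
#'
#' @param readSeq,matureSeq character sequences
#' @param maxShift maximum absolute 5' offset
#' @param threshold identity needed over the overlap to accept the read
#' @param maxPos last reference position profiled (+18)
#' @param maxSubs maximum substitutions before the read is excluded
#' @return NULL if the read is excluded, else a list with \code{offset}
#'   (reference position of read base 1), \code{covered} (profiled
#'   reference positions), and \code{calls} (data.frame pos/from/to/class)
#' @export
alignToMature <- function(readSeq, matureSeq, maxShift = 2L,
                          threshold = 0.9, maxPos = 18L, maxSubs = 2L) {
    r <- strsplit(toupper(readSeq), "", fixed = TRUE)[[1L]]
    m <- strsplit(toupper(matureSeq), "", fixed = TRUE)[[1L]]
    best <- NULL
    for (off in .EDIT_OFFSETS) {
        if (abs(off) > maxShift) next
        ## read base i sits at reference position i + off
        refPos <- seq_along(r) + off
        keep <- refPos >= 1L & refPos <= length(m)
        span <- sum(keep)
        if (span == 0L) next
        matches <- sum(r[keep] == m[refPos[keep]])
        idn <- matches / span
        if (idn > threshold && (is.null(best) || idn > best$idn)) {
            best <- list(off = off, idn = idn, refPos = refPos, keep = keep)
        }
    }
    if (is.null(best)) return(NULL)
    refPos <- best$refPos
    keep <- best$keep
    lastRef <- max(refPos[keep])            # 3'-variable region starts here
    window <- keep & refPos <= min(maxPos, lastRef)
    mm <- window & r != m[pmin(pmax(refPos, 1L), length(m))]
    calls <- data.frame(pos = refPos[mm], from = m[refPos[mm]],
                        to = r[mm], stringsAsFactors = FALSE)
    if (nrow(calls) > maxSubs) return(NULL)
    if (nrow(calls))
        calls$class <- .editClass(calls$from, calls$to)
    else
        calls$class <- character(0)
    list(offset = 1L + best$off, identity = best$idn,
         covered = intersect(refPos[window], seq_len(min(maxPos, lastRef))),
         calls = calls)
}

#' Per-position modification profile of one miRNA
#'
#' Aligns every mature-assigned clone read of a miRNA to its reference and
#' tabulates, per tissue group and position/substitution, the clone-count
#' fraction of modified reads among reads covering the position. A site is
#' reported when its fraction reaches \code{reportThreshold} in some group
#' and it is not masked as a SNP; groups with fewer than \code{minReads}
#' clones get undefined (NA) fractions. Calls at seed positions +2..+8 are
#' flagged.
#'
#' @param reads data.frame(seq, count, group) of clone reads assigned to
#'   this miRNA (e.g. a slice of the \code{\link{classifyReads}} table
#'   joined with sample groups)
#' @param matureSeq mature reference sequence
#' @param mirna miRNA id used in the output
#' @param minReads minimum clones per group for a defined fraction
#' @param reportThreshold minimum fraction for a site to be reported
#' @param snpMask optional data.frame(mirna, pos) of positions to exclude
#' @param ... passed to \code{\link{alignToMature}}
#' @return list of class \code{ModificationProfile}: \code{sites}
#'   (data.frame mirna, pos, from, to, class, seed, group, n_edited,
#'   n_covering, fraction), \code{groupFraction} (per-group modified-read
#'   fraction), \code{nExcluded} (clones dropped by alignment filters)
#' @export
modificationProfile <- function(reads, matureSeq, mirna = "miRNA",
                                minReads = 10L, reportThreshold = 0.05,
                                snpMask = NULL, ...) {
    stopifnot(all(c("seq", "count", "group") %in% names(reads)))
    reads <- stats::aggregate(count ~ seq + group, data = reads, FUN = sum)
    useq <- unique(reads$seq)
    aligned <- lapply(useq, alignToMature, matureSeq = matureSeq, ...)
    names(aligned) <- useq

    groups <- unique(reads$group)
    cover <- list()      # per group: clone count covering each position
    edited <- list()     # per group: clone counts per (pos, from, to)
    groupTotal <- stats::setNames(numeric(length(groups)), groups)
    groupMod <- stats::setNames(numeric(length(groups)), groups)
    nExcluded <- 0L

    maxPos <- 18L
    for (g in groups) {
        cover[[g]] <- numeric(maxPos)
        edited[[g]] <- list()
    }
    for (k in seq_len(nrow(reads))) {
        al <- aligned[[reads$seq[k]]]
        g <- reads$group[k]
        cnt <- reads$count[k]
        if (is.null(al)) {
            nExcluded <- nExcluded + cnt
            next
        }
        cover[[g]][al$covered] <- cover[[g]][al$covered] + cnt
        groupTotal[g] <- groupTotal[g] + cnt
        if (nrow(al$calls)) {
            groupMod[g] <- groupMod[g] + cnt
            for (j in seq_len(nrow(al$calls))) {
                key <- paste0(al$calls$pos[j], ":", al$calls$from[j], ">",
                              al$calls$to[j])
                edited[[g]][[key]] <- (edited[[g]][[key]] %||% 0) + cnt
            }
        }
    }

    keys <- unique(unlist(lapply(edited, names)))
    sites <- NULL
    if (length(keys)) {
        parts <- do.call(rbind, strsplit(keys, "[:>]"))
        pos <- as.integer(parts[, 1L])
        rows <- lapply(seq_along(keys), function(j) {
            frac <- vapply(groups, function(g) {
                cov <- cover[[g]][pos[j]]
                if (cov < minReads) return(NA_real_)
                (edited[[g]][[keys[j]]] %||% 0) / cov
            }, numeric(1))
            data.frame(mirna = mirna, pos = pos[j], from = parts[j, 2L],
                       to = parts[j, 3L],
                       class = .editClass(parts[j, 2L], parts[j, 3L]),
                       seed = pos[j] >= 2L & pos[j] <= 8L,
                       group = groups,
                       n_edited = vapply(groups, function(g)
                           edited[[g]][[keys[j]]] %||% 0, numeric(1)),
                       n_covering = vapply(groups, function(g)
                           cover[[g]][pos[j]], numeric(1)),
                       fraction = frac,
                       stringsAsFactors = FALSE, row.names = NULL)
        })
        sites <- do.call(rbind, rows)
        if (!is.null(snpMask)) {
            masked <- paste(sites$mirna, sites$pos) %in%
                paste(snpMask$mirna, snpMask$pos)
            sites <- sites[!masked, , drop = FALSE]
        }
        keep <- tapply(sites$fraction, paste(sites$pos, sites$from, sites$to),
                       function(x) any(!is.na(x) & x >= reportThreshold))
        sites <- sites[keep[paste(sites$pos, sites$from, sites$to)], ,
                       drop = FALSE]
        sites <- sites[order(sites$pos, sites$group), , drop = FALSE]
        rownames(sites) <- NULL
    }
    if (is.null(sites))
        sites <- data.frame(mirna = character(0), pos = integer(0),
                            from = character(0), to = character(0),
                            class = character(0), seed = logical(0),
                            group = character(0), n_edited = numeric(0),
                            n_covering = numeric(0), fraction = numeric(0))
    out <- list(sites = sites,
                groupFraction = ifelse(groupTotal >= minReads,
                                       groupMod / groupTotal, NA_real_),
                nExcluded = nExcluded, mirna = mirna)
    class(out) <- "ModificationProfile"
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split expression into modified / nonmodified / total forms
#'
#' Classifies every mature-assigned clone read as modified (it carries at
#' least one substitution call at +1..+18) or nonmodified, and builds a
#' \code{SummarizedExperiment} with three rows per miRNA (forms
#' nonmodified, modified, total; total = nonmodified + modified) carrying
#' clone-count and per-1000-normalized assays. Normalization uses each
#' sample's total-form clone count, so normalized totals sum to 1000.
#'
#' @param annot annotation table from \code{\link{classifyReads}}
#' @param matureSeqs named character vector (or DNAStringSet) of mature
#'   reference sequences
#' @param ... passed to \code{\link{alignToMature}}
#' @return a \code{SummarizedExperiment}; rowData has \code{mirna} and
#'   \code{form}, assays are \code{counts} and \code{normalized}
#' @export
splitExpressionForms <- function(annot, matureSeqs, ...) {
    if (is(matureSeqs, "DNAStringSet"))
        matureSeqs <- stats::setNames(as.character(matureSeqs),
                                      names(matureSeqs))
    mat <- annot[annot$db_class == "miRNA" & !annot$precursor_only, ]
    mat <- mat[mat$ref_id %in% names(matureSeqs), ]
    ukey <- !duplicated(paste(mat$seq, mat$ref_id))
    uni <- mat[ukey, c("seq", "ref_id")]
    modified <- mapply(function(s, id) {
        al <- alignToMature(s, matureSeqs[[id]], ...)
        if (is.null(al)) NA else nrow(al$calls) > 0L
    }, uni$seq, uni$ref_id)
    mat$modified <- modified[match(paste(mat$seq, mat$ref_id),
                                   paste(uni$seq, uni$ref_id))]
    mat <- mat[!is.na(mat$modified), ]

    samples <- sort(unique(mat$sample))
    mirnas <- sort(unique(mat$ref_id))
    tab <- function(sub) {
        t <- tapply(sub$count, list(factor(sub$ref_id, mirnas),
                                    factor(sub$sample, samples)),
                    sum, default = 0L)
        t[is.na(t)] <- 0L
        t
    }
    nonmod <- tab(mat[!mat$modified, ])
    mod <- tab(mat[mat$modified, ])
    total <- nonmod + mod

    counts <- rbind(nonmod, mod, total)
    forms <- rep(c("nonmodified", "modified", "total"),
                 each = length(mirnas))
    denom <- colSums(total)
    normalized <- t(t(counts) * 1000 / denom)
    rd <- S4Vectors::DataFrame(mirna = rep(mirnas, 3L), form = forms)
    rownames(counts) <- rownames(normalized) <-
        paste0(rep(mirnas, 3L), ".", forms)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts, normalized = normalized),
        rowData = rd,
        colData = S4Vectors::DataFrame(sample = samples,
                                       row.names = samples))
}
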