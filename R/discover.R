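## Novel miRNA discovery: group genome-matched, database-unmatched reads
## (plus precursor-only opposite-arm candidates) into loci and classify
## each locus as novel / opposite / antisense / rejected.

#' Group candidate reads into genomic loci
#'
#' Takes the novel-candidate pool from \code{\link{classifyReads}} --
#' genome-class reads plus precursor-only miRNA reads -- and merges
#' same-strand reads whose genomic intervals overlap by at least 1 nt
#' (single-linkage). Each group's representative sequence is the one with
#' the highest total clone count (ties: lexicographically smallest).
#'
#' @param annot annotation table from \code{\link{classifyReads}}
#' @param minReads minimum total clone count for a group to remain a
#'   candidate (suppresses singleton sequencing errors)
#' @param chrom chromosome name of the (single-chromosome) genome
#' @return data.frame: group_id, chrom, start, end, strand (group extent),
#'   support (total clones), n_seqs, rep_seq, rep_start, rep_end
#' @export
groupCandidates <- function(annot, minReads = 2L, chrom = "chrS") {
    cand <- annot[(annot$db_class == "genome" | annot$precursor_only) &
                  !is.na(annot$genome_start), ]
    if (!nrow(cand))
        return(data.frame(group_id = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), support = integer(0),
                          n_seqs = integer(0), rep_seq = character(0),
                          rep_start = integer(0), rep_end = integer(0)))
    key <- paste(cand$seq, cand$genome_start, cand$genome_strand)
    agg <- cand[!duplicated(key), c("seq", "genome_start", "genome_end",
                                    "genome_strand")]
    agg$count <- as.integer(tapply(cand$count, key, sum)[key[!duplicated(key)]])

    gr <- GenomicRanges::GRanges(chrom,
              IRanges::IRanges(agg$genome_start, agg$genome_end),
              strand = agg$genome_strand)
    merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
    hit <- GenomicRanges::findOverlaps(gr, merged)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]

    out <- lapply(split(seq_len(nrow(agg)), grp), function(idx) {
        sub <- agg[idx, ]
        total <- sum(sub$count)
        byseq <- tapply(sub$count, sub$seq, sum)
        best <- names(byseq)[order(-byseq, names(byseq))][1L]
        bi <- idx[sub$seq == best][1L]
        g <- grp[bi]
        data.frame(chrom = chrom,
                   start = GenomicRanges::start(merged)[g],
                   end = GenomicRanges::end(merged)[g],
                   strand = as.character(GenomicRanges::strand(merged))[g],
                   support = total, n_seqs = length(byseq),
                   rep_seq = best,
                   rep_start = agg$genome_start[bi],
                   rep_end = agg$genome_end[bi],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    out <- out[order(out$start, out$strand), , drop = FALSE]
    out <- out[out$support >= minReads, , drop = FALSE]
    if (nrow(out))
        out <- cbind(group_id = sprintf("cand-%03d", seq_len(nrow(out))),
                     out, stringsAsFactors = FALSE)
    else
        out <- cbind(group_id = character(0), out)
    rownames(out) <- NULL
    out
}

## terminal-loop midpoint of a known precursor (cached), used to decide
## which arm a candidate sits on
.precursorLoopMid <- function(preSeq, matureStart, matureEnd, cache = NULL,
                              key = NULL) {
    if (!is.null(cache) && !is.null(key) && !is.null(cache[[key]]))
        return(cache[[key]])
    f <- foldRNA(preSeq)
    u <- .matureUnit(f@pairs, matureStart, matureEnd)
    mid <- (nchar(preSeq) + 1L) / 2
    if (!is.na(u$anchor)) {
        tree <- u$tree
        hp <- u$subtree[vapply(u$subtree, function(k)
            length(tree$children[[k]]) == 0L, logical(1))]
        if (length(hp) == 1L)
            mid <- (tree$open[hp] + tree$close[hp]) / 2
    }
    if (!is.null(cache) && !is.null(key)) cache[[key]] <- mid
    mid
}

#' Classify candidate loci as novel, opposite, antisense or rejected
#'
#' Decision cascade for each grouped locus: (1) a group overlapping a known
#' precursor on the same strand is \code{opposite} if it lies on the arm
#' across the terminal loop from the annotated mature, otherwise rejected;
#' (2) a group overlapping a known mature locus on the opposite strand that
#' folds (on its own strand's context) into a hairpin passing the
#' structural criteria is \code{antisense} -- no conservation required;
#' (3) a group overlapping no known locus and passing the criteria plus the
#' stem-conservation test is \code{novel}; anything else is rejected with
#' the first failing reason.
#'
#' @param groups candidate table from \code{\link{groupCandidates}}
#' @param knownLoci GRanges of known annotations with metadata columns
#'   \code{class} ("known-precursor" / "known-mature"), \code{id},
#'   \code{mature_start}, \code{mature_end}
#' @param genome genome sequence
#' @param track per-base conservation track (novel calls are disabled with
#'   a warning when absent)
#' @param context,windowSize,step window-scan geometry
#' @param minMaturePaired,loopMax,internalMax,bulgeMax criterion bounds
#' @param consWindow,consCutoff conservation window and cutoff
#' @return the \code{groups} table with columns \code{class},
#'   \code{reason}, criterion verdicts and measured values appended
#' @export
classifyCandidates <- function(groups, knownLoci, genome, track = NULL,
                               context = 88L, windowSize = 110L, step = 5L,
                               minMaturePaired = 16L, loopMax = 20L,
                               internalMax = 10L, bulgeMax = 5L,
                               consWindow = 15L, consCutoff = 0.8) {
    if (is.null(track))
        warning("no conservation track: novel calls disabled")
    pre <- knownLoci[knownLoci$class == "known-precursor"]
    mat <- knownLoci[knownLoci$class == "known-mature"]
    known <- c(pre, mat)
    gseq <- .asGenomeString(genome)
    foldCache <- new.env(parent = emptyenv())

    n <- nrow(groups)
    cls <- character(n)
    reason <- rep(NA_character_, n)
    rp <- vector("list", n)

    firstFailure <- function(report, needCons) {
        if (!report@a) return("no-stem-loop")
        if (!report@b) return(paste0("mature-pairing<=", minMaturePaired))
        if (!report@c) return(paste0("terminal-loop>=", loopMax))
        if (!report@d) return(paste0("internal-loop>=", internalMax))
        if (!report@e) return(paste0("bulge>=", bulgeMax))
        if (needCons && !isTRUE(report@conserved)) return("not-conserved")
        NA_character_
    }

    for (i in seq_len(n)) {
        g <- GenomicRanges::GRanges(groups$chrom[i],
                 IRanges::IRanges(groups$start[i], groups$end[i]),
                 strand = groups$strand[i])
        samePre <- pre[IRanges::overlapsAny(pre, g, ignore.strand = FALSE)]
        if (length(samePre)) {
            p <- samePre[1L]
            local <- function(x) x - GenomicRanges::start(p) + 1L
            loopMid <- .precursorLoopMid(
                as.character(Biostrings::subseq(gseq,
                    GenomicRanges::start(p), GenomicRanges::end(p))),
                local(p$mature_start), local(p$mature_end),
                cache = foldCache, key = p$id)
            matMid <- local((p$mature_start + p$mature_end) / 2)
            candMid <- local((groups$start[i] + groups$end[i]) / 2)
            if (sign(candMid - loopMid) != 0 &&
                sign(candMid - loopMid) != sign(matMid - loopMid)) {
                cls[i] <- "opposite"
            } else {
                cls[i] <- "rejected"
                reason[i] <- "overlaps-known-mature"
            }
            next
        }
        antiMat <- mat[IRanges::overlapsAny(mat, g, ignore.strand = TRUE) &
                       as.character(GenomicRanges::strand(mat)) !=
                           groups$strand[i]]
        isAnti <- length(antiMat) > 0L
        overlapsKnown <- IRanges::overlapsAny(g, known, ignore.strand = TRUE)
        if (!isAnti && overlapsKnown) {
            ## same-strand overlap with a mature locus (not its precursor):
            ## treated as annotated territory
            cls[i] <- "rejected"
            reason[i] <- "overlaps-known-mature"
            next
        }
        res <- assessHairpin(gseq, groups$rep_start[i], groups$rep_end[i],
                             strand = groups$strand[i],
                             track = if (isAnti) NULL else track,
                             context = context, windowSizes = c(windowSize, 85L, 65L),
                             step = step,
                             minMaturePaired = minMaturePaired,
                             loopMax = loopMax, internalMax = internalMax,
                             bulgeMax = bulgeMax, consWindow = consWindow,
                             consCutoff = consCutoff,
                             requireConserved = !isAnti)
        rp[[i]] <- res$report
        if (isAnti) {
            if (res$pass) {
                cls[i] <- "antisense"
            } else {
                cls[i] <- "rejected"
                reason[i] <- firstFailure(res$report, needCons = FALSE)
            }
        } else if (is.null(track)) {
            cls[i] <- "rejected"
            reason[i] <- "no-conservation-track"
        } else if (res$pass) {
            cls[i] <- "novel"
        } else {
            cls[i] <- "rejected"
            reason[i] <- firstFailure(res$report, needCons = TRUE)
        }
    }

    rep0 <- function(get, na) vapply(rp, function(r)
        if (is.null(r)) na else get(r), na)
    cbind(groups,
          class = cls, reason = reason,
          crit_a = rep0(function(r) r@a, NA),
          crit_b = rep0(function(r) r@b, NA),
          crit_c = rep0(function(r) r@c, NA),
          crit_d = rep0(function(r) r@d, NA),
          crit_e = rep0(function(r) r@e, NA),
          mature_paired = rep0(function(r) r@maturePaired, NA_integer_),
          terminal_loop = rep0(function(r) r@terminalLoopSize, NA_integer_),
          max_internal = rep0(function(r) r@maxInternalLoop, NA_integer_),
          max_bulge = rep0(function(r) r@maxBulge, NA_integer_),
          conserved = rep0(function(r) r@conserved, NA),
          best_cons_mean = rep0(function(r) r@bestWindowMean, NA_real_),
          stringsAsFactors = FALSE)
}

#' Discover novel, opposite and antisense miRNAs end to end
#'
#' Convenience wrapper: \code{\link{groupCandidates}} followed by
#' \code{\link{classifyCandidates}}.
#'
#' @inheritParams groupCandidates
#' @inheritParams classifyCandidates
#' @param ... passed to \code{\link{classifyCandidates}}
#' @return annotated candidate table (one row per locus)
#' @export
discoverNovel <- function(annot, knownLoci, genome, track = NULL,
                          minReads = 2L, chrom = "chrS", ...) {
    groups <- groupCandidates(annot, minReads = minReads, chrom = chrom)
    if (!nrow(groups)) {
        empty <- classifyCandidates(groups, knownLoci, genome,
                                    track = track, ...)
        return(empty)
    }
    classifyCandidates(groups, knownLoci, genome, track = track, ...)
}
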