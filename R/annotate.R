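## Read classification against reference databases in fixed priority order
## (miRNA, piRNA, rRNA, tRNA, snRNA, snoRNA, mRNA, then genome), clone
## counting and per-1000 normalization.

.DB_PRIORITY <- c("miRNA", "piRNA", "rRNA", "tRNA", "snRNA", "snoRNA",
                  "mRNA")
.SPACER <- 40L   # >= max read length, so no alignment spans two references

## concatenate the databases (in priority order) into one subject with N
## spacers; class priority is encoded by block order, so the leftmost exact
## hit is automatically the highest-priority one
.dbSubject <- function(dbs) {
    allRefs <- do.call(c, lapply(names(dbs), function(cl) {
        db <- dbs[[cl]]
        stats::setNames(as.character(db), names(db))
    }))
    refClass <- rep(names(dbs), vapply(dbs, length, integer(1)))
    lens <- nchar(allRefs)
    spacer <- paste(rep("N", .SPACER), collapse = "")
    subj <- paste0(spacer, paste(allRefs, collapse = spacer), spacer)
    refStarts <- .SPACER + 1L +
        cumsum(c(0L, utils::head(lens, -1L) + .SPACER))
    refIdx <- integer(nchar(subj))
    for (i in seq_along(lens))
        refIdx[refStarts[i]:(refStarts[i] + lens[i] - 1L)] <- i
    isN <- refIdx == 0L
    list(subject = Biostrings::DNAString(subj),
         refStarts = refStarts, refLens = unname(lens),
         refNames = names(allRefs), refClass = refClass,
         refClassRank = match(refClass, .DB_PRIORITY),
         refIdx = refIdx, cumN0 = c(0L, cumsum(isN)))
}

#' Classify clone reads against reference databases and the genome
#'
#' For every read, searches the databases in the fixed priority order
#' miRNA, piRNA, rRNA, tRNA, snRNA, snoRNA, mRNA for the best ungapped
#' match with identity strictly greater than \code{threshold} (identity =
#' matches / aligned span; up to \code{maxOverhang} read bases may extend
#' past a reference end and are excluded from the span, so end variation is
#' recorded but not penalized). The first class in priority order with a
#' valid hit wins, regardless of database file order; within a class the
#' best-identity hit wins (ties: first database entry). Reads matching no
#' database but matching the genome exactly (identity 1.0, either strand)
#' are classed \code{genome} -- the novel-candidate pool; everything else
#' is \code{unmatched}. miRNA-class reads whose only hit is a precursor
#' entry (id suffix \code{"-pre"}, no mature hit) are flagged
#' \code{precursor_only}: these are opposite-arm candidates and are also
#' mapped to the genome.
#'
#' @param reads data.frame(read_id, sample, seq, count) as from
#'   \code{\link{readReadsFasta}}, or a character vector of sequences
#' @param dbs named list of \code{DNAStringSet} databases; names must be
#'   among the priority classes (order of the list is irrelevant)
#' @param genome optional genome (\code{DNAString}/character) for the
#'   novel-candidate pool
#' @param threshold identity threshold; a hit requires identity strictly
#'   above it (0.90 exactly is rejected)
#' @param maxOverhang maximum read bases allowed past a reference end
#' @return data.frame with one row per read: read_id, sample, seq, count,
#'   db_class, ref_id, identity, offset (1-based read start on the
#'   reference), end5, end3 (end variation: read start/end minus reference
#'   start/end), precursor_only, genome_start, genome_end, genome_strand
#' @export
classifyReads <- function(reads, dbs, genome = NULL, threshold = 0.9,
                          maxOverhang = 3L) {
    if (is.character(reads))
        reads <- data.frame(read_id = sprintf("r%06d", seq_along(reads)),
                            sample = "S1", seq = reads, count = 1L,
                            stringsAsFactors = FALSE)
    stopifnot(all(c("read_id", "sample", "seq", "count") %in% names(reads)))
    if (length(dbs) == 0L) stop("empty database set")
    bad <- setdiff(names(dbs), .DB_PRIORITY)
    if (length(bad))
        stop("unknown database class(es): ", paste(bad, collapse = ", "))
    dbs <- dbs[vapply(dbs, length, integer(1)) > 0L]
    dbs <- dbs[.DB_PRIORITY[.DB_PRIORITY %in% names(dbs)]]
    if (length(dbs) == 0L) stop("empty database set")

    useq <- unique(reads$seq)
    nU <- length(useq)
    uLen <- nchar(useq)
    uSet <- Biostrings::DNAStringSet(useq)

    cls <- rep(NA_character_, nU)
    refId <- rep(NA_character_, nU)
    ident <- rep(NA_real_, nU)
    offset <- rep(NA_integer_, nU)
    end5 <- rep(NA_integer_, nU)
    end3 <- rep(NA_integer_, nU)
    gStart <- rep(NA_integer_, nU)
    gEnd <- rep(NA_integer_, nU)
    gStrand <- rep(NA_character_, nU)

    sub <- .dbSubject(dbs)
    slen <- length(sub$refIdx)

    ## stage A: exact substring matches; leftmost hit = highest priority
    ## class (blocks are concatenated in priority order), first entry within
    ## the class (mature miRNA entries precede precursor entries)
    for (w in unique(uLen)) {
        idx <- which(uLen == w)
        pd <- Biostrings::PDict(uSet[idx])
        st <- Biostrings::startIndex(Biostrings::matchPDict(pd, sub$subject))
        for (k in seq_along(idx)) {
            if (is.null(st[[k]]) || !length(st[[k]])) next
            i <- idx[k]
            at <- st[[k]][1L]
            ref <- sub$refIdx[at]
            cls[i] <- sub$refClass[ref]
            refId[i] <- sub$refNames[ref]
            ident[i] <- 1.0
            offset[i] <- at - sub$refStarts[ref] + 1L
            end5[i] <- offset[i] - 1L
            end3[i] <- (offset[i] + w - 1L) - sub$refLens[ref]
        }
    }

    ## stage B: mismatch / end-overhang matches for the remainder
    atCache <- list()
    nNCache <- list()
    for (i in which(is.na(cls))) {
        L <- uLen[i]
        key <- as.character(L)
        if (is.null(atCache[[key]])) {
            at <- seq_len(max(slen - L + 1L, 0L))
            atCache[[key]] <- at
            nNCache[[key]] <- sub$cumN0[at + L] - sub$cumN0[at]
        }
        at <- atCache[[key]]
        if (!length(at)) next
        nN <- nNCache[[key]]
        ned <- as.integer(Biostrings::neditStartingAt(
            uSet[[i]], sub$subject, starting.at = at))
        span <- L - nN
        idn <- (span - (ned - nN)) / span
        ok <- which(nN <= maxOverhang & span > 0L & idn > threshold)
        if (!length(ok)) next
        ## the reference under the window = the one covering its non-N part
        ## (with <= maxOverhang Ns, at least one of start/middle/end is on it)
        refHit <- pmax(sub$refIdx[ok], sub$refIdx[ok + L %/% 2L],
                       sub$refIdx[ok + L - 1L])
        o <- order(sub$refClassRank[refHit], -idn[ok], refHit, ok)[1L]
        best <- ok[o]
        ref <- refHit[o]
        cls[i] <- sub$refClass[ref]
        refId[i] <- sub$refNames[ref]
        ident[i] <- idn[best]
        offset[i] <- best - sub$refStarts[ref] + 1L
        end5[i] <- offset[i] - 1L
        end3[i] <- (offset[i] + L - 1L) - sub$refLens[ref]
    }

    ## precursor-only flag: miRNA hits on a "-pre" entry (no mature hit wins
    ## because mature entries precede precursors in the database)
    preOnly <- !is.na(cls) & cls == "miRNA" & grepl("-pre$", refId)

    ## stage C: exact genome matching for the candidate pool (unmatched
    ## reads) and for opposite-arm (precursor-only) reads
    if (!is.null(genome)) {
        gseq <- .asGenomeString(genome)
        glen <- Biostrings::nchar(gseq)
        grc <- Biostrings::reverseComplement(gseq)
        mapIdx <- which(is.na(cls) | preOnly)
        for (w in unique(uLen[mapIdx])) {
            idx <- mapIdx[uLen[mapIdx] == w]
            pd <- Biostrings::PDict(uSet[idx])
            stP <- Biostrings::startIndex(Biostrings::matchPDict(pd, gseq))
            stM <- Biostrings::startIndex(Biostrings::matchPDict(pd, grc))
            for (k in seq_along(idx)) {
                i <- idx[k]
                if (!is.null(stP[[k]]) && length(stP[[k]])) {
                    gStart[i] <- stP[[k]][1L]
                    gEnd[i] <- gStart[i] + w - 1L
                    gStrand[i] <- "+"
                } else if (!is.null(stM[[k]]) && length(stM[[k]])) {
                    s <- stM[[k]][1L]
                    gStart[i] <- glen - (s + w - 1L) + 1L
                    gEnd[i] <- gStart[i] + w - 1L
                    gStrand[i] <- "-"
                }
                if (is.na(cls[i]) && !is.na(gStart[i])) {
                    cls[i] <- "genome"
                    ident[i] <- 1.0
                }
            }
        }
    }
    cls[is.na(cls)] <- "unmatched"

    m <- match(reads$seq, useq)
    data.frame(reads[c("read_id", "sample", "seq", "count")],
               db_class = cls[m], ref_id = refId[m], identity = ident[m],
               offset = offset[m], end5 = end5[m], end3 = end3[m],
               precursor_only = preOnly[m], genome_start = gStart[m],
               genome_end = gEnd[m], genome_strand = gStrand[m],
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Count clones and normalize expression per 1000 reads
#'
#' Builds the miRNA expression matrix from mature-assigned reads (miRNA
#' class, not precursor-only), with per-sample normalization
#' \code{count * 1000 / total}, where total is the sample's clone count in
#' the matrix -- so each sample's normalized values sum to 1000. Also
#' returns the per-sample class-composition table over all reads.
#'
#' @param annot annotation table from \code{\link{classifyReads}}
#' @return list of class \code{MirExpression}: \code{counts} (miRNA x
#'   sample clone counts), \code{normalized} (per-1000), \code{composition}
#'   (sample x class fractions), \code{samples}
#' @export
countAndNormalize <- function(annot) {
    samples <- unique(annot$sample)
    zero <- vapply(samples, function(s)
        sum(annot$count[annot$sample == s]) == 0L, logical(1))
    if (any(zero)) {
        warning("excluding sample(s) with zero reads: ",
                paste(samples[zero], collapse = ", "))
        samples <- samples[!zero]
        annot <- annot[annot$sample %in% samples, ]
    }
    comp <- tapply(annot$count,
                   list(annot$sample, annot$db_class), sum, default = 0L)
    comp <- comp / rowSums(comp)

    mat <- annot[annot$db_class == "miRNA" & !annot$precursor_only, ]
    counts <- tapply(mat$count, list(mat$ref_id, mat$sample), sum,
                     default = 0L)
    counts <- counts[, intersect(samples, colnames(counts)), drop = FALSE]
    empty <- colSums(counts) == 0L
    noMir <- c(setdiff(samples, colnames(counts)), colnames(counts)[empty])
    if (length(noMir)) {
        warning("excluding sample(s) with zero miRNA reads: ",
                paste(noMir, collapse = ", "))
        counts <- counts[, !empty, drop = FALSE]
    }
    normalized <- t(t(counts) * 1000 / colSums(counts))
    out <- list(counts = counts, normalized = normalized,
                composition = comp, samples = samples)
    class(out) <- "MirExpression"
    out
}
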