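## Synthetic study generator: a single-chromosome toy genome with planted
## known/novel miRNA hairpins and decoy small RNA loci, a per-base
## conservation track, paired tumour/normal clone libraries with 3' end
## variation, per-position editing and sequencing error, and clinical
## outcomes in which one expression cluster carries elevated hazard.

#' Evaluate an expression with a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so simulations are
#' reproducible without disturbing the session.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of \code{expr}
#' @export
withSeed <- function(seed, expr) {
    hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hasSeed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (hasSeed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

.randSeq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.mirId <- function(i) sprintf("syn-miR-%02d", i)

.defaultEditingSpec <- function(nKnown) {
    spec <- data.frame(
        mirna = .mirId(2:5),
        pos = c(6L, 6L, 10L, 17L),
        from = c("A", "A", "C", "T"),
        to = c("G", "G", "A", "A"),
        rate_hcc = c(0.31, 0.86, 0.96, 0.74),
        rate_anl = c(0.50, 0.50, 1.00, 0.78),
        stringsAsFactors = FALSE)
    spec[match(spec$mirna, .mirId(seq_len(nKnown)), nomatch = 0L) > 0L, ]
}

.defaultFoldChangeSpec <- function(nKnown) {
    spec <- data.frame(
        mirna = .mirId(c(1L, 6L, 7L, 8L, 9L, 10L)),
        lfc = c(1.5, 2, 2, 2, -2, -2),
        stringsAsFactors = FALSE)
    spec[match(spec$mirna, .mirId(seq_len(nKnown)), nomatch = 0L) > 0L, ]
}

#' Configuration of a synthetic small RNA study
#'
#' Defaults describe the emulated study design: 18 tumour (HCC) / adjacent
#' normal (ANL) pairs, about 80\% of clone reads from annotated miRNAs with
#' a small piRNA contamination (0.76\%), heavy-tailed (log-normal) miRNA
#' abundances, 3' end trimming of 0-3 nt, per-position editing at the
#' reported sites and rates (a seed-region +6 A-to-G pair, a +10 C-to-A
#' site at rates 0.96/1.00, a +17 U-to-A site at 0.74/0.78), tumour fold
#' changes including three 4-fold up-regulated miRNAs and a high-risk
#' tumour subgroup with elevated marker expression and an 8-fold recurrence
#' hazard.
#'
#' @param seed master seed; stage seeds are derived by fixed offsets
#' @param n_pairs number of HCC/ANL sample pairs
#' @param n_known_mirnas,n_novel_hairpins,n_decoys planted locus counts
#' @param n_opposite,n_antisense known precursors with opposite-arm reads /
#'   antisense-locus reads
#' @param n_controls additional unpaired control samples
#' @param library_size clone reads per sample
#' @param genome_length length of the single synthetic chromosome
#' @param editing_spec data.frame(mirna, pos, from, to, rate_hcc, rate_anl)
#' @param trim3_probs probabilities of trimming 0/1/2/3 nt from the 3' end
#' @param seq_error_rate per-base sequencing error probability
#' @param fold_change_spec data.frame(mirna, lfc): tumour log2 fold changes
#' @param class_mix named read-mass fractions for channels known, opposite,
#'   novel, antisense, piRNA, mRNA, otherDecoy (must sum to 1)
#' @param sdlog_gene log-normal sd of baseline abundances
#' @param sdlog_sample per-sample log-normal abundance jitter
#' @param marker_frac fraction of the known-miRNA mass given to the marker
#'   miRNA (the first known miRNA; its expression defines the high-risk
#'   cluster)
#' @param highrisk_frac fraction of tumours in the high-risk cluster
#' @param highrisk_boost extra marker expression multiplier in high-risk
#'   tumours
#' @param highrisk_profile_sd log-sd of the shared expression-profile
#'   perturbation of high-risk tumours across known miRNAs; this is what
#'   makes the high-risk cluster discoverable by expression clustering
#'   (the emulated cluster is a profile-level subgroup, not a single
#'   marker shift)
#' @param hazard_ratio recurrence hazard ratio of the high-risk cluster
#' @param censor_rate expected fraction of censored observations
#' @param base_hazard baseline exponential hazard (per month)
#' @param n_covariates independent binary pathological covariates
#' @return a validated list of class \code{SimConfig}
#' @export
simConfig <- function(seed = 1L,
                      n_pairs = 18L,
                      n_known_mirnas = 30L,
                      n_novel_hairpins = 10L,
                      n_decoys = 50L,
                      n_opposite = 5L,
                      n_antisense = 3L,
                      n_controls = 0L,
                      library_size = 2000L,
                      genome_length = 100000L,
                      editing_spec = NULL,
                      trim3_probs = c(`0` = 0.55, `1` = 0.25,
                                      `2` = 0.15, `3` = 0.05),
                      seq_error_rate = 0.005,
                      fold_change_spec = NULL,
                      class_mix = c(known = 0.78, opposite = 0.02,
                                    novel = 0.03, antisense = 0.007,
                                    piRNA = 0.0076, mRNA = 0.01,
                                    otherDecoy = 0.1454),
                      sdlog_gene = 1.5,
                      sdlog_sample = 0.3,
                      marker_frac = 0.06,
                      highrisk_frac = 0.25,
                      highrisk_boost = 2.5,
                      highrisk_profile_sd = 0.8,
                      hazard_ratio = 8,
                      censor_rate = 0.3,
                      base_hazard = log(2) / 24,
                      n_covariates = 5L) {
    if (is.null(editing_spec))
        editing_spec <- .defaultEditingSpec(n_known_mirnas)
    if (is.null(fold_change_spec))
        fold_change_spec <- .defaultFoldChangeSpec(n_known_mirnas)
    cfg <- list(seed = as.integer(seed), n_pairs = as.integer(n_pairs),
                n_known_mirnas = as.integer(n_known_mirnas),
                n_novel_hairpins = as.integer(n_novel_hairpins),
                n_decoys = as.integer(n_decoys),
                n_opposite = as.integer(n_opposite),
                n_antisense = as.integer(n_antisense),
                n_controls = as.integer(n_controls),
                library_size = as.integer(library_size),
                genome_length = as.integer(genome_length),
                editing_spec = editing_spec,
                trim3_probs = trim3_probs,
                seq_error_rate = seq_error_rate,
                fold_change_spec = fold_change_spec,
                class_mix = class_mix,
                sdlog_gene = sdlog_gene, sdlog_sample = sdlog_sample,
                marker_frac = marker_frac,
                highrisk_frac = highrisk_frac,
                highrisk_boost = highrisk_boost,
                highrisk_profile_sd = highrisk_profile_sd,
                hazard_ratio = hazard_ratio,
                censor_rate = censor_rate,
                base_hazard = base_hazard,
                n_covariates = as.integer(n_covariates))
    class(cfg) <- "SimConfig"
    validateSimConfig(cfg)
    cfg
}

#' Validate a SimConfig
#'
#' @param cfg a \code{SimConfig}
#' @return invisibly TRUE; stops with the violated constraint otherwise
#' @export
validateSimConfig <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    if (cfg$library_size <= 0L) stop("library_size must be positive")
    if (cfg$n_pairs < 1L) stop("n_pairs must be at least 1")
    rates <- c(cfg$editing_spec$rate_hcc, cfg$editing_spec$rate_anl,
               cfg$seq_error_rate, cfg$censor_rate, cfg$trim3_probs)
    if (any(rates < 0 | rates > 1))
        stop("all rates and probabilities must lie in [0, 1]")
    if (abs(sum(cfg$trim3_probs) - 1) > 1e-8)
        stop("trim3_probs must sum to 1")
    if (abs(sum(cfg$class_mix) - 1) > 1e-6)
        stop("class_mix must sum to 1")
    knownIds <- .mirId(seq_len(cfg$n_known_mirnas))
    bad <- setdiff(cfg$editing_spec$mirna, knownIds)
    if (length(bad))
        stop("editing_spec names unknown miRNA: ", paste(bad, collapse = ", "))
    bad <- setdiff(cfg$fold_change_spec$mirna, knownIds)
    if (length(bad))
        stop("fold_change_spec names unknown miRNA: ",
             paste(bad, collapse = ", "))
    if (cfg$n_opposite + cfg$n_antisense > cfg$n_known_mirnas)
        stop("n_opposite + n_antisense exceeds n_known_mirnas")
    invisible(TRUE)
}

## Build one hairpin: mature arm + loop + (mismatched) reverse-complement
## arm. The loop is drawn from {A, C} so that it cannot base-pair with
## itself (no AU/GC/GU combination): planted precursors must be genuine
## stem-loops under the maximum-pairing folding model, and a self-pairing
## "loop" would branch into a multiloop. Returns the precursor sequence
## plus mature offsets within it.
.makeHairpin <- function(matureLen, loopLen, nMismatch, matureArm = "5p") {
    mature <- .randSeq(matureLen)
    other <- .revcomp(mature)
    if (nMismatch > 0L) {
        pos <- sort(sample(3:(matureLen - 3L), nMismatch))
        for (p in pos) {
            cur <- substr(other, p, p)
            substr(other, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
        }
    }
    ## homopolymer loop (A or C): inert under the pairing weights on BOTH
    ## strands (an A/C mix reverse-complements to G/T, which wobble-pairs)
    loop <- strrep(sample(c("A", "C"), 1L), loopLen)
    if (matureArm == "5p") {
        pre <- paste0(mature, loop, other)
        mstart <- 1L
    } else {
        pre <- paste0(other, loop, mature)
        mstart <- nchar(other) + loopLen + 1L
    }
    list(precursor = pre, mature = mature,
         matureStart = mstart, matureEnd = mstart + matureLen - 1L,
         otherStart = if (matureArm == "5p") matureLen + loopLen + 1L else 1L,
         otherEnd = if (matureArm == "5p") nchar(pre) else nchar(other),
         matureArm = matureArm)
}

#' Generate the synthetic reference: genome, databases, track and truth
#'
#' Plants known miRNA precursors (genuine hairpins: mature arm + loop +
#' reverse-complement arm with at most a few mismatches), novel hairpins
#' (perfect stems, stem conservation at least 0.9), and decoy
#' t/r/sn/sno/piRNA loci (conservation below 0.5) on a single random
#' chromosome, and builds the reference databases (mature + precursor
#' miRNA, piRNA, rRNA, tRNA, snRNA, snoRNA, mRNA) and the per-base
#' conservation track. Deterministic given \code{cfg$seed}.
#'
#' @param cfg a \code{\link{simConfig}}
#' @return a list of class \code{SimTruth}: \code{genome} (DNAString),
#'   \code{conservation} (numeric), \code{loci} (GRanges with locus class
#'   annotations), \code{dbs} (named list of DNAStringSet), \code{channels}
#'   (read-source table with baseline proportions), \code{samples} (sample
#'   sheet with true cluster labels), \code{editing} (resolved editing
#'   spec), \code{config}
#' @export
generateReference <- function(cfg) {
    validateSimConfig(cfg)
    withSeed(cfg$seed, {
        nK <- cfg$n_known_mirnas
        nN <- cfg$n_novel_hairpins
        nD <- cfg$n_decoys

        ## antisense targets need >= 3 arm mismatches so that the antisense
        ## read (exact reverse complement of the mature) stays below the 90%
        ## homology threshold against the precursor's other arm
        antisenseIdx <- if (cfg$n_antisense > 0L) seq_len(cfg$n_antisense) + 1L else integer(0)
        antisenseIdx <- antisenseIdx[antisenseIdx <= nK]
        oppositeIdx <- setdiff(seq_len(nK), antisenseIdx)
        oppositeIdx <- utils::tail(oppositeIdx, cfg$n_opposite)

        editPos <- cfg$editing_spec

        knowns <- vector("list", nK)
        for (i in seq_len(nK)) {
            nm <- if (i %in% antisenseIdx) 3L else sample(0:2, 1L)
            hp <- .makeHairpin(matureLen = sample(21:23, 1L),
                               loopLen = sample(8:15, 1L),
                               nMismatch = nm,
                               matureArm = if (i %% 2L) "5p" else "3p")
            ## force reference bases at configured editing sites
            rows <- which(editPos$mirna == .mirId(i))
            for (r in rows) {
                p <- editPos$pos[r]
                mpos <- hp$matureStart + p - 1L
                substr(hp$precursor, mpos, mpos) <- editPos$from[r]
                substr(hp$mature, p, p) <- editPos$from[r]
            }
            knowns[[i]] <- hp
        }

        novels <- lapply(seq_len(nN), function(i)
            .makeHairpin(matureLen = sample(21:22, 1L),
                         loopLen = sample(8:12, 1L),
                         nMismatch = 0L, matureArm = "5p"))

        decoyClasses <- rep(c("tRNA", "rRNA", "snRNA", "snoRNA", "piRNA"),
                            length.out = nD)
        decoyLens <- c(tRNA = 72L, rRNA = 120L, snRNA = 100L,
                       snoRNA = 90L, piRNA = 30L)
        decoys <- lapply(seq_len(nD), function(i)
            .randSeq(decoyLens[[decoyClasses[i]]]))

        ## place loci left to right with random gaps
        seqs <- c(vapply(knowns, `[[`, "", "precursor"),
                  vapply(novels, `[[`, "", "precursor"),
                  unlist(decoys))
        lens <- nchar(seqs)
        nLoci <- length(seqs)
        gaps <- sample(200:500, nLoci, replace = TRUE)
        starts <- cumsum(gaps) + cumsum(c(0L, lens[-nLoci]))
        ends <- starts + lens - 1L
        if (ends[nLoci] + 200L > cfg$genome_length)
            stop("genome_length (", cfg$genome_length,
                 ") too small for the planted loci (need at least ",
                 ends[nLoci] + 200L, " nt)")

        genomeChars <- sample(c("A", "C", "G", "T"), cfg$genome_length,
                              replace = TRUE)
        for (i in seq_len(nLoci))
            genomeChars[starts[i]:ends[i]] <-
                strsplit(seqs[i], "", fixed = TRUE)[[1L]]
        genome <- Biostrings::DNAString(paste(genomeChars, collapse = ""))

        ## conservation: low background, hard-guaranteed bands on plants
        cons <- pmin(pmax(stats::rnorm(cfg$genome_length, 0.30, 0.05), 0), 1)
        addBand <- function(s, e, base, lo = 0, hi = 1) {
            v <- stats::rnorm(e - s + 1L, base, 0.05)
            cons[s:e] <<- pmin(pmax(v, lo), hi)
        }
        for (i in seq_len(nK))
            addBand(starts[i], ends[i], 0.85)
        for (i in seq_len(nN)) {
            k <- nK + i
            addBand(starts[k], ends[k], 0.95, lo = 0.9)
        }
        for (i in seq_len(nD)) {
            k <- nK + nN + i
            addBand(starts[k], ends[k], 0.20, hi = 0.49)
        }

        ## locus table
        mkRange <- function(s, e, strand, id, class, mirna, ms, me) {
            GenomicRanges::GRanges("chrS", IRanges::IRanges(s, e),
                strand = strand, id = id, class = class, mirna = mirna,
                mature_start = ms, mature_end = me)
        }
        ranges <- list()
        for (i in seq_len(nK)) {
            hp <- knowns[[i]]
            ms <- starts[i] + hp$matureStart - 1L
            me <- starts[i] + hp$matureEnd - 1L
            ranges[[length(ranges) + 1L]] <-
                mkRange(starts[i], ends[i], "+", paste0(.mirId(i), "-pre"),
                        "known-precursor", .mirId(i), ms, me)
            ranges[[length(ranges) + 1L]] <-
                mkRange(ms, me, "+", .mirId(i), "known-mature", .mirId(i),
                        ms, me)
            if (i %in% antisenseIdx)
                ranges[[length(ranges) + 1L]] <-
                    mkRange(ms, me, "-", paste0(.mirId(i), "-as"),
                            "antisense-target", .mirId(i), ms, me)
        }
        for (i in seq_len(nN)) {
            k <- nK + i
            hp <- novels[[i]]
            id <- sprintf("syn-novel-%02d", i)
            ms <- starts[k] + hp$matureStart - 1L
            me <- starts[k] + hp$matureEnd - 1L
            ranges[[length(ranges) + 1L]] <-
                mkRange(starts[k], ends[k], "+", id, "novel-hairpin", id,
                        ms, me)
        }
        for (i in seq_len(nD)) {
            k <- nK + nN + i
            cls <- decoyClasses[i]
            id <- sprintf("syn-%s-%02d", tolower(cls), i)
            ranges[[length(ranges) + 1L]] <-
                mkRange(starts[k], ends[k], "+", id,
                        paste0("decoy-", sub("RNA$", "", cls)), id,
                        NA_integer_, NA_integer_)
        }
        loci <- do.call(c, ranges)

        ## reference databases
        matureSeqs <- Biostrings::DNAStringSet(
            vapply(knowns, `[[`, "", "mature"))
        names(matureSeqs) <- .mirId(seq_len(nK))
        preSeqs <- Biostrings::DNAStringSet(
            vapply(knowns, `[[`, "", "precursor"))
        names(preSeqs) <- paste0(.mirId(seq_len(nK)), "-pre")
        mirnaDb <- c(matureSeqs, preSeqs)    # mature entries first
        dbFor <- function(cls) {
            idx <- which(decoyClasses == cls)
            if (!length(idx)) return(Biostrings::DNAStringSet())
            s <- Biostrings::DNAStringSet(unlist(decoys[idx]))
            names(s) <- sprintf("syn-%s-%02d", tolower(cls), idx)
            s
        }
        mrnaDb <- Biostrings::DNAStringSet(c(.randSeq(300L), .randSeq(300L)))
        names(mrnaDb) <- c("syn-mRNA-01", "syn-mRNA-02")
        dbs <- list(miRNA = mirnaDb, piRNA = dbFor("piRNA"),
                    rRNA = dbFor("rRNA"), tRNA = dbFor("tRNA"),
                    snRNA = dbFor("snRNA"), snoRNA = dbFor("snoRNA"),
                    mRNA = mrnaDb)

        ## read-source channels with baseline mass
        mix <- cfg$class_mix
        lnorm <- function(n) {
            if (n == 0L) return(numeric(0))
            w <- stats::rlnorm(n, 0, cfg$sdlog_gene)
            w / sum(w)
        }
        knownW <- lnorm(nK)
        marker <- .mirId(1L)
        if (nK >= 2L) {
            ## pin the marker's share of the known-miRNA mass
            knownW[1L] <- cfg$marker_frac / (1 - cfg$marker_frac) *
                sum(knownW[-1L])
            knownW <- knownW / sum(knownW)
        }
        channels <- data.frame(
            channel = .mirId(seq_len(nK)),
            type = "known",
            source = vapply(knowns, `[[`, "", "mature"),
            mirna = .mirId(seq_len(nK)),
            mass = mix[["known"]] * knownW,
            stringsAsFactors = FALSE)
        if (length(oppositeIdx)) {
            oppW <- lnorm(length(oppositeIdx))
            opp <- data.frame(
                channel = paste0(.mirId(oppositeIdx), "-opp"),
                type = "opposite",
                source = vapply(knowns[oppositeIdx], function(hp)
                    substr(hp$precursor, hp$otherStart, hp$otherEnd), ""),
                mirna = .mirId(oppositeIdx),
                mass = mix[["opposite"]] * oppW,
                stringsAsFactors = FALSE)
            channels <- rbind(channels, opp)
        }
        if (nN > 0L) {
            novW <- lnorm(nN)
            channels <- rbind(channels, data.frame(
                channel = sprintf("syn-novel-%02d", seq_len(nN)),
                type = "novel",
                source = vapply(novels, `[[`, "", "mature"),
                mirna = sprintf("syn-novel-%02d", seq_len(nN)),
                mass = mix[["novel"]] * novW,
                stringsAsFactors = FALSE))
        }
        if (length(antisenseIdx)) {
            asW <- lnorm(length(antisenseIdx))
            channels <- rbind(channels, data.frame(
                channel = paste0(.mirId(antisenseIdx), "-as"),
                type = "antisense",
                source = vapply(knowns[antisenseIdx], function(hp)
                    .revcomp(hp$mature), ""),
                mirna = .mirId(antisenseIdx),
                mass = mix[["antisense"]] * asW,
                stringsAsFactors = FALSE))
        }
        piIdx <- which(decoyClasses == "piRNA")
        othIdx <- which(decoyClasses != "piRNA")
        if (length(piIdx)) {
            piW <- lnorm(length(piIdx))
            channels <- rbind(channels, data.frame(
                channel = sprintf("syn-pirna-%02d", piIdx),
                type = "decoy-piRNA",
                source = unlist(decoys[piIdx]),
                mirna = NA_character_,
                mass = mix[["piRNA"]] * piW,
                stringsAsFactors = FALSE))
        }
        if (length(othIdx)) {
            othW <- lnorm(length(othIdx))
            channels <- rbind(channels, data.frame(
                channel = sprintf("syn-%s-%02d",
                                  tolower(decoyClasses[othIdx]), othIdx),
                type = paste0("decoy-", sub("RNA$", "", decoyClasses[othIdx])),
                mirna = NA_character_,
                source = unlist(decoys[othIdx]),
                mass = mix[["otherDecoy"]] * othW,
                stringsAsFactors = FALSE)[, c("channel", "type", "source",
                                              "mirna", "mass")])
        }
        mrnaW <- lnorm(2L)
        channels <- rbind(channels, data.frame(
            channel = c("syn-mRNA-01", "syn-mRNA-02"),
            type = "decoy-mRNA",
            source = as.character(mrnaDb),
            mirna = NA_character_,
            mass = mix[["mRNA"]] * mrnaW,
            stringsAsFactors = FALSE))
        channels$mass <- channels$mass / sum(channels$mass)

        ## sample sheet with true cluster labels
        pairs <- sprintf("P%02d", seq_len(cfg$n_pairs))
        samples <- data.frame(
            sample_id = c(sprintf("T%02d", seq_len(cfg$n_pairs)),
                          sprintf("N%02d", seq_len(cfg$n_pairs)),
                          if (cfg$n_controls > 0L)
                              sprintf("C%02d", seq_len(cfg$n_controls))),
            group = c(rep("HCC", cfg$n_pairs), rep("ANL", cfg$n_pairs),
                      rep("CTRL", cfg$n_controls)),
            pair_id = c(pairs, pairs, rep(NA_character_, cfg$n_controls)),
            stringsAsFactors = FALSE)
        nHR <- max(1L, round(cfg$highrisk_frac * cfg$n_pairs))
        hrTumours <- sample(sprintf("T%02d", seq_len(cfg$n_pairs)), nHR)
        samples$highrisk <- samples$sample_id %in% hrTumours

        ## shared expression-profile perturbation of the high-risk
        ## cluster over known miRNAs (the emulated cluster-2 analogue);
        ## mass-normalized so the total known-miRNA share and the marker's
        ## own share are preserved -- the marker contrast comes only from
        ## highrisk_boost
        hrProfile <- rep(1, nrow(channels))
        isKnown <- channels$type == "known" &
            channels$channel != marker
        raw <- stats::rlnorm(sum(isKnown), 0, cfg$highrisk_profile_sd)
        raw <- raw * sum(channels$mass[isKnown]) /
            sum(channels$mass[isKnown] * raw)
        hrProfile[isKnown] <- raw

        truth <- list(genome = genome, conservation = cons, loci = loci,
                      dbs = dbs, channels = channels, samples = samples,
                      hrProfile = hrProfile,
                      editing = editPos, marker = marker, config = cfg)
        class(truth) <- "SimTruth"
        truth
    })
}

## expected channel proportions for one sample (before multinomial draw)
.channelProps <- function(truth, sampleRow, jitter = NULL) {
    cfg <- truth$config
    p <- truth$channels$mass
    if (sampleRow$group == "HCC") {
        fc <- cfg$fold_change_spec
        idx <- match(fc$mirna, truth$channels$channel)
        p[idx] <- p[idx] * 2^fc$lfc
        if (isTRUE(sampleRow$highrisk)) {
            p <- p * truth$hrProfile
            m <- match(truth$marker, truth$channels$channel)
            p[m] <- p[m] * cfg$highrisk_boost
        }
    }
    if (!is.null(jitter)) p <- p * jitter
    p / sum(p)
}

#' Simulate clone read libraries from the synthetic reference
#'
#' Draws each sample's clone counts from a multinomial over the read-source
#' channels (baseline log-normal masses, tumour fold changes, high-risk
#' marker boost, per-sample log-normal jitter), then applies 3' end
#' trimming (0-3 nt), configured per-position editing at group-specific
#' rates, and uniform per-base sequencing error. miRNA-derived reads are
#' 18-24 nt after trimming; decoy piRNA fragments are 26-31 nt, truncated
#' into the 18-24 nt window with probability 0.1.
#'
#' @param truth a \code{SimTruth} from \code{\link{generateReference}}
#' @param cfg the same \code{\link{simConfig}} (defaults to
#'   \code{truth$config})
#' @return a list with \code{reads} (data.frame: read_id, sample, seq,
#'   count -- one row per read), \code{counts} (channel x sample true count
#'   matrix) and \code{samples} (the sample sheet)
#' @export
simulateReads <- function(truth, cfg = truth$config) {
    stopifnot(inherits(truth, "SimTruth"))
    withSeed(cfg$seed + 1L, {
        ch <- truth$channels
        nCh <- nrow(ch)
        samples <- truth$samples
        counts <- matrix(0L, nCh, nrow(samples),
                         dimnames = list(ch$channel, samples$sample_id))
        out <- vector("list", nrow(samples))
        trims <- as.integer(names(cfg$trim3_probs))
        readNo <- 0L
        for (s in seq_len(nrow(samples))) {
            row <- samples[s, ]
            jit <- stats::rlnorm(nCh, 0, cfg$sdlog_sample)
            p <- .channelProps(truth, row, jitter = jit)
            n <- stats::rmultinom(1L, cfg$library_size, p)[, 1L]
            counts[, s] <- n
            seqs <- character(cfg$library_size)
            pos <- 0L
            for (k in seq_len(nCh)) {
                if (n[k] == 0L) next
                src <- ch$source[k]
                cnt <- n[k]
                if (ch$type[k] %in% c("known", "opposite", "novel",
                                      "antisense")) {
                    reads <- rep(src, cnt)
                    ## editing before trimming (site may sit near the 3' end)
                    if (ch$type[k] == "known") {
                        rows <- which(truth$editing$mirna == ch$mirna[k])
                        for (r in rows) {
                            rate <- if (row$group == "HCC")
                                truth$editing$rate_hcc[r]
                            else truth$editing$rate_anl[r]
                            hit <- stats::runif(cnt) < rate
                            if (any(hit)) {
                                pp <- truth$editing$pos[r]
                                substr(reads[hit], pp, pp) <-
                                    truth$editing$to[r]
                            }
                        }
                    }
                    tr <- sample(trims, cnt, replace = TRUE,
                                 prob = cfg$trim3_probs)
                    reads <- substr(reads, 1L, nchar(reads) - tr)
                } else if (ch$type[k] == "decoy-piRNA") {
                    len <- sample(26:31, cnt, replace = TRUE)
                    trunc <- stats::runif(cnt) < 0.1
                    len[trunc] <- sample(18:24, sum(trunc), replace = TRUE)
                    maxStart <- nchar(src) - len + 1L
                    st <- floor(stats::runif(cnt) * maxStart) + 1L
                    reads <- substr(rep(src, cnt), st, st + len - 1L)
                } else {
                    len <- sample(18:24, cnt, replace = TRUE)
                    maxStart <- nchar(src) - len + 1L
                    st <- floor(stats::runif(cnt) * maxStart) + 1L
                    reads <- substr(rep(src, cnt), st, st + len - 1L)
                }
                ## sequencing error
                if (cfg$seq_error_rate > 0) {
                    nErr <- stats::rbinom(cnt, nchar(reads),
                                          cfg$seq_error_rate)
                    for (i in which(nErr > 0L)) {
                        for (e in seq_len(nErr[i])) {
                            pp <- sample.int(nchar(reads[i]), 1L)
                            cur <- substr(reads[i], pp, pp)
                            substr(reads[i], pp, pp) <-
                                sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
                        }
                    }
                }
                seqs[(pos + 1L):(pos + cnt)] <- reads
                pos <- pos + cnt
            }
            out[[s]] <- data.frame(
                read_id = sprintf("r%07d", readNo + seq_len(pos)),
                sample = row$sample_id,
                seq = seqs[seq_len(pos)],
                count = 1L,
                stringsAsFactors = FALSE)
            readNo <- readNo + pos
        }
        list(reads = do.call(rbind, out), counts = counts,
             samples = samples)
    })
}

#' Simulate clinical outcomes tied to the true expression clusters
#'
#' Tumour recurrence times are exponential with the baseline hazard
#' multiplied by \code{hazard_ratio} for the high-risk cluster; censoring
#' is independent exponential calibrated so that about \code{censor_rate}
#' of baseline observations are censored (none when \code{censor_rate} is
#' 0). Binary pathological covariates are generated independently of the
#' cluster.
#'
#' @param truth a \code{SimTruth}
#' @param cfg a \code{\link{simConfig}} (defaults to \code{truth$config})
#' @return data.frame: sample_id, time_months, event, covariates
#' @export
simulateClinical <- function(truth, cfg = truth$config) {
    stopifnot(inherits(truth, "SimTruth"))
    withSeed(cfg$seed + 2L, {
        tumours <- truth$samples[truth$samples$group == "HCC", ]
        n <- nrow(tumours)
        rate <- cfg$base_hazard * ifelse(tumours$highrisk,
                                         cfg$hazard_ratio, 1)
        tEvent <- stats::rexp(n, rate)
        if (cfg$censor_rate > 0) {
            cRate <- cfg$base_hazard * cfg$censor_rate / (1 - cfg$censor_rate)
            tCens <- stats::rexp(n, cRate)
        } else {
            tCens <- rep(Inf, n)
        }
        time <- pmin(tEvent, tCens)
        event <- as.integer(tEvent <= tCens)
        cov <- matrix(stats::rbinom(n * cfg$n_covariates, 1L, 0.5), n,
                      dimnames = list(NULL,
                          sprintf("path%02d", seq_len(cfg$n_covariates))))
        data.frame(sample_id = tumours$sample_id,
                   time_months = time, event = event, cov,
                   stringsAsFactors = FALSE)
    })
}

#' Simulate a normalized expression matrix directly
#'
#' Light-weight generator for the expression statistics: per-gene
#' log-normal baseline masses, optional planted tumour log2 fold changes,
#' per-sample jitter, multinomial clone counts and per-1000 normalization.
#' Columns are \code{n_pairs} tumours followed by \code{n_pairs} normals.
#'
#' @param nGenes number of genes (miRNAs)
#' @param nPairs sample pairs
#' @param lfc numeric vector of length \code{nGenes} of tumour log2 fold
#'   changes (0 = null)
#' @param librarySize clone reads per sample
#' @param sdlogGene,sdlogSample abundance heterogeneity / sample jitter
#' @param seed RNG seed
#' @return list: \code{normalized} (matrix), \code{counts}, \code{groups},
#'   \code{pairIds}
#' @export
simulateCountMatrix <- function(nGenes, nPairs, lfc = rep(0, nGenes),
                                librarySize = 2000L, sdlogGene = 1.5,
                                sdlogSample = 0.3, seed = 1L) {
    stopifnot(length(lfc) == nGenes)
    withSeed(seed, {
        base <- stats::rlnorm(nGenes, 0, sdlogGene)
        base <- base / sum(base)
        nS <- 2L * nPairs
        groups <- rep(c("HCC", "ANL"), each = nPairs)
        counts <- matrix(0L, nGenes, nS)
        for (s in seq_len(nS)) {
            p <- base * 2^(lfc * (groups[s] == "HCC")) *
                stats::rlnorm(nGenes, 0, sdlogSample)
            counts[, s] <- stats::rmultinom(1L, librarySize, p / sum(p))[, 1L]
        }
        rownames(counts) <- sprintf("gene%04d", seq_len(nGenes))
        colnames(counts) <- c(sprintf("T%02d", seq_len(nPairs)),
                              sprintf("N%02d", seq_len(nPairs)))
        normalized <- t(t(counts) * 1000 / colSums(counts))
        list(normalized = normalized, counts = counts, groups = groups,
             pairIds = rep(sprintf("P%02d", seq_len(nPairs)), 2L))
    })
}
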