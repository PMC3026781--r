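## minimal genome-class annotation rows for grouping tests
candRow <- function(seq, start, strand = "+", sample = "S1", count = 1L,
                    id = seq) {
    data.frame(read_id = id, sample = sample, seq = seq, count = count,
               db_class = "genome", ref_id = NA_character_, identity = 1,
               offset = NA_integer_, end5 = NA_integer_, end3 = NA_integer_,
               precursor_only = FALSE, genome_start = start,
               genome_end = start + nchar(seq) - 1L,
               genome_strand = strand, stringsAsFactors = FALSE)
}

test_that("overlapping same-strand reads merge into one locus", {
    ann <- rbind(candRow(strrep("A", 22L), 100L, id = "r1"),
                 candRow(strrep("C", 22L), 105L, id = "r2"))
    g <- groupCandidates(ann, minReads = 1L)
    expect_equal(nrow(g), 1L)
    expect_equal(g$start, 100L)
    expect_equal(g$end, 126L)

    ## same intervals on opposite strands stay separate
    ann2 <- rbind(candRow(strrep("A", 22L), 100L, id = "r1"),
                  candRow(strrep("C", 22L), 105L, strand = "-", id = "r2"))
    g2 <- groupCandidates(ann2, minReads = 1L)
    expect_equal(nrow(g2), 2L)
})

test_that("grouping is single linkage over the overlap graph", {
    ## a overlaps b, b overlaps c, a does not overlap c -> one group
    ann <- rbind(candRow(strrep("A", 20L), 100L, id = "a"),
                 candRow(strrep("C", 20L), 115L, id = "b"),
                 candRow(strrep("G", 20L), 130L, id = "c"))
    g <- groupCandidates(ann, minReads = 1L)
    expect_equal(nrow(g), 1L)
    expect_equal(c(g$start, g$end), c(100L, 149L))

    ## brute-force connected components agree
    iv <- data.frame(s = c(100L, 115L, 130L), e = c(119L, 134L, 149L))
    adj <- outer(seq_len(3), seq_len(3), Vectorize(function(i, j)
        iv$s[i] <= iv$e[j] & iv$s[j] <= iv$e[i]))
    comp <- seq_len(3)
    for (it in 1:3) for (i in 1:3) for (j in 1:3)
        if (adj[i, j]) comp[j] <- comp[i] <- min(comp[i], comp[j])
    expect_equal(length(unique(comp)), nrow(g))
})

test_that("the representative sequence has the top clone count with
           lexicographic ties", {
    ann <- rbind(candRow("CCCCCCCCCCCCCCCCCCCC", 100L, count = 2L, id = "r1"),
                 candRow("AAAAAAAAAAAAAAAAAAAA", 103L, count = 2L, id = "r2"),
                 candRow("GGGGGGGGGGGGGGGGGGGG", 106L, count = 1L, id = "r3"))
    g <- groupCandidates(ann)
    expect_equal(g$rep_seq, "AAAAAAAAAAAAAAAAAAAA")
    expect_equal(g$support, 5L)
    expect_equal(g$n_seqs, 3L)
})

test_that("groups below the support threshold are dropped", {
    ann <- rbind(candRow(strrep("A", 20L), 100L, id = "r1"),
                 candRow(strrep("C", 20L), 500L, count = 3L, id = "r2"))
    g <- groupCandidates(ann, minReads = 2L)
    expect_equal(nrow(g), 1L)
    expect_equal(g$start, 500L)
})

test_that("candidate input order never changes the calls", {
    st <- smallStudy()
    calls1 <- suppressWarnings(discoverNovel(
        st$annot, st$truth$loci, st$truth$genome,
        track = st$truth$conservation))
    set.seed(99)
    shuffled <- st$annot[sample(nrow(st$annot)), ]
    calls2 <- suppressWarnings(discoverNovel(
        shuffled, st$truth$loci, st$truth$genome,
        track = st$truth$conservation))
    expect_identical(calls1, calls2)
})

test_that("the cascade assigns exactly one class per group and recovers
           the planted classes end to end", {
    st <- smallStudy()
    truth <- st$truth
    calls <- discoverNovel(st$annot, truth$loci, truth$genome,
                           track = truth$conservation)
    expect_true(all(calls$class %in%
                    c("novel", "opposite", "antisense", "rejected")))
    expect_true(all(!is.na(calls$reason[calls$class == "rejected"])))
    expect_true(all(is.na(calls$reason[calls$class != "rejected"])))

    loci <- truth$loci
    overlap <- function(cls, a, b) any(
        GenomicRanges::start(loci[loci$class == cls]) <= b &
        GenomicRanges::end(loci[loci$class == cls]) >= a)
    for (i in seq_len(nrow(calls))) {
        if (calls$class[i] == "novel")
            expect_true(overlap("novel-hairpin", calls$start[i],
                                calls$end[i]))
        if (calls$class[i] == "opposite")
            expect_true(overlap("known-precursor", calls$start[i],
                                calls$end[i]))
        if (calls$class[i] == "antisense") {
            expect_equal(calls$strand[i], "-")
            expect_true(overlap("known-mature", calls$start[i],
                                calls$end[i]))
        }
    }
    ## no decoy locus is ever called novel
    dec <- loci[grepl("^decoy", loci$class)]
    nov <- calls[calls$class == "novel", ]
    for (j in seq_len(nrow(nov)))
        expect_false(any(GenomicRanges::start(dec) <= nov$end[j] &
                         GenomicRanges::end(dec) >= nov$start[j]))
    ## every planted novel with >= 2 supporting clones is recovered
    novLoci <- loci[loci$class == "novel-hairpin"]
    cnt <- rowSums(st$reads$counts)
    for (i in seq_along(novLoci)) {
        if (cnt[novLoci$id[i]] >= 2L)
            expect_true(any(nov$start <= GenomicRanges::end(novLoci)[i] &
                            nov$end >= GenomicRanges::start(novLoci)[i]),
                        info = novLoci$id[i])
    }
})

test_that("structurally sound but unconserved hairpins are rejected as
           not-conserved, and a missing track disables novel calls", {
    set.seed(71)
    arm <- randSeq(22)
    hp <- paste0(arm, strrep("A", 9L), revcompChr(arm))
    genome <- paste0(randSeq(200), hp, randSeq(200))
    ann <- candRow(arm, 201L, count = 3L)
    knowns <- GenomicRanges::GRanges("chrS", IRanges::IRanges(1, 1),
                                     strand = "+", id = "x",
                                     class = "none", mirna = "x",
                                     mature_start = 1L, mature_end = 1L)

    lowTrack <- rep(0.1, nchar(genome))
    calls <- classifyCandidates(groupCandidates(ann, minReads = 1L),
                                knowns, genome, track = lowTrack)
    expect_equal(calls$class, "rejected")
    expect_equal(calls$reason, "not-conserved")
    expect_true(calls$crit_a & calls$crit_b & calls$crit_c)

    highTrack <- rep(0.95, nchar(genome))
    calls2 <- classifyCandidates(groupCandidates(ann, minReads = 1L),
                                 knowns, genome, track = highTrack)
    expect_equal(calls2$class, "novel")

    expect_warning(
        calls3 <- classifyCandidates(groupCandidates(ann, minReads = 1L),
                                     knowns, genome, track = NULL),
        "novel calls disabled")
    expect_equal(calls3$class, "rejected")
    expect_equal(calls3$reason, "no-conservation-track")
})

test_that("opposite-arm groups are recognized by position across the
           terminal loop", {
    st <- smallStudy()
    truth <- st$truth
    calls <- discoverNovel(st$annot, truth$loci, truth$genome,
                           track = truth$conservation)
    opp <- calls[calls$class == "opposite", ]
    expect_gt(nrow(opp), 0L)
    loci <- truth$loci
    for (i in seq_len(nrow(opp))) {
        pre <- loci[loci$class == "known-precursor" &
                    GenomicRanges::start(loci) <= opp$end[i] &
                    GenomicRanges::end(loci) >= opp$start[i]]
        expect_equal(length(pre), 1L)
        ## the group does not overlap the annotated mature span
        expect_true(opp$start[i] > pre$mature_end ||
                    opp$end[i] < pre$mature_start)
    }
})
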