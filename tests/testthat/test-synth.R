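test_that("reference generation is deterministic and self-consistent", {
    cfg <- simConfig(seed = 3L, n_pairs = 2L, library_size = 400L)
    t1 <- generateReference(cfg)
    t2 <- generateReference(cfg)
    expect_identical(as.character(t1$genome), as.character(t2$genome))
    expect_identical(t1$channels, t2$channels)
    expect_identical(t1$conservation, t2$conservation)

    ## database holds one mature and one precursor entry per known miRNA
    expect_equal(sum(!grepl("-pre$", names(t1$dbs$miRNA))),
                 cfg$n_known_mirnas)
    expect_equal(sum(grepl("-pre$", names(t1$dbs$miRNA))),
                 cfg$n_known_mirnas)

    ## every precursor is planted verbatim in the genome
    g <- as.character(t1$genome)
    pre <- t1$dbs$miRNA[grepl("-pre$", names(t1$dbs$miRNA))]
    for (p in as.character(pre))
        expect_true(grepl(p, g, fixed = TRUE))

    ## conservation track covers the genome; planted bands hold
    expect_equal(length(t1$conservation), cfg$genome_length)
    loci <- t1$loci
    nov <- loci[loci$class == "novel-hairpin"]
    for (i in seq_along(nov))
        expect_gte(min(t1$conservation[
            GenomicRanges::start(nov)[i]:GenomicRanges::end(nov)[i]]), 0.9)
    dec <- loci[grepl("^decoy", loci$class)]
    for (i in seq_along(dec))
        expect_lt(max(t1$conservation[
            GenomicRanges::start(dec)[i]:GenomicRanges::end(dec)[i]]), 0.5)
})

test_that("infeasible or invalid configurations fail with the constraint", {
    expect_error(simConfig(seed = 1, library_size = 0), "library_size")
    expect_error(simConfig(seed = 1, censor_rate = 1.2), "rates")
    expect_error(
        simConfig(seed = 1, editing_spec = data.frame(
            mirna = "nope", pos = 6L, from = "A", to = "G",
            rate_hcc = 0.5, rate_anl = 0.5)),
        "unknown miRNA")
    cfg <- simConfig(seed = 1, genome_length = 5000L)
    expect_error(generateReference(cfg), "genome_length")
})

test_that("simulated reads respect lengths, counts and determinism", {
    cfg <- simConfig(seed = 5L, n_pairs = 2L, library_size = 500L)
    truth <- generateReference(cfg)
    r1 <- simulateReads(truth)
    r2 <- simulateReads(truth)
    expect_identical(r1$reads, r2$reads)

    ## per-sample true counts sum to the library size
    expect_true(all(colSums(r1$counts) == cfg$library_size))

    ## all read lengths in [18, 31]; piRNA fragments explain the >24 tail
    expect_true(all(nchar(r1$reads$seq) >= 18L))
    expect_true(all(nchar(r1$reads$seq) <= 31L))

    ## without piRNA decoys every read is 18-24 nt
    mix <- c(known = 0.85, opposite = 0.02, novel = 0.03,
             antisense = 0.007, piRNA = 0, mRNA = 0.01, otherDecoy = 0.083)
    cfg2 <- simConfig(seed = 6L, n_pairs = 1L, library_size = 400L,
                      class_mix = mix)
    r3 <- simulateReads(generateReference(cfg2))
    expect_true(all(nchar(r3$reads$seq) %in% 18:24))
})

test_that("zero editing and zero error give exact substrings of sources", {
    cfg <- simConfig(seed = 7L, n_pairs = 1L, library_size = 300L,
                     seq_error_rate = 0,
                     editing_spec = data.frame(mirna = character(0),
                                               pos = integer(0),
                                               from = character(0),
                                               to = character(0),
                                               rate_hcc = numeric(0),
                                               rate_anl = numeric(0)))
    truth <- generateReference(cfg)
    rd <- simulateReads(truth)
    srcs <- truth$channels$source
    ok <- vapply(rd$reads$seq, function(s)
        any(grepl(s, srcs, fixed = TRUE)), logical(1))
    expect_true(all(ok))
})

test_that("editing rates are realized per group", {
    ## one miRNA, rate 1.0 at +6: every read carries G at position 6
    es <- data.frame(mirna = "syn-miR-01", pos = 6L, from = "A", to = "G",
                     rate_hcc = 1.0, rate_anl = 1.0)
    mix <- c(known = 1, opposite = 0, novel = 0, antisense = 0,
             piRNA = 0, mRNA = 0, otherDecoy = 0)
    cfg <- simConfig(seed = 8L, n_pairs = 1L, n_known_mirnas = 1L,
                     n_novel_hairpins = 0L, n_decoys = 0L,
                     n_opposite = 0L, n_antisense = 0L,
                     library_size = 300L, seq_error_rate = 0,
                     editing_spec = es, class_mix = mix,
                     fold_change_spec = data.frame(mirna = character(0),
                                                   lfc = numeric(0)))
    truth <- generateReference(cfg)
    rd <- simulateReads(truth)
    expect_true(all(substr(rd$reads$seq, 6L, 6L) == "G"))

    ## rate 0.3, ~1000 reads: observed fraction within the central 99%
    ## binomial interval
    es$rate_hcc <- es$rate_anl <- 0.3
    cfg2 <- simConfig(seed = 9L, n_pairs = 1L, n_known_mirnas = 1L,
                      n_novel_hairpins = 0L, n_decoys = 0L,
                      n_opposite = 0L, n_antisense = 0L,
                      library_size = 500L, seq_error_rate = 0,
                      editing_spec = es, class_mix = mix,
                      fold_change_spec = data.frame(mirna = character(0),
                                                    lfc = numeric(0)))
    rd2 <- simulateReads(generateReference(cfg2))
    n <- nrow(rd2$reads)          # 1000 reads over the two samples
    edited <- sum(substr(rd2$reads$seq, 6L, 6L) == "G")
    bounds <- qbinom(c(0.005, 0.995), n, 0.3)
    expect_gte(edited, bounds[1L])
    expect_lte(edited, bounds[2L])
})

test_that("clinical outcomes follow the configured censoring and hazard", {
    cfg <- simConfig(seed = 10L, n_pairs = 22L, censor_rate = 0,
                     highrisk_frac = 0.5, library_size = 100L)
    truth <- generateReference(cfg)
    clin <- simulateClinical(truth)
    expect_true(all(clin$event == 1L))
    expect_equal(nrow(clin), 22L)

    ## hazard_ratio 8 with 11 vs 11: the high-risk arm's median recurrence
    ## time is shorter in at least 95% of seeds
    hr <- truth$samples$highrisk[match(clin$sample_id,
                                       truth$samples$sample_id)]
    expect_equal(sum(hr), 11L)
    wins <- 0L
    for (s in 1:200) {
        cfg2 <- cfg
        cfg2$seed <- 1000L + s
        cl <- simulateClinical(truth, cfg2)
        if (median(cl$time_months[hr]) < median(cl$time_months[!hr]))
            wins <- wins + 1L
    }
    expect_gte(wins / 200, 0.95)
})

test_that("the study writes deterministically and the config round-trips", {
    cfg <- simConfig(seed = 12L, n_pairs = 1L, library_size = 200L)
    truth <- generateReference(cfg)
    rd <- simulateReads(truth)
    cl <- simulateClinical(truth)
    d1 <- tempfile("study1"); d2 <- tempfile("study2")
    writeStudy(truth, rd, cl, d1)
    writeStudy(truth, rd, cl, d2)
    f1 <- list.files(d1, recursive = TRUE)
    expect_identical(f1, list.files(d2, recursive = TRUE))
    for (f in f1)
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         info = f)

    cfg2 <- readSimConfig(file.path(d1, "config.yaml"))
    expect_equal(cfg2$seed, cfg$seed)
    expect_equal(cfg2$class_mix, cfg$class_mix)
    expect_equal(cfg2$editing_spec, cfg$editing_spec)
    ## the round-tripped config reproduces the run
    expect_identical(as.character(generateReference(cfg2)$genome),
                     as.character(truth$genome))
    unlink(c(d1, d2), recursive = TRUE)
})
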