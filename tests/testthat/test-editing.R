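MAT <- "TGAGGTAGTAGGTTGTATAGTT"    # 22 nt reference

test_that("alignment to the mature reference calls substitutions at
           +1..+18 and ignores the 3'-variable end", {
    ## identical read: no calls
    al <- alignToMature(MAT, MAT)
    expect_equal(nrow(al$calls), 0L)
    expect_equal(al$offset, 1L)

    ## single A>G substitution (reference +10 is A): called as A-to-I
    r <- MAT
    substr(r, 10L, 10L) <- "G"
    al <- alignToMature(r, MAT)
    expect_equal(al$calls$pos, 10L)
    expect_equal(al$calls$from, "A")
    expect_equal(al$calls$to, "G")
    expect_equal(al$calls$class, "A-to-I")

    ## read shorter by 3 nt at the 3' end: no calls (3' variation)
    al <- alignToMature(substr(MAT, 1L, 19L), MAT)
    expect_equal(nrow(al$calls), 0L)
    expect_equal(max(al$covered), 18L)

    ## substitution beyond +18 is never called
    r2 <- MAT
    substr(r2, 20L, 20L) <- "C"
    al2 <- alignToMature(r2, MAT)
    expect_equal(nrow(al2$calls), 0L)

    ## 5' offset up to 2 nt is recovered
    al3 <- alignToMature(substr(MAT, 3L, 22L), MAT)
    expect_equal(al3$offset, 3L)
    expect_equal(nrow(al3$calls), 0L)

    ## more than 2 substitutions in the profiled window: excluded
    r4 <- MAT
    substr(r4, 3L, 3L) <- "C"; substr(r4, 7L, 7L) <- "C"
    substr(r4, 11L, 11L) <- "C"
    expect_null(alignToMature(r4, MAT))
    ## unalignable read: excluded
    expect_null(alignToMature(randSeq(22), MAT))
})

test_that("modification classes use the editing nomenclature", {
    r <- MAT; substr(r, 2L, 2L) <- "C"       # G>C at +2
    al <- alignToMature(r, MAT)
    expect_equal(al$calls$class, "G-to-C")
    ## reference bases: +10 A, +9 T, +13 T, +11 G
    cases <- data.frame(pos = c(10L, 9L, 13L, 11L),
                        to = c("G", "C", "A", "A"),
                        class = c("A-to-I", "U-to-C", "U-to-A", "G-to-A"))
    for (i in seq_len(nrow(cases))) {
        r <- MAT
        substr(r, cases$pos[i], cases$pos[i]) <- cases$to[i]
        al <- alignToMature(r, MAT)
        expect_equal(al$calls$class, cases$class[i], info = i)
    }
})

test_that("clone-count fractions are exact and gated by minReads and the
           report threshold", {
    ## 31 of 100 clones edited at +10 (A>G) -> fraction 0.31
    edited <- MAT; substr(edited, 10L, 10L) <- "G"
    reads <- data.frame(seq = c(edited, MAT), count = c(31L, 69L),
                        group = "HCC")
    prof <- modificationProfile(reads, MAT, mirna = "m")
    expect_equal(prof$sites$fraction, 0.31)
    expect_equal(prof$sites$n_covering, 100)
    expect_true(prof$sites$seed == FALSE)
    expect_equal(unname(prof$groupFraction["HCC"]), 0.31)

    ## all reads reference-identical -> empty call list
    prof0 <- modificationProfile(data.frame(seq = MAT, count = 50L,
                                            group = "HCC"), MAT)
    expect_equal(nrow(prof0$sites), 0L)

    ## a group below minReads gets an undefined fraction
    reads2 <- rbind(reads, data.frame(seq = edited, count = 4L,
                                      group = "ANL"))
    prof2 <- modificationProfile(reads2, MAT, mirna = "m")
    expect_true(is.na(prof2$sites$fraction[prof2$sites$group == "ANL"]))

    ## sub-threshold sites are not reported
    reads3 <- data.frame(seq = c(edited, MAT), count = c(3L, 97L),
                         group = "HCC")
    prof3 <- modificationProfile(reads3, MAT)
    expect_equal(nrow(prof3$sites), 0L)

    ## a SNP mask silences the site
    prof4 <- modificationProfile(reads, MAT, mirna = "m",
                                 snpMask = data.frame(mirna = "m", pos = 10L))
    expect_equal(nrow(prof4$sites), 0L)

    ## seed positions +2..+8 are flagged
    seedEd <- MAT; substr(seedEd, 5L, 5L) <- "C"
    prof5 <- modificationProfile(
        data.frame(seq = c(seedEd, MAT), count = c(20L, 80L),
                   group = "HCC"), MAT)
    expect_true(all(prof5$sites$seed))
})

test_that("editing rates are recovered with small error at n = 1000", {
    set.seed(33)
    for (rate in c(0.1, 0.5, 0.9)) {
        edited <- MAT; substr(edited, 10L, 10L) <- "G"
        nEd <- rbinom(1L, 1000L, rate)
        reads <- data.frame(seq = c(edited, MAT),
                            count = c(nEd, 1000L - nEd), group = "HCC")
        prof <- modificationProfile(reads, MAT)
        expect_lt(abs(prof$sites$fraction - rate), 0.05)
    }
})

test_that("expression forms split into nonmodified/modified/total and
           conserve counts", {
    edited <- MAT; substr(edited, 10L, 10L) <- "G"
    ann <- data.frame(read_id = c("r1", "r2"), sample = "S1",
                      seq = c(edited, MAT), count = c(3L, 7L),
                      db_class = "miRNA", ref_id = "m", identity = 1,
                      offset = 1L, end5 = 0L, end3 = 0L,
                      precursor_only = FALSE, genome_start = NA,
                      genome_end = NA, genome_strand = NA)
    se <- splitExpressionForms(ann, c(m = MAT))
    counts <- SummarizedExperiment::assay(se, "counts")
    expect_equal(unname(counts[, "S1"]), c(7, 3, 10))
    rd <- SummarizedExperiment::rowData(se)
    expect_equal(rd$form, c("nonmodified", "modified", "total"))

    ## no modifications: modified row zero, total = nonmodified
    ann0 <- ann[2L, ]
    se0 <- splitExpressionForms(ann0, c(m = MAT))
    c0 <- SummarizedExperiment::assay(se0, "counts")
    expect_equal(unname(c0[, "S1"]), c(7, 0, 7))
})

test_that("modified + nonmodified = total for every miRNA and sample on
           simulated data, and normalized totals sum to 1000", {
    st <- smallStudy()
    mature <- st$truth$dbs$miRNA[!grepl("-pre$",
                                        names(st$truth$dbs$miRNA))]
    se <- splitExpressionForms(st$annot, mature)
    rd <- SummarizedExperiment::rowData(se)
    counts <- SummarizedExperiment::assay(se, "counts")
    normalized <- SummarizedExperiment::assay(se, "normalized")
    for (m in unique(rd$mirna)) {
        i <- which(rd$mirna == m)
        expect_equal(counts[i[rd$form[i] == "total"], ],
                     counts[i[rd$form[i] == "nonmodified"], ] +
                         counts[i[rd$form[i] == "modified"], ])
    }
    tot <- normalized[rd$form == "total", , drop = FALSE]
    expect_true(all(abs(colSums(tot) - 1000) < 1e-9))
})

test_that("form splitting changes clustering when groups differ only in
           editing", {
    ## two groups of samples with identical total clone counts; group B
    ## expresses miRNA m1 half-edited, group A unedited; m2 is a stable
    ## second miRNA so sample profiles have enough variation to correlate
    edited <- MAT; substr(edited, 10L, 10L) <- "G"
    samples <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
    rows <- list()
    for (s in names(samples)) {
        ed <- if (samples[[s]] == "B") 50L else 0L
        rows[[s]] <- data.frame(
            read_id = paste0(s, 1:3), sample = s,
            seq = c(edited, MAT, "ACGTACGTACGTACGTACGTAC"),
            count = c(ed, 100L - ed, 30L),
            db_class = "miRNA", ref_id = c("m1", "m1", "m2"),
            identity = 1, offset = 1L, end5 = 0L, end3 = 0L,
            precursor_only = FALSE, genome_start = NA, genome_end = NA,
            genome_strand = NA)
    }
    ann <- do.call(rbind, rows)
    se <- splitExpressionForms(ann, c(m1 = MAT,
                                      m2 = "ACGTACGTACGTACGTACGTAC"))
    rd <- SummarizedExperiment::rowData(se)
    norm <- SummarizedExperiment::assay(se, "normalized")

    ## totals are identical across samples: no separation signal
    tot <- norm[rd$form == "total", ]
    expect_true(all(apply(tot, 1L, function(x) diff(range(x)) == 0)))

    ## form-aware rows separate the groups at k = 2
    forms <- norm[rd$form %in% c("nonmodified", "modified"), ]
    forms <- forms[rowSums(forms) > 0, , drop = FALSE]
    cl <- clusterSamples(forms, k = 2L)
    expect_equal(adjustedRand(cl$labels, samples[colnames(forms)]), 1)
})
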