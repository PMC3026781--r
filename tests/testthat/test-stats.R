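test_that("prevalence filter drops rows below, and keeps rows at, the
           threshold", {
    m <- rbind(quarter = c(5, 0, 0, 0),      # 1 of 4 = 25%: retained
               zero = c(0, 0, 0, 0),         # dropped
               full = c(1, 2, 3, 4))
    out <- prevalenceFilter(m)
    expect_setequal(rownames(out), c("quarter", "full"))

    m8 <- matrix(0, 1, 8, dimnames = list("oneofeight", NULL))
    m8[1, 1] <- 5                            # 12.5% < 25%: dropped
    expect_equal(nrow(prevalenceFilter(m8)), 0L)
})

test_that("clustering merges identical samples first and recovers
           separated groups", {
    set.seed(61)
    base <- matrix(rlnorm(20 * 4, 3, 1), 20, 4,
                   dimnames = list(sprintf("g%02d", 1:20),
                                   c("S1", "S2", "S3", "S4")))
    base[, 2L] <- base[, 1L]                 # identical pair
    cl <- clusterSamples(base, k = 3L)
    expect_equal(cl$hclust$height[1L], 0, tolerance = 1e-12)
    expect_equal(sort(cl$hclust$merge[1L, ]), c(-2L, -1L))

    ## two well-separated sample groups (distinct expression profiles,
    ## small within-group jitter): cut at k = 2 has ARI 1
    profA <- rlnorm(30, 3, 1.5)
    profB <- rlnorm(30, 3, 1.5)
    jit <- function() exp(rnorm(30, 0, 0.1))
    m <- cbind(sapply(1:5, function(i) profA * jit()),
               sapply(1:5, function(i) profB * jit()))
    colnames(m) <- sprintf("S%02d", 1:10)
    rownames(m) <- sprintf("g%02d", 1:30)
    truthLab <- rep(c(1, 2), each = 5)
    cl2 <- clusterSamples(m, k = 2L)
    expect_equal(adjustedRand(cl2$labels, truthLab), 1)
})

test_that("the high-risk flag marks exactly the all-tumour cluster with
           marker expression above the threshold", {
    set.seed(62)
    groups <- stats::setNames(rep(c("HCC", "ANL"), each = 6L),
                              sprintf("S%02d", 1:12))
    ## three distinct expression profiles: high-risk tumours (S01-S03,
    ## marker > 250), other tumours (S04-S06), normals (S07-S12)
    profiles <- replicate(3L, rlnorm(30, 3, 1.5))
    jit <- function() exp(rnorm(30, 0, 0.1))
    cols <- lapply(1:12, function(i) {
        p <- if (i <= 3) 1L else if (i <= 6) 2L else 3L
        profiles[, p] * jit()
    })
    m <- do.call(cbind, cols)
    dimnames(m) <- list(c("marker", sprintf("g%02d", 2:30)), names(groups))
    m["marker", 1:3] <- c(430, 480, 520)
    m["marker", 4:12] <- 50
    cl <- clusterSamples(m, k = 3L, groups = groups, marker = "marker",
                         markerThreshold = 250)
    expect_equal(sum(cl$highRisk), 1L)
    expect_setequal(cl$highRiskSamples, c("S01", "S02", "S03"))
})

test_that("the correlation distance is invariant under library-size
           (column) and global rescaling", {
    set.seed(63)
    m <- matrix(rlnorm(25 * 6, 2, 1), 25, 6,
                dimnames = list(NULL, sprintf("S%d", 1:6)))
    cl1 <- clusterSamples(m, k = 3L, log2 = FALSE)
    m2 <- t(t(m) * runif(6, 0.5, 2))         # per-sample depth rescaling
    cl2 <- clusterSamples(m2, k = 3L, log2 = FALSE)
    expect_equal(cl1$hclust$merge, cl2$hclust$merge)
    expect_equal(cl1$labels, cl2$labels)
    cl3 <- clusterSamples(m * 7, k = 3L, log2 = FALSE)
    expect_equal(cl1$labels, cl3$labels)
})

test_that("SAM d statistics are zero for equal group means and invariant
           to relabeling within groups", {
    set.seed(64)
    m <- matrix(rlnorm(20 * 8, 3, 1), 20, 8,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("S%d", 1:8)))
    groups <- rep(c("HCC", "ANL"), each = 4L)
    m[1L, ] <- rep(c(5, 6, 7, 8), 2L)        # identical group profiles
    r <- samTest(m, groups, nPerm = 50L, seed = 1L)
    expect_equal(unname(r$d["g01"]), 0)

    perm <- c(sample(1:4), sample(5:8))      # shuffle within groups
    r2 <- samTest(m[, perm], groups, nPerm = 50L, seed = 1L)
    expect_equal(sort(r$d), sort(r2$d))
})

test_that("SAM recovers a strong planted effect and reports a finite
           zero-false-positive delta", {
    sim <- simulateCountMatrix(60, 10, lfc = c(rep(3, 4), rep(0, 56)),
                               seed = 9L)
    r <- samTest(sim$normalized, sim$groups, nPerm = 200L, seed = 2L)
    expect_true(all(sprintf("gene%04d", 1:4) %in% r$significant))
    expect_true(is.finite(r$delta))
    expect_true(all(sprintf("gene%04d", 1:4) %in% r$up))

    ## paired mode agrees on the planted genes
    rp <- samTest(sim$normalized, sim$groups, paired = TRUE,
                  pairIds = sim$pairIds, nPerm = 200L, seed = 2L)
    expect_true(all(sprintf("gene%04d", 1:4) %in% rp$significant))
})

test_that("paired t handles degenerate rows by the stated conventions and
           matches t.test elsewhere", {
    set.seed(65)
    n <- 6L
    m <- matrix(rlnorm(10 * 2 * n, 3, 1), 10, 2L * n)
    colnames(m) <- c(sprintf("T%d", 1:n), sprintf("N%d", 1:n))
    groups <- rep(c("HCC", "ANL"), each = n)
    pairs <- rep(sprintf("P%d", 1:n), 2L)
    m[1L, ] <- rep(c(10, 20, 30, 40, 50, 60), 2L)  # all differences zero
    ## constant nonzero difference on the log2(x+1) scale
    m[2L, 1:n] <- 4 * (m[2L, (n + 1):(2L * n)] + 1) - 1

    tt <- pairedTTest(m, groups, pairs)
    expect_equal(tt$t[1L], 0)
    expect_equal(tt$p[1L], 1)
    expect_true(tt$flagged[1L])
    expect_true(is.na(tt$p[2L]) && tt$flagged[2L])

    for (i in 3:10) {
        ref <- t.test(log2(m[i, 1:n] + 1), log2(m[i, (n + 1):(2 * n)] + 1),
                      paired = TRUE)
        expect_equal(tt$t[i], unname(ref$statistic), tolerance = 1e-10)
        expect_equal(tt$p[i], ref$p.value, tolerance = 1e-10)
    }

    expect_error(pairedTTest(m, groups, c(pairs[-1L], "PX")), "unpaired")
})

test_that("paired t p-values are uniform under the null", {
    sim <- simulateCountMatrix(2000, 10, librarySize = 20000L, seed = 17L)
    tt <- pairedTTest(sim$normalized, sim$groups, sim$pairIds)
    ks <- suppressWarnings(ks.test(tt$p[!tt$flagged], "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("Fisher enrichment matches exhaustive hypergeometric
           enumeration and ranks by p", {
    ## the worked 2x2 example: (8,2; 2,8) in a universe of 20
    universe <- sprintf("g%02d", 1:20)
    target <- universe[1:10]
    terms <- list(hot = universe[c(1:8, 11, 12)],
                  cold = universe[13:16],
                  all = universe)
    out <- fisherEnrichment(target, universe, terms)
    expect_equal(out$p[out$term == "hot"],
                 bruteFisherP(8L, 2L, 2L, 8L), tolerance = 1e-12)
    expect_equal(out$term[1L], "hot")
    expect_false(is.unsorted(out$p))

    ## random tables with margins <= 30 agree with enumeration
    set.seed(66)
    for (rep in 1:25) {
        N <- sample(10:30, 1L)
        uni <- sprintf("x%02d", seq_len(N))
        tg <- sample(uni, sample(2:(N - 2L), 1L))
        tm <- sample(uni, sample(2:(N - 2L), 1L))
        a <- length(intersect(tg, tm))
        res <- fisherEnrichment(tg, uni, list(t = tm))
        expect_equal(res$p,
                     bruteFisherP(a, length(tg) - a, length(tm) - a,
                                  N - length(tg) - length(tm) + a),
                     tolerance = 1e-9, info = rep)
    }

    expect_error(fisherEnrichment(character(0), universe, terms), "empty")
    expect_error(fisherEnrichment("zzz", universe, terms), "subset")
})
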