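test_that("PSI matches the min-sum definition on worked examples", {
    expect_equal(psi(c(0.6, 0.3, 0.1), c(0.4, 0.4, 0.2)), 80)
    expect_equal(psi(c(1, 0), c(0, 1)), 0)
    set.seed(41)
    p <- randomProfile(12)
    expect_equal(psi(p, p), 100)
})

test_that("PSI is symmetric and tied to the L1 metric", {
    set.seed(42)
    for (i in 1:200) {
        p <- randomProfile(15); q <- randomProfile(15)
        v <- psi(p, q)
        expect_equal(v, psi(q, p))
        expect_equal(100 - v, 50 * sum(abs(p - q)), tolerance = 1e-9)
        expect_gte(v, 0); expect_lte(v, 100)
    }
})

test_that("mismatched taxon lists error unless union-aligned", {
    p <- c(a = 0.5, b = 0.5)
    q <- c(b = 0.25, c = 0.75)
    expect_error(psi(p, q), "alignTaxa")
    expect_equal(psi(p, q, alignTaxa = TRUE), 100 * 0.25)
    expect_error(psi(c(0.5, 0.5), c(0.2, 0.2, 0.6), alignTaxa = TRUE),
                 "named")
    expect_error(psi(c(0.5, 0.6), c(0.5, 0.5)), "proportion")
})

test_that("interval pairing counts calendar days, not sample indices", {
    m <- matrix(rgamma(4 * 3, 1) + 1, 4, 3,
                dimnames = list(NULL, c("A", "B", "C")))
    cts <- CommunityTimeSeries(m, as.Date("2013-06-01") + 0:3)
    cv <- psiByInterval(cts, labelPartition(rep(1, 4), "2013-06-01"), 3)[["1"]]
    expect_identical(cv@nPairs, c(3L, 2L, 1L))

    # six-day run with day 4 unsampled: the gap removes one 1-day pair and
    # the pair spanning the gap appears at the 2-day interval
    d <- as.Date("2013-06-01") + c(0, 1, 2, 4, 5)
    m2 <- matrix(rgamma(5 * 3, 1) + 1, 5, 3,
                 dimnames = list(NULL, c("A", "B", "C")))
    cts2 <- CommunityTimeSeries(m2, d)
    part <- new("ClusterPartition", dates = d, rawLabels = rep(1L, 5),
                smoothedLabels = rep(1L, 5), nClusters = 1L,
                exemptions = as.Date(character()))
    cv2 <- psiByInterval(cts2, part, 3)[["1"]]
    expect_identical(cv2@nPairs[1], 3L)   # days (1,2) (2,3) (5,6)
    expect_identical(cv2@nPairs[2], 2L)   # days (1,3) (3,5) - one spans the gap
    expect_identical(cv2@nPairs[3], 2L)   # days (2,5) (3,6)
})

test_that("pairs must share the cluster label and other clusters do not
           leak in", {
    set.seed(43)
    m <- matrix(rgamma(8 * 3, 1) + 1, 8, 3,
                dimnames = list(NULL, c("A", "B", "C")))
    cts <- CommunityTimeSeries(m, as.Date("2013-06-01") + 0:7)
    both <- psiByInterval(cts, labelPartition(rep(c(1, 2), each = 4),
                                              "2013-06-01"), 3)
    # cluster 1 statistics are unaffected by what cluster 2 contains
    solo <- psiByInterval(CommunityTimeSeries(m[1:4, ],
                              as.Date("2013-06-01") + 0:3),
                          labelPartition(rep(1, 4), "2013-06-01"), 3)[["1"]]
    expect_equal(both[["1"]]@meanPSI, solo@meanPSI)
    expect_identical(both[["1"]]@nPairs, solo@nPairs)
    # taxon order is irrelevant
    perm <- c(3, 1, 2)
    ctsP <- CommunityTimeSeries(m[, perm], as.Date("2013-06-01") + 0:7)
    bothP <- psiByInterval(ctsP, labelPartition(rep(c(1, 2), each = 4),
                                                "2013-06-01"), 3)
    expect_equal(bothP[["1"]]@meanPSI, both[["1"]]@meanPSI)
})

test_that("latent PSI decay follows the closed-form replacement law", {
    r <- 0.05
    cts <- oneRegimeSeries(r, ndays = 61L, depth = 10000L, seed = 5)
    lat <- S4Vectors::metadata(cts)$latent
    for (s in 1:10) {
        n <- nrow(lat) - s
        obs <- mean(vapply(seq_len(n), function(i)
            100 * sum(pmin(lat[i, ], lat[i + s, ])), numeric(1)))
        expect_equal(obs, 100 * (1 - r)^s, tolerance = 1e-6)
    }
})

test_that("observed PSI sits below the law by the counting deficit", {
    cts <- oneRegimeSeries(0.05, ndays = 61L, depth = 10000L, seed = 5)
    cv <- psiByInterval(cts, truePartition(cts), 10)[["1"]]
    law <- 100 * (1 - 0.05)^(1:10)
    expect_true(all(cv@meanPSI[1:5] < law[1:5]))  # counting depresses PSI
    expect_true(all(abs(law - cv@meanPSI) < 4))   # but only by a few points
})

test_that("ASF censoring mirrors flat, collapsed and analytic curves", {
    flat <- estimateASF(meanCurve(rep(80, 30)), threshold = 60)
    expect_identical(flat@censoring, "above_horizon")
    expect_true(is.na(flat@asfDays))

    low <- estimateASF(meanCurve(c(55, rep(70, 29))), threshold = 60)
    expect_identical(low@censoring, "below_one_day")

    r13 <- 1 - 0.6^(1 / 13)
    an <- estimateASF(meanCurve(100 * (1 - r13)^(1:30)), threshold = 60)
    expect_identical(an@censoring, "none")
    expect_equal(an@asfDays, 13)

    # skipped (no-pair) intervals do not enter the quantifier
    mu <- 100 * (1 - r13)^(1:30); mu[c(5, 9)] <- NA
    an2 <- estimateASF(meanCurve(mu), threshold = 60)
    expect_equal(an2@asfDays, 13)

    expect_error(estimateASF(meanCurve(rep(NA_real_, 5))), "no evaluable")
    expect_error(estimateASF(meanCurve(c(NA, 80, 80))), "interval 1")
})

test_that("increasing the replacement rate never increases the ASF", {
    for (seed in 1:5) {
        asfs <- sapply(c(0.02, 0.05, 0.1, 0.3, 0.7), function(r) {
            cts <- oneRegimeSeries(r, ndays = 70L, depth = 10000L,
                                   seed = seed)
            e <- estimateASF(psiByInterval(cts, truePartition(cts),
                                           30)[["1"]], 60)
            switch(e@censoring, none = e@asfDays, above_horizon = Inf,
                   below_one_day = 0)
        })
        expect_true(all(diff(asfs) <= 0))
    }
})

test_that("asfTable assembles labels and estimates per cluster", {
    curves <- list("1" = meanCurve(rep(80, 30), "1"),
                   "2" = meanCurve(100 * 0.96^(1:30), "2"),
                   "4" = meanCurve(c(50, rep(40, 29)), "4"))
    tab <- asfTable(curves, threshold = 60)
    expect_identical(tab$label, c("> 30 days", "12 days", "< 1 day"))
    expect_identical(tab$censoring,
                     c("above_horizon", "none", "below_one_day"))
    expect_equal(tab$asf_days[2], 12)
})
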