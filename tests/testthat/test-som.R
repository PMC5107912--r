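test_that("map-size heuristic reproduces the 10x9 lattice at n = 348", {
    g <- mapSizeHeuristic(348, maxAspect = 1.3)
    expect_identical(c(g@rows, g@cols), c(10L, 9L))
})

test_that("map-size heuristic matches a brute-force enumeration oracle", {
    oracleUnits <- function(n, maxAspect = 1.3) {
        target <- 5 * sqrt(n)
        best <- NULL; bestErr <- Inf
        for (r in 2:40) for (c in 2:40) {
            if (max(r, c) / min(r, c) > maxAspect + 1e-12) next
            err <- abs(r * c - target)
            if (err < bestErr) { bestErr <- err; best <- r * c }
        }
        best
    }
    for (n in c(4, 100, 50, 348, 1000)) {
        g <- mapSizeHeuristic(n)
        expect_identical(g@rows * g@cols, as.integer(oracleUnits(n)),
                         label = paste("n =", n))
    }
    # n = 4: target 10, nearest admissible grid is 3x3 = 9 units
    g4 <- mapSizeHeuristic(4)
    expect_identical(c(g4@rows, g4@cols), c(3L, 3L))
})

test_that("selected grid is always within one grid step of 5*sqrt(n)", {
    for (n in c(5, 17, 60, 120, 348, 900, 2500)) {
        g <- mapSizeHeuristic(n)
        expect_lte(abs(g@rows * g@cols - 5 * sqrt(n)), max(g@rows, g@cols))
    }
})

test_that("hexagonal lattice gives interior units exactly six neighbours", {
    g <- somGrid(5, 6)
    d2 <- as.matrix(dist(g@unitCoords))^2
    nNeigh <- as.integer(rowSums(d2 <= 1.0001) - 1L)
    expect_identical(max(nNeigh), 6L)
    expect_true(all(nNeigh >= 2L))
    # unit in the middle of the lattice
    mid <- (2L * 6L) + 3L
    expect_identical(nNeigh[mid], 6L)
})

test_that("training is bit-reproducible for fixed seed and init", {
    set.seed(5)
    d <- matrix(rnorm(80 * 6), 80, 6)
    m1 <- trainSOM(d, somGrid(4, 4), epochs = 15)
    m2 <- trainSOM(d, somGrid(4, 4), epochs = 15)
    expect_identical(m1@codebook, m2@codebook)
    expect_identical(m1@bmu, m2@bmu)
    r1 <- trainSOM(d, somGrid(4, 4), epochs = 15, init = "random", seed = 9L)
    r2 <- trainSOM(d, somGrid(4, 4), epochs = 15, init = "random", seed = 9L)
    expect_identical(r1@codebook, r2@codebook)
})

test_that("quantization error decreases across epochs and is near zero for
           duplicated vectors", {
    set.seed(3)
    v <- matrix(rnorm(3 * 6), 3, 6)
    d <- v[rep(1:3, each = 40), ]
    m <- trainSOM(d, somGrid(4, 4), epochs = 40)
    expect_true(all(diff(m@qeHistory) <= 1e-9))
    expect_lt(m@quantizationError, 0.05 * mean(dist(v)))
    # generic data: monotone too
    set.seed(42)
    d2 <- matrix(rnorm(200 * 8), 200, 8)
    m2 <- trainSOM(d2, somGrid(6, 5), epochs = 30)
    expect_true(all(diff(m2@qeHistory) <= 1e-9))
    expect_gte(m2@topographicError, 0)
    expect_lte(m2@topographicError, 1)
})

test_that("degenerate all-identical data trains with QE 0 and a warning", {
    d <- matrix(1, 30, 4)
    expect_warning(m <- trainSOM(d, somGrid(3, 3), epochs = 5), "identical")
    expect_equal(m@quantizationError, 0)
})

test_that("well-separated regimes occupy disjoint lattice regions", {
    win <- as.Date(c("2013-01-01", "2013-03-31"))
    rg <- list(regimeSpec("a", win[1], "2013-01-30", 0, 1),
               regimeSpec("b", "2013-01-31", "2013-02-28", 0, 1),
               regimeSpec("c", "2013-03-01", win[2], 0, 1))
    cts <- generateCommunity(simulationConfig(rg, window = win,
        nMissing = 0L, countingDepth = 2000L, seed = 4))
    prof <- profiles(cts)
    model <- trainSOM(prof, somGrid(6, 5), epochs = 25)
    part <- clusterCodebook(model, prof, sampleDates(cts), k = 3L)
    truth <- truePartition(cts)
    # label purity of the k = 3 cut against the generating regimes
    tab <- table(rawLabels(part), rawLabels(truth))
    purity <- sum(apply(tab, 2, max)) / sum(tab)
    expect_gte(purity, 0.95)
})

test_that("U-matrix agrees with a brute-force neighbour-loop oracle", {
    set.seed(8)
    d <- matrix(rnorm(60 * 5), 60, 5)
    m <- trainSOM(d, somGrid(4, 5), epochs = 10)
    u <- uMatrix(m)
    co <- m@grid@unitCoords
    for (i in seq_len(nrow(co))) {
        nb <- c()
        for (j in seq_len(nrow(co)))
            if (i != j && sum((co[i, ] - co[j, ])^2) <= 1.0001)
                nb <- c(nb, sqrt(sum((m@codebook[i, ] - m@codebook[j, ])^2)))
        expect_equal(t(u)[i], mean(nb), tolerance = 1e-12)
    }
})

test_that("U-matrix is zero for a constant codebook and ridges at a block
           boundary", {
    g <- somGrid(4, 6)
    cbk <- matrix(1, 24, 3)
    mConst <- new("SOMModel", grid = g, codebook = cbk,
                  quantizationError = 0, topographicError = 0,
                  bmu = integer(), qeHistory = numeric())
    expect_true(all(uMatrix(mConst) == 0))
    # left half = a, right half = b: largest values on the middle columns
    col <- rep(rep(1:6, times = 4), 1)
    cbk2 <- matrix(0, 24, 3); cbk2[col >= 4, ] <- 10
    mBlock <- new("SOMModel", grid = g, codebook = cbk2,
                  quantizationError = 0, topographicError = 0,
                  bmu = integer(), qeHistory = numeric())
    u <- uMatrix(mBlock)
    expect_true(all(apply(u, 1, which.max) %in% c(3L, 4L)))
})
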