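# Shared fixtures, all built in code.

# A tiny 3-taxon series on consecutive days.
tinySeries <- function(n = 4L, start = "2013-04-25") {
    m <- matrix(c(30, 10, 0,
                  20,  5, 15,
                  10, 10, 10,
                   5, 25,  0)[seq_len(3L * n)],
                nrow = n, byrow = TRUE,
                dimnames = list(NULL, c("Ach", "Nav", "Coc")))
    CommunityTimeSeries(m, as.Date(start) + seq_len(n) - 1L)
}

# Five precipitation-linked regimes tiling the study window, shared
# replacement rate r.
fiveRegimes <- function(r = 0) {
    list(regimeSpec("1", "2013-04-25", "2013-05-31", r, 1.8),
         regimeSpec("2", "2013-06-01", "2013-07-31", r, 1.4),
         regimeSpec("3", "2013-08-01", "2013-11-30", r, 1.2),
         regimeSpec("4", "2013-12-01", "2014-01-31", r, 8.0),
         regimeSpec("5", "2014-02-01", "2014-04-30", r, 4.0))
}

# One-regime simulation over `ndays` days.
oneRegimeSeries <- function(r, ndays = 90L, depth = 10000L, seed = 1L,
                            nTaxa = 113L, nMissing = 0L) {
    win <- as.Date("2013-01-01") + c(0L, ndays - 1L)
    rg <- list(regimeSpec("A", win[1L], win[2L], r, 2))
    generateCommunity(simulationConfig(rg, nTaxa = nTaxa, window = win,
        nMissing = nMissing, countingDepth = depth, seed = seed))
}

# Fraction of date pairs on which two labelings agree about co-membership.
pairAgreement <- function(a, b) {
    ca <- outer(a, a, "==")
    cb <- outer(b, b, "==")
    mean(ca[upper.tri(ca)] == cb[upper.tri(cb)])
}

# Random proportion vector (uniform Dirichlet).
randomProfile <- function(k) {
    g <- -log(runif(k))
    g / sum(g)
}

# Build a ClusterPartition directly from labels on consecutive days.
labelPartition <- function(labels, start = "2013-01-01") {
    labels <- as.integer(labels)
    new("ClusterPartition",
        dates = as.Date(start) + seq_along(labels) - 1L,
        rawLabels = labels, smoothedLabels = labels,
        nClusters = length(unique(labels)),
        exemptions = as.Date(character()))
}

# Build a PSICurve directly from a mean vector (NA = no pairs).
meanCurve <- function(mu, id = "c") {
    np <- ifelse(is.na(mu), 0L, 5L)
    new("PSICurve", clusterId = id, intervals = seq_along(mu),
        meanPSI = mu, sdPSI = ifelse(np > 0L, 1, NA_real_),
        sePSI = ifelse(np > 0L, 1 / sqrt(5), NA_real_),
        nPairs = as.integer(np))
}
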