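#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats sd dist hclust cutree prcomp quantile cor rmultinom
#'   rbinom rgamma runif complete.cases lm coef setNames
#' @importFrom utils read.csv head
NULL

setOldClass("Date")

#' CommunityTimeSeries: a daily taxon-abundance matrix with calendar gaps
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with taxa as rows and
#' sampled dates as columns (assay `"abundance"`). Dates missing inside the
#' observation window (days with no sample) are kept explicitly so that
#' downstream interval pairing works on true calendar gaps rather than sample
#' indices. Values may be densities (cells/L) or raw counts; every analysis in
#' the package converts samples to proportions first, so the unit cancels.
#'
#' @slot windowStart,windowEnd first and last calendar day of the observation
#'   window (inclusive).
#' @slot missingDates days inside the window with no sample.
#'
#' @seealso [CommunityTimeSeries()] for the constructor,
#'   [readCommunityTable()] for file input.
#' @export
setClass("CommunityTimeSeries",
    contains = "SummarizedExperiment",
    representation(
        windowStart  = "Date",
        windowEnd    = "Date",
        missingDates = "Date"
    )
)

setValidity("CommunityTimeSeries", function(object) {
    msg <- character()
    a <- SummarizedExperiment::assay(object, "abundance")
    if (nrow(a) < 1L)
        msg <- c(msg, "at least one taxon is required")
    if (ncol(a) < 2L)
        msg <- c(msg, "at least two sampled dates are required")
    if (any(!is.finite(a)) || any(a < 0))
        msg <- c(msg, "abundance values must be finite and non-negative")
    d <- SummarizedExperiment::colData(object)$date
    if (is.null(d)) {
        msg <- c(msg, "colData must carry a 'date' column")
    } else {
        d <- as.Date(d)
        if (anyDuplicated(d))
            msg <- c(msg, paste0("duplicate sampling date(s): ",
                paste(unique(format(d[duplicated(d)])), collapse = ", ")))
        if (is.unsorted(d, strictly = TRUE))
            msg <- c(msg, "sampling dates must be strictly increasing")
        win <- seq(object@windowStart, object@windowEnd, by = "day")
        if (any(d < object@windowStart) || any(d > object@windowEnd))
            msg <- c(msg, "sampling dates fall outside the observation window")
        # bookkeeping identity: sampled = window days - missing days
        if (length(d) != length(win) - length(object@missingDates))
            msg <- c(msg, sprintf(
                "%d sampled dates != %d window days - %d missing dates",
                length(d), length(win), length(object@missingDates)))
        if (length(intersect(object@missingDates, d)))
            msg <- c(msg, "a date cannot be both sampled and missing")
    }
    if (length(msg)) msg else TRUE
})

#' Hexagonal SOM lattice geometry
#'
#' @slot rows,cols lattice dimensions (units = rows * cols).
#' @slot topology lattice type; always `"hexagonal"`.
#' @slot unitCoords units x 2 matrix of planar positions; neighbouring units
#'   sit at distance 1, giving interior units six neighbours.
#' @export
setClass("SOMGrid", representation(
    rows = "integer", cols = "integer",
    topology = "character", unitCoords = "matrix"
))

setValidity("SOMGrid", function(object) {
    msg <- character()
    if (object@rows < 2L || object@cols < 2L)
        msg <- c(msg, "rows and cols must both be >= 2")
    if (nrow(object@unitCoords) != object@rows * object@cols)
        msg <- c(msg, "unitCoords must have rows*cols rows")
    if (!identical(object@topology, "hexagonal"))
        msg <- c(msg, "only hexagonal topology is supported")
    if (length(msg)) msg else TRUE
})

#' A trained batch self-organizing map
#'
#' @slot grid the [SOMGrid-class] lattice.
#' @slot codebook units x taxa matrix of unit weight vectors.
#' @slot quantizationError mean Euclidean distance of each sample to its
#'   best-matching unit (BMU).
#' @slot topographicError fraction of samples whose two nearest units are not
#'   lattice-adjacent.
#' @slot bmu per-sample BMU index.
#' @slot qeHistory per-epoch quantization error, for convergence diagnostics.
#' @export
setClass("SOMModel", representation(
    grid = "SOMGrid", codebook = "matrix",
    quantizationError = "numeric", topographicError = "numeric",
    bmu = "integer", qeHistory = "numeric"
))

setValidity("SOMModel", function(object) {
    msg <- character()
    if (object@quantizationError < 0)
        msg <- c(msg, "quantizationError must be >= 0")
    if (object@topographicError < 0 || object@topographicError > 1)
        msg <- c(msg, "topographicError must lie in [0, 1]")
    nu <- object@grid@rows * object@grid@cols
    if (nrow(object@codebook) != nu)
        msg <- c(msg, "codebook must have one row per lattice unit")
    if (length(object@bmu) && (min(object@bmu) < 1L || max(object@bmu) > nu))
        msg <- c(msg, "bmu indices out of lattice range")
    if (length(msg)) msg else TRUE
})

#' Temporal cluster assignment of sampling dates
#'
#' Holds the raw Ward-cut labels and the contiguity-smoothed labels in which
#' short interruptions of a temporal run are absorbed into their neighbouring
#' run (the automated counterpart of reassigning isolated "exemption" dates by
#' hand). Dates whose raw and smoothed labels differ are listed as exemptions.
#'
#' @slot dates sampled dates, strictly increasing.
#' @slot rawLabels,smoothedLabels integer cluster id per date.
#' @slot nClusters number of distinct raw clusters.
#' @slot exemptions dates where the smoothed label differs from the raw one.
#' @export
setClass("ClusterPartition", representation(
    dates = "Date", rawLabels = "integer", smoothedLabels = "integer",
    nClusters = "integer", exemptions = "Date"
))

setValidity("ClusterPartition", function(object) {
    msg <- character()
    n <- length(object@dates)
    if (length(object@rawLabels) != n || length(object@smoothedLabels) != n)
        msg <- c(msg, "labels must align with dates")
    if (n && is.unsorted(object@dates, strictly = TRUE))
        msg <- c(msg, "dates must be strictly increasing")
    diff <- object@dates[object@rawLabels != object@smoothedLabels]
    if (!setequal(diff, object@exemptions))
        msg <- c(msg, "exemptions must be exactly the dates whose labels differ")
    if (length(msg)) msg else TRUE
})

#' Per-cluster PSI decay over sampling intervals
#'
#' Mean/SD/SE of the percentage similarity index over all within-cluster date
#' pairs separated by each calendar-day interval. Intervals with no pairs have
#' `NA` statistics (absent, not zero).
#'
#' @slot clusterId cluster label.
#' @slot intervals 1..maxInterval, in calendar days.
#' @slot meanPSI,sdPSI,sePSI per-interval statistics, in percent.
#' @slot nPairs per-interval number of date pairs.
#' @export
setClass("PSICurve", representation(
    clusterId = "character", intervals = "integer",
    meanPSI = "numeric", sdPSI = "numeric", sePSI = "numeric",
    nPairs = "integer"
))

setValidity("PSICurve", function(object) {
    msg <- character()
    k <- length(object@intervals)
    if (any(lengths(list(object@meanPSI, object@sdPSI, object@sePSI,
                         object@nPairs)) != k))
        msg <- c(msg, "all per-interval vectors must share one length")
    ok <- !is.na(object@meanPSI)
    if (any(object@meanPSI[ok] < -1e-9 | object@meanPSI[ok] > 100 + 1e-9))
        msg <- c(msg, "meanPSI must lie in [0, 100]")
    if (any(is.na(object@meanPSI) & object@nPairs > 0L))
        msg <- c(msg, "intervals with pairs must carry a mean")
    if (any(!is.na(object@meanPSI) & object@nPairs == 0L))
        msg <- c(msg, "intervals without pairs must carry NA, not a value")
    if (length(msg)) msg else TRUE
})

#' Appropriate sampling frequency for one temporal cluster
#'
#' The ASF is the largest sampling interval (days) at which the mean PSI still
#' meets the similarity threshold at every evaluable shorter interval. When the
#' curve never drops below the threshold within the horizon the estimate is
#' censored above (reported "> horizon days"); when it is already below the
#' threshold at a one-day interval it is censored below ("< 1 day").
#'
#' @slot clusterId cluster label.
#' @slot asfDays the estimate in days, `NA` when censored.
#' @slot censoring one of `"none"`, `"above_horizon"`, `"below_one_day"`.
#' @slot threshold PSI threshold in percent.
#' @slot horizon largest interval examined, days.
#' @export
setClass("ASFEstimate", representation(
    clusterId = "character", asfDays = "numeric", censoring = "character",
    threshold = "numeric", horizon = "integer"
))

setValidity("ASFEstimate", function(object) {
    msg <- character()
    if (!object@censoring %in% c("none", "above_horizon", "below_one_day"))
        msg <- c(msg, "unknown censoring marker")
    if (object@censoring == "none" &&
        (is.na(object@asfDays) || object@asfDays < 1 ||
         object@asfDays > object@horizon))
        msg <- c(msg, "uncensored ASF must lie in [1, horizon]")
    if (object@censoring != "none" && !is.na(object@asfDays))
        msg <- c(msg, "censored ASF must be NA")
    if (length(msg)) msg else TRUE
})

#' Monthly decay coefficients for the antecedent precipitation index
#'
#' One decay coefficient k per calendar month. k expresses the day-to-day loss
#' of catchment moisture (mainly evapotranspiration), so it is low in summer
#' and high in winter; values outside the conventional [0.85, 0.98] band are
#' rejected unless explicitly overridden.
#'
#' @slot kByMonth numeric vector of length 12 (January..December).
#' @export
setClass("KSchedule", representation(kByMonth = "numeric"))

setValidity("KSchedule", function(object) {
    msg <- character()
    if (length(object@kByMonth) != 12L)
        msg <- c(msg, "kByMonth must have one value per calendar month")
    if (any(!is.finite(object@kByMonth)) ||
        any(object@kByMonth <= 0 | object@kByMonth >= 1))
        msg <- c(msg, "every k must lie in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' Daily antecedent precipitation index with wetness classes
#'
#' @slot dates contiguous daily dates.
#' @slot precipitation daily precipitation, mm.
#' @slot api daily API, mm.
#' @slot wetness per-day class `"low"`, `"moderate"` or `"high"` (`NA` until
#'   classified).
#' @slot q1,q3 classification thresholds in mm (`NA` until classified).
#' @slot burnin TRUE for the initial spin-up days excluded from quartile
#'   fitting.
#' @export
setClass("APISeries", representation(
    dates = "Date", precipitation = "numeric", api = "numeric",
    wetness = "character", q1 = "numeric", q3 = "numeric", burnin = "logical"
))

setValidity("APISeries", function(object) {
    msg <- character()
    n <- length(object@dates)
    if (any(lengths(list(object@precipitation, object@api, object@wetness,
                         object@burnin)) != n))
        msg <- c(msg, "all daily vectors must share one length")
    if (n > 1L && any(as.integer(diff(object@dates)) != 1L))
        msg <- c(msg, "dates must be daily-contiguous")
    if (any(object@precipitation < 0))
        msg <- c(msg, "precipitation must be non-negative")
    if (any(object@api < 0))
        msg <- c(msg, "api must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Multi-response permutation procedure result
#'
#' @slot A chance-corrected within-group agreement, `1 - delta/E(delta)`.
#' @slot deltaObserved weighted mean within-group distance.
#' @slot deltaExpected mean of the permutation distribution of delta.
#' @slot pValue Monte-Carlo probability with the +1 correction, so the
#'   smallest attainable value is `1/(nPermutations + 1)`.
#' @slot nPermutations number of label permutations.
#' @slot seed RNG seed used for the permutations (`NA` if unseeded).
#' @export
setClass("MRPPResult", representation(
    A = "numeric", deltaObserved = "numeric", deltaExpected = "numeric",
    pValue = "numeric", nPermutations = "integer", seed = "integer"
))

setValidity("MRPPResult", function(object) {
    msg <- character()
    if (object@deltaExpected > 0) {
        a <- 1 - object@deltaObserved / object@deltaExpected
        if (abs(a - object@A) > 1e-12)
            msg <- c(msg, "A must equal 1 - delta/E(delta)")
    }
    if (object@A > 1 + 1e-12)
        msg <- c(msg, "A cannot exceed 1")
    if (object@pValue <= 0 || object@pValue > 1)
        msg <- c(msg, "pValue must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' One temporal regime of the synthetic community model
#'
#' @slot regimeId label.
#' @slot startDate,endDate inclusive date window of the regime.
#' @slot baseProfile taxon proportions at the regime start (may be length 0,
#'   meaning "draw one from the configured profile generator").
#' @slot replacementRate fraction r of community proportion replaced by novel
#'   taxa per day; expected PSI between days s apart is 100 (1 - r)^s.
#' @slot precipitationLevel mean rainfall of the regime's generator, mm/day.
#' @export
setClass("RegimeSpec", representation(
    regimeId = "character", startDate = "Date", endDate = "Date",
    baseProfile = "numeric", replacementRate = "numeric",
    precipitationLevel = "numeric"
))

setValidity("RegimeSpec", function(object) {
    msg <- character()
    if (object@endDate < object@startDate)
        msg <- c(msg, "endDate must not precede startDate")
    if (object@replacementRate < 0 || object@replacementRate >= 1)
        msg <- c(msg, "replacementRate must lie in [0, 1)")
    if (object@precipitationLevel < 0)
        msg <- c(msg, "precipitationLevel must be non-negative")
    if (length(object@baseProfile)) {
        if (any(object@baseProfile < 0) ||
            abs(sum(object@baseProfile) - 1) > 1e-9)
            msg <- c(msg, "baseProfile must be non-negative and sum to 1")
    }
    if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic daily community simulation
#'
#' @slot nTaxa number of taxa in the pool.
#' @slot windowStart,windowEnd study window (inclusive).
#' @slot nMissing number of unsampled days inside the window.
#' @slot countingDepth valves counted per sample (multinomial depth).
#' @slot regimes list of [RegimeSpec-class] tiling the window.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig", representation(
    nTaxa = "integer", windowStart = "Date", windowEnd = "Date",
    nMissing = "integer", countingDepth = "integer", regimes = "list",
    seed = "integer"
))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    ndays <- as.integer(object@windowEnd - object@windowStart) + 1L
    if (object@nMissing >= ndays)
        msg <- c(msg, "nMissing must be smaller than the window length")
    if (object@countingDepth < 50L)
        msg <- c(msg, "countingDepth must be >= 50 valves")
    if (!length(object@regimes))
        msg <- c(msg, "at least one regime is required")
    if (!all(vapply(object@regimes, is, logical(1L), "RegimeSpec")))
        msg <- c(msg, "regimes must all be RegimeSpec objects")
    else {
        covered <- unlist(lapply(object@regimes, function(r)
            as.integer(seq(r@startDate, r@endDate, by = "day"))))
        win <- as.integer(seq(object@windowStart, object@windowEnd, by = "day"))
        if (anyDuplicated(covered))
            msg <- c(msg, "regime windows must not overlap")
        if (!setequal(covered, win))
            msg <- c(msg, "regime windows must tile the study window exactly")
        bp <- vapply(object@regimes, function(r)
            length(r@baseProfile) %in% c(0L, object@nTaxa), logical(1L))
        if (!all(bp))
            msg <- c(msg, "baseProfile length must be 0 or nTaxa")
    }
    if (length(msg)) msg else TRUE
})
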