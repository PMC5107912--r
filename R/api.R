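#' Monthly schedule of API decay coefficients
#'
#' @param k numeric vector of 12 monthly decay coefficients
#'   (January..December).
#' @param strict if TRUE (default), values outside the conventional
#'   [0.85, 0.98] band are rejected; set FALSE to override.
#' @return a [KSchedule-class].
#' @export
kSchedule <- function(k, strict = TRUE) {
    k <- as.numeric(k)
    if (strict && (any(k < 0.85) || any(k > 0.98)))
        stop("k outside [0.85, 0.98]; use strict = FALSE to override",
             call. = FALSE)
    new("KSchedule", kByMonth = k)
}

#' Default seasonal decay schedule
#'
#' A smooth annual ramp between a winter maximum of 0.98 (little
#' evapotranspiration, moisture persists) and a summer minimum of 0.85
#' (rapid moisture loss), shaped as a cosine over the calendar year with its
#' minimum in July. Intended for temperate northern-hemisphere catchments;
#' replace with an evaporation-derived schedule where one is available.
#'
#' @return a [KSchedule-class].
#' @export
defaultKSchedule <- function() {
    m <- 1:12
    k <- 0.915 + 0.065 * cos(2 * pi * (m - 1) / 12)
    kSchedule(round(k, 4))
}

setMethod("show", "KSchedule", function(object) {
    cat("KSchedule:", paste(sprintf("%.3f", object@kByMonth),
                            collapse = " "), "\n")
})

#' Daily antecedent precipitation index
#'
#' Computes the recursion `API_t = k(month of t) * API_{t-1} + P_{t-1}`
#' where `P_{t-1}` is the previous day's precipitation (mm) and `k` the
#' month's decay coefficient; the first day takes `apiInit`. The first
#' `spinup` days are flagged as burn-in so that the arbitrary
#' initialization does not enter quartile fitting. The recursion is linear
#' in the precipitation input.
#'
#' The alternative form `API_t = k * (API_{t-1} + P_{t-1})`, which decays
#' the new rain by one day as well, is available via `form = "decay_rain"`.
#'
#' @param dates daily-contiguous `Date` vector.
#' @param precip daily precipitation, mm (no gaps, no negatives; missing
#'   days are an error, not an imputation).
#' @param k a [KSchedule-class].
#' @param apiInit API on the first day, mm.
#' @param spinup number of leading burn-in days.
#' @param form recursion variant, see above.
#' @return an [APISeries-class] (wetness unclassified; see
#'   [classifyWetness()]).
#' @examples
#' d <- as.Date("2013-01-01") + 0:5
#' p <- c(10, 0, 0, 0, 0, 0)
#' computeAPI(d, p, kSchedule(rep(0.9, 12), strict = FALSE),
#'            spinup = 0)   # 0, 10, 9, 8.1, ...
#' @export
computeAPI <- function(dates, precip, k = defaultKSchedule(), apiInit = 0,
                       spinup = 30L, form = c("standard", "decay_rain")) {
    form <- match.arg(form)
    dates <- as.Date(dates)
    n <- length(dates)
    stopifnot(length(precip) == n, n >= 1L)
    if (n > 1L && any(as.integer(diff(dates)) != 1L))
        stop("precipitation series has gaps; a daily-contiguous series is required",
             call. = FALSE)
    if (any(!is.finite(precip)) || any(precip < 0))
        stop("precipitation must be finite and non-negative", call. = FALSE)
    if (apiInit < 0) stop("apiInit must be non-negative", call. = FALSE)
    km <- k@kByMonth[as.integer(format(dates, "%m"))]
    api <- numeric(n)
    api[1L] <- apiInit
    if (form == "standard") {
        for (t in seq_len(n)[-1L])
            api[t] <- km[t] * api[t - 1L] + precip[t - 1L]
    } else {
        for (t in seq_len(n)[-1L])
            api[t] <- km[t] * (api[t - 1L] + precip[t - 1L])
    }
    new("APISeries", dates = dates, precipitation = precip, api = api,
        wetness = rep(NA_character_, n), q1 = NA_real_, q3 = NA_real_,
        burnin = seq_len(n) <= spinup)
}

#' Classify daily catchment wetness from API quartiles
#'
#' Labels each day `"low"` when its API is at or below the first quartile,
#' `"high"` at or above the third quartile, and `"moderate"` in between.
#' Quartiles are taken from a long-term reference API series when one is
#' supplied (at least 365 non-burn-in days), from the series itself
#' otherwise, or given literally via `q1`/`q3` (e.g. 15.5 and 63.4 mm to
#' mirror a published record). Percentiles use linear interpolation between
#' order statistics.
#'
#' @param x an [APISeries-class].
#' @param reference optional long-term [APISeries-class] supplying the
#'   quartiles.
#' @param q1,q3 literal thresholds in mm, overriding any empirical fit.
#' @return `x` with `wetness`, `q1`, `q3` filled.
#' @export
classifyWetness <- function(x, reference = NULL, q1 = NULL, q3 = NULL) {
    if (is.null(q1) != is.null(q3))
        stop("supply both q1 and q3, or neither", call. = FALSE)
    if (is.null(q1)) {
        src <- if (is.null(reference)) x else reference
        vals <- src@api[!src@burnin]
        if (!is.null(reference) && length(vals) < 365L)
            stop("reference must span at least 365 non-burn-in days",
                 call. = FALSE)
        qs <- quantile(vals, c(0.25, 0.75), names = FALSE, type = 7)
        q1 <- qs[1L]; q3 <- qs[2L]
    }
    if (q3 < q1) stop("q3 must be >= q1", call. = FALSE)
    w <- ifelse(x@api <= q1, "low", ifelse(x@api >= q3, "high", "moderate"))
    x@wetness <- w
    x@q1 <- q1
    x@q3 <- q3
    x
}

setMethod("show", "APISeries", function(object) {
    cat("APISeries:", length(object@dates), "days,",
        format(object@dates[1L]), "..",
        format(object@dates[length(object@dates)]), "\n")
    if (!is.na(object@q1))
        cat(sprintf("  wetness quartiles q1 = %.1f mm, q3 = %.1f mm\n",
                    object@q1, object@q3))
})

#' @describeIn computeAPI coerce an API series to a per-day data.frame
#'   (columns `date`, `precip_mm`, `api_mm`, `wetness`, `burnin`).
#' @param x an [APISeries-class].
#' @param row.names,optional,... ignored; present for the generic.
#' @export
as.data.frame.APISeries <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
    data.frame(date = x@dates, precip_mm = x@precipitation, api_mm = x@api,
               wetness = x@wetness, burnin = x@burnin)
}

#' Mean API over each temporal cluster
#'
#' @param x a classified or unclassified [APISeries-class].
#' @param partition a [ClusterPartition-class]; every sampled date must have
#'   API coverage.
#' @return a `data.frame` with columns `cluster`, `mean_api`, `n_days`, and
#'   (when wetness is classified) the modal `wetness` class of the
#'   cluster's days.
#' @export
summarizeAPIByCluster <- function(x, partition) {
    idx <- match(partition@dates, x@dates)
    if (anyNA(idx)) {
        bad <- unique(partition@smoothedLabels[is.na(idx)])
        stop("no API coverage for cluster(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
    }
    labs <- sort(unique(partition@smoothedLabels))
    out <- do.call(rbind, lapply(labs, function(cl) {
        i <- idx[partition@smoothedLabels == cl]
        row <- data.frame(cluster = as.character(cl),
                          mean_api = mean(x@api[i]), n_days = length(i))
        if (!anyNA(x@wetness[i])) {
            tab <- table(x@wetness[i])
            row$wetness <- names(tab)[which.max(tab)]
        }
        row
    }))
    rownames(out) <- NULL
    out
}

#' Relationship between sampling frequency and catchment wetness
#'
#' Pairs each cluster's ASF with its mean API and summarizes the relation by
#' a Pearson correlation and an ordinary least-squares line. Estimates
#' censored below one day enter at the conventional 0.5 days; estimates
#' censored above the horizon cannot be placed on the day axis, so they are
#' excluded from the fit and reported separately.
#'
#' @param asf the `data.frame` from [asfTable()] (or one with columns
#'   `cluster`, `asf_days`, `censoring`).
#' @param apiMeans the `data.frame` from [summarizeAPIByCluster()] (columns
#'   `cluster`, `mean_api`).
#' @return a list with elements `r` (Pearson correlation), `slope`,
#'   `intercept`, `points` (data.frame of the fitted points), `excluded`
#'   (clusters censored above), and `status` (`"ok"` or `"undetermined"`
#'   when fewer than 3 usable points exist).
#' @export
asfAPIRelation <- function(asf, apiMeans) {
    m <- merge(asf, apiMeans, by = "cluster")
    m$asf_used <- ifelse(m$censoring == "below_one_day", 0.5, m$asf_days)
    excluded <- m$cluster[m$censoring == "above_horizon"]
    pts <- m[m$censoring != "above_horizon",
             c("cluster", "mean_api", "asf_used")]
    if (nrow(pts) < 3L)
        return(list(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                    points = pts, excluded = excluded,
                    status = "undetermined"))
    r <- if (sd(pts$mean_api) == 0 || sd(pts$asf_used) == 0) NA_real_
         else cor(pts$mean_api, pts$asf_used)
    fit <- lm(asf_used ~ mean_api, data = pts)
    list(r = r, slope = unname(coef(fit)[2L]),
         intercept = unname(coef(fit)[1L]), points = pts,
         excluded = excluded, status = "ok")
}
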