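#' Percentage similarity index between two community profiles
#'
#' `PSI = 100 * sum_k min(P_ik, P_jk)` over taxa: the sum of the lower of
#' the two relative abundances of each taxon (Renkonen similarity). 100
#' means identical composition, 0 means no shared taxa. For proper
#' proportion vectors it is tied to the L1 metric by
#' `100 - PSI = 50 * sum |p - q|`.
#'
#' @param p,q proportion vectors (non-negative, summing to 1). If both are
#'   named, taxa are union-aligned by name (absent taxa count as zero) when
#'   `alignTaxa = TRUE`; unnamed vectors must have equal length.
#' @param alignTaxa allow union alignment of differing taxon sets by name.
#' @return similarity in percent, in [0, 100].
#' @examples
#' psi(c(0.6, 0.3, 0.1), c(0.4, 0.4, 0.2))   # 80
#' @export
psi <- function(p, q, alignTaxa = FALSE) {
    checkProfile <- function(v, nm) {
        if (any(!is.finite(v)) || any(v < 0) || abs(sum(v) - 1) > 1e-9)
            stop("'", nm, "' is not a proportion vector (non-negative, sum 1)",
                 call. = FALSE)
    }
    checkProfile(p, "p"); checkProfile(q, "q")
    if (length(p) != length(q) ||
        (!is.null(names(p)) && !is.null(names(q)) &&
         !identical(names(p), names(q)))) {
        if (!alignTaxa)
            stop("taxon lists differ; set alignTaxa = TRUE to union-align",
                 call. = FALSE)
        if (is.null(names(p)) || is.null(names(q)))
            stop("union alignment requires named profiles", call. = FALSE)
        all <- union(names(p), names(q))
        p <- setNames(p[all], all); p[is.na(p)] <- 0
        q <- setNames(q[all], all); q[is.na(q)] <- 0
    }
    100 * sum(pmin(p, q))
}

#' PSI decay curves over sampling intervals, per temporal cluster
#'
#' For every cluster and every interval `s = 1..maxInterval` (in calendar
#' days), collects the PSI over all date pairs `(d, d + s)` in which both
#' days were sampled and both carry that cluster's smoothed label. Missing
#' dates therefore create genuine gaps: a pair spanning an unsampled day
#' contributes at the larger calendar interval, never at a re-indexed one.
#'
#' @param series a [CommunityTimeSeries-class].
#' @param partition a [ClusterPartition-class] covering all sampled dates.
#' @param maxInterval largest interval examined, days.
#' @return a named list of [PSICurve-class], one per cluster label. Clusters
#'   with fewer than two sampled dates yield an all-`NA` curve with a
#'   warning.
#' @export
psiByInterval <- function(series, partition, maxInterval = 30L) {
    stopifnot(maxInterval >= 1L)
    d <- sampleDates(series)
    if (!all(d %in% partition@dates))
        stop("partition must cover every sampled date")
    lab <- partition@smoothedLabels[match(d, partition@dates)]
    prof <- profiles(series)
    dayNo <- as.integer(d)
    out <- list()
    for (cl in sort(unique(lab))) {
        idx <- which(lab == cl)
        iv <- seq_len(maxInterval)
        mu <- sdv <- sev <- rep(NA_real_, maxInterval)
        np <- integer(maxInterval)
        if (length(idx) < 2L) {
            warning("cluster ", cl, " has fewer than 2 sampled dates")
        } else {
            pos <- setNames(idx, dayNo[idx])
            for (s in iv) {
                j <- match(as.character(dayNo[idx] + s), names(pos))
                have <- !is.na(j)
                if (!any(have)) next
                vals <- vapply(which(have), function(ii)
                    100 * sum(pmin(prof[idx[ii], ], prof[pos[j[ii]], ])),
                    numeric(1L))
                np[s] <- length(vals)
                mu[s] <- mean(vals)
                if (np[s] >= 2L) {
                    sdv[s] <- sd(vals)
                    sev[s] <- sdv[s] / sqrt(np[s])
                }
            }
        }
        out[[as.character(cl)]] <- new("PSICurve",
            clusterId = as.character(cl), intervals = iv,
            meanPSI = mu, sdPSI = sdv, sePSI = sev, nPairs = np)
    }
    out
}

#' @describeIn psiByInterval coerce a PSI curve to a data.frame (columns
#'   `cluster`, `interval`, `mean_psi`, `sd_psi`, `se_psi`, `n_pairs`).
#' @param x a [PSICurve-class].
#' @param row.names,optional,... ignored; present for the generic.
#' @export
as.data.frame.PSICurve <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
    data.frame(cluster = x@clusterId, interval = x@intervals,
               mean_psi = x@meanPSI, sd_psi = x@sdPSI, se_psi = x@sePSI,
               n_pairs = x@nPairs)
}

setMethod("show", "PSICurve", function(object) {
    ok <- !is.na(object@meanPSI)
    cat("PSICurve for cluster", object@clusterId, "-",
        sum(ok), "evaluable interval(s) of", length(object@intervals), "\n")
    if (any(ok))
        cat(sprintf("  mean PSI %.1f%% at interval 1 .. %.1f%% at interval %d\n",
            object@meanPSI[which(ok)[1L]],
            object@meanPSI[max(which(ok))], max(which(ok))))
})

#' Appropriate sampling frequency from a PSI decay curve
#'
#' The ASF is read off the similarity threshold with a first-crossing
#' convention: it is the largest interval `s` such that the mean PSI meets
#' the threshold at every evaluable interval up to `s` (intervals with no
#' pairs are skipped in the quantifier). A curve that never drops below the
#' threshold within the horizon is censored above (reported "> horizon
#' days"); a curve already below the threshold at a one-day interval is
#' censored below ("< 1 day").
#'
#' @param curve a [PSICurve-class] whose interval-1 mean is evaluable.
#' @param threshold PSI threshold, percent; 60 is the conventional cut-off
#'   for an ecologically stable community.
#' @return an [ASFEstimate-class].
#' @export
estimateASF <- function(curve, threshold = 60) {
    mu <- curve@meanPSI
    horizon <- length(mu)
    if (all(is.na(mu)))
        stop("curve for cluster ", curve@clusterId,
             " has no evaluable interval", call. = FALSE)
    if (is.na(mu[1L]))
        stop("mean PSI at interval 1 is not evaluable for cluster ",
             curve@clusterId, "; censoring cannot be determined",
             call. = FALSE)
    evaluable <- which(!is.na(mu))
    below <- evaluable[mu[evaluable] < threshold]
    if (!length(below)) {
        cens <- "above_horizon"; asf <- NA_real_
    } else if (below[1L] == 1L) {
        cens <- "below_one_day"; asf <- NA_real_
    } else {
        cens <- "none"; asf <- below[1L] - 1
    }
    new("ASFEstimate", clusterId = curve@clusterId, asfDays = asf,
        censoring = cens, threshold = threshold,
        horizon = as.integer(horizon))
}

setMethod("show", "ASFEstimate", function(object) {
    lbl <- switch(object@censoring,
        none = sprintf("%g days", object@asfDays),
        above_horizon = sprintf("> %d days", object@horizon),
        below_one_day = "< 1 day")
    cat(sprintf("ASF for cluster %s: %s (PSI threshold %g%%)\n",
                object@clusterId, lbl, object@threshold))
})

#' ASF table for a set of PSI curves
#'
#' @param curves list of [PSICurve-class] as returned by [psiByInterval()].
#' @param threshold PSI threshold, percent.
#' @return a `data.frame` with columns `cluster`, `asf_days` (`NA` when
#'   censored), `censoring`, `label` (e.g. `"> 30 days"`), plus the list of
#'   [ASFEstimate-class] objects as attribute `"estimates"`.
#' @export
asfTable <- function(curves, threshold = 60) {
    est <- lapply(curves, estimateASF, threshold = threshold)
    out <- do.call(rbind, lapply(est, function(e) data.frame(
        cluster = e@clusterId, asf_days = e@asfDays, censoring = e@censoring,
        label = switch(e@censoring,
            none = sprintf("%g days", e@asfDays),
            above_horizon = sprintf("> %d days", e@horizon),
            below_one_day = "< 1 day"))))
    rownames(out) <- NULL
    attr(out, "estimates") <- est
    out
}
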