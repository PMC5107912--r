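#' Construct a CommunityTimeSeries
#'
#' @param abundance numeric matrix with one row per sampled date and one
#'   column per taxon; densities (cells/L) or raw counts, non-negative.
#' @param dates `Date` vector (or ISO-8601 strings), one per row of
#'   `abundance`, strictly increasing.
#' @param window length-2 `Date` vector giving the inclusive observation
#'   window; defaults to the range of `dates`. Days inside the window that are
#'   absent from `dates` are recorded as missing dates.
#' @param taxa taxon names; defaults to `colnames(abundance)`.
#'
#' @return a [CommunityTimeSeries-class] object.
#' @examples
#' m <- matrix(c(30, 10, 0, 20, 5, 15), nrow = 3, byrow = TRUE,
#'             dimnames = list(NULL, c("Achnanthidium", "Navicula")))
#' cts <- CommunityTimeSeries(m, as.Date("2013-04-25") + c(0, 1, 3))
#' sampleDates(cts)
#' missingDates(cts)   # 2013-04-27 was never sampled
#' @export
CommunityTimeSeries <- function(abundance, dates,
                                window = range(dates),
                                taxa = colnames(abundance)) {
    abundance <- as.matrix(abundance)
    dates <- as.Date(dates)
    if (nrow(abundance) != length(dates))
        stop("'abundance' must have one row per date", call. = FALSE)
    if (is.null(taxa))
        taxa <- paste0("taxon", seq_len(ncol(abundance)))
    window <- as.Date(window)
    windays <- seq(window[1L], window[2L], by = "day")
    miss <- windays[!windays %in% dates]
    a <- t(abundance)
    rownames(a) <- taxa
    colnames(a) <- format(dates)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = a),
        colData = S4Vectors::DataFrame(date = dates, row.names = format(dates)))
    new("CommunityTimeSeries", se,
        windowStart = window[1L], windowEnd = window[2L], missingDates = miss)
}

#' Read a daily community table from delimited text
#'
#' Expects a header row, a `date` column in ISO-8601 (`YYYY-MM-DD`) and one
#' column per taxon. Taxon order is preserved as in the header. Rows whose
#' date cannot be parsed are rejected with an error naming the row; duplicate
#' dates and negative abundances are likewise rejected.
#'
#' @param path path to the file.
#' @param sep field delimiter, `","` (default) or `"\t"`.
#' @param window optional length-2 observation window passed to
#'   [CommunityTimeSeries()]; days inside it without a row become missing
#'   dates.
#' @return a [CommunityTimeSeries-class].
#' @export
readCommunityTable <- function(path, sep = ",", window = NULL) {
    tab <- read.csv(path, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
    if (!"date" %in% names(tab))
        stop("no 'date' column found in ", path, call. = FALSE)
    d <- as.Date(tab$date, format = "%Y-%m-%d")
    if (anyNA(d))
        stop("unparseable date in row(s) ",
             paste(which(is.na(d)), collapse = ", "), " of ", path,
             call. = FALSE)
    if (anyDuplicated(d))
        stop("duplicated date(s): ",
             paste(format(unique(d[duplicated(d)])), collapse = ", "),
             call. = FALSE)
    m <- as.matrix(tab[, setdiff(names(tab), "date"), drop = FALSE])
    storage.mode(m) <- "double"
    if (anyNA(m))
        stop("non-numeric abundance value(s) in ", path, call. = FALSE)
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg))
        stop("negative abundance at row ", neg[1L, 1L], ", column '",
             colnames(m)[neg[1L, 2L]], "'", call. = FALSE)
    o <- order(d)
    if (is.null(window)) window <- range(d)
    CommunityTimeSeries(m[o, , drop = FALSE], d[o], window = window)
}

#' Accessors for CommunityTimeSeries
#'
#' `sampleDates()` returns the sampled dates; `missingDates()` the unsampled
#' days inside the observation window; `taxa()` the taxon names;
#' `abundances()` the taxa x dates abundance matrix; `profiles()` the dates x
#' taxa matrix of per-sample proportions (each row sums to 1), the form every
#' downstream analysis consumes.
#'
#' @param x a [CommunityTimeSeries-class].
#' @name CommunityTimeSeries-accessors
NULL

#' @rdname CommunityTimeSeries-accessors
#' @export
setMethod("sampleDates", "CommunityTimeSeries", function(x)
    as.Date(SummarizedExperiment::colData(x)$date))

#' @rdname CommunityTimeSeries-accessors
#' @export
setMethod("missingDates", "CommunityTimeSeries", function(x) x@missingDates)

#' @rdname CommunityTimeSeries-accessors
#' @export
setMethod("taxa", "CommunityTimeSeries", function(x) rownames(x))

#' @rdname CommunityTimeSeries-accessors
#' @export
setMethod("abundances", "CommunityTimeSeries", function(x)
    SummarizedExperiment::assay(x, "abundance"))

#' @rdname CommunityTimeSeries-accessors
#' @export
setMethod("profiles", "CommunityTimeSeries", function(x) {
    a <- t(SummarizedExperiment::assay(x, "abundance"))
    tot <- rowSums(a)
    if (any(tot <= 0))
        stop("all-zero sample(s) on ",
             paste(rownames(a)[tot <= 0], collapse = ", "), call. = FALSE)
    a / tot
})

setMethod("show", "CommunityTimeSeries", function(object) {
    cat("CommunityTimeSeries:", nrow(object), "taxa x", ncol(object),
        "sampled dates\n")
    cat("  window ", format(object@windowStart), " .. ",
        format(object@windowEnd), " (", length(object@missingDates),
        " missing dates)\n", sep = "")
})

#' Convert an abundance vector to a community profile
#'
#' Divides by the total so proportions sum to one; zero taxa stay zero. This
#' is the `P_k` form entering the percentage similarity index, so densities
#' and raw counts give the same result.
#'
#' @param x non-negative abundance vector with at least one positive entry.
#' @return numeric vector of proportions, same names as `x`.
#' @examples
#' toProfile(c(30, 10, 0))   # 0.75 0.25 0.00
#' @export
toProfile <- function(x) {
    vals <- as.numeric(x)
    if (any(!is.finite(vals)) || any(vals < 0))
        stop("abundances must be finite and non-negative", call. = FALSE)
    tot <- sum(vals)
    if (tot <= 0)
        stop("profile undefined for an all-zero sample", call. = FALSE)
    setNames(vals / tot, names(x))
}

#' Diversity indices of one sample
#'
#' Computes the four standard summaries: species richness (taxa with nonzero
#' abundance), Shannon-Wiener H (natural log by default), Simpson diversity
#' in its complement form `1 - sum(p^2)`, and Pielou evenness
#' `J = H / log(richness)` (defined as 0 for a single-taxon sample).
#'
#' @param x non-negative abundance vector (any unit; converted to
#'   proportions).
#' @param base logarithm base for Shannon and for the evenness denominator.
#' @return a one-row `data.frame` with columns `richness`, `shannon`,
#'   `simpson`, `evenness`.
#' @examples
#' diversitySummary(c(1, 1, 1, 1))   # uniform: H = log(4), J = 1
#' @export
diversitySummary <- function(x, base = exp(1)) {
    p <- toProfile(x)
    pos <- p[p > 0]
    rich <- length(pos)
    h <- -sum(pos * log(pos, base = base))
    data.frame(
        richness = rich,
        shannon  = h,
        simpson  = 1 - sum(pos^2),
        evenness = if (rich > 1L) h / log(rich, base = base) else 0
    )
}

#' Per-date diversity table for a community series
#'
#' @param x a [CommunityTimeSeries-class].
#' @param base logarithm base, see [diversitySummary()].
#' @return a `data.frame` with one row per sampled date (column `date`
#'   first), suitable for writing as CSV.
#' @export
diversityTable <- function(x, base = exp(1)) {
    a <- t(abundances(x))
    out <- do.call(rbind, lapply(seq_len(nrow(a)), function(i)
        diversitySummary(a[i, ], base = base)))
    cbind(data.frame(date = sampleDates(x)), out)
}
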