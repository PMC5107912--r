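#' Davies-Bouldin index of a partition
#'
#' Lower is better. For each cluster the scatter `S_i` is the mean Euclidean
#' distance of its members to the cluster centroid; the index is the mean
#' over clusters of `max_{j != i} (S_i + S_j) / d(c_i, c_j)`.
#'
#' @param data samples x variables matrix.
#' @param labels integer cluster label per sample (>= 2 distinct values).
#' @return a single number.
#' @export
daviesBouldin <- function(data, labels) {
    labels <- as.integer(factor(labels))
    k <- max(labels)
    if (k < 2L) stop("at least two clusters are required")
    cent <- t(vapply(seq_len(k), function(g)
        colMeans(data[labels == g, , drop = FALSE]), numeric(ncol(data))))
    scat <- vapply(seq_len(k), function(g)
        mean(sqrt(rowCrossDist2(data[labels == g, , drop = FALSE],
                                cent[g, , drop = FALSE]))), numeric(1L))
    cd <- sqrt(rowCrossDist2(cent, cent))
    r <- vapply(seq_len(k), function(i)
        max((scat[i] + scat[-i]) / cd[i, -i]), numeric(1L))
    mean(r)
}

#' Cut the SOM codebook into temporal clusters by Ward's method
#'
#' Agglomerates the codebook vectors with Ward's linkage on Euclidean
#' distances and scores every candidate number of clusters by the
#' Davies-Bouldin index computed on the sample-level assignments (each
#' sample inherits the cluster of its best-matching unit, so empty units
#' cannot distort the score). The cut minimizing the index is selected
#' unless `k` is forced.
#'
#' @param model a trained [SOMModel-class].
#' @param data the samples x variables matrix the model was trained on.
#' @param dates `Date` vector, one per sample.
#' @param kRange candidate numbers of clusters (each must be at most
#'   units/2).
#' @param k optional forced number of clusters, overriding the automatic
#'   choice.
#' @return a [ClusterPartition-class] with raw labels (smoothed labels are
#'   initialized to the raw ones; see [smoothContiguity()]). The attribute
#'   `"dbScores"` carries the per-k index values, `NA` for skipped cuts.
#' @export
clusterCodebook <- function(model, data, dates, kRange = 2:8, k = NULL) {
    nu <- nrow(model@codebook)
    kRange <- kRange[kRange >= 2L & kRange <= nu / 2]
    if (!length(kRange) && is.null(k))
        stop("kRange must contain a value in [2, units/2]")
    tree <- hclust(dist(model@codebook), method = "ward.D2")
    scoreCut <- function(kk) {
        unitLab <- cutree(tree, k = kk)
        smpLab <- unitLab[model@bmu]
        if (length(unique(smpLab)) < kk) return(NA_real_)  # empty cluster
        daviesBouldin(data, smpLab)
    }
    if (is.null(k)) {
        db <- vapply(kRange, scoreCut, numeric(1L))
        if (all(is.na(db)))
            stop("every candidate cut produced an empty cluster")
        skipped <- kRange[is.na(db)]
        if (length(skipped))
            message("skipped k = ", paste(skipped, collapse = ", "),
                    " (empty cluster at that cut)")
        k <- kRange[which.min(db)]
        names(db) <- kRange
    } else {
        db <- setNames(scoreCut(k), k)
    }
    lab <- as.integer(cutree(tree, k = k)[model@bmu])
    out <- new("ClusterPartition", dates = as.Date(dates), rawLabels = lab,
               smoothedLabels = lab, nClusters = as.integer(k),
               exemptions = as.Date(character()))
    attr(out, "dbScores") <- db
    out
}

## Maximal runs of identical labels: data.frame(start, end, label, len)
labelRuns <- function(labels) {
    r <- rle(labels)
    end <- cumsum(r$lengths)
    data.frame(start = end - r$lengths + 1L, end = end,
               label = r$values, len = r$lengths)
}

#' Absorb short label runs into their temporal neighbours
#'
#' Replaces the by-hand reassignment of isolated "exemption" dates: any
#' maximal run of identical raw labels shorter than `minRun` is relabelled
#' with the label of its temporally dominant neighbour (the longer adjacent
#' run; ties go to the earlier run), and the rule is iterated to a fixpoint.
#' The operation is idempotent. Dates whose label changed are recorded as
#' exemptions.
#'
#' @param partition a [ClusterPartition-class] (raw labels are smoothed).
#' @param minRun shortest run length that survives on its own, in samples.
#' @return the partition with `smoothedLabels` and `exemptions` filled.
#' @export
smoothContiguity <- function(partition, minRun = 5L) {
    lab <- partition@rawLabels
    repeat {
        runs <- labelRuns(lab)
        if (nrow(runs) < 2L) break
        short <- which(runs$len < minRun)
        if (!length(short)) break
        ## absorb one run per pass, recomputing runs after each merge:
        ## shortest first, then the run with the longer dominant neighbour,
        ## then the earlier run
        leftLen  <- ifelse(short > 1L, runs$len[short - 1L], -1L)
        rightLen <- ifelse(short < nrow(runs), runs$len[short + 1L], -1L)
        i <- short[order(runs$len[short], -pmax(leftLen, rightLen),
                         runs$start[short])][1L]
        left  <- if (i > 1L) runs$len[i - 1L] else -1L
        right <- if (i < nrow(runs)) runs$len[i + 1L] else -1L
        donor <- if (left >= right) i - 1L else i + 1L
        lab[runs$start[i]:runs$end[i]] <- runs$label[donor]
    }
    partition@smoothedLabels <- lab
    partition@exemptions <-
        partition@dates[lab != partition@rawLabels]
    validObject(partition)
    partition
}

#' Accessors for ClusterPartition
#' @param x a [ClusterPartition-class].
#' @name ClusterPartition-accessors
NULL

#' @rdname ClusterPartition-accessors
#' @export
setMethod("rawLabels", "ClusterPartition", function(x)
    setNames(x@rawLabels, format(x@dates)))

#' @rdname ClusterPartition-accessors
#' @export
setMethod("smoothedLabels", "ClusterPartition", function(x)
    setNames(x@smoothedLabels, format(x@dates)))

#' @rdname ClusterPartition-accessors
#' @export
setMethod("exemptions", "ClusterPartition", function(x) x@exemptions)

#' @rdname ClusterPartition-accessors
#' @export
setMethod("nClusters", "ClusterPartition", function(x) x@nClusters)

setMethod("show", "ClusterPartition", function(object) {
    cat("ClusterPartition:", length(object@dates), "dates in",
        object@nClusters, "clusters;", length(object@exemptions),
        "exemption(s) smoothed\n")
})

#' @describeIn clusterCodebook coerce a partition to a per-date data.frame
#'   (columns `date`, `raw`, `smoothed`, `exemption`).
#' @param x a [ClusterPartition-class].
#' @param row.names,optional,... ignored; present for the generic.
#' @export
as.data.frame.ClusterPartition <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
    data.frame(date = x@dates, raw = x@rawLabels, smoothed = x@smoothedLabels,
               exemption = x@dates %in% x@exemptions)
}

#' One-call temporal classification of a community series
#'
#' Convenience wrapper chaining [trainSOM()], [clusterCodebook()] and
#' [smoothContiguity()] on the sample profiles of a series.
#'
#' @param series a [CommunityTimeSeries-class].
#' @param grid,epochs,seed,init passed to [trainSOM()].
#' @param kRange,k passed to [clusterCodebook()].
#' @param minRun passed to [smoothContiguity()].
#' @return a list with elements `model` ([SOMModel-class]) and `partition`
#'   ([ClusterPartition-class]).
#' @export
classifyDates <- function(series, grid = NULL, epochs = 30L, seed = 1L,
                          init = "pca", kRange = 2:8, k = NULL,
                          minRun = 5L) {
    prof <- profiles(series)
    model <- trainSOM(prof, grid = grid, epochs = epochs, seed = seed,
                      init = init)
    part <- clusterCodebook(model, prof, sampleDates(series),
                            kRange = kRange, k = k)
    part <- smoothContiguity(part, minRun = minRun)
    list(model = model, partition = part)
}
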