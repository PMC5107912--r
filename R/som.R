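## Hex layout: odd rows shifted right by 0.5, row pitch sqrt(3)/2, so every
## interior unit has exactly six neighbours at planar distance 1.
hexCoords <- function(rows, cols) {
    i <- rep(seq_len(rows) - 1L, each = cols)
    j <- rep(seq_len(cols) - 1L, times = rows)
    cbind(x = j + 0.5 * (i %% 2L), y = i * sqrt(3) / 2)
}

#' Build a hexagonal SOM grid of given dimensions
#'
#' @param rows,cols lattice dimensions, both >= 2.
#' @return a [SOMGrid-class].
#' @export
somGrid <- function(rows, cols) {
    new("SOMGrid", rows = as.integer(rows), cols = as.integer(cols),
        topology = "hexagonal", unitCoords = hexCoords(rows, cols))
}

#' Choose a SOM lattice size from the sample count
#'
#' Applies the standard map-size heuristic: the target number of units is
#' `5 * sqrt(n)`. All rows x cols grids whose aspect ratio does not exceed
#' `maxAspect` are enumerated and the grid whose unit count is nearest the
#' target is selected; ties are broken toward the squarer grid and then
#' toward `rows >= cols`.
#'
#' @param n number of samples (>= 4).
#' @param maxAspect largest admissible `max(rows, cols) / min(rows, cols)`.
#' @return a [SOMGrid-class].
#' @examples
#' g <- mapSizeHeuristic(348)   # 10 x 9 lattice, 90 units
#' @export
mapSizeHeuristic <- function(n, maxAspect = 1.3) {
    stopifnot(n >= 4, maxAspect >= 1)
    target <- 5 * sqrt(n)
    upper <- max(3L, ceiling(sqrt(target * maxAspect)) + 2L)
    cand <- expand.grid(rows = 2:upper, cols = 2:upper)
    cand <- cand[pmax(cand$rows, cand$cols) / pmin(cand$rows, cand$cols)
                 <= maxAspect + 1e-12, ]
    cand$units <- cand$rows * cand$cols
    cand$aspect <- pmax(cand$rows, cand$cols) / pmin(cand$rows, cand$cols)
    o <- order(abs(cand$units - target), cand$aspect, cand$cols)
    best <- cand[o[1L], ]
    somGrid(best$rows, best$cols)
}

setMethod("show", "SOMGrid", function(object)
    cat("SOMGrid:", object@rows, "x", object@cols, "hexagonal lattice (",
        object@rows * object@cols, "units )\n"))

## Squared Euclidean distances between all rows of x and all rows of y.
rowCrossDist2 <- function(x, y) {
    d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
    d2[d2 < 0] <- 0
    d2
}

## PCA-plane initialization: units span +-2 sd along the first two PCs.
pcaInitCodebook <- function(data, grid) {
    ctr <- colMeans(data)
    cb <- matrix(ctr, nrow = grid@rows * grid@cols, ncol = ncol(data),
                 byrow = TRUE)
    pc <- tryCatch(prcomp(data, center = TRUE, scale. = FALSE), error = function(e) NULL)
    if (!is.null(pc) && ncol(pc$rotation) >= 1L) {
        co <- grid@unitCoords
        u1 <- if (diff(range(co[, 1L])) > 0)
            2 * (co[, 1L] - mean(range(co[, 1L]))) / diff(range(co[, 1L])) else
            rep(0, nrow(co))
        u2 <- if (diff(range(co[, 2L])) > 0)
            2 * (co[, 2L] - mean(range(co[, 2L]))) / diff(range(co[, 2L])) else
            rep(0, nrow(co))
        cb <- cb + outer(u1 * pc$sdev[1L], pc$rotation[, 1L])
        if (ncol(pc$rotation) >= 2L && pc$sdev[2L] > 0)
            cb <- cb + outer(u2 * pc$sdev[2L], pc$rotation[, 2L])
    }
    cb
}

#' Train a batch self-organizing map on a hexagonal lattice
#'
#' Batch Kohonen training: each epoch, every sample is assigned to its
#' best-matching unit (BMU) by Euclidean distance and every codebook vector
#' is replaced by the Gaussian-neighbourhood-weighted mean of the samples,
#' with the neighbourhood radius shrinking linearly from
#' `max(rows, cols) / 2` to 1 across epochs. Training is deterministic for a
#' fixed seed and initialization, so repeated runs are bit-identical.
#'
#' @param data samples x variables numeric matrix (no missing values), or a
#'   [CommunityTimeSeries-class] whose sample profiles are used.
#' @param grid a [SOMGrid-class]; defaults to [mapSizeHeuristic()] of the
#'   sample count.
#' @param epochs number of batch epochs.
#' @param seed integer seed (only consulted for `init = "random"`).
#' @param init `"pca"` (deterministic plane spanned by the first two
#'   principal components) or `"random"` (codebook sampled from the data).
#' @param scale if TRUE, scale each variable to unit variance first
#'   (constant variables are left unscaled).
#' @return a [SOMModel-class].
#' @export
setGeneric("trainSOM", function(data, grid = NULL, epochs = 30L,
                                seed = 1L, init = c("pca", "random"),
                                scale = FALSE)
    standardGeneric("trainSOM"))

#' @rdname trainSOM
#' @export
setMethod("trainSOM", "CommunityTimeSeries",
    function(data, grid, epochs, seed, init, scale)
        trainSOM(profiles(data), grid = grid, epochs = epochs, seed = seed,
                 init = init, scale = scale))

#' @rdname trainSOM
#' @export
setMethod("trainSOM", "matrix",
function(data, grid, epochs, seed, init, scale) {
    init <- match.arg(init)
    if (anyNA(data)) stop("'data' must not contain missing values")
    if (is.null(grid)) grid <- mapSizeHeuristic(nrow(data))
    nu <- grid@rows * grid@cols
    if (nrow(data) < nu / 2)
        warning("fewer than units/2 samples; the map will be sparsely used")
    if (scale) {
        s <- apply(data, 2L, sd)
        s[s == 0] <- 1
        data <- sweep(data, 2L, s, "/")
    }
    degenerate <- all(rowCrossDist2(data, data[1L, , drop = FALSE]) < 1e-24)
    if (degenerate)
        warning("all samples identical; quantization error is 0")

    cb <- if (init == "pca") {
        pcaInitCodebook(data, grid)
    } else {
        set.seed(seed)
        data[sample.int(nrow(data), nu, replace = nrow(data) < nu), ,
             drop = FALSE]
    }
    co <- grid@unitCoords
    latDist2 <- rowCrossDist2(co, co)
    r0 <- max(grid@rows, grid@cols) / 2
    radii <- if (epochs > 1L) seq(r0, 1, length.out = epochs) else 1
    qeHist <- numeric(epochs)
    bmuIdx <- integer(nrow(data))
    for (e in seq_len(epochs)) {
        d2 <- rowCrossDist2(data, cb)
        bmuIdx <- max.col(-d2, ties.method = "first")
        qeHist[e] <- mean(sqrt(d2[cbind(seq_len(nrow(data)), bmuIdx)]))
        h <- exp(-latDist2 / (2 * radii[e]^2))     # units x units
        w <- h[bmuIdx, , drop = FALSE]             # samples x units
        den <- colSums(w)
        num <- crossprod(w, data)
        upd <- den > 1e-12
        cb[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    }
    d2 <- rowCrossDist2(data, cb)
    bmuIdx <- max.col(-d2, ties.method = "first")
    qe <- mean(sqrt(d2[cbind(seq_len(nrow(data)), bmuIdx)]))
    ## report QE at the end of each epoch (the loop measures it just before
    ## the next epoch's update, so shift by one and close with the final QE)
    qeHist <- c(qeHist[-1L], qe)
    ord <- apply(d2, 1L, order)        # columns: per-sample unit ranking
    adj <- latDist2 <= 1.0001          # lattice adjacency (distance 1)
    te <- mean(!adj[cbind(ord[1L, ], ord[2L, ])])
    new("SOMModel", grid = grid, codebook = cb,
        quantizationError = qe, topographicError = te,
        bmu = as.integer(bmuIdx), qeHistory = qeHist)
})

#' @rdname SOMModel-accessors
#' @export
setMethod("codebook", "SOMModel", function(x) x@codebook)

#' @rdname SOMModel-accessors
#' @export
setMethod("bmu", "SOMModel", function(x) x@bmu)

#' Accessors for SOMModel
#' @param x a [SOMModel-class].
#' @name SOMModel-accessors
NULL

#' @rdname SOMModel-accessors
#' @export
setMethod("quantizationError", "SOMModel", function(x) x@quantizationError)

#' @rdname SOMModel-accessors
#' @export
setMethod("topographicError", "SOMModel", function(x) x@topographicError)

setMethod("show", "SOMModel", function(object) {
    cat("SOMModel on a", object@grid@rows, "x", object@grid@cols,
        "hexagonal lattice\n")
    cat(sprintf("  quantization error %.4g, topographic error %.4g\n",
                object@quantizationError, object@topographicError))
})

#' Unified distance matrix (U-matrix) of a trained SOM
#'
#' For every lattice unit, the mean Euclidean distance between its codebook
#' vector and those of its lattice-adjacent units (six in the interior of a
#' hexagonal lattice, fewer at the edges). Ridges of large values mark
#' cluster boundaries on the map.
#'
#' @param model a trained [SOMModel-class].
#' @return a rows x cols numeric matrix in lattice layout.
#' @export
uMatrix <- function(model) {
    grid <- model@grid
    latDist2 <- rowCrossDist2(grid@unitCoords, grid@unitCoords)
    adj <- latDist2 <= 1.0001
    diag(adj) <- FALSE
    cbd <- sqrt(rowCrossDist2(model@codebook, model@codebook))
    u <- vapply(seq_len(nrow(adj)), function(i) mean(cbd[i, adj[i, ]]),
                numeric(1L))
    matrix(u, nrow = grid@rows, ncol = grid@cols, byrow = TRUE)
}
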