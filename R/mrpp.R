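## Weighted mean within-group distance for one labelling.
## dmat: full symmetric distance matrix; w: weight scheme.
mrppDelta <- function(dmat, labels, weight) {
    groups <- unique(labels)
    n <- lengths(split(seq_along(labels), labels))[as.character(groups)]
    within <- vapply(groups, function(g) {
        idx <- which(labels == g)
        m <- dmat[idx, idx, drop = FALSE]
        sum(m) / (length(idx) * (length(idx) - 1L))
    }, numeric(1L))
    w <- switch(weight,
        "n"          = n / sum(n),
        "n-1"        = (n - 1L) / sum(n - 1L),
        "unweighted" = rep(1 / length(n), length(n)),
        stop("unknown weight scheme '", weight, "'"))
    sum(w * within)
}

#' Multi-response permutation procedure
#'
#' Tests whether community composition differs among a-priori groups. The
#' observed statistic is the group-size-weighted mean within-group distance
#' `delta`; its null distribution is obtained by uniformly permuting the
#' group labels. The chance-corrected agreement is `A = 1 - delta/E(delta)`
#' (A = 1 when groups are internally identical, ~0 under random labels), and
#' the Monte-Carlo p-value uses the +1 correction,
#' `p = (1 + #\{delta_perm <= delta_obs\}) / (1 + nPerm)`, so the smallest
#' attainable p is `1/(1 + nPerm)` (0.001 at 999 permutations).
#'
#' @param data samples x variables matrix (typically community profiles).
#' @param labels group label per sample; every group needs >= 2 members.
#' @param nPerm number of label permutations.
#' @param seed integer seed for the permutations (`NA` to leave the RNG
#'   state untouched).
#' @param distance `"euclidean"` or `"bray"` (Bray-Curtis via
#'   [vegan::vegdist()]).
#' @param weight group weighting for delta: `"n"` (group size, default),
#'   `"n-1"`, or `"unweighted"`.
#' @return an [MRPPResult-class].
#' @export
mrppTest <- function(data, labels, nPerm = 999L, seed = 1L,
                     distance = c("euclidean", "bray"),
                     weight = c("n", "n-1", "unweighted")) {
    distance <- match.arg(distance)
    weight <- match.arg(weight)
    labels <- as.character(labels)
    sizes <- table(labels)
    if (length(sizes) < 2L)
        stop("at least two groups are required")
    if (any(sizes < 2L))
        stop("group(s) with fewer than 2 members: ",
             paste(names(sizes)[sizes < 2L], collapse = ", "))
    if (nPerm < 1L) stop("nPerm must be >= 1")
    dmat <- as.matrix(if (distance == "euclidean") dist(data)
                      else vegan::vegdist(data, method = "bray"))
    if (any(!is.finite(dmat)))
        stop("non-finite distances between samples")
    dObs <- mrppDelta(dmat, labels, weight)
    if (!is.na(seed)) set.seed(seed)
    dPerm <- vapply(seq_len(nPerm), function(i)
        mrppDelta(dmat, sample(labels), weight), numeric(1L))
    dExp <- mean(dPerm)
    new("MRPPResult",
        A = if (dExp > 0) 1 - dObs / dExp else 0,
        deltaObserved = dObs, deltaExpected = dExp,
        pValue = (1 + sum(dPerm <= dObs + 1e-12)) / (1 + nPerm),
        nPermutations = as.integer(nPerm), seed = as.integer(seed))
}

setMethod("show", "MRPPResult", function(object) {
    cat(sprintf(
        "MRPP: A = %.4f, delta = %.4g (expected %.4g), p = %.4g (%d permutations)\n",
        object@A, object@deltaObserved, object@deltaExpected,
        object@pValue, object@nPermutations))
})

#' Pairwise MRPP between all cluster pairs
#'
#' Runs [mrppTest()] on every unordered pair of groups (subsetting the rows
#' first) plus the all-groups test, mirroring the usual
#' cluster-validation table (pair, A, p). Pairwise p-values are reported raw
#' by default; Holm adjustment is available.
#'
#' @inheritParams mrppTest
#' @param adjust if TRUE, Holm-adjust the pairwise p-values (the overall row
#'   is never adjusted).
#' @return a `data.frame` with columns `group1`, `group2` (`NA` for the
#'   overall row), `A`, `p`, `n1`, `n2`.
#' @export
pairwiseMRPP <- function(data, labels, nPerm = 999L, seed = 1L,
                         distance = c("euclidean", "bray"),
                         weight = c("n", "n-1", "unweighted"),
                         adjust = FALSE) {
    distance <- match.arg(distance)
    weight <- match.arg(weight)
    labels <- as.character(labels)
    groups <- sort(unique(labels))
    pairs <- utils::combn(groups, 2L)
    rows <- lapply(seq_len(ncol(pairs)), function(j) {
        keep <- labels %in% pairs[, j]
        r <- mrppTest(data[keep, , drop = FALSE], labels[keep],
                      nPerm = nPerm, seed = seed, distance = distance,
                      weight = weight)
        data.frame(group1 = pairs[1L, j], group2 = pairs[2L, j],
                   A = r@A, p = r@pValue,
                   n1 = sum(labels == pairs[1L, j]),
                   n2 = sum(labels == pairs[2L, j]))
    })
    out <- do.call(rbind, rows)
    if (adjust) out$p <- stats::p.adjust(out$p, method = "holm")
    all <- mrppTest(data, labels, nPerm = nPerm, seed = seed,
                    distance = distance, weight = weight)
    rbind(out, data.frame(group1 = "all", group2 = NA_character_,
                          A = all@A, p = all@pValue,
                          n1 = length(labels), n2 = NA_integer_))
}
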