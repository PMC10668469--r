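#' Per-bin mean z-score profiles over gestational age
#'
#' Samples are grouped into gestational-age bins (half-open `[lo, hi)`
#' intervals from `binEdges`, with the last bin closed on the right); per
#' feature, the mean log-normalized value in each bin is computed and then
#' z-scored across bins (mean 0, SD 1). Features constant across bins are
#' excluded and reported in the `"constant"` attribute.
#'
#' @param norm numeric matrix of log-normalized values, features x samples.
#' @param ages numeric gestational ages (weeks), one per sample.
#' @param binEdges increasing bin edges (default `c(8,10,12,14,16,18,19)`,
#'   i.e. bins 8-10, 10-12, 12-14, 14-16, 16-18, 18-19).
#' @return matrix of z-score profiles (features x bins) with attribute
#'   `constant` (character vector of excluded features).
#' @export
binMeanZscores <- function(norm, ages, binEdges = c(8, 10, 12, 14, 16, 18, 19)) {
    norm <- as.matrix(norm)
    ages <- as.numeric(ages)
    if (length(ages) != ncol(norm))
        stop("one age per sample required")
    if (is.unsorted(binEdges, strictly = TRUE))
        stop("binEdges must be strictly increasing")
    lo <- binEdges[1L]; hi <- binEdges[length(binEdges)]
    out <- which(ages < lo | ages > hi)
    if (length(out))
        stop(sprintf("sample age(s) outside [%g, %g]: %s", lo, hi,
                     paste(signif(ages[out], 4), collapse = ", ")))
    bin <- findInterval(ages, binEdges, rightmost.closed = TRUE)
    nb <- length(binEdges) - 1L
    binLabels <- sprintf("[%g,%g%s", binEdges[-length(binEdges)],
                         binEdges[-1L],
                         c(rep(")", nb - 1L), "]"))
    empty <- setdiff(seq_len(nb), unique(bin))
    if (length(empty))
        stop("empty age bin(s): ", paste(binLabels[empty], collapse = ", "))
    binMeans <- vapply(seq_len(nb), function(b)
        rowMeans(norm[, bin == b, drop = FALSE]), numeric(nrow(norm)))
    if (is.null(dim(binMeans)))
        binMeans <- matrix(binMeans, nrow = 1L,
                           dimnames = list(rownames(norm), NULL))
    colnames(binMeans) <- binLabels
    sds <- apply(binMeans, 1L, sd)
    constant <- sds <= .Machine$double.eps^0.5 * pmax(abs(rowMeans(binMeans)), 1)
    z <- (binMeans - rowMeans(binMeans)) / sds
    z <- z[!constant, , drop = FALSE]
    structure(z, constant = rownames(binMeans)[constant])
}

#' Cluster temporal z-score profiles
#'
#' Pairwise distance `1 - Pearson(profile_i, profile_j)`, average-linkage
#' agglomerative clustering cut at `cutHeight`; clusters smaller than
#' `minSize` are dissolved and their members reported as unassigned.
#' Features are processed in lexicographic id order, so the partition is
#' invariant to input ordering; surviving clusters are renumbered by
#' decreasing size.
#'
#' @param zpm z-profile matrix from [binMeanZscores()].
#' @param minSize minimum members per cluster (default 15).
#' @param cutHeight correlation-distance cut height (default 0.25).
#' @return list with `assignments` (named integer, `NA` = unassigned),
#'   `sizes` (per-cluster member counts), `profiles` (cluster-mean
#'   z-profiles) and `unassigned` (character vector).
#' @export
clusterZProfiles <- function(zpm, minSize = 15, cutHeight = 0.25) {
    zpm <- as.matrix(zpm)
    if (is.null(rownames(zpm))) stop("z-profile matrix needs feature ids")
    if (nrow(zpm) < minSize)
        stop(sprintf("need at least minSize = %d features", minSize))
    zpm <- zpm[order(rownames(zpm)), , drop = FALSE]
    sds <- apply(zpm, 1L, sd)
    if (all(sds == 0)) stop("all profiles are constant")
    d <- as.dist(1 - cor(t(zpm)))
    d[d < 0] <- 0  # numeric fuzz on identical profiles
    tree <- hclust(d, method = "average")
    raw <- cutree(tree, h = cutHeight)
    tab <- table(raw)
    keepIds <- names(tab)[tab >= minSize]
    assignments <- rep(NA_integer_, nrow(zpm))
    names(assignments) <- rownames(zpm)
    if (length(keepIds)) {
        sizes <- sort(tab[keepIds], decreasing = TRUE)
        newId <- setNames(seq_along(sizes), names(sizes))
        inKeep <- as.character(raw) %in% keepIds
        assignments[inKeep] <- newId[as.character(raw)[inKeep]]
    }
    k <- max(assignments, na.rm = TRUE)
    if (!is.finite(k)) k <- 0L
    profiles <- if (k > 0) t(vapply(seq_len(k), function(cl)
        colMeans(zpm[which(assignments == cl), , drop = FALSE]),
        numeric(ncol(zpm)))) else
        matrix(numeric(), 0L, ncol(zpm))
    if (k > 0) rownames(profiles) <- paste0("cluster", seq_len(k))
    colnames(profiles) <- colnames(zpm)
    list(assignments = assignments,
         sizes = if (k > 0) as.integer(table(assignments)) else integer(),
         profiles = profiles,
         unassigned = names(assignments)[is.na(assignments)])
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions (pair-counting form).
#' Unassigned features (`NA` in either labelling) are dropped.
#'
#' @param a,b cluster labellings of the same features.
#' @return ARI in \[-1, 1\]; 1 means identical partitions.
#' @export
adjustedRandIndex <- function(a, b) {
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    if (!length(a)) stop("no jointly assigned features")
    tab <- table(a, b)
    n <- sum(tab)
    sumIJ <- sum(choose(tab, 2))
    sumI <- sum(choose(rowSums(tab), 2))
    sumJ <- sum(choose(colSums(tab), 2))
    expected <- sumI * sumJ / choose(n, 2)
    maxIdx <- (sumI + sumJ) / 2
    if (maxIdx == expected) return(1)
    (sumIJ - expected) / (maxIdx - expected)
}
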