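#' Per-gene directional statistics for reporter analysis
#'
#' Extracts from an mRNA DE table the adjusted p value (clamped to
#' `[eps, 1 - eps]`) and the direction sign of each gene. Genes with
#' `log2FoldChange == 0` or missing values are excluded with a warning.
#'
#' @param de a [DEResults-class] table.
#' @param eps clamping epsilon (default 1e-12), preventing infinite
#'   normal quantiles.
#' @return data.frame with `gene_id`, `p`, `sign`.
#' @export
geneStats <- function(de, eps = 1e-12) {
    p <- de$padj
    lfc <- de$log2FoldChange
    bad <- is.na(p) | is.na(lfc) | lfc == 0
    if (any(bad))
        warning(sprintf("%d gene(s) excluded (missing statistics or zero fold change)",
                        sum(bad)))
    data.frame(gene_id = rownames(de)[!bad],
               p = pmin(pmax(p[!bad], eps), 1 - eps),
               sign = ifelse(lfc[!bad] > 0, 1, -1),
               stringsAsFactors = FALSE)
}

#' Signed directional z score
#'
#' Maps a (two-sided adjusted) p value and a fold-change sign to a
#' direction-specific standard-normal score: for direction `"up"`,
#' `p_dir = p/2` for up-regulated genes and `1 - p/2` for down-regulated
#' ones (mirrored for `"down"`); the score is the upper normal quantile
#' `qnorm(1 - p_dir)`.
#'
#' @param p p values in (0, 1).
#' @param sign +1 or -1 per gene.
#' @param direction `"up"` or `"down"`.
#' @return numeric z scores.
#' @export
signedDirectionalZ <- function(p, sign, direction = c("up", "down")) {
    direction <- match.arg(direction)
    if (any(p <= 0 | p >= 1)) stop("p values must lie strictly in (0, 1)")
    if (!all(sign %in% c(-1, 1))) stop("sign must be +1 or -1")
    up <- if (direction == "up") sign > 0 else sign < 0
    pDir <- ifelse(up, p / 2, 1 - p / 2)
    qnorm(1 - pDir)
}

#' Aggregate gene z scores into a set score
#'
#' `Z = sum(z) / sqrt(k)`: under independent standard-normal gene scores
#' the set score is again standard normal.
#'
#' @param z numeric vector of member z scores (k >= 1).
#' @return the set score.
#' @export
setScore <- function(z) {
    if (!length(z)) stop("empty set")
    sum(z) / sqrt(length(z))
}

#' Permutation p value for a set score
#'
#' Draws `nPerm` random size-`k` gene subsets of the background without
#' replacement, recomputes the set score and applies the add-one
#' estimator `p = (1 + #\{Z* >= Z\}) / (1 + nPerm)`. In exhaustive mode all
#' `choose(n, k)` subsets are enumerated and the exact proportion
#' `#\{Z* >= Z\} / choose(n, k)` is returned instead.
#'
#' @param zObs observed set score.
#' @param background numeric vector of per-gene z scores (length >= k).
#' @param k set size.
#' @param nPerm number of permutations (default 1000).
#' @param exhaustive enumerate all subsets instead of sampling.
#' @return the permutation p value.
#' @export
permutationPvalue <- function(zObs, background, k, nPerm = 1000,
                              exhaustive = FALSE) {
    n <- length(background)
    if (k > n) stop("background smaller than set size")
    if (nPerm < 1) stop("nPerm must be >= 1")
    if (exhaustive) {
        idx <- combn(n, k)
        zStar <- colSums(matrix(background[idx], nrow = k)) / sqrt(k)
        return(mean(zStar >= zObs))
    }
    zStar <- vapply(seq_len(nPerm), function(i)
        sum(background[sample.int(n, k)]) / sqrt(k), 0)
    (1 + sum(zStar >= zObs)) / (1 + nPerm)
}

#' Directional reporter gene-set analysis
#'
#' For each gene set: intersect members with the gene statistics, skip
#' sets with `k` outside `[minK, maxK]`, compute up- and down-directional
#' set scores from signed inverse-normal gene scores, and assess each
#' against a subset-sampling permutation null over the corresponding
#' directional background (all genes with statistics). P values are
#' Benjamini-Hochberg adjusted within each direction across evaluated
#' sets; each set is called `up`, `down` (the direction with adjusted
#' p < `alpha`; the smaller one if both) or `none`.
#'
#' The same permuted gene subsets are reused for the up and down scores,
#' so flipping every gene's sign under an identical seed swaps the up and
#' down outputs exactly.
#'
#' @param stats data.frame from [geneStats()].
#' @param gsc a [GeneSetCollection-class].
#' @param minK,maxK evaluated set-size window (defaults 5 and 500).
#' @param nPerm permutations per set (default 1000).
#' @param alpha adjusted-p call cutoff (default 0.05).
#' @param exhaustive use exhaustive enumeration in [permutationPvalue()].
#' @return list with `records` (data.frame: set_id, k, Z_up, Z_down, p_up,
#'   p_down, padj_up, padj_down, call) and `skipped` (data.frame: set_id,
#'   reason).
#' @export
runReporter <- function(stats, gsc, minK = 5, maxK = 500, nPerm = 1000,
                        alpha = 0.05, exhaustive = FALSE) {
    if (!nrow(stats)) stop("empty gene statistics")
    if (!is(gsc, "GeneSetCollection") || nSets(gsc) == 0L)
        stop("empty gene-set collection")
    zUp <- signedDirectionalZ(stats$p, stats$sign, "up")
    zDown <- signedDirectionalZ(stats$p, stats$sign, "down")
    nGenes <- nrow(stats)
    ids <- setIds(gsc)
    members <- setMembers(gsc)
    rows <- list(); skip <- list()
    for (s in seq_along(ids)) {
        idx <- match(members[[s]], stats$gene_id)
        idx <- idx[!is.na(idx)]
        k <- length(idx)
        if (k < minK || k > maxK) {
            skip[[length(skip) + 1L]] <- data.frame(
                set_id = ids[s],
                reason = if (k < minK) "k<min" else "k>max",
                k = k, stringsAsFactors = FALSE)
            next
        }
        ZupObs <- setScore(zUp[idx])
        ZdownObs <- setScore(zDown[idx])
        if (exhaustive && choose(nGenes, k) <= 1e5) {
            pUp <- permutationPvalue(ZupObs, zUp, k, nPerm, exhaustive = TRUE)
            pDown <- permutationPvalue(ZdownObs, zDown, k, nPerm,
                                       exhaustive = TRUE)
        } else {
            permIdx <- matrix(0L, nrow = k, ncol = nPerm)
            for (j in seq_len(nPerm))
                permIdx[, j] <- sample.int(nGenes, k)
            zStarUp <- colSums(matrix(zUp[permIdx], nrow = k)) / sqrt(k)
            zStarDown <- colSums(matrix(zDown[permIdx], nrow = k)) / sqrt(k)
            pUp <- (1 + sum(zStarUp >= ZupObs)) / (1 + nPerm)
            pDown <- (1 + sum(zStarDown >= ZdownObs)) / (1 + nPerm)
        }
        rows[[length(rows) + 1L]] <- data.frame(
            set_id = ids[s], k = k, Z_up = ZupObs, Z_down = ZdownObs,
            p_up = pUp, p_down = pDown, stringsAsFactors = FALSE)
    }
    records <- if (length(rows)) do.call(rbind, rows) else
        data.frame(set_id = character(), k = integer(), Z_up = numeric(),
                   Z_down = numeric(), p_up = numeric(), p_down = numeric(),
                   stringsAsFactors = FALSE)
    records$padj_up <- adjustBH(records$p_up)
    records$padj_down <- adjustBH(records$p_down)
    records$call <- character(nrow(records))
    if (nrow(records)) {
        records$call <- "none"
        upSig <- records$padj_up < alpha
        downSig <- records$padj_down < alpha
        records$call[upSig &
            (!downSig | records$padj_up <= records$padj_down)] <- "up"
        records$call[downSig &
            (!upSig | records$padj_down < records$padj_up)] <- "down"
    }
    skipped <- if (length(skip)) do.call(rbind, skip) else
        data.frame(set_id = character(), reason = character(), k = integer(),
                   stringsAsFactors = FALSE)
    list(records = records, skipped = skipped)
}

#' Reporter analysis on a random control gene selection
#'
#' Samples `n` differentially expressed genes without replacement
#' (optionally excluding, e.g., all predicted miRNA targets) and reruns
#' the reporter analysis on that subset, emulating random and
#' random-non-target control runs.
#'
#' @param mrnaDe a [DEResults-class] for the mRNA layer.
#' @param n number of genes to select.
#' @param gsc a [GeneSetCollection-class].
#' @param exclude character vector of gene ids excluded from the pool.
#' @param alphaDe DE cutoff defining the eligible pool (default 0.05,
#'   adjusted p).
#' @param ... passed on to [runReporter()].
#' @return list with `genes` (the selection) plus the [runReporter()]
#'   output.
#' @export
randomControlRun <- function(mrnaDe, n, gsc, exclude = character(),
                             alphaDe = 0.05, ...) {
    sig <- !is.na(mrnaDe$padj) & mrnaDe$padj < alphaDe
    pool <- setdiff(rownames(mrnaDe)[sig], exclude)
    if (length(pool) < n)
        stop(sprintf("eligible pool (%d) smaller than n = %d",
                     length(pool), n))
    genes <- sort(sample(pool, n))
    stats <- geneStats(mrnaDe[genes, , drop = FALSE])
    c(list(genes = genes), runReporter(stats, gsc, ...))
}
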