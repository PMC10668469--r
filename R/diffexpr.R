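#' @importFrom stats glm pnorm pt qnorm coef vcov lm sd cor var median
#'   prcomp rnbinom rnorm runif setNames p.adjust complete.cases t.test
#'   cutree hclust as.dist ks.test as.formula
#' @importFrom utils head tail
#' @importFrom MASS negative.binomial
NULL

#' Median-of-ratios size factors
#'
#' Per-sample scale factors: for each feature with positive counts in all
#' samples, take the ratio of its count to its geometric mean across
#' samples; a sample's factor is the median of these ratios, rescaled so
#' the factors have geometric mean 1.
#'
#' @param cm an [OmicCounts-class] object or a count matrix.
#' @param pseudoReference if `TRUE`, fall back to computing the geometric
#'   mean over positive counts only, so libraries with no feature positive
#'   everywhere can still be normalized.
#' @return named positive numeric vector of size factors (geometric mean 1).
#' @export
medianRatioSizeFactors <- function(cm, pseudoReference = FALSE) {
    cts <- if (is(cm, "OmicCounts")) counts(cm) else as.matrix(cm)
    if (pseudoReference) {
        logGeo <- apply(cts, 1L, function(x) {
            pos <- x > 0
            if (!any(pos)) return(NA_real_)
            mean(log(x[pos]))
        })
        use <- is.finite(logGeo)
    } else {
        allPos <- rowSums(cts > 0) == ncol(cts)
        if (!any(allPos))
            stop("no feature has positive counts in all samples; ",
                 "re-run with pseudoReference = TRUE")
        logGeo <- rowMeans(log(cts))
        logGeo[!allPos] <- NA_real_
        use <- allPos
    }
    sf <- vapply(seq_len(ncol(cts)), function(j)
        median(cts[use, j] / exp(logGeo[use]), na.rm = TRUE), 0)
    names(sf) <- colnames(cts)
    if (any(!is.finite(sf) | sf <= 0))
        stop("non-positive size factor; counts too sparse for median-of-ratios")
    sf / exp(mean(log(sf)))
}

#' Normalize counts by size factors
#'
#' @param cm an [OmicCounts-class] or count matrix.
#' @param sf named size factors matching the samples (defaults to
#'   [medianRatioSizeFactors()]).
#' @param log2 if `TRUE`, return `log2(normalized + pseudocount)`.
#' @param pseudocount added before the log transform.
#' @return numeric matrix of normalized (optionally log2) values.
#' @export
normalizeCounts <- function(cm, sf = NULL, log2 = FALSE, pseudocount = 1) {
    cts <- if (is(cm, "OmicCounts")) counts(cm) else as.matrix(cm)
    if (is.null(sf)) sf <- medianRatioSizeFactors(cts)
    if (is.null(names(sf)) || !setequal(names(sf), colnames(cts)) ||
        length(sf) != ncol(cts))
        stop("size factors do not match the samples of the matrix")
    sf <- sf[colnames(cts)]
    out <- sweep(cts, 2L, sf, "/")
    if (log2) out <- log2(out + pseudocount)
    out
}

.rowVars <- function(x) {
    m <- rowMeans(x)
    rowSums((x - m)^2) / (ncol(x) - 1L)
}

# Per-feature NB dispersion: method of moments on normalized counts,
# shrunk 50/50 toward a fitted 1/mu trend, floored.
.estimateDispersions <- function(norm, sf, floor = 1e-8) {
    mu <- rowMeans(norm)
    v <- .rowVars(norm)
    xi <- mean(1 / sf)  # Var(K/s) = mu/s + alpha*mu^2 per sample
    alphaMom <- (v - mu * xi) / mu^2
    alphaMom[!is.finite(alphaMom)] <- NA_real_
    use <- !is.na(alphaMom) & alphaMom > 0 & mu > 1
    if (sum(use) >= 10L) {
        fit <- lm(alphaMom[use] ~ I(1 / mu[use]))
        a0 <- max(coef(fit)[1L], 0); a1 <- max(coef(fit)[2L], 0)
        if (a0 == 0 && a1 == 0) a0 <- median(alphaMom[use])
    } else {
        a0 <- median(alphaMom[use], na.rm = TRUE)
        if (!is.finite(a0)) a0 <- 0.1
        a1 <- 0
    }
    trend <- a0 + a1 / mu
    alpha <- 0.5 * pmax(alphaMom, 0, na.rm = FALSE) + 0.5 * trend
    alpha[is.na(alphaMom)] <- trend[is.na(alphaMom)]
    pmax(alpha, floor)
}

#' Negative-binomial differential expression against a continuous covariate
#'
#' Per-feature NB regression with log link; design is intercept +
#' covariate (+ optional extra covariates such as batch), with
#' log size factors as offsets. Dispersion is estimated per feature by
#' method of moments on normalized counts, shrunk 50/50 toward a fitted
#' mean-dispersion trend and floored at 1e-8. The covariate coefficient is
#' reported in log2 units per week with a Wald t test (residual degrees of
#' freedom), followed by Benjamini-Hochberg adjustment across features with
#' `status == "ok"`.
#'
#' @param cm an [OmicCounts-class] object with sample metadata in
#'   `colData`, or a count matrix (then supply `sampleData`).
#' @param covariate name of the continuous covariate column (default
#'   `"gestational_age"`).
#' @param extraCovariates character vector of additional fixed-effect
#'   columns (e.g. `"batch"`); silently dropped if absent or constant.
#' @param sampleData sample metadata when `cm` is a bare matrix.
#' @param sf optional precomputed size factors.
#' @return a [DEResults-class] table, one row per feature.
#' @export
fitNbContinuous <- function(cm, covariate = "gestational_age",
                            extraCovariates = "batch", sampleData = NULL,
                            sf = NULL) {
    if (is(cm, "OmicCounts")) {
        cts <- counts(cm)
        sdat <- as.data.frame(colData(cm))
    } else {
        cts <- as.matrix(cm)
        if (is.null(sampleData)) stop("sampleData required for a bare matrix")
        sdat <- as.data.frame(sampleData)
        if ("sample_id" %in% colnames(sdat)) rownames(sdat) <- sdat$sample_id
        if (!all(colnames(cts) %in% rownames(sdat)))
            stop("sampleData does not cover all samples")
        sdat <- sdat[colnames(cts), , drop = FALSE]
    }
    if (ncol(cts) < 6L) stop("need at least 6 samples")
    if (!covariate %in% colnames(sdat))
        stop("covariate column not found: ", covariate)
    x <- as.numeric(sdat[[covariate]])
    if (sd(x) == 0) stop("covariate does not vary")
    extras <- intersect(extraCovariates, colnames(sdat))
    extras <- extras[vapply(extras,
                            function(e) length(unique(sdat[[e]])) > 1L,
                            TRUE)]
    design <- data.frame(x = x)
    for (e in extras) design[[e]] <- factor(sdat[[e]])
    if (is.null(sf)) sf <- medianRatioSizeFactors(cts)
    norm <- normalizeCounts(cts, sf)
    alpha <- .estimateDispersions(norm, sf)
    off <- log(sf)
    form <- if (length(extras))
        as.formula(paste("y ~ x +", paste(extras, collapse = " + ")))
    else y ~ x
    n <- nrow(cts)
    res <- data.frame(baseMean = rowMeans(norm),
                      log2FoldChange = NA_real_, lfcSE = NA_real_,
                      stat = NA_real_, pvalue = NA_real_, padj = NA_real_,
                      status = "ok", row.names = rownames(cts),
                      stringsAsFactors = FALSE)
    dfResid <- ncol(cts) - (2L + sum(vapply(extras, function(e)
        nlevels(design[[e]]) - 1L, 0L)))
    for (g in seq_len(n)) {
        y <- cts[g, ]
        if (all(y == 0)) {
            res$status[g] <- "low_count"
            next
        }
        fit <- tryCatch({
            dat <- design; dat$y <- y
            suppressWarnings(glm(form, data = dat,
                family = negative.binomial(theta = 1 / alpha[g], link = "log"),
                offset = off))
        }, error = function(e) NULL)
        if (is.null(fit) || !fit$converged || !"x" %in% names(coef(fit)) ||
            !is.finite(coef(fit)[["x"]])) {
            res$status[g] <- "failed"
            next
        }
        # summary.glm with dispersion fixed at 1 (NB variance is in the family)
        se <- tryCatch(sqrt(diag(vcov(fit, dispersion = 1))[["x"]]),
                       error = function(e) NA_real_)
        if (!is.finite(se) || se <= 0) {
            res$status[g] <- "failed"
            next
        }
        b <- coef(fit)[["x"]]
        res$log2FoldChange[g] <- b / log(2)
        res$lfcSE[g] <- se / log(2)
        res$stat[g] <- b / se
        res$pvalue[g] <- 2 * pt(-abs(b / se), df = dfResid)
    }
    ok <- res$status == "ok"
    res$padj[ok] <- adjustBH(res$pvalue[ok])
    .DEResults(res, design = paste(c("~", covariate,
                                     if (length(extras)) paste("+", extras)),
                                   collapse = " "),
               covariate = covariate, sizeFactors = sf,
               dispersions = alpha, dfResid = dfResid)
}

#' Two-group differential abundance on log2 values
#'
#' Welch t test per feature on log2 abundances; `log2FoldChange` is the
#' group-mean difference (second level minus first). P values are reported
#' raw (no multiplicity adjustment by default), matching how differential
#' protein abundance is called; `padj` is set equal to `pvalue` unless
#' `adjust = TRUE`.
#'
#' @param abundances numeric matrix of log2 abundances, features x samples
#'   (NAs allowed; a feature needs >= 2 observed values per group).
#' @param groups factor/character of group labels, one per sample.
#' @param adjust if `TRUE`, apply Benjamini-Hochberg to the p values.
#' @return a [DEResults-class] table.
#' @export
fitTwoGroup <- function(abundances, groups, adjust = FALSE) {
    abundances <- as.matrix(abundances)
    groups <- factor(groups)
    if (nlevels(groups) != 2L) stop("exactly two groups required")
    if (length(groups) != ncol(abundances))
        stop("one group label per sample required")
    g1 <- groups == levels(groups)[1L]
    res <- data.frame(baseMean = rowMeans(abundances, na.rm = TRUE),
                      log2FoldChange = NA_real_, lfcSE = NA_real_,
                      stat = NA_real_, pvalue = NA_real_, padj = NA_real_,
                      status = "ok", row.names = rownames(abundances),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(abundances))) {
        a <- abundances[i, g1]; b <- abundances[i, !g1]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2L || length(b) < 2L) {
            res$status[i] <- "failed"
            next
        }
        lfc <- mean(b) - mean(a)
        res$log2FoldChange[i] <- lfc
        if (sd(a) == 0 && sd(b) == 0) {
            # degenerate: identical within groups
            res$lfcSE[i] <- 0
            res$stat[i] <- if (lfc == 0) 0 else sign(lfc) * Inf
            res$pvalue[i] <- if (lfc == 0) 1 else 0
            next
        }
        tt <- t.test(b, a)
        res$lfcSE[i] <- tt$stderr
        res$stat[i] <- unname(tt$statistic)
        res$pvalue[i] <- tt$p.value
    }
    ok <- res$status == "ok"
    res$padj[ok] <- if (adjust) adjustBH(res$pvalue[ok]) else res$pvalue[ok]
    .DEResults(res, design = "two-group Welch",
               groups = levels(groups), adjusted = adjust)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement. `NA` values
#' propagate and are excluded from the number of tests.
#'
#' @param p numeric vector of p values in \[0, 1\] (NAs allowed).
#' @return adjusted p values, same length and order as `p`.
#' @export
adjustBH <- function(p) {
    if (!is.numeric(p)) stop("p must be numeric")
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Sample PCA on log-normalized values
#'
#' PCA of samples using the `nTop` highest-variance features of a
#' feature-centered log-normalized matrix.
#'
#' @param norm numeric matrix (features x samples), typically
#'   `normalizeCounts(..., log2 = TRUE)`.
#' @param nTop number of top-variance features to use (default 500).
#' @return list with `coordinates` (samples x PCs) and
#'   `varianceExplained` (fraction per PC, non-increasing).
#' @export
pcaSamples <- function(norm, nTop = 500) {
    norm <- as.matrix(norm)
    if (ncol(norm) < 2L) stop("need at least 2 samples")
    v <- .rowVars(norm)
    keep <- head(order(v, decreasing = TRUE), min(nTop, nrow(norm)))
    keep <- keep[v[keep] > 0]
    if (!length(keep)) stop("no feature with positive variance")
    pc <- prcomp(t(norm[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    list(coordinates = pc$x, varianceExplained = ve)
}

#' Small-RNA subtype composition
#'
#' Proportion of total counts attributed to each subtype, plus the number
#' of distinct species per subtype.
#'
#' @param cm an [OmicCounts-class] object.
#' @return data.frame with `subtype`, `countProportion`, `nSpecies`.
#' @export
subtypeComposition <- function(cm) {
    if (nrow(cm) == 0L) stop("empty count matrix")
    st <- featureSubtype(cm)
    tot <- rowSums(counts(cm))
    agg <- tapply(tot, st, sum)
    data.frame(subtype = names(agg),
               countProportion = as.numeric(agg) / sum(tot),
               nSpecies = as.integer(table(st)[names(agg)]),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Split DE features by direction of change
#'
#' @param de a [DEResults-class] table.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return list with `up` and `down` character vectors of feature ids;
#'   features with `log2FoldChange == 0` belong to neither.
#' @export
splitByDirection <- function(de, alpha = 0.05) {
    sig <- !is.na(de$padj) & de$padj < alpha
    list(up = rownames(de)[sig & de$log2FoldChange > 0],
         down = rownames(de)[sig & de$log2FoldChange < 0])
}
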