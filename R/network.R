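#' Candidate miRNA-mRNA pairs
#'
#' Restricts a predicted target map to pairs whose miRNA and mRNA are both
#' differentially expressed.
#'
#' @param deMirnas character vector of DE miRNA ids.
#' @param deMrnas character vector of DE mRNA ids.
#' @param tm a [TargetMap-class].
#' @return a [TargetMap-class] of the retained pairs.
#' @export
candidatePairs <- function(deMirnas, deMrnas, tm) {
    keep <- tm$mirna_id %in% deMirnas & tm$mrna_id %in% deMrnas
    TargetMap(tm$mirna_id[keep], tm$mrna_id[keep])
}

#' Pearson correlation with a two-sided p value
#'
#' Sample Pearson r; two-sided p from `t = r * sqrt((n-2) / (1-r^2))` on
#' `n - 2` degrees of freedom; `|r| = 1` gives p = 0.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, both non-constant.
#' @return named numeric vector `c(r = , p = )`.
#' @export
pearsonEdge <- function(x, y) {
    x <- as.numeric(x); y <- as.numeric(y)
    n <- length(x)
    if (length(y) != n) stop("x and y must have equal length")
    if (n < 3L) stop("need at least 3 observations")
    if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    r <- max(min(r, 1), -1)
    p <- if (abs(r) >= 1) 0 else {
        tstat <- r * sqrt((n - 2) / (1 - r^2))
        2 * pt(-abs(tstat), df = n - 2)
    }
    c(r = r, p = p)
}

#' Correlate candidate pairs over shared samples
#'
#' One correlation edge per (miRNA, mRNA) pair, computed on log-normalized
#' values over the explicit shared-sample subset. Pairs with a
#' zero-variance vector are dropped with a warning.
#'
#' @param pairs a [TargetMap-class] (or data.frame with `mirna_id`,
#'   `mrna_id`).
#' @param normMirna,normMrna log-normalized matrices (features x samples).
#' @param sharedSamples character vector of sample ids present in both
#'   matrices; at least 3.
#' @return data.frame of correlation edges: `mirna_id`, `mrna_id`, `r`,
#'   `p`, `n`.
#' @export
correlatePairs <- function(pairs, normMirna, normMrna, sharedSamples) {
    sharedSamples <- as.character(sharedSamples)
    if (length(sharedSamples) < 3L) stop("need at least 3 shared samples")
    missM <- setdiff(sharedSamples, colnames(normMirna))
    missG <- setdiff(sharedSamples, colnames(normMrna))
    if (length(missM) || length(missG))
        stop("shared samples absent from matrices: ",
             paste(unique(c(missM, missG)), collapse = ", "))
    pairs <- as.data.frame(pairs)
    if (!nrow(pairs))
        return(data.frame(mirna_id = character(), mrna_id = character(),
                          r = numeric(), p = numeric(), n = integer()))
    badM <- setdiff(pairs$mirna_id, rownames(normMirna))
    badG <- setdiff(pairs$mrna_id, rownames(normMrna))
    if (length(badM) || length(badG))
        stop("pair features absent from matrices: ",
             paste(unique(c(badM, badG)), collapse = ", "))
    xm <- normMirna[pairs$mirna_id, sharedSamples, drop = FALSE]
    ym <- normMrna[pairs$mrna_id, sharedSamples, drop = FALSE]
    n <- length(sharedSamples)
    res <- vapply(seq_len(nrow(pairs)), function(i) {
        x <- xm[i, ]; y <- ym[i, ]
        if (sd(x) == 0 || sd(y) == 0) return(c(NA_real_, NA_real_))
        pearsonEdge(x, y)
    }, numeric(2))
    out <- data.frame(mirna_id = pairs$mirna_id, mrna_id = pairs$mrna_id,
                      r = res[1L, ], p = res[2L, ], n = n,
                      stringsAsFactors = FALSE)
    dropped <- is.na(out$r)
    if (any(dropped))
        warning(sprintf("%d pair(s) dropped for zero variance", sum(dropped)))
    out[!dropped, , drop = FALSE]
}

#' Retain significant anti-correlated edges
#'
#' Keeps exactly the edges with `p < pMax` and `r < rMax` (strict
#' inequalities).
#'
#' @param edges correlation-edge data.frame from [correlatePairs()].
#' @param pMax p-value cutoff (default 0.05).
#' @param rMax correlation cutoff (default 0).
#' @return the filtered data.frame.
#' @export
filterAnticorrelated <- function(edges, pMax = 0.05, rMax = 0) {
    edges[edges$p < pMax & edges$r < rMax, , drop = FALSE]
}

#' Partition edges by mRNA direction of change
#'
#' Groups anti-correlated edges by the sign of the target mRNA's log2 fold
#' change; targets with `log2FoldChange == 0` fall in neither group (with a
#' warning).
#'
#' @param edges correlation-edge data.frame.
#' @param mrnaDe a [DEResults-class] for the mRNA layer.
#' @return list with `up` and `down` edge data.frames.
#' @export
partitionByMrnaDirection <- function(edges, mrnaDe) {
    miss <- setdiff(edges$mrna_id, rownames(mrnaDe))
    if (length(miss))
        stop("mRNA(s) absent from DE table: ", paste(miss, collapse = ", "))
    lfc <- mrnaDe[edges$mrna_id, "log2FoldChange"]
    zero <- !is.na(lfc) & lfc == 0
    if (any(zero))
        warning(sprintf("%d edge(s) with log2FoldChange == 0 dropped", sum(zero)))
    list(up = edges[!is.na(lfc) & lfc > 0, , drop = FALSE],
         down = edges[!is.na(lfc) & lfc < 0, , drop = FALSE])
}

#' Select the most negatively correlated fraction of edges
#'
#' Sorts ascending by r (most negative first), breaking ties by smaller p
#' and then lexicographic (miRNA, mRNA), and returns the first
#' `ceiling(fraction * N)` edges.
#'
#' @param edges correlation-edge data.frame.
#' @param fraction fraction in (0, 1\] (default 0.05).
#' @return the selected edges.
#' @export
selectTopFraction <- function(edges, fraction = 0.05) {
    if (fraction <= 0 || fraction > 1)
        stop("fraction must be in (0, 1]")
    if (!nrow(edges)) return(edges)
    ord <- order(edges$r, edges$p, edges$mirna_id, edges$mrna_id)
    edges[ord[seq_len(ceiling(fraction * nrow(edges)))], , drop = FALSE]
}

#' Apply a figure-level correlation threshold
#'
#' Retains edges with `r < rCut` (strict), e.g. the focused subnetworks at
#' r < -0.7 and r < -0.85.
#'
#' @param edges correlation-edge data.frame.
#' @param rCut negative correlation cutoff.
#' @return the filtered edges.
#' @export
thresholdEdges <- function(edges, rCut) {
    if (rCut >= 0) stop("rCut must be negative")
    edges[edges$r < rCut, , drop = FALSE]
}

#' Retain proteins detected in every sample
#'
#' @param abundances numeric matrix of protein abundances with `NA` for
#'   not-detected; at least 2 samples.
#' @return the matrix restricted to proteins with no missing value.
#' @export
commonProteinFilter <- function(abundances) {
    abundances <- as.matrix(abundances)
    if (ncol(abundances) < 2L) stop("need at least 2 samples")
    abundances[complete.cases(abundances), , drop = FALSE]
}

#' Direction-concordant mRNA-protein pairs
#'
#' Proteins significant at raw `p < alpha` whose matching mRNA is
#' significant at adjusted `p < alpha` with the same direction of change.
#'
#' @param proteinDe a [DEResults-class] for the protein layer (raw p in
#'   `padj` by construction of [fitTwoGroup()]).
#' @param mrnaDe a [DEResults-class] for the mRNA layer.
#' @param alpha significance cutoff (default 0.05).
#' @param idMap optional named character vector mapping protein id ->
#'   gene id (defaults to identity).
#' @return data.frame `protein_id`, `gene_id`, `protein_lfc`, `mrna_lfc`,
#'   `direction`.
#' @export
concordantPairs <- function(proteinDe, mrnaDe, alpha = 0.05, idMap = NULL) {
    prot <- rownames(proteinDe)
    genes <- if (is.null(idMap)) setNames(prot, prot) else idMap[prot]
    keep <- !is.na(genes) & genes %in% rownames(mrnaDe)
    prot <- prot[keep]; genes <- genes[keep]
    pSig <- !is.na(proteinDe[prot, "pvalue"]) & proteinDe[prot, "pvalue"] < alpha
    mSig <- !is.na(mrnaDe[genes, "padj"]) & mrnaDe[genes, "padj"] < alpha
    pl <- proteinDe[prot, "log2FoldChange"]
    ml <- mrnaDe[genes, "log2FoldChange"]
    same <- !is.na(pl) & !is.na(ml) & sign(pl) == sign(ml) & sign(pl) != 0
    sel <- pSig & mSig & same
    data.frame(protein_id = prot[sel], gene_id = unname(genes[sel]),
               protein_lfc = pl[sel], mrna_lfc = ml[sel],
               direction = ifelse(pl[sel] > 0, "up", "down"),
               stringsAsFactors = FALSE)
}

#' Build a polarity-constrained tripartite network
#'
#' Combines anti-correlation miRNA->mRNA edges with concordant
#' mRNA-protein pairs into one network, keeping only paths obeying the
#' requested polarity: `"down-up-enriched"` (down-regulated miRNA,
#' up-regulated mRNA, enriched protein) or `"up-down-depleted"`.
#'
#' @param edges anti-correlation edge data.frame (already filtered).
#' @param mirnaDe,mrnaDe [DEResults-class] tables providing directions.
#' @param concordant data.frame from [concordantPairs()].
#' @param polarity `"down-up-enriched"` or `"up-down-depleted"`.
#' @return a [TripartiteNetwork-class]; validity re-checks every path.
#' @export
buildTripartite <- function(edges, mirnaDe, mrnaDe, concordant,
                            polarity = c("down-up-enriched",
                                         "up-down-depleted")) {
    polarity <- match.arg(polarity)
    mirDir <- if (polarity == "down-up-enriched") "down" else "up"
    tgtDir <- if (mirDir == "down") "up" else "down"
    dirOfDe <- function(de, ids) ifelse(de[ids, "log2FoldChange"] > 0, "up",
                                        ifelse(de[ids, "log2FoldChange"] < 0,
                                               "down", "none"))
    conc <- concordant[concordant$direction == tgtDir, , drop = FALSE]
    keep <- edges$mrna_id %in% conc$gene_id &
        dirOfDe(mirnaDe, edges$mirna_id) == mirDir &
        dirOfDe(mrnaDe, edges$mrna_id) == tgtDir
    e <- edges[keep, , drop = FALSE]
    conc <- conc[conc$gene_id %in% e$mrna_id, , drop = FALSE]
    mirIds <- unique(e$mirna_id)
    mrnaIds <- unique(e$mrna_id)
    nodes <- rbind(
        if (length(mirIds)) DataFrame(
            nodeId = paste0("miRNA:", mirIds), name = mirIds,
            layer = "miRNA", direction = mirDir,
            log2FoldChange = mirnaDe[mirIds, "log2FoldChange"]) else NULL,
        if (length(mrnaIds)) DataFrame(
            nodeId = paste0("mRNA:", mrnaIds), name = mrnaIds,
            layer = "mRNA", direction = tgtDir,
            log2FoldChange = mrnaDe[mrnaIds, "log2FoldChange"]) else NULL,
        if (nrow(conc)) DataFrame(
            nodeId = paste0("protein:", conc$protein_id),
            name = conc$protein_id, layer = "protein", direction = tgtDir,
            log2FoldChange = conc$protein_lfc) else NULL)
    if (is.null(nodes))
        nodes <- DataFrame(nodeId = character(), name = character(),
                           layer = character(), direction = character(),
                           log2FoldChange = numeric())
    edgeTab <- rbind(
        if (nrow(e)) DataFrame(
            source = paste0("miRNA:", e$mirna_id),
            target = paste0("mRNA:", e$mrna_id),
            type = "targeting", r = e$r, p = e$p) else NULL,
        if (nrow(conc)) DataFrame(
            source = paste0("mRNA:", conc$gene_id),
            target = paste0("protein:", conc$protein_id),
            type = "concordance", r = NA_real_, p = NA_real_) else NULL)
    if (is.null(edgeTab))
        edgeTab <- DataFrame(source = character(), target = character(),
                             type = character(), r = numeric(), p = numeric())
    rownames(nodes) <- NULL
    rownames(edgeTab) <- NULL
    new("TripartiteNetwork", nodes = nodes, edges = edgeTab,
        polarity = polarity)
}

#' Re-validate retained edges against their filter definitions
#'
#' Independent check that every retained edge satisfies all active filters
#' (recomputes the predicate from scratch).
#'
#' @param edges filtered edge data.frame.
#' @param pMax,rMax the active thresholds.
#' @return `TRUE` if every edge passes; otherwise stops naming the first
#'   offending edge.
#' @export
revalidateEdges <- function(edges, pMax = 0.05, rMax = 0) {
    if (!nrow(edges)) return(TRUE)
    ok <- edges$p < pMax & edges$r < rMax
    if (!all(ok)) {
        i <- which(!ok)[1L]
        stop(sprintf("edge %s -> %s violates filter (r = %.4g, p = %.4g)",
                     edges$mirna_id[i], edges$mrna_id[i],
                     edges$r[i], edges$p[i]))
    }
    TRUE
}
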