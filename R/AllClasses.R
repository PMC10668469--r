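#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<- colData<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.SMALL_RNA_SUBTYPES <- c("miRNA", "piRNA", "circRNA", "snoRNA", "snRNA",
                         "tRNA", "mRNA", "other")

#' OmicCounts: an annotated feature-by-sample count container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a single
#' `counts` assay of non-negative integers. Feature annotations live in
#' `rowData()` (`subtype`, one of miRNA/piRNA/circRNA/snoRNA/snRNA/tRNA/
#' mRNA/other, and `uniquelyMapped`, a logical multi-mapping flag); sample
#' metadata (gestational age in weeks, sex, batch) lives in `colData()`.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @export
setClass("OmicCounts", contains = "SummarizedExperiment")

setValidity("OmicCounts", function(object) {
    msg <- character()
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- assay(object, "counts")
        if (anyNA(cts) || any(cts < 0))
            msg <- c(msg, "counts must be non-negative and non-missing")
        else if (any(cts != round(cts)))
            msg <- c(msg, "counts must be integers")
    }
    rn <- rownames(object); cn <- colnames(object)
    if (is.null(rn) || anyDuplicated(rn))
        msg <- c(msg, "feature identifiers must be present and unique")
    if (is.null(cn) || anyDuplicated(cn))
        msg <- c(msg, "sample identifiers must be present and unique")
    rd <- rowData(object)
    if (!all(c("subtype", "uniquelyMapped") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain 'subtype' and 'uniquelyMapped'")
    else {
        if (!all(rd$subtype %in% .SMALL_RNA_SUBTYPES))
            msg <- c(msg, sprintf("subtype must be one of: %s",
                                  paste(.SMALL_RNA_SUBTYPES, collapse = ", ")))
        if (!is.logical(rd$uniquelyMapped) || anyNA(rd$uniquelyMapped))
            msg <- c(msg, "uniquelyMapped must be logical without NA")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an OmicCounts object
#'
#' @param counts integer matrix, features x samples, with dimnames.
#' @param subtype character vector of feature subtypes (recycled scalar
#'   allowed); defaults to `"other"`.
#' @param uniquelyMapped logical vector of unique-mapping flags; defaults to
#'   `TRUE`.
#' @param sampleData optional `DataFrame`/data.frame of per-sample metadata
#'   (rownames or a `sample_id` column matching `colnames(counts)`).
#' @return an [OmicCounts-class] object.
#' @examples
#' m <- matrix(0:3, 2, 2, dimnames = list(c("miR-1", "miR-2"), c("s1", "s2")))
#' oc <- OmicCounts(m, subtype = "miRNA")
#' @export
OmicCounts <- function(counts, subtype = "other", uniquelyMapped = TRUE,
                       sampleData = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    rd <- DataFrame(
        subtype = rep_len(as.character(subtype), nrow(counts)),
        uniquelyMapped = rep_len(as.logical(uniquelyMapped), nrow(counts)),
        row.names = rownames(counts))
    cd <- .asSampleData(sampleData, colnames(counts))
    new("OmicCounts", SummarizedExperiment(
        assays = SimpleList(counts = counts), rowData = rd, colData = cd))
}

.asSampleData <- function(sampleData, sampleIds) {
    if (is.null(sampleData))
        return(DataFrame(row.names = sampleIds))
    sd <- as(sampleData, "DataFrame")
    if ("sample_id" %in% colnames(sd) &&
        (is.null(rownames(sd)) || all(rownames(sd) == as.character(seq_len(nrow(sd))))))
        rownames(sd) <- sd$sample_id
    missing <- setdiff(sampleIds, rownames(sd))
    if (length(missing))
        stop("samples absent from sample table: ",
             paste(missing, collapse = ", "))
    sd[sampleIds, , drop = FALSE]
}

#' DEResults: per-feature differential expression table
#'
#' A `DFrame` with columns `baseMean` (mean normalized count),
#' `log2FoldChange` (slope in log2 units per week for a continuous design,
#' or group log2 ratio), `lfcSE`, `stat` (Wald/t statistic), `pvalue`,
#' `padj` (Benjamini-Hochberg within the layer) and `status`
#' (`ok`/`low_count`/`failed`). Fit metadata (design, alpha) is stored in
#' `metadata()`.
#'
#' @export
setClass("DEResults", contains = "DFrame")

setValidity("DEResults", function(object) {
    need <- c("baseMean", "log2FoldChange", "lfcSE", "stat", "pvalue",
              "padj", "status")
    msg <- character()
    if (!all(need %in% colnames(object)))
        return(sprintf("missing columns: %s",
                       paste(setdiff(need, colnames(object)), collapse = ", ")))
    p <- object$pvalue; q <- object$padj
    if (any(p < 0 | p > 1, na.rm = TRUE) || any(q < 0 | q > 1, na.rm = TRUE))
        msg <- c(msg, "pvalue/padj must lie in [0, 1]")
    both <- !is.na(p) & !is.na(q)
    if (any(q[both] < p[both] - 1e-12))
        msg <- c(msg, "padj must be >= pvalue")
    if (!all(object$status %in% c("ok", "low_count", "failed")))
        msg <- c(msg, "status must be ok/low_count/failed")
    ok <- object$status == "ok"
    if (any(!is.finite(object$log2FoldChange[ok])))
        msg <- c(msg, "status 'ok' rows must have finite estimates")
    if (length(msg)) msg else TRUE
})

.DEResults <- function(df, ...) {
    out <- new("DEResults", as(df, "DFrame"))
    md <- list(...)
    metadata(out)[names(md)] <- md
    out
}

#' GeneSetCollection: named gene sets (metabolites or subsystems)
#'
#' Gene-set collections as used for reporter-metabolite analysis: each set
#' has an identifier (metabolite or pathway name), a free-text description
#' and a deduplicated, non-empty member gene list.
#'
#' @slot setIds character, unique set identifiers.
#' @slot descriptions character, one per set.
#' @slot members list of character vectors of gene identifiers.
#' @export
setClass("GeneSetCollection",
         representation(setIds = "character", descriptions = "character",
                        members = "list"))

setValidity("GeneSetCollection", function(object) {
    msg <- character()
    if (anyDuplicated(object@setIds))
        msg <- c(msg, "set identifiers must be unique")
    if (length(object@descriptions) != length(object@setIds) ||
        length(object@members) != length(object@setIds))
        msg <- c(msg, "setIds, descriptions and members must be parallel")
    if (any(lengths(object@members) == 0L))
        msg <- c(msg, "every set must have at least one member")
    if (any(vapply(object@members, anyDuplicated, 0L) > 0L))
        msg <- c(msg, "members within a set must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param members named list of character member vectors; duplicates within
#'   a set are collapsed.
#' @param descriptions optional character vector (defaults to set names).
#' @return a [GeneSetCollection-class].
#' @export
GeneSetCollection <- function(members, descriptions = NULL) {
    ids <- names(members)
    if (is.null(ids)) stop("members must be a named list")
    if (is.null(descriptions)) descriptions <- ids
    new("GeneSetCollection", setIds = ids,
        descriptions = as.character(descriptions),
        members = lapply(members, function(m) unique(as.character(m))))
}

#' TargetMap: predicted miRNA to mRNA edges
#'
#' A `DFrame` of unique predicted (miRNA, mRNA) target pairs, consumed from
#' an external target-prediction tool (never computed here).
#'
#' @export
setClass("TargetMap", contains = "DFrame")

setValidity("TargetMap", function(object) {
    msg <- character()
    if (!all(c("mirna_id", "mrna_id") %in% colnames(object)))
        return("columns 'mirna_id' and 'mrna_id' are required")
    if (any(!nzchar(object$mirna_id)) || any(!nzchar(object$mrna_id)) ||
        anyNA(object$mirna_id) || anyNA(object$mrna_id))
        msg <- c(msg, "identifiers must be non-empty")
    if (anyDuplicated(paste(object$mirna_id, object$mrna_id, sep = "\r")))
        msg <- c(msg, "duplicate (miRNA, mRNA) pairs")
    if (length(msg)) msg else TRUE
})

TargetMap <- function(mirna_id, mrna_id) {
    new("TargetMap", DataFrame(mirna_id = as.character(mirna_id),
                               mrna_id = as.character(mrna_id)))
}

#' TripartiteNetwork: miRNA - mRNA - protein regulatory network
#'
#' Nodes carry a layer (`miRNA`, `mRNA`, `protein`), a direction of change
#' (`up`/`down`) and per-layer statistics; edges are miRNA->mRNA
#' anti-correlation links (with r, p) and mRNA->protein concordance links.
#' Validity enforces the polarity constraint along every path (e.g. a
#' down-regulated miRNA may only connect to an up-regulated mRNA whose
#' protein is enriched).
#'
#' @slot nodes DFrame with columns nodeId, name, layer, direction, ...
#' @slot edges DFrame with columns source, target, type, r, p.
#' @slot polarity `"down-up-enriched"` or `"up-down-depleted"`.
#' @export
setClass("TripartiteNetwork",
         representation(nodes = "DFrame", edges = "DFrame",
                        polarity = "character"))

setValidity("TripartiteNetwork", function(object) {
    nd <- object@nodes; ed <- object@edges
    msg <- character()
    if (!all(c("nodeId", "name", "layer", "direction") %in% colnames(nd)))
        return("nodes need nodeId, name, layer, direction")
    if (!all(c("source", "target", "type") %in% colnames(ed)))
        return("edges need source, target, type")
    if (anyDuplicated(nd$nodeId))
        msg <- c(msg, "node identifiers must be unique")
    unknown <- setdiff(c(ed$source, ed$target), nd$nodeId)
    if (length(unknown))
        msg <- c(msg, sprintf("edges reference unknown nodes: %s",
                              paste(unknown, collapse = ", ")))
    if (length(object@polarity) != 1L ||
        !object@polarity %in% c("down-up-enriched", "up-down-depleted"))
        msg <- c(msg, "polarity must be down-up-enriched or up-down-depleted")
    else if (nrow(ed) && !length(msg)) {
        dirOf <- setNames(nd$direction, nd$nodeId)
        layOf <- setNames(nd$layer, nd$nodeId)
        mirDir <- if (object@polarity == "down-up-enriched") "down" else "up"
        tgtDir <- if (mirDir == "down") "up" else "down"
        for (i in seq_len(nrow(ed))) {
            s <- ed$source[i]; t <- ed$target[i]
            bad <- switch(ed$type[i],
                targeting = layOf[[s]] != "miRNA" || layOf[[t]] != "mRNA" ||
                    dirOf[[s]] != mirDir || dirOf[[t]] != tgtDir,
                concordance = layOf[[s]] != "mRNA" || layOf[[t]] != "protein" ||
                    dirOf[[s]] != tgtDir || dirOf[[t]] != tgtDir,
                TRUE)
            if (bad) {
                msg <- c(msg, sprintf(
                    "polarity violation on %s edge %s -> %s", ed$type[i], s, t))
                break
            }
        }
        prot <- nd$nodeId[nd$layer == "protein"]
        nIn <- table(factor(ed$target[ed$type == "concordance"], levels = prot))
        if (length(prot) && any(nIn != 1L))
            msg <- c(msg, "every protein node must link to exactly one mRNA")
        mrna <- nd$nodeId[nd$layer == "mRNA"]
        inTgt <- mrna %in% ed$target[ed$type == "targeting"]
        if (length(mrna) && !all(inTgt))
            msg <- c(msg, "every mRNA node must appear in >= 1 miRNA edge")
    }
    if (length(msg)) msg else TRUE
})
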