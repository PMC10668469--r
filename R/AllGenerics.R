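#' @importFrom BiocGenerics counts
NULL

#' Extract the count matrix
#'
#' @param object an [OmicCounts-class] object.
#' @param ... ignored.
#' @return numeric matrix of counts.
#' @export
setMethod("counts", "OmicCounts", function(object, ...) {
    assay(object, "counts")
})

#' Feature subtype annotations
#' @param object an [OmicCounts-class] object.
#' @return character vector of subtypes, named by feature.
#' @export
setGeneric("featureSubtype", function(object) standardGeneric("featureSubtype"))

#' @rdname featureSubtype
#' @export
setMethod("featureSubtype", "OmicCounts", function(object) {
    setNames(as.character(rowData(object)$subtype), rownames(object))
})

#' Unique-mapping flags
#' @param object an [OmicCounts-class] object.
#' @return named logical vector.
#' @export
setGeneric("uniquelyMapped", function(object) standardGeneric("uniquelyMapped"))

#' @rdname uniquelyMapped
#' @export
setMethod("uniquelyMapped", "OmicCounts", function(object) {
    setNames(rowData(object)$uniquelyMapped, rownames(object))
})

#' Gestational ages of the samples
#' @param object an [OmicCounts-class] object whose `colData` has a
#'   `gestational_age` column.
#' @return named numeric vector of ages in weeks.
#' @export
setGeneric("gestationalAge", function(object) standardGeneric("gestationalAge"))

#' @rdname gestationalAge
#' @export
setMethod("gestationalAge", "OmicCounts", function(object) {
    if (!"gestational_age" %in% colnames(colData(object)))
        stop("colData has no 'gestational_age' column")
    setNames(as.numeric(colData(object)$gestational_age), colnames(object))
})

#' Number of sets in a collection
#' @param object a [GeneSetCollection-class].
#' @export
setGeneric("nSets", function(object) standardGeneric("nSets"))

#' @rdname nSets
#' @export
setMethod("nSets", "GeneSetCollection", function(object) length(object@setIds))

#' Set identifiers
#' @param object a [GeneSetCollection-class].
#' @export
setGeneric("setIds", function(object) standardGeneric("setIds"))

#' @rdname setIds
#' @export
setMethod("setIds", "GeneSetCollection", function(object) object@setIds)

#' Member genes of each set
#' @param object a [GeneSetCollection-class].
#' @return named list of character vectors.
#' @export
setGeneric("setMembers", function(object) standardGeneric("setMembers"))

#' @rdname setMembers
#' @export
setMethod("setMembers", "GeneSetCollection", function(object) {
    setNames(object@members, object@setIds)
})

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@setIds))

#' Subset a gene-set collection
#' @param x a [GeneSetCollection-class].
#' @param i index or set identifiers.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "GeneSetCollection", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@setIds)
    new("GeneSetCollection", setIds = x@setIds[i],
        descriptions = x@descriptions[i], members = x@members[i])
})

setMethod("show", "OmicCounts", function(object) {
    cat(sprintf("OmicCounts: %d features x %d samples\n",
                nrow(object), ncol(object)))
    tab <- table(rowData(object)$subtype)
    cat("subtypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
    cat(sprintf("uniquely mapped: %d/%d\n",
                sum(rowData(object)$uniquelyMapped), nrow(object)))
    if ("gestational_age" %in% colnames(colData(object))) {
        ga <- colData(object)$gestational_age
        cat(sprintf("gestational age: %.1f-%.1f weeks\n", min(ga), max(ga)))
    }
})

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection: %d sets, member counts %d-%d\n",
                length(object@setIds),
                if (length(object@members)) min(lengths(object@members)) else 0L,
                if (length(object@members)) max(lengths(object@members)) else 0L))
})

setMethod("show", "TripartiteNetwork", function(object) {
    lay <- table(factor(object@nodes$layer,
                        levels = c("miRNA", "mRNA", "protein")))
    cat(sprintf(
        "TripartiteNetwork (%s): %d miRNA, %d mRNA, %d protein nodes; %d edges\n",
        object@polarity, lay[["miRNA"]], lay[["mRNA"]], lay[["protein"]],
        nrow(object@edges)))
})

#' Nodes of a tripartite network
#' @param object a [TripartiteNetwork-class].
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "TripartiteNetwork", function(object) object@nodes)

#' Edges of a tripartite network
#' @param object a [TripartiteNetwork-class].
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname networkEdges
#' @export
setMethod("networkEdges", "TripartiteNetwork", function(object) object@edges)
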