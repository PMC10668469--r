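#' @importFrom utils read.delim write.table combn packageVersion
#' @importFrom igraph graph_from_data_frame write_graph read_graph
#'   as_data_frame
NULL

.readTsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    read.delim(path, header = TRUE, sep = "\t", quote = "",
               stringsAsFactors = FALSE, check.names = FALSE,
               na.strings = "NA")
}

#' Read an annotated count matrix from TSV
#'
#' Expects a tab-separated table whose first column holds feature
#' identifiers and whose remaining columns are per-sample counts, except for
#' optional annotation columns named by `subtypeColumn` /
#' `uniqueColumn`. Absent annotations default to subtype `"other"` and
#' `uniquelyMapped = TRUE`.
#'
#' @param path TSV file path.
#' @param subtypeColumn name of the subtype annotation column, or `NULL`.
#' @param uniqueColumn name of the unique-mapping flag column, or `NULL`.
#' @param sampleData optional sample metadata (see [OmicCounts()]).
#' @return an [OmicCounts-class] object.
#' @seealso [writeCountMatrix()]
#' @export
readCountMatrix <- function(path, subtypeColumn = NULL, uniqueColumn = NULL,
                            sampleData = NULL) {
    df <- .readTsv(path)
    if (ncol(df) < 2L) stop("count matrix needs a feature column and >= 1 sample")
    ids <- as.character(df[[1L]])
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate feature identifiers: ", paste(dup, collapse = ", "))
    ann <- c(subtypeColumn, uniqueColumn)
    missingAnn <- setdiff(ann, colnames(df))
    if (length(missingAnn))
        stop("annotation column(s) not found: ",
             paste(missingAnn, collapse = ", "))
    sampleCols <- setdiff(colnames(df)[-1L], ann)
    dupS <- unique(sampleCols[duplicated(sampleCols)])
    if (length(dupS))
        stop("duplicate sample identifiers: ", paste(dupS, collapse = ", "))
    cts <- as.matrix(df[, sampleCols, drop = FALSE])
    bad <- which(is.na(cts) | !is.finite(cts) | cts < 0 | cts != round(cts),
                 arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf(
            "invalid count at feature '%s', sample '%s': %s",
            ids[bad[1L, 1L]], sampleCols[bad[1L, 2L]],
            as.character(df[bad[1L, 1L], sampleCols[bad[1L, 2L]]])))
    rownames(cts) <- ids
    subtype <- if (is.null(subtypeColumn)) "other" else as.character(df[[subtypeColumn]])
    uniq <- if (is.null(uniqueColumn)) TRUE else {
        u <- df[[uniqueColumn]]
        if (is.character(u)) u <- tolower(u) %in% c("true", "1", "yes")
        as.logical(u)
    }
    OmicCounts(cts, subtype = subtype, uniquelyMapped = uniq,
               sampleData = sampleData)
}

#' Write an OmicCounts object to TSV
#'
#' Inverse of [readCountMatrix()]: writes feature ids, annotation columns
#' `subtype` and `uniquely_mapped`, then one column per sample.
#'
#' @param oc an [OmicCounts-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(oc, path) {
    df <- data.frame(feature_id = rownames(oc),
                     subtype = featureSubtype(oc),
                     uniquely_mapped = uniquelyMapped(oc),
                     counts(oc), check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `gestational_age` (weeks), and optionally
#' `sex` (F/M/unknown) and `batch`.
#'
#' @param path TSV file path.
#' @return a `DataFrame` keyed by sample id.
#' @export
readSampleTable <- function(path) {
    df <- .readTsv(path)
    need <- c("sample_id", "gestational_age")
    if (!all(need %in% colnames(df)))
        stop("sample table needs columns: ", paste(need, collapse = ", "))
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    if (length(dup))
        stop("duplicate sample identifiers: ", paste(dup, collapse = ", "))
    if (anyNA(df$gestational_age) || !is.numeric(df$gestational_age) ||
        any(!is.finite(df$gestational_age)))
        stop("gestational_age must be finite numeric")
    out <- as(df, "DataFrame")
    rownames(out) <- df$sample_id
    out
}

#' Restrict to uniquely mapped features
#'
#' Multi-mapping small RNAs give ambiguous counts; only uniquely mapped
#' features are retained for downstream analysis.
#'
#' @param oc an [OmicCounts-class] object.
#' @return the filtered [OmicCounts-class]; warns if nothing remains.
#' @export
filterUniqueFeatures <- function(oc) {
    keep <- uniquelyMapped(oc)
    removed <- sum(!keep)
    message(sprintf("filterUniqueFeatures: removed %d multi-mapped of %d features",
                    removed, length(keep)))
    if (!any(keep)) warning("no uniquely mapped features remain")
    oc[keep, ]
}

#' Read a GMT gene-set file
#'
#' One set per line: set name, description, then member genes, all
#' tab-separated. Duplicate members within a set are collapsed with a
#' warning.
#'
#' @param path GMT file path.
#' @return a [GeneSetCollection-class] preserving input set order.
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    members <- list(); descriptions <- character()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 2L)
            stop(sprintf("malformed GMT line %d: expected >= 2 tab-separated fields", i))
        genes <- f[-(1:2)]
        genes <- genes[nzchar(genes)]
        if (!length(genes))
            stop(sprintf("malformed GMT line %d: set '%s' has no members", i, f[1L]))
        if (anyDuplicated(genes))
            warning(sprintf("GMT line %d ('%s'): duplicate members collapsed",
                            i, f[1L]))
        members[[f[1L]]] <- unique(genes)
        descriptions <- c(descriptions, f[2L])
    }
    GeneSetCollection(members, descriptions)
}

#' Write a GeneSetCollection to GMT
#' @param gsc a [GeneSetCollection-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(gsc, path) {
    lines <- vapply(seq_len(nSets(gsc)), function(i)
        paste(c(gsc@setIds[i], gsc@descriptions[i], gsc@members[[i]]),
              collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Read a predicted miRNA-target edge table
#'
#' Two-column TSV (`mirna_id`, `mrna_id`); a header row is detected by
#' column names. Duplicate rows are collapsed with a message.
#'
#' @param path TSV file path.
#' @return a [TargetMap-class] of unique edges.
#' @export
readTargetMap <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
        warning("empty target map")
        return(TargetMap(character(), character()))
    }
    start <- 1L
    first <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(first) >= 2L && identical(tolower(first[1:2]),
                                         c("mirna_id", "mrna_id")))
        start <- 2L
    mir <- character(); mrna <- character()
    for (i in seq(from = start, length.out = length(lines) - start + 1L)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L]))
            stop(sprintf("malformed target-map line %d: need two non-empty fields", i))
        mir <- c(mir, f[1L]); mrna <- c(mrna, f[2L])
    }
    if (!length(mir)) {
        warning("empty target map")
        return(TargetMap(character(), character()))
    }
    key <- paste(mir, mrna, sep = "\r")
    if (anyDuplicated(key))
        message(sprintf("readTargetMap: %d duplicate edges collapsed",
                        sum(duplicated(key))))
    keep <- !duplicated(key)
    TargetMap(mir[keep], mrna[keep])
}

#' Write a target map to TSV
#' @param tm a [TargetMap-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTargetMap <- function(tm, path) {
    write.table(as.data.frame(tm), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Write a network as TSV tables or GraphML
#'
#' TSV mode writes `<path>_nodes.tsv` and `<path>_edges.tsv`; GraphML mode
#' writes one document with all node/edge attributes as typed keys, so that
#' re-reading reproduces the same node and edge sets.
#'
#' @param nodes data.frame/DFrame with at least `nodeId` plus attribute
#'   columns.
#' @param edges data.frame/DFrame with `source`, `target` plus attribute
#'   columns.
#' @param path output path (prefix in TSV mode, file path in GraphML mode).
#' @param format `"tsv"` or `"graphml"`.
#' @return the path(s) written, invisibly.
#' @export
writeNetwork <- function(nodes, edges, path, format = c("tsv", "graphml")) {
    format <- match.arg(format)
    nodes <- as.data.frame(nodes)
    edges <- as.data.frame(edges)
    if (!"nodeId" %in% colnames(nodes)) stop("nodes need a 'nodeId' column")
    if (nrow(edges) && !all(c("source", "target") %in% colnames(edges)))
        stop("edges need 'source' and 'target' columns")
    if (nrow(edges)) {
        unknown <- setdiff(c(edges$source, edges$target), nodes$nodeId)
        if (length(unknown))
            stop("edge references unknown node(s): ",
                 paste(unique(unknown), collapse = ", "))
    }
    if (format == "tsv") {
        np <- paste0(path, "_nodes.tsv"); ep <- paste0(path, "_edges.tsv")
        write.table(nodes, np, sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(edges, ep, sep = "\t", quote = FALSE, row.names = FALSE)
        return(invisible(c(np, ep)))
    }
    vertices <- data.frame(name = nodes$nodeId,
                           nodes[, setdiff(colnames(nodes), "nodeId"),
                                 drop = FALSE],
                           stringsAsFactors = FALSE)
    rel <- if (nrow(edges)) {
        data.frame(from = edges$source, to = edges$target,
                   edges[, setdiff(colnames(edges), c("source", "target")),
                         drop = FALSE], stringsAsFactors = FALSE)
    } else data.frame(from = character(), to = character())
    g <- graph_from_data_frame(rel, directed = TRUE, vertices = vertices)
    write_graph(g, path, format = "graphml")
    invisible(path)
}

#' Read a GraphML network back into node and edge tables
#'
#' @param path GraphML file as written by [writeNetwork()].
#' @return list with `nodes` and `edges` data.frames.
#' @export
readNetworkGraphml <- function(path) {
    g <- read_graph(path, format = "graphml")
    nodes <- as_data_frame(g, what = "vertices")
    colnames(nodes)[colnames(nodes) == "name"] <- "nodeId"
    nodes$id <- NULL  # igraph's internal n0/n1 labels
    rownames(nodes) <- NULL
    edges <- as_data_frame(g, what = "edges")
    if (nrow(edges)) {
        colnames(edges)[colnames(edges) == "from"] <- "source"
        colnames(edges)[colnames(edges) == "to"] <- "target"
    } else edges <- data.frame(source = character(), target = character())
    list(nodes = nodes, edges = edges)
}
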