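test_that("candidate pairs are the DE-restricted target map", {
    tm <- TargetMap(c("a", "a", "b"), c("X", "Y", "Z"))
    got <- candidatePairs("a", c("X", "Z"), tm)
    expect_identical(as.data.frame(got),
                     data.frame(mirna_id = "a", mrna_id = "X",
                                stringsAsFactors = FALSE))
    expect_identical(nrow(candidatePairs("a", "X",
                                         TargetMap(character(), character()))),
                     0L)
    expect_identical(nrow(candidatePairs(c("a", "b"), c("X", "Y", "Z"), tm)),
                     3L)
})

test_that("pearsonEdge matches the closed form and the brute-force oracle", {
    e <- pearsonEdge(c(1, 2, 3, 4), c(2, 1, 4, 3))
    expect_equal(unname(e["r"]), 0.6, tolerance = 1e-12)
    expect_equal(unname(e["p"]),
                 2 * pt(-0.6 * sqrt(2 / (1 - 0.36)), df = 2),
                 tolerance = 1e-12)
    x <- c(1, 2, 3); y <- c(3, 2, 1)
    anti <- pearsonEdge(x, y)
    expect_equal(unname(anti["r"]), -1)
    expect_equal(unname(anti["p"]), 0)
    expect_error(pearsonEdge(c(1, 1, 1), y), "zero variance")
    expect_error(pearsonEdge(1:2, 2:1), "3 observations")
    set.seed(13)
    for (i in 1:300) {
        n <- sample(3:40, 1)
        a <- rnorm(n); b <- rnorm(n)
        expect_equal(unname(pearsonEdge(a, b)), unname(brutePearson(a, b)),
                     tolerance = 1e-12)
    }
})

test_that("correlatePairs works over shared samples and guards inputs", {
    set.seed(14)
    nm <- matrix(rnorm(40), 4, 10,
                 dimnames = list(paste0("m", 1:4), paste0("s", 1:10)))
    ng <- rbind(nm[1, ] * -2 + rnorm(10, sd = 0.1),
                matrix(rnorm(30), 3, 10))
    dimnames(ng) <- list(paste0("g", 1:4), paste0("s", 1:10))
    pairs <- data.frame(mirna_id = c("m1", "m2"), mrna_id = c("g1", "g2"))
    edges <- correlatePairs(pairs, nm, ng, paste0("s", 1:10))
    expect_identical(nrow(edges), 2L)
    expect_lt(edges$r[1], -0.9)
    expect_identical(edges$n, c(10L, 10L))
    expect_error(correlatePairs(pairs, nm, ng, c("s1", "s2")), "3 shared")
    expect_error(correlatePairs(data.frame(mirna_id = "nope",
                                           mrna_id = "g1"),
                                nm, ng, paste0("s", 1:10)), "absent")
    # zero-variance pair dropped with warning
    ng2 <- ng; ng2["g2", ] <- 5
    expect_warning(ed2 <- correlatePairs(pairs, nm, ng2, paste0("s", 1:10)),
                   "zero variance")
    expect_identical(ed2$mrna_id, "g1")
    expect_identical(nrow(correlatePairs(pairs[0, ], nm, ng,
                                         paste0("s", 1:10))), 0L)
})

test_that("anti-correlation filter applies strict dual thresholds idempotently", {
    edges <- data.frame(mirna_id = c("a", "b", "c"),
                        mrna_id = c("X", "Y", "Z"),
                        r = c(-0.5, -0.5, 0.9),
                        p = c(0.01, 0.06, 1e-9))
    kept <- filterAnticorrelated(edges)
    expect_identical(kept$mirna_id, "a")
    expect_identical(filterAnticorrelated(kept), kept)
    expect_true(revalidateEdges(kept))
    expect_error(revalidateEdges(edges), "violates")
})

test_that("edges partition by the target's fold-change sign", {
    de <- new("DEResults", S4Vectors::DataFrame(
        baseMean = 1, log2FoldChange = c(1.2, -0.3, 0),
        lfcSE = 1, stat = 1, pvalue = 0.01, padj = 0.02, status = "ok",
        row.names = c("U", "D", "Z")))
    edges <- data.frame(mirna_id = c("a", "b", "c"),
                        mrna_id = c("U", "D", "Z"),
                        r = -0.5, p = 0.01)
    expect_warning(part <- partitionByMrnaDirection(edges, de),
                   "log2FoldChange == 0")
    expect_identical(part$up$mrna_id, "U")
    expect_identical(part$down$mrna_id, "D")
    expect_error(partitionByMrnaDirection(
        data.frame(mirna_id = "a", mrna_id = "missing", r = -1, p = 0), de),
        "absent")
})

test_that("top-fraction selection uses ceil and deterministic tie-breaks", {
    set.seed(15)
    edges <- data.frame(mirna_id = sprintf("m%03d", 1:100),
                        mrna_id = sprintf("g%03d", 1:100),
                        r = runif(100, -1, 0), p = runif(100))
    expect_identical(nrow(selectTopFraction(edges, 0.05)), 5L)
    expect_identical(nrow(selectTopFraction(edges[1:10, ], 0.05)), 1L)
    # selected edges are the most negative
    top <- selectTopFraction(edges, 0.05)
    expect_true(max(top$r) <= min(edges$r[!paste(edges$mirna_id) %in%
                                          top$mirna_id]))
    # tie on r broken by smaller p
    tie <- data.frame(mirna_id = c("m1", "m2"), mrna_id = c("g1", "g2"),
                      r = c(-0.9, -0.9), p = c(0.01, 0.001))
    expect_identical(selectTopFraction(tie, 0.5)$mirna_id, "m2")
    # fraction 1 is the identity up to ordering
    all <- selectTopFraction(edges, 1)
    expect_setequal(paste(all$mirna_id, all$mrna_id),
                    paste(edges$mirna_id, edges$mrna_id))
    expect_error(selectTopFraction(edges, 0), "fraction")
})

test_that("figure-level r threshold is strict", {
    edges <- data.frame(mirna_id = c("a", "b"), mrna_id = c("X", "Y"),
                        r = c(-0.71, -0.7), p = 0.01)
    kept <- thresholdEdges(edges, -0.7)
    expect_identical(kept$mirna_id, "a")
    expect_identical(nrow(thresholdEdges(edges, -0.85)), 0L)
    expect_error(thresholdEdges(edges, 0.5), "negative")
})

test_that("common-protein filter matches a brute-force recount", {
    set.seed(16)
    ab <- matrix(rnorm(600), 100, 6,
                 dimnames = list(sprintf("p%03d", 1:100), paste0("s", 1:6)))
    ab[runif(600) < 0.1] <- NA
    kept <- commonProteinFilter(ab)
    brute <- sum(apply(ab, 1, function(x) !any(is.na(x))))
    expect_identical(nrow(kept), brute)
    expect_false(anyNA(kept))
    expect_error(commonProteinFilter(ab[, 1, drop = FALSE]), "2 samples")
})

test_that("concordance requires significance on both layers and same sign", {
    protein <- new("DEResults", S4Vectors::DataFrame(
        baseMean = 1, log2FoldChange = c(1, 1, 1, -2),
        lfcSE = 1, stat = 1, pvalue = c(0.01, 0.01, 0.2, 0.03),
        padj = c(0.01, 0.01, 0.2, 0.03), status = "ok",
        row.names = c("A", "B", "C", "D")))
    mrna <- new("DEResults", S4Vectors::DataFrame(
        baseMean = 1, log2FoldChange = c(2, -1, 2, -1),
        lfcSE = 1, stat = 1, pvalue = 0.001, padj = 0.001, status = "ok",
        row.names = c("A", "B", "C", "D")))
    conc <- concordantPairs(protein, mrna)
    expect_setequal(conc$protein_id, c("A", "D"))
    expect_identical(conc$direction[conc$protein_id == "A"], "up")
    expect_identical(conc$direction[conc$protein_id == "D"], "down")
})

test_that("tripartite network enforces the polarity constraint", {
    mirnaDe <- new("DEResults", S4Vectors::DataFrame(
        baseMean = 1, log2FoldChange = -0.4, lfcSE = 1, stat = 1,
        pvalue = 0.001, padj = 0.001, status = "ok", row.names = "miR-9"))
    mrnaDe <- new("DEResults", S4Vectors::DataFrame(
        baseMean = 1, log2FoldChange = 0.3, lfcSE = 1, stat = 1,
        pvalue = 0.001, padj = 0.001, status = "ok", row.names = "HADHA"))
    edges <- data.frame(mirna_id = "miR-9", mrna_id = "HADHA",
                        r = -0.8, p = 0.001)
    conc <- data.frame(protein_id = "HADHA", gene_id = "HADHA",
                       protein_lfc = 1.5, mrna_lfc = 0.3, direction = "up",
                       stringsAsFactors = FALSE)
    tri <- buildTripartite(edges, mirnaDe, mrnaDe, conc, "down-up-enriched")
    expect_identical(nrow(networkNodes(tri)), 3L)
    expect_identical(nrow(networkEdges(tri)), 2L)
    # opposite polarity excludes everything
    tri2 <- buildTripartite(edges, mirnaDe, mrnaDe, conc,
                            "up-down-depleted")
    expect_identical(nrow(networkEdges(tri2)), 0L)
    # a protein whose mRNA has no surviving miRNA edge is excluded
    conc2 <- rbind(conc, data.frame(protein_id = "OTHER", gene_id = "OTHER",
                                    protein_lfc = 1, mrna_lfc = 1,
                                    direction = "up"))
    tri3 <- buildTripartite(edges, mirnaDe, mrnaDe, conc2,
                            "down-up-enriched")
    expect_false("protein:OTHER" %in% networkNodes(tri3)$nodeId)
    # hand-built polarity violations are refused by the validator
    badNodes <- S4Vectors::DataFrame(
        nodeId = c("miRNA:m", "mRNA:g"), name = c("m", "g"),
        layer = c("miRNA", "mRNA"), direction = c("up", "up"))
    badEdges <- S4Vectors::DataFrame(source = "miRNA:m", target = "mRNA:g",
                                     type = "targeting", r = -1, p = 0)
    expect_error(new("TripartiteNetwork", nodes = badNodes,
                     edges = badEdges, polarity = "down-up-enriched"),
                 "polarity violation")
})
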