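test_that("signed directional z follows the quantile construction", {
    expect_equal(signedDirectionalZ(0.05, 1, "up"), qnorm(0.975),
                 tolerance = 1e-12)
    expect_equal(signedDirectionalZ(0.05, -1, "up"), qnorm(0.025),
                 tolerance = 1e-12)
    expect_equal(signedDirectionalZ(0.05, -1, "down"), qnorm(0.975),
                 tolerance = 1e-12)
    # p near 1 gives a near-zero score
    expect_equal(signedDirectionalZ(1 - 1e-12, 1, "up"), 0,
                 tolerance = 1e-5)
    expect_error(signedDirectionalZ(0, 1, "up"), "strictly")
    expect_error(signedDirectionalZ(0.5, 0, "up"), "sign")
})

test_that("set scores aggregate as sum over sqrt(k)", {
    z <- rep(qnorm(0.975), 4)
    expect_equal(setScore(z), 4 * qnorm(0.975) / 2, tolerance = 1e-12)
    expect_equal(setScore(2.5), 2.5)
    expect_equal(setScore(c(-1, 1)), 0)
    expect_error(setScore(numeric()), "empty")
})

test_that("permutation p values are floored, seeded and match enumeration", {
    bg <- c(-2, -1, 0, 1, 2)
    # unattainably large observed score hits the add-one floor
    expect_equal(permutationPvalue(100, bg, 2, nPerm = 50), 1 / 51)
    set.seed(1); p1 <- permutationPvalue(0.5, bg, 2, nPerm = 100)
    set.seed(1); p2 <- permutationPvalue(0.5, bg, 2, nPerm = 100)
    expect_identical(p1, p2)
    expect_error(permutationPvalue(1, bg, 9), "smaller than")
    # exhaustive mode equals the brute-force enumeration over all 56 subsets
    set.seed(2)
    bg8 <- rnorm(8)
    zObs <- setScore(bg8[c(1, 4, 6)])
    pex <- permutationPvalue(zObs, bg8, 3, exhaustive = TRUE)
    comb <- combn(8, 3)
    brute <- mean(apply(comb, 2, function(i) sum(bg8[i]) / sqrt(3)) >= zObs)
    expect_identical(pex, brute)
})

test_that("reporter skips out-of-window sets and keeps exact bookkeeping", {
    stats <- data.frame(gene_id = sprintf("g%02d", 1:30),
                        p = runif(30, 0.01, 0.99),
                        sign = rep(c(1, -1), 15))
    gsc <- GeneSetCollection(list(
        tiny = stats$gene_id[1:4],
        okA = stats$gene_id[1:10],
        okB = stats$gene_id[11:25],
        unmatched = c("x1", "x2", "x3")))
    set.seed(3)
    res <- runReporter(stats, gsc, minK = 5, maxK = 500, nPerm = 50)
    expect_identical(res$skipped$set_id, c("tiny", "unmatched"))
    expect_true(all(res$skipped$reason == "k<min"))
    expect_identical(nrow(res$records) + nrow(res$skipped), nSets(gsc))
    expect_true(all(res$records$padj_up >= res$records$p_up))
})

test_that("sign flip swaps up and down outputs exactly under one seed", {
    set.seed(4)
    stats <- data.frame(gene_id = sprintf("g%03d", 1:150),
                        p = runif(150, 1e-6, 1 - 1e-6),
                        sign = sample(c(-1, 1), 150, TRUE))
    gsc <- GeneSetCollection(list(A = stats$gene_id[1:20],
                                  B = stats$gene_id[50:90],
                                  C = stats$gene_id[c(3, 7, 100:120)]))
    set.seed(99); fwd <- runReporter(stats, gsc, nPerm = 200)
    flipped <- stats; flipped$sign <- -flipped$sign
    set.seed(99); rev <- runReporter(flipped, gsc, nPerm = 200)
    expect_identical(fwd$records$Z_up, rev$records$Z_down)
    expect_identical(fwd$records$Z_down, rev$records$Z_up)
    expect_identical(fwd$records$p_up, rev$records$p_down)
    expect_identical(fwd$records$padj_up, rev$records$padj_down)
})

test_that("increasing member scores never decreases the up score", {
    stats <- data.frame(gene_id = sprintf("g%02d", 1:40),
                        p = runif(40, 0.05, 0.95),
                        sign = sample(c(-1, 1), 40, TRUE))
    zUp <- signedDirectionalZ(stats$p, stats$sign, "up")
    idx <- 5:14
    expect_gte(setScore(zUp[idx] + 0.3), setScore(zUp[idx]))
})

test_that("gene statistics clamp p values and drop zero fold changes", {
    de <- new("DEResults", S4Vectors::DataFrame(
        baseMean = 1, log2FoldChange = c(2, -1, 0, 1),
        lfcSE = 1, stat = 1, pvalue = c(0, 0.5, 0.1, NA),
        padj = c(0, 0.5, 0.1, NA), status = c("ok", "ok", "ok", "low_count"),
        row.names = c("a", "b", "zero", "na")))
    expect_warning(st <- geneStats(de), "2 gene")
    expect_identical(st$gene_id, c("a", "b"))
    expect_equal(st$p[1], 1e-12)
    expect_identical(st$sign, c(1, -1))
})

test_that("random control selections respect the pool and exclusions", {
    de <- new("DEResults", S4Vectors::DataFrame(
        baseMean = 1, log2FoldChange = rep(c(1, -1), 25),
        lfcSE = 1, stat = 1, pvalue = 0.001, padj = 0.001, status = "ok",
        row.names = sprintf("g%02d", 1:50)))
    gsc <- GeneSetCollection(list(S = sprintf("g%02d", 1:20)))
    set.seed(5)
    run <- suppressWarnings(randomControlRun(de, 10, gsc,
                                             exclude = sprintf("g%02d", 1:30),
                                             nPerm = 20))
    expect_identical(length(run$genes), 10L)
    expect_true(all(run$genes %in% sprintf("g%02d", 31:50)))
    set.seed(5)
    run2 <- suppressWarnings(randomControlRun(de, 10, gsc,
                                              exclude = sprintf("g%02d", 1:30),
                                              nPerm = 20))
    expect_identical(run$genes, run2$genes)
    expect_error(suppressWarnings(randomControlRun(de, 30, gsc,
        exclude = sprintf("g%02d", 1:30))), "pool")
})
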