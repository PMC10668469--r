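test_that("size factors obey symmetry, equivariance and the hand example", {
    # identical columns -> all factors 1
    m <- matrix(c(5L, 5L, 9L, 9L, 2L, 2L), 3, 2, byrow = TRUE,
                dimnames = list(letters[1:3], c("s1", "s2")))
    expect_equal(unname(medianRatioSizeFactors(m)), c(1, 1))
    # doubling one column doubles its factor relative to the original
    m2 <- cbind(m, s3 = m[, "s1"] * 2L)
    sf <- medianRatioSizeFactors(m2)
    expect_equal(unname(sf["s3"] / sf["s1"]), 2, tolerance = 1e-12)
    # hand-computed 3x2 example: all ratios are 1/sqrt(2) and sqrt(2)
    m3 <- matrix(c(10, 20, 100, 200, 1, 2), 3, 2, byrow = TRUE,
                 dimnames = list(letters[1:3], c("s1", "s2")))
    expect_equal(unname(medianRatioSizeFactors(m3)),
                 c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
    # geometric mean is always 1
    set.seed(1)
    r <- matrix(rnbinom(300, mu = 50, size = 5), 30, 10,
                dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
    expect_equal(exp(mean(log(medianRatioSizeFactors(r)))), 1,
                 tolerance = 1e-12)
    # no feature positive everywhere -> error advising the fallback
    z <- matrix(c(0L, 3L, 4L, 0L), 2, 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
    expect_error(medianRatioSizeFactors(z), "pseudoReference")
    expect_silent(medianRatioSizeFactors(z, pseudoReference = TRUE))
})

test_that("count normalization divides by factors and applies log2", {
    m <- matrix(c(3L, 6L), 1, 2, dimnames = list("g", c("s1", "s2")))
    sf <- c(s1 = 1, s2 = 1)
    expect_identical(normalizeCounts(m, sf), matrix(c(3, 6), 1, 2,
        dimnames = list("g", c("s1", "s2"))))
    sf2 <- c(s1 = 2, s2 = 2)
    ln <- normalizeCounts(m, sf2, log2 = TRUE, pseudocount = 1)
    expect_equal(ln[1, "s1"], log2(2.5), tolerance = 1e-12)
    zero <- matrix(0L, 1, 2, dimnames = list("g", c("s1", "s2")))
    expect_equal(unname(normalizeCounts(zero, sf2, log2 = TRUE)[1, ]),
                 c(0, 0))
    expect_error(normalizeCounts(m, c(x = 1, y = 2)), "do not match")
})

test_that("BH adjustment matches the brute-force reference", {
    expect_equal(adjustBH(0.03), 0.03)
    expect_equal(adjustBH(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_identical(adjustBH(c(0.04, NA)), c(0.04, NA))
    expect_error(adjustBH(c(0.5, 1.2)), "\\[0, 1\\]")
    set.seed(11)
    for (i in 1:100) {
        p <- runif(sample(1:50, 1))
        if (i %% 3 == 0) p[sample(length(p), 1)] <- NA
        expect_equal(adjustBH(p), bruteBH(p), tolerance = 1e-15)
    }
})

test_that("NB continuous fit is calibrated and recovers planted slopes", {
    cfg <- simulationConfig(nSamplesSmallRna = 30, nSharedSamples = 20,
                            nSmallRna = 600, fractionDeSmallRna = 0,
                            clusterMembers = 0, fractionMultimapped = 0)
    set.seed(21)
    simNull <- simulateSmallRna(cfg)
    deNull <- fitNbContinuous(simNull$counts)
    expect_true(mean(deNull$pvalue < 0.05, na.rm = TRUE) < 0.09)
    # planted balanced slopes are detected and unbiased
    cfg2 <- simulationConfig(nSamplesSmallRna = 30, nSharedSamples = 20,
                             nSmallRna = 600, fractionDeSmallRna = 0.5,
                             slopeRange = c(0.2, 0.2), upFraction = 0.5,
                             baselineLog2Range = c(log2(100), log2(100)),
                             clusterMembers = 0, fractionMultimapped = 0)
    set.seed(22)
    sim <- simulateSmallRna(cfg2)
    de <- fitNbContinuous(sim$counts)
    up <- sim$truth$slope > 0
    expect_gt(mean(de$pvalue[up] < 0.05, na.rm = TRUE), 0.8)
    expect_lt(abs(mean(de$log2FoldChange[up], na.rm = TRUE) - 0.2), 0.05)
    expect_s4_class(de, "DEResults")
})

test_that("all-zero features get low_count status and stay out of BH", {
    cts <- matrix(rnbinom(10 * 8, mu = 40, size = 10), 10, 8,
                  dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
    cts[3, ] <- 0L
    sdat <- data.frame(sample_id = colnames(cts),
                       gestational_age = seq(8, 19, length.out = 8))
    de <- fitNbContinuous(cts, sampleData = sdat)
    expect_identical(de$status[3], "low_count")
    expect_true(is.na(de$padj[3]))
    expect_identical(adjustBH(de$pvalue[de$status == "ok"]),
                     de$padj[de$status == "ok"])
})

test_that("two-group fit handles degenerate and constructed cases", {
    ab <- rbind(same = c(1, 1, 1, 1, 1, 1),
                shift = c(1, 1.01, 0.99, 2, 2.01, 1.99))
    colnames(ab) <- paste0("s", 1:6)
    g <- rep(c("w10", "w18"), each = 3)
    de <- fitTwoGroup(ab, g)
    expect_equal(de["same", "log2FoldChange"], 0)
    expect_equal(de["same", "pvalue"], 1)
    expect_equal(de["shift", "log2FoldChange"], 1, tolerance = 0.05)
    expect_lt(de["shift", "pvalue"], 0.05)
    # group with < 2 observations fails that feature
    ab2 <- ab; ab2[1, 1:2] <- NA
    de2 <- fitTwoGroup(ab2, g)
    expect_identical(de2["same", "status"], "failed")
    # null calibration
    set.seed(31)
    null <- matrix(rnorm(400 * 6), 400, 6,
                   dimnames = list(paste0("p", 1:400), paste0("s", 1:6)))
    deN <- fitTwoGroup(null, g)
    expect_true(abs(mean(deN$pvalue < 0.05) - 0.05) < 0.035)
})

test_that("sample PCA is well-formed and tracks an age-linear signal", {
    set.seed(41)
    age <- seq(8, 19, length.out = 12)
    sig <- outer(rnorm(100), age - 13.5) +
        matrix(rnorm(1200, sd = 0.3), 100, 12)
    dimnames(sig) <- list(paste0("g", 1:100), paste0("s", 1:12))
    pc <- pcaSamples(sig)
    expect_true(all(diff(pc$varianceExplained) <= 1e-12))
    expect_lte(sum(pc$varianceExplained), 1 + 1e-8)
    expect_gt(abs(cor(pc$coordinates[, 1], age)), 0.9)
    # permutation of feature order leaves variance fractions unchanged
    perm <- sig[sample(nrow(sig)), ]
    expect_equal(pcaSamples(perm)$varianceExplained, pc$varianceExplained)
    expect_error(pcaSamples(sig[, 1, drop = FALSE]), "2 samples")
})

test_that("subtype composition sums to one and matches arithmetic", {
    oc <- tinyCounts()
    comp <- subtypeComposition(oc)
    expect_equal(sum(comp$countProportion), 1, tolerance = 1e-12)
    two <- OmicCounts(matrix(c(300L, 100L), 2, 1,
                             dimnames = list(c("a", "b"), "s1")),
                      subtype = c("miRNA", "piRNA"))
    comp2 <- subtypeComposition(two)
    expect_equal(comp2$countProportion[comp2$subtype == "miRNA"], 0.75)
    expect_equal(comp2$countProportion[comp2$subtype == "piRNA"], 0.25)
    expect_error(subtypeComposition(two[0, ]), "empty")
})

test_that("direction split respects the zero fold-change tie rule", {
    de <- new("DEResults", S4Vectors::DataFrame(
        baseMean = c(10, 10, 10), log2FoldChange = c(1, -2, 0),
        lfcSE = 1, stat = 1, pvalue = c(0.001, 0.2, 0.0005),
        padj = c(0.01, 0.2, 0.001), status = "ok",
        row.names = c("up1", "ns1", "zero1")))
    s <- splitByDirection(de, alpha = 0.05)
    expect_identical(s$up, "up1")
    expect_identical(s$down, character(0))
})
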