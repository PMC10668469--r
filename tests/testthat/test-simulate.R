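test_that("age draws are bounded, sorted and reproducible", {
    set.seed(1); a1 <- simulateAges(5)
    set.seed(1); a2 <- simulateAges(5)
    expect_identical(a1, a2)
    expect_false(is.unsorted(a1))
    expect_true(all(a1 >= 8 & a1 <= 19))
    expect_error(simulateAges(0), ">= 1")
    set.seed(2)
    big <- simulateAges(10000)
    expect_gt(mean(big), 12.5)
    expect_lt(mean(big), 14.5)
})

test_that("simulation config is validated", {
    expect_error(simulationConfig(subtypeProportions = c(miRNA = 0.5)),
                 "sum to 1")
    expect_error(simulationConfig(nSharedSamples = 60), "cohort sizes")
    expect_error(simulationConfig(ageRange = c(19, 8)), "increasing")
})

test_that("study generation is byte-identical under a fixed seed", {
    cfg <- smallSimConfig()
    s1 <- simulateStudy(cfg, seed = 5)
    s2 <- simulateStudy(cfg, seed = 5)
    expect_identical(counts(s1$smallRna), counts(s2$smallRna))
    expect_identical(counts(s1$mrna), counts(s2$mrna))
    expect_identical(as.data.frame(s1$targetMap), as.data.frame(s2$targetMap))
    expect_identical(s1$proteins$abundance, s2$proteins$abundance)
    expect_identical(setMembers(s1$geneSets), setMembers(s2$geneSets))
    expect_identical(s1$truth, s2$truth)
})

test_that("target map has the requested disjoint planted and decoy edges", {
    cfg <- smallSimConfig()
    study <- simulateStudy(cfg, seed = 6)
    edges <- study$truth$edges
    expect_identical(sum(edges$type == "planted"), 40L)
    expect_identical(sum(edges$type == "decoy"), 80L)
    key <- paste(edges$mirna_id, edges$mrna_id)
    expect_identical(anyDuplicated(key), 0L)
    expect_identical(nrow(study$targetMap), nrow(edges))
    # planted edges are a subset of the emitted map
    mapKey <- paste(study$targetMap$mirna_id, study$targetMap$mrna_id)
    expect_true(all(key %in% mapKey))
    # infeasible counts are refused
    tiny <- simulationConfig(nMrna = 2, nTrueEdges = 10, nDecoyEdges = 10)
    set.seed(1)
    sm <- simulateSmallRna(simulationConfig(nSmallRna = 200,
                                            clusterMembers = 2))
    smTruth <- sm$truth[1:3, ]
    smTruth$subtype <- "miRNA"
    expect_error(simulateTargetMap(tiny, smTruth), "infeasible")
})

test_that("planted repression induces negative correlation; strength 0 does not", {
    cfg <- smallSimConfig()
    study <- simulateStudy(cfg, seed = 7)
    normS <- normalizeCounts(study$smallRna, log2 = TRUE)
    normM <- normalizeCounts(study$mrna, log2 = TRUE)
    edges <- study$truth$edges
    corOf <- function(e) vapply(seq_len(nrow(e)), function(i)
        cor(normS[e$mirna_id[i], study$sharedSamples],
            normM[e$mrna_id[i], study$sharedSamples]), 0)
    rPlanted <- corOf(edges[edges$type == "planted", ])
    expect_gte(mean(rPlanted < 0), 0.95)
    expect_lt(median(rPlanted), -0.3)
    # with repression off, planted pairs look like decoys
    cfg0 <- smallSimConfig(repressionStrength = 0)
    study0 <- simulateStudy(cfg0, seed = 7)
    nS0 <- normalizeCounts(study0$smallRna, log2 = TRUE)
    nM0 <- normalizeCounts(study0$mrna, log2 = TRUE)
    e0 <- study0$truth$edges
    corOf0 <- function(e) vapply(seq_len(nrow(e)), function(i)
        cor(nS0[e$mirna_id[i], study0$sharedSamples],
            nM0[e$mrna_id[i], study0$sharedSamples]), 0)
    ks <- suppressWarnings(ks.test(corOf0(e0[e0$type == "planted", ]),
                                   corOf0(e0[e0$type == "decoy", ])))
    expect_gt(ks$p.value, 0.01)
})

test_that("null generation drives DE to its nominal false-positive rate", {
    cfg <- simulationConfig(nSamplesSmallRna = 30, nSharedSamples = 20,
                            nSmallRna = 800, fractionDeSmallRna = 0,
                            clusterMembers = 0, fractionMultimapped = 0)
    set.seed(8)
    sim <- simulateSmallRna(cfg)
    de <- fitNbContinuous(sim$counts)
    expect_lt(abs(mean(de$pvalue < 0.05, na.rm = TRUE) - 0.05), 0.03)
})

test_that("protein simulation encodes concordance and dropout", {
    cfg <- smallSimConfig()
    study <- simulateStudy(cfg, seed = 9)
    ab <- study$proteins$abundance
    expect_identical(dim(ab), c(80L, 6L))
    expect_gt(sum(is.na(ab)), 0)
    tr <- study$truth$proteins
    feat <- study$truth$features
    slope <- setNames(feat$slope, feat$feature_id)
    conc <- tr[tr$concordant, ]
    expect_true(all(sign(conc$effect) == sign(slope[conc$gene_id])))
    # large effect + full concordance: every detected DE protein concordant
    cfgC <- smallSimConfig(concordanceFraction = 1, proteinDropout = 0)
    studyC <- simulateStudy(cfgC, seed = 10)
    trC <- studyC$truth$proteins
    deP <- fitTwoGroup(commonProteinFilter(studyC$proteins$abundance),
                       studyC$proteins$groups)
    sig <- rownames(deP)[!is.na(deP$pvalue) & deP$pvalue < 0.01 &
                         abs(deP$log2FoldChange) > 0.5]
    sigTruth <- trC[match(sig, trC$protein_id), ]
    expect_gt(mean(sigTruth$concordant), 0.95)
})

test_that("gene-set sizes are bounded and directions recorded", {
    cfg <- smallSimConfig()
    study <- simulateStudy(cfg, seed = 11)
    sizes <- lengths(setMembers(study$geneSets))
    expect_true(all(sizes >= 5 & sizes <= 500))
    expect_setequal(unique(study$truth$sets$direction),
                    c("up", "down", "null"))
    expect_identical(nSets(study$geneSets), nrow(study$truth$sets))
})

test_that("protein-effect-free generation is calibrated", {
    cfg <- smallSimConfig(proteinEffect = 0, proteinDropout = 0,
                          nProtein = 400, nMrna = 600)
    study <- simulateStudy(cfg, seed = 12)
    de <- fitTwoGroup(study$proteins$abundance, study$proteins$groups)
    expect_lt(abs(mean(de$pvalue < 0.05, na.rm = TRUE) - 0.05), 0.04)
})
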