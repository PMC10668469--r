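# Small in-code fixtures and independent brute-force oracles.

# write a TSV and return its path
writeTempTsv <- function(df, dir = tempdir(), name = "fixture.tsv") {
    path <- file.path(dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

# a tiny annotated count matrix
tinyCounts <- function() {
    m <- matrix(c(0L, 2L, 1L, 3L, 10L, 20L), nrow = 3, byrow = TRUE,
                dimnames = list(c("miR-1", "piR-1", "circ-1"),
                                c("s1", "s2")))
    OmicCounts(m, subtype = c("miRNA", "piRNA", "circRNA"),
               uniquelyMapped = c(TRUE, TRUE, FALSE))
}

# brute-force Benjamini-Hochberg: p * m / rank, then cumulative min from the
# largest p down, capped at 1 (independent of stats::p.adjust)
bruteBH <- function(p) {
    out <- rep(NA_real_, length(p))
    obs <- which(!is.na(p))
    if (!length(obs)) return(out)
    pv <- p[obs]
    m <- length(pv)
    ord <- order(pv, decreasing = TRUE)
    adj <- pv[ord] * m / (m:1)
    adj <- pmin(cummin(adj), 1)
    out[obs[ord]] <- adj
    out
}

# definition-based Pearson r and p (sums written out; no cor()/cor.test())
brutePearson <- function(x, y) {
    n <- length(x)
    sx <- sum(x); sy <- sum(y)
    num <- n * sum(x * y) - sx * sy
    den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
    r <- num / den
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    c(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# a compact synthetic study for pipeline-level tests
smallSimConfig <- function(...) {
    args <- list(nSamplesSmallRna = 24, nSamplesMrna = 28,
                 nSharedSamples = 20, nSmallRna = 700, nMrna = 500,
                 nProtein = 80, clusterMembers = 12,
                 nTrueEdges = 40, nDecoyEdges = 80,
                 nProteinFromTargets = 30, nMetaboliteSets = 30,
                 setSizeRange = c(8, 40))
    do.call(simulationConfig, utils::modifyList(args, list(...)))
}
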