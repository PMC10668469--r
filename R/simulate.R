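#' Default temporal cluster templates
#'
#' Six z-score profiles over the six gestational-age bins, emulating the
#' qualitative pattern classes seen in developing-heart miRNA expression:
#' two upward patterns (early saturating rise; late rise), one monotone
#' decline, two rise-then-fall shapes peaking mid- or late-gestation, and
#' one fall-then-recover shape. Shapes were chosen with pairwise
#' correlations <= 0.63 so they are separable under correlation-distance
#' clustering.
#'
#' @return 6 x 6 numeric matrix (templates x bins), each row mean 0, SD 1.
#' @export
defaultClusterTemplates <- function() {
    zs <- function(x) (x - mean(x)) / sd(x)
    rbind(
        up_early    = zs(c(0, 2.5, 4, 4.8, 5.4, 6)),
        up_late     = zs(c(0, 0, 0.1, 0.2, 1, 5)),
        down_linear = zs(c(6, 5, 4, 3, 2, 1)),
        peak_mid    = zs(c(-1, 1.5, 3.5, 3, 0.5, -2)),
        trough_mid  = zs(c(2.5, 0, -2, -1.5, 0.5, 2)),
        peak_late   = zs(c(-2, -1.5, -0.5, 1, 3, -1)))
}

#' Synthetic-study configuration
#'
#' Parameters of the synthetic multi-omic study generator. The defaults
#' mirror the emulated study design: 37 small-RNA samples and 53 mRNA
#' samples spanning 8-19 gestational weeks with 30 shared samples, six
#' small-RNA subtypes, age-linear negative-binomial expression with
#' per-sample biological noise, six planted temporal pattern templates,
#' planted repressive miRNA->target edges plus non-functional decoy
#' edges, 3 vs 3 protein samples at weeks 10 and 18, and metabolite gene
#' sets with planted directions.
#'
#' @param nSamplesSmallRna,nSamplesMrna,nSharedSamples cohort sizes.
#' @param ageRange gestational-age range in weeks.
#' @param nSmallRna,nMrna,nProtein feature counts per layer.
#' @param subtypeProportions named proportions over the six small-RNA
#'   classes (must sum to 1).
#' @param fractionDeSmallRna,fractionDeMrna fraction of features with a
#'   non-zero age slope.
#' @param slopeRange magnitude range of age slopes (log2 units per week).
#' @param upFraction probability that a DE slope is positive.
#' @param nbDispersion NB dispersion alpha (variance `mu + alpha mu^2`).
#' @param bioSd per-feature-per-sample biological noise SD (log2 units).
#' @param libsizeRange library-size factor range (log-uniform).
#' @param baselineLog2Range per-feature baseline log2 mean range.
#' @param fractionMultimapped fraction of small-RNA features flagged as
#'   multi-mapped (removed by the unique-mapping filter).
#' @param clusterMembers miRNA features per temporal template.
#' @param clusterAmplitude template amplitude in log2 units.
#' @param clusterTemplates template matrix (see
#'   [defaultClusterTemplates()]).
#' @param nTrueEdges,nDecoyEdges planted repressive and decoy target-map
#'   edges.
#' @param repressionStrength log2 decrease of a target's mean per SD of
#'   its regulator's latent signal.
#' @param minRegulatorSlope minimum |slope| of planted regulators and
#'   targets (log2/week).
#' @param proteinAges the two protein group ages (weeks).
#' @param nPerProteinGroup protein samples per group.
#' @param proteinEffect group log2 shift of proteins of DE genes.
#' @param proteinSd residual protein SD (log2).
#' @param concordanceFraction fraction of DE-gene proteins shifting in the
#'   mRNA direction (the rest shift oppositely).
#' @param proteinDropout per-(protein, sample) missingness probability.
#' @param nProteinFromTargets proteins drawn from planted target genes.
#' @param nMetaboliteSets number of synthetic gene sets.
#' @param setSizeRange member-count range per set.
#' @param fractionDirectional fraction of sets with a planted direction
#'   (split evenly up/down; the rest are null).
#' @param directionalPurity probability that a directional set's member is
#'   drawn from same-direction DE genes rather than at random.
#' @return a validated `SimulationConfig` (classed list).
#' @export
simulationConfig <- function(nSamplesSmallRna = 37, nSamplesMrna = 53,
                             nSharedSamples = 30, ageRange = c(8, 19),
                             nSmallRna = 3000, nMrna = 2500, nProtein = 200,
                             subtypeProportions = c(miRNA = 0.20, piRNA = 0.30,
                                                    circRNA = 0.35,
                                                    snoRNA = 0.08,
                                                    snRNA = 0.04, tRNA = 0.03),
                             fractionDeSmallRna = 0.3, fractionDeMrna = 0.5,
                             slopeRange = c(0.1, 0.35), upFraction = 0.5,
                             nbDispersion = 0.1, bioSd = 0.5,
                             libsizeRange = c(0.5, 2),
                             baselineLog2Range = c(3, 10),
                             fractionMultimapped = 0.1,
                             clusterMembers = 40, clusterAmplitude = 1,
                             clusterTemplates = defaultClusterTemplates(),
                             nTrueEdges = 150, nDecoyEdges = 350,
                             repressionStrength = 1,
                             minRegulatorSlope = 0.15,
                             proteinAges = c(10, 18), nPerProteinGroup = 3,
                             proteinEffect = 1.5, proteinSd = 0.25,
                             concordanceFraction = 0.8,
                             proteinDropout = 0.1,
                             nProteinFromTargets = 60,
                             nMetaboliteSets = 120,
                             setSizeRange = c(10, 100),
                             fractionDirectional = 0.3,
                             directionalPurity = 0.85) {
    cfg <- as.list(environment())
    class(cfg) <- "SimulationConfig"
    validateSimulationConfig(cfg)
    cfg
}

#' Validate a simulation configuration
#' @param cfg a `SimulationConfig`.
#' @return `cfg` invisibly; stops if invalid.
#' @export
validateSimulationConfig <- function(cfg) {
    if (abs(sum(cfg$subtypeProportions) - 1) > 1e-8)
        stop("subtypeProportions must sum to 1")
    if (!all(names(cfg$subtypeProportions) %in%
             c("miRNA", "piRNA", "circRNA", "snoRNA", "snRNA", "tRNA")))
        stop("subtypeProportions must be named by the six small-RNA classes")
    if (cfg$nSharedSamples > min(cfg$nSamplesSmallRna, cfg$nSamplesMrna))
        stop("nSharedSamples must be <= both cohort sizes")
    if (cfg$ageRange[1L] >= cfg$ageRange[2L])
        stop("ageRange must be increasing")
    for (nm in c("nSamplesSmallRna", "nSamplesMrna", "nSharedSamples",
                 "nSmallRna", "nMrna", "nProtein", "nTrueEdges",
                 "nDecoyEdges", "nMetaboliteSets"))
        if (cfg[[nm]] < 0) stop(nm, " must be >= 0")
    if (cfg$nbDispersion < 0 || cfg$bioSd < 0)
        stop("noise parameters must be >= 0")
    if (ncol(cfg$clusterTemplates) < 2L)
        stop("clusterTemplates needs >= 2 bins")
    invisible(cfg)
}

#' Draw sorted gestational ages
#'
#' @param n number of samples (>= 1).
#' @param range age range in weeks.
#' @return sorted numeric ages, uniform over `range`.
#' @export
simulateAges <- function(n, range = c(8, 19)) {
    if (n < 1) stop("n must be >= 1")
    if (range[1L] >= range[2L]) stop("range must be increasing")
    sort(runif(n, range[1L], range[2L]))
}

# Sample frame shared by both expression layers: shared samples carry the
# same id and age in both cohorts.
.simSampleFrame <- function(cfg) {
    nSh <- cfg$nSharedSamples
    nSOnly <- cfg$nSamplesSmallRna - nSh
    nMOnly <- cfg$nSamplesMrna - nSh
    ids <- c(sprintf("S%02d", seq_len(nSh)),
             if (nSOnly) sprintf("SR%02d", seq_len(nSOnly)),
             if (nMOnly) sprintf("MR%02d", seq_len(nMOnly)))
    ages <- c(simulateAges(nSh, cfg$ageRange),
              if (nSOnly) simulateAges(nSOnly, cfg$ageRange),
              if (nMOnly) simulateAges(nMOnly, cfg$ageRange))
    sex <- sample(c("F", "M"), length(ids), replace = TRUE)
    data.frame(sample_id = ids, gestational_age = ages, sex = sex,
               shared = c(rep(TRUE, nSh), rep(FALSE, nSOnly + nMOnly)),
               layer = c(rep("both", nSh), rep("smallRNA", nSOnly),
                         rep("mRNA", nMOnly)),
               stringsAsFactors = FALSE)
}

# Interpolate a template (z over bins) at arbitrary ages.
.templateAt <- function(tpl, ages, ageRange) {
    nb <- length(tpl)
    edges <- seq(ageRange[1L], ageRange[2L], length.out = nb + 1L)
    mids <- (edges[-1L] + edges[-(nb + 1L)]) / 2
    stats::approx(mids, tpl, xout = ages, rule = 2)$y
}

#' Simulate the small-RNA layer
#'
#' Counts are NB(mean, dispersion) with
#' `log2 mean = baseline + slope * (age - midpoint) + biological noise +
#' log2 libsize`; non-DE features have slope 0; temporal-template members
#' (miRNAs) follow interpolated template profiles instead of a linear
#' slope; subtypes and multi-mapping flags are drawn per configuration.
#'
#' @param cfg a [simulationConfig()].
#' @param samples optional precomputed sample frame (internal use).
#' @return list with `counts` (an [OmicCounts-class]), `truth` (per-feature
#'   data.frame) and `log2mu` (latent log2 mean matrix, library-size term
#'   excluded).
#' @export
simulateSmallRna <- function(cfg, samples = NULL) {
    if (is.null(samples)) samples <- .simSampleFrame(cfg)
    sm <- samples[samples$layer %in% c("both", "smallRNA"), , drop = FALSE]
    n <- cfg$nSmallRna
    subtype <- sample(names(cfg$subtypeProportions), n, replace = TRUE,
                      prob = cfg$subtypeProportions)
    prefix <- c(miRNA = "miR-%04d", piRNA = "piR-%04d", circRNA = "circ-%04d",
                snoRNA = "SNORD%04d", snRNA = "RNU%04d", tRNA = "tRNA-%04d")
    ids <- sprintf(prefix[subtype], seq_len(n))
    uniq <- runif(n) > cfg$fractionMultimapped
    isDe <- runif(n) < cfg$fractionDeSmallRna
    slope <- ifelse(isDe,
                    ifelse(runif(n) < cfg$upFraction, 1, -1) *
                        runif(n, cfg$slopeRange[1L], cfg$slopeRange[2L]),
                    0)
    clusterId <- rep(NA_integer_, n)
    nTpl <- nrow(cfg$clusterTemplates)
    eligible <- which(subtype == "miRNA" & uniq)
    need <- nTpl * cfg$clusterMembers
    if (length(eligible) < need)
        stop(sprintf("only %d uniquely mapped miRNAs; %d template members needed",
                     length(eligible), need))
    memberIdx <- sample(eligible, need)
    clusterId[memberIdx] <- rep(seq_len(nTpl), each = cfg$clusterMembers)
    isDe[memberIdx] <- TRUE
    slope[memberIdx] <- NA_real_  # template-shaped, not linear
    baseline <- runif(n, cfg$baselineLog2Range[1L], cfg$baselineLog2Range[2L])
    mid <- mean(cfg$ageRange)
    ages <- sm$gestational_age
    log2mu <- baseline +
        outer(slope, ages - mid, function(s, a) ifelse(is.na(s), 0, s) * a) +
        matrix(rnorm(n * nrow(sm), sd = cfg$bioSd), n, nrow(sm))
    for (t in seq_len(nTpl)) {
        rows <- which(clusterId == t)
        shape <- .templateAt(cfg$clusterTemplates[t, ], ages, cfg$ageRange)
        log2mu[rows, ] <- log2mu[rows, , drop = FALSE] +
            rep(cfg$clusterAmplitude * shape, each = length(rows))
    }
    lib <- exp(runif(nrow(sm), log(cfg$libsizeRange[1L]),
                     log(cfg$libsizeRange[2L])))
    mu <- 2^sweep(log2mu, 2L, log2(lib), "+")
    cts <- matrix(rnbinom(length(mu), mu = mu,
                          size = if (cfg$nbDispersion > 0)
                              1 / cfg$nbDispersion else Inf),
                  n, nrow(sm), dimnames = list(ids, sm$sample_id))
    oc <- OmicCounts(cts, subtype = subtype, uniquelyMapped = uniq,
                     sampleData = sm[, c("sample_id", "gestational_age",
                                         "sex")])
    # dominant age-trend direction: slope sign, or the template's linear
    # projection where it is strong (|cor with bin order| > 0.5)
    tplTrend <- apply(cfg$clusterTemplates, 1L, function(z) {
        r <- cor(z, seq_along(z))
        if (abs(r) > 0.5) sign(r) else 0
    })
    trendSign <- ifelse(is.na(slope), tplTrend[clusterId], sign(slope))
    trendSign[is.na(trendSign)] <- 0
    truth <- data.frame(layer = "smallRNA", feature_id = ids,
                        subtype = subtype, uniquely_mapped = uniq,
                        is_de = isDe, slope = slope, cluster_id = clusterId,
                        trend_sign = trendSign, stringsAsFactors = FALSE)
    rownames(log2mu) <- ids
    colnames(log2mu) <- sm$sample_id
    list(counts = oc, truth = truth, log2mu = log2mu)
}

# Draw the mRNA feature truth frame (ids, DE flags, slopes) ahead of the
# target map so decoy sampling can see both layers' trend directions.
.simMrnaTruth <- function(cfg) {
    n <- cfg$nMrna
    ids <- sprintf("GENE%05d", seq_len(n))
    isDe <- runif(n) < cfg$fractionDeMrna
    slope <- ifelse(isDe,
                    ifelse(runif(n) < cfg$upFraction, 1, -1) *
                        runif(n, cfg$slopeRange[1L], cfg$slopeRange[2L]),
                    0)
    data.frame(layer = "mRNA", feature_id = ids, subtype = "mRNA",
               uniquely_mapped = TRUE, is_de = isDe, slope = slope,
               cluster_id = NA_integer_, trend_sign = sign(slope),
               stringsAsFactors = FALSE)
}

#' Simulate the predicted target map
#'
#' Emits the union of planted repressive edges (regulators: uniquely
#' mapped, slope-DE miRNAs with |slope| >= `minRegulatorSlope`) and decoy
#' edges with no repression, as disjoint sets. Decoy pairs whose two
#' endpoints carry strong opposite age trends are excluded: such pairs
#' anti-correlate for purely developmental reasons and are inherently
#' indistinguishable from repression by the anti-correlation signature,
#' so they would probe the confounding of the signature rather than the
#' specificity of the filter.
#'
#' @param cfg a [simulationConfig()].
#' @param smallTruth per-feature truth from [simulateSmallRna()].
#' @param mrnaTruth per-feature mRNA truth (generated internally by
#'   [simulateStudy()]).
#' @return list with `map` (a [TargetMap-class]), `edges` (data.frame with
#'   `mirna_id`, `mrna_id`, `type`, `strength`) and `mrnaTruth`.
#' @export
simulateTargetMap <- function(cfg, smallTruth, mrnaTruth = NULL) {
    if (is.null(mrnaTruth)) mrnaTruth <- .simMrnaTruth(cfg)
    mirIds <- smallTruth$feature_id[smallTruth$subtype == "miRNA"]
    mrnaIds <- mrnaTruth$feature_id
    if (cfg$nTrueEdges + cfg$nDecoyEdges > length(mirIds) * length(mrnaIds))
        stop("infeasible edge counts for the feature space")
    reg <- smallTruth$feature_id[smallTruth$subtype == "miRNA" &
                                 smallTruth$uniquely_mapped &
                                 !is.na(smallTruth$slope) &
                                 abs(smallTruth$slope) >= cfg$minRegulatorSlope]
    if (!length(reg) && cfg$nTrueEdges > 0)
        stop("no eligible regulator miRNAs for planted edges")
    nReg <- min(length(reg), max(1L, ceiling(cfg$nTrueEdges / 3)))
    regs <- sample(reg, nReg)
    planted <- if (cfg$nTrueEdges > 0) data.frame(
        mirna_id = regs[(seq_len(cfg$nTrueEdges) - 1L) %% nReg + 1L],
        mrna_id = sample(mrnaIds, cfg$nTrueEdges),
        type = "planted", strength = cfg$repressionStrength,
        stringsAsFactors = FALSE) else
        data.frame(mirna_id = character(), mrna_id = character(),
                   type = character(), strength = numeric())
    plantedKey <- paste(planted$mirna_id, planted$mrna_id, sep = "\r")
    mirTrend <- setNames(smallTruth$trend_sign, smallTruth$feature_id)
    mrnaTrend <- setNames(mrnaTruth$trend_sign, mrnaTruth$feature_id)
    decoy <- data.frame(mirna_id = character(), mrna_id = character())
    nNeed <- cfg$nDecoyEdges
    while (nrow(decoy) < nNeed) {
        cand <- data.frame(
            mirna_id = sample(mirIds, 2L * nNeed, replace = TRUE),
            mrna_id = sample(mrnaIds, 2L * nNeed, replace = TRUE),
            stringsAsFactors = FALSE)
        key <- paste(cand$mirna_id, cand$mrna_id, sep = "\r")
        confounded <- mirTrend[cand$mirna_id] *
            mrnaTrend[cand$mrna_id] == -1
        cand <- cand[!key %in% plantedKey & !duplicated(key) & !confounded, ,
                     drop = FALSE]
        decoy <- rbind(decoy, cand)
        decoy <- decoy[!duplicated(paste(decoy$mirna_id, decoy$mrna_id,
                                         sep = "\r")), , drop = FALSE]
    }
    decoy <- decoy[seq_len(nNeed), , drop = FALSE]
    decoy$type <- "decoy"; decoy$strength <- 0
    edges <- rbind(planted, decoy)
    rownames(edges) <- NULL
    list(map = TargetMap(edges$mirna_id, edges$mrna_id), edges = edges,
         mrnaTruth = mrnaTruth)
}

#' Simulate the mRNA layer with planted miRNA repression
#'
#' Same count model as [simulateSmallRna()]; additionally, planted targets
#' are forced to be DE with the sign opposite their regulator's, and over
#' the shared samples each planted target's log2 mean is reduced by
#' `repressionStrength` times the standardized latent signal (log2
#' expected value, library size excluded) of its regulator, inducing
#' negative Pearson correlation. Decoy targets are untouched.
#'
#' @param cfg a [simulationConfig()].
#' @param smallSim output of [simulateSmallRna()].
#' @param targetEdges `edges` data.frame from [simulateTargetMap()].
#' @param mrnaTruth the mRNA truth frame from [simulateTargetMap()].
#' @param samples optional precomputed sample frame (internal use).
#' @return list with `counts` (an [OmicCounts-class]) and `truth`.
#' @export
simulateMrnaWithRepression <- function(cfg, smallSim, targetEdges,
                                       mrnaTruth = NULL, samples = NULL) {
    if (is.null(samples)) stop("pass the sample frame used for the small-RNA layer")
    if (is.null(mrnaTruth)) mrnaTruth <- .simMrnaTruth(cfg)
    mr <- samples[samples$layer %in% c("both", "mRNA"), , drop = FALSE]
    shared <- samples$sample_id[samples$shared]
    n <- cfg$nMrna
    ids <- mrnaTruth$feature_id
    isDe <- mrnaTruth$is_de
    slope <- mrnaTruth$slope
    planted <- targetEdges[targetEdges$type == "planted", , drop = FALSE]
    unknown <- setdiff(planted$mrna_id, ids)
    if (length(unknown))
        stop("planted edge references unknown mRNA: ",
             paste(unknown, collapse = ", "))
    regSlope <- setNames(smallSim$truth$slope, smallSim$truth$feature_id)
    # sustained repression by a monotonically changing miRNA also drives an
    # opposite developmental slope in its target; at strength 0 there is no
    # effect of any kind
    forced <- planted[planted$strength > 0, , drop = FALSE]
    ti <- match(forced$mrna_id, ids)
    if (length(ti)) {
        isDe[ti] <- TRUE
        slope[ti] <- -sign(regSlope[forced$mirna_id]) *
            runif(nrow(forced), max(cfg$minRegulatorSlope, cfg$slopeRange[1L]),
                  cfg$slopeRange[2L])
    }
    baseline <- runif(n, cfg$baselineLog2Range[1L], cfg$baselineLog2Range[2L])
    mid <- mean(cfg$ageRange)
    ages <- mr$gestational_age
    log2mu <- baseline + outer(slope, ages - mid) +
        matrix(rnorm(n * nrow(mr), sd = cfg$bioSd), n, nrow(mr))
    dimnames(log2mu) <- list(ids, mr$sample_id)
    if (nrow(planted) && length(shared) >= 2L) {
        tiAll <- match(planted$mrna_id, ids)
        lat <- smallSim$log2mu[planted$mirna_id, shared, drop = FALSE]
        zLat <- t(scale(t(lat)))  # standardize each regulator over shared
        log2mu[cbind(rep(tiAll, length(shared)),
                     rep(match(shared, mr$sample_id), each = nrow(planted)))] <-
            log2mu[tiAll, shared, drop = FALSE] -
                planted$strength * zLat
    }
    batch <- rep_len(c("b1", "b2"), nrow(mr))
    lib <- exp(runif(nrow(mr), log(cfg$libsizeRange[1L]),
                     log(cfg$libsizeRange[2L])))
    mu <- 2^sweep(log2mu, 2L, log2(lib), "+")
    cts <- matrix(rnbinom(length(mu), mu = mu,
                          size = if (cfg$nbDispersion > 0)
                              1 / cfg$nbDispersion else Inf),
                  n, nrow(mr), dimnames = list(ids, mr$sample_id))
    sdat <- data.frame(sample_id = mr$sample_id,
                       gestational_age = mr$gestational_age, sex = mr$sex,
                       batch = batch, stringsAsFactors = FALSE)
    oc <- OmicCounts(cts, subtype = "mRNA", uniquelyMapped = TRUE,
                     sampleData = sdat)
    truth <- data.frame(layer = "mRNA", feature_id = ids, subtype = "mRNA",
                        uniquely_mapped = TRUE, is_de = isDe, slope = slope,
                        cluster_id = NA_integer_, trend_sign = sign(slope),
                        stringsAsFactors = FALSE)
    list(counts = oc, truth = truth)
}

#' Simulate the protein layer
#'
#' Two groups at the configured ages (default weeks 10 and 18, n = 3
#' each); log2 abundances are normal around a per-protein base, shifted by
#' `proteinEffect` in the direction of the encoding gene's mRNA slope for
#' concordant proteins and oppositely for the rest; per-(protein, sample)
#' dropout introduces missing values for the common-protein filter.
#'
#' @param cfg a [simulationConfig()].
#' @param mrnaTruth per-feature truth from [simulateMrnaWithRepression()].
#' @param targetEdges edge truth (planted targets are preferentially
#'   sampled so tripartite paths exist).
#' @return list with `abundance` (log2 matrix with NA dropout), `groups`
#'   (factor of group ages) and `truth` (per-protein data.frame).
#' @export
simulateProteins <- function(cfg, mrnaTruth, targetEdges = NULL) {
    nP <- cfg$nProtein
    plantedGenes <- if (!is.null(targetEdges))
        unique(targetEdges$mrna_id[targetEdges$type == "planted"]) else
        character()
    nFromTargets <- min(cfg$nProteinFromTargets, length(plantedGenes), nP)
    fromTargets <- if (nFromTargets) sample(plantedGenes, nFromTargets) else
        character()
    pool <- setdiff(mrnaTruth$feature_id, fromTargets)
    genes <- c(fromTargets, sample(pool, nP - nFromTargets))
    geneSlope <- setNames(mrnaTruth$slope, mrnaTruth$feature_id)[genes]
    geneDe <- setNames(mrnaTruth$is_de, mrnaTruth$feature_id)[genes]
    concordant <- runif(nP) < cfg$concordanceFraction
    effect <- ifelse(geneDe & geneSlope != 0,
                     ifelse(concordant, 1, -1) * sign(geneSlope) *
                         cfg$proteinEffect,
                     0)
    nG <- cfg$nPerProteinGroup
    groups <- factor(rep(cfg$proteinAges, each = nG))
    sampleIds <- paste0("P", rep(cfg$proteinAges, each = nG), "_",
                        rep(seq_len(nG), 2L))
    base <- runif(nP, 20, 28)
    ab <- base + outer(effect, as.numeric(groups == levels(groups)[2L])) +
        matrix(rnorm(nP * 2L * nG, sd = cfg$proteinSd), nP, 2L * nG)
    dimnames(ab) <- list(genes, sampleIds)
    ab[matrix(runif(length(ab)) < cfg$proteinDropout, nP, 2L * nG)] <- NA
    truth <- data.frame(protein_id = genes, gene_id = genes,
                        effect = effect, concordant = concordant & geneDe &
                            geneSlope != 0,
                        stringsAsFactors = FALSE)
    list(abundance = ab, groups = groups, truth = truth)
}

#' Simulate metabolite-like gene sets with planted directions
#'
#' "up" sets oversample genes with positive true slopes, "down" sets
#' genes with negative slopes (at `directionalPurity`), and null sets are
#' uniform draws from the gene universe.
#'
#' @param cfg a [simulationConfig()].
#' @param mrnaTruth per-feature truth from [simulateMrnaWithRepression()].
#' @return list with `gsc` (a [GeneSetCollection-class]) and `truth`
#'   (data.frame: set_id, direction).
#' @export
simulateGeneSets <- function(cfg, mrnaTruth) {
    universe <- mrnaTruth$feature_id
    upPool <- mrnaTruth$feature_id[mrnaTruth$is_de & !is.na(mrnaTruth$slope) &
                                   mrnaTruth$slope > 0]
    downPool <- mrnaTruth$feature_id[mrnaTruth$is_de & !is.na(mrnaTruth$slope) &
                                     mrnaTruth$slope < 0]
    nDir <- round(cfg$nMetaboliteSets * cfg$fractionDirectional / 2) * 2L
    direction <- c(rep(c("up", "down"), nDir / 2L),
                   rep("null", cfg$nMetaboliteSets - nDir))
    members <- vector("list", cfg$nMetaboliteSets)
    for (i in seq_len(cfg$nMetaboliteSets)) {
        k <- sample(seq(cfg$setSizeRange[1L], cfg$setSizeRange[2L]), 1L)
        m <- if (direction[i] == "null") sample(universe, k) else {
            pool <- if (direction[i] == "up") upPool else downPool
            fromPool <- runif(k) < cfg$directionalPurity
            unique(c(sample(pool, sum(fromPool),
                            replace = sum(fromPool) > length(pool)),
                     sample(universe, sum(!fromPool))))
        }
        members[[i]] <- m
    }
    names(members) <- sprintf("met_%03d", seq_len(cfg$nMetaboliteSets))
    truth <- data.frame(set_id = names(members), direction = direction,
                        stringsAsFactors = FALSE)
    list(gsc = GeneSetCollection(members,
                                 descriptions = paste("synthetic set,",
                                                      direction)),
         truth = truth)
}

#' Simulate a complete synthetic multi-omic study
#'
#' Chains the layer generators under one seed and returns all matrices,
#' tables and the ground truth needed to score recovery of differential
#' expression, temporal clusters, repressive edges, protein concordance
#' and gene-set directions.
#'
#' @param cfg a [simulationConfig()].
#' @param seed integer seed; the run is fully deterministic given
#'   (cfg, seed).
#' @return a `SyntheticStudy` (classed list) with elements `smallRna`,
#'   `mrna` ([OmicCounts-class]), `targetMap`, `proteins`, `geneSets`,
#'   `sharedSamples`, `truth` (list: features, edges, proteins, sets) and
#'   `config`.
#' @export
simulateStudy <- function(cfg = simulationConfig(), seed = 1L) {
    set.seed(as.integer(seed))
    samples <- .simSampleFrame(cfg)
    small <- simulateSmallRna(cfg, samples = samples)
    tm <- simulateTargetMap(cfg, small$truth)
    mrna <- simulateMrnaWithRepression(cfg, small, tm$edges,
                                       mrnaTruth = tm$mrnaTruth,
                                       samples = samples)
    prot <- simulateProteins(cfg, mrna$truth, tm$edges)
    sets <- simulateGeneSets(cfg, mrna$truth)
    structure(list(
        smallRna = small$counts, mrna = mrna$counts, targetMap = tm$map,
        proteins = prot[c("abundance", "groups")],
        geneSets = sets$gsc,
        sharedSamples = samples$sample_id[samples$shared],
        truth = list(features = rbind(small$truth, mrna$truth),
                     edges = tm$edges, proteins = prot$truth,
                     sets = sets$truth),
        config = cfg, seed = as.integer(seed)),
        class = "SyntheticStudy")
}

#' Simulate noisy z-profiles from the temporal templates
#'
#' Planted template z-profiles plus normal noise, re-standardized per
#' feature; used to exercise pattern-cluster recovery in isolation.
#'
#' @param nPerTemplate members per template (scalar or vector).
#' @param noiseSd additive noise SD before re-standardization.
#' @param templates template matrix (rows = templates).
#' @return list with `z` (profile matrix) and `labels` (true template
#'   index per feature).
#' @export
simulateTemplateProfiles <- function(nPerTemplate = 40, noiseSd = 0.3,
                                     templates = defaultClusterTemplates()) {
    nT <- nrow(templates)
    nPer <- rep_len(nPerTemplate, nT)
    labels <- rep(seq_len(nT), nPer)
    raw <- templates[labels, , drop = FALSE] +
        matrix(rnorm(length(labels) * ncol(templates), sd = noiseSd),
               length(labels), ncol(templates))
    z <- t(apply(raw, 1L, function(x) (x - mean(x)) / sd(x)))
    rownames(z) <- sprintf("f%04d", seq_along(labels))
    colnames(z) <- colnames(templates)
    names(labels) <- rownames(z)
    list(z = z, labels = labels)
}
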