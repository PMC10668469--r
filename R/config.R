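#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with the defaults used
#' throughout: per-layer DE significance `alphaDe = 0.05` on adjusted p
#' (no fold-change cutoff), anti-correlation retention `alphaCorr = 0.05`
#' with `rMax = 0` (strict inequalities), top negatively correlated
#' fraction 0.05, figure-level correlation cuts -0.7 and -0.85, raw protein
#' `alphaProtein = 0.05`, reporter set-size window [5, 500] with 1000
#' permutations and adjusted-p cutoffs 0.05 (and figure-level 0.01),
#' gestational-age bin edges 8,10,12,14,16,18,19 and a minimum pattern
#' cluster size of 15.
#'
#' @param alphaDe,alphaCorr,alphaProtein,alphaReporter,figureAlphaReporter
#'   significance cutoffs in (0, 1).
#' @param rMax retain correlations strictly below this value (default 0).
#' @param topFraction fraction of most negative correlations to keep.
#' @param figureRCuts stricter correlation cuts used for focused subnetworks.
#' @param minK,maxK reporter gene-set size window.
#' @param nPerm number of reporter permutations.
#' @param binEdges gestational-age bin edges in weeks (half-open bins,
#'   last bin closed).
#' @param minClusterSize minimum members per temporal pattern cluster.
#' @param cutHeight correlation-distance tree cut height for clustering.
#' @param seed integer random seed for the run.
#' @return a validated `PipelineConfig` (classed list).
#' @export
pipelineConfig <- function(alphaDe = 0.05, alphaCorr = 0.05, rMax = 0,
                           topFraction = 0.05, figureRCuts = c(-0.7, -0.85),
                           alphaProtein = 0.05, minK = 5, maxK = 500,
                           nPerm = 1000, alphaReporter = 0.05,
                           figureAlphaReporter = 0.01,
                           binEdges = c(8, 10, 12, 14, 16, 18, 19),
                           minClusterSize = 15, cutHeight = 0.25,
                           seed = 1L) {
    cfg <- list(alphaDe = alphaDe, alphaCorr = alphaCorr, rMax = rMax,
                topFraction = topFraction, figureRCuts = figureRCuts,
                alphaProtein = alphaProtein, minK = minK, maxK = maxK,
                nPerm = nPerm, alphaReporter = alphaReporter,
                figureAlphaReporter = figureAlphaReporter,
                binEdges = binEdges, minClusterSize = minClusterSize,
                cutHeight = cutHeight, seed = as.integer(seed))
    validatePipelineConfig(cfg)
    structure(cfg, class = "PipelineConfig")
}

#' Validate a pipeline configuration
#' @param cfg a list as produced by [pipelineConfig()].
#' @return `cfg` invisibly; stops with an informative error if invalid.
#' @export
validatePipelineConfig <- function(cfg) {
    chkAlpha <- function(nm) {
        v <- cfg[[nm]]
        if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
            stop(sprintf("config: %s must be a single value in (0, 1)", nm))
    }
    for (nm in c("alphaDe", "alphaCorr", "alphaProtein", "alphaReporter",
                 "figureAlphaReporter"))
        chkAlpha(nm)
    if (cfg$topFraction <= 0 || cfg$topFraction > 1)
        stop("config: topFraction must be in (0, 1]")
    if (any(cfg$figureRCuts >= 0))
        stop("config: figureRCuts must be negative")
    if (cfg$minK > cfg$maxK) stop("config: minK must be <= maxK")
    if (cfg$nPerm < 1) stop("config: nPerm must be >= 1")
    if (length(cfg$binEdges) < 2L || is.unsorted(cfg$binEdges, strictly = TRUE))
        stop("config: binEdges must be strictly increasing")
    if (cfg$minClusterSize < 1) stop("config: minClusterSize must be >= 1")
    if (cfg$cutHeight <= 0) stop("config: cutHeight must be > 0")
    invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [pipelineConfig()] defaults. A `simulate:` block, if present, is passed
#' to [simulationConfig()] and an `inputs:` block may name count-matrix /
#' sample-table / target-map / protein / GMT paths for non-synthetic runs.
#'
#' @param path YAML file path.
#' @return list with elements `pipeline` (a `PipelineConfig`), `simulate`
#'   (a `SimulationConfig` or `NULL`) and `inputs` (named paths or `NULL`).
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    if (is.null(y)) y <- list()
    known <- c("pipeline", "simulate", "inputs")
    unknown <- setdiff(names(y), known)
    if (length(unknown))
        stop("unknown config section(s): ", paste(unknown, collapse = ", "))
    pArgs <- y$pipeline %||% list()
    bad <- setdiff(names(pArgs), names(formals(pipelineConfig)))
    if (length(bad))
        stop("unknown pipeline option(s): ", paste(bad, collapse = ", "))
    pipeline <- do.call(pipelineConfig, pArgs)
    simulate <- NULL
    if (!is.null(y$simulate)) {
        sArgs <- if (isTRUE(y$simulate)) list() else y$simulate
        badS <- setdiff(names(sArgs), names(formals(simulationConfig)))
        if (length(badS))
            stop("unknown simulate option(s): ", paste(badS, collapse = ", "))
        simulate <- do.call(simulationConfig, sArgs)
    }
    list(pipeline = pipeline, simulate = simulate, inputs = y$inputs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
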