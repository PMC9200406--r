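#' Configuration for the synthetic metabolome generator
#'
#' Defaults emulate the study design the pipeline targets: 6 biological
#' replicates per population x tissue x feeding-state cell across 3
#' populations (Surface, Tinaja, Pachon), 3 tissues and 3 feeding states,
#' with 174 identified primary metabolites, 483 identified lipids and 50
#' unidentified peaks. Peak heights are log-normal: on the log10 scale a
#' feature's intensity is its baseline plus a tissue offset, any planted
#' effects, an orthogonal nuisance latent factor, and measurement noise.
#' A fraction of (feature, population x tissue) cells is zeroed to mimic
#' metabolites absent from a population/organ, and each sample's column is
#' jittered multiplicatively so that mTIC normalization is actually
#' exercised.
#'
#' Planted effect magnitudes are expressed in z-units of the measurement
#' noise: a magnitude-m effect shifts log10 intensity by m * noiseSd in
#' the affected cells.
#'
#' @param nReps replicates per design cell (>= 3; default 6).
#' @param populations,tissues,states factor levels to generate.
#' @param nPrimary,nLipid,nUnknown feature counts (defaults 174/483/50).
#' @param baselineLogMean,baselineLogSd per-feature baseline distribution
#'   on the log10 scale (defaults 5 and 0.8: peak heights around 1e5).
#' @param tissueOffsetSd SD of per-feature tissue offsets (default 0.3).
#' @param noiseSd residual SD on the log10 scale (default 0.25).
#' @param nuisanceLoadingSd,nuisanceScoreSd latent-factor loading and
#'   score SDs (defaults 0.3 and 1); the factor is drawn independently of
#'   all class labels, hence orthogonal to them in expectation.
#' @param zeroRate fraction of (feature, population x tissue) cells set
#'   to all-zero (default 0.05; must be < 1).
#' @param mticJitterSd SD of the per-sample multiplicative log10 jitter
#'   (default 0.1).
#' @param effects list of [plantedEffect()] specs (default none).
#' @return A list of class \code{"simConfig"}.
#' @export
simConfig <- function(nReps = 6L,
                      populations = populationLevels(),
                      tissues = tissueLevels(),
                      states = feedingStateLevels(),
                      nPrimary = 174L, nLipid = 483L, nUnknown = 50L,
                      baselineLogMean = 5, baselineLogSd = 0.8,
                      tissueOffsetSd = 0.3, noiseSd = 0.25,
                      nuisanceLoadingSd = 0.3, nuisanceScoreSd = 1,
                      zeroRate = 0.05, mticJitterSd = 0.1,
                      effects = list()) {
    if (nReps < 3) stop("nReps must be >= 3")
    if (zeroRate < 0 || zeroRate >= 1) stop("zeroRate must be in [0, 1)")
    if (!all(populations %in% .POPULATIONS)) stop("unknown population")
    if (!all(tissues %in% .TISSUES)) stop("unknown tissue")
    if (!all(states %in% .STATES)) stop("unknown feeding state")
    structure(list(nReps = as.integer(nReps), populations = populations,
                   tissues = tissues, states = states,
                   nPrimary = as.integer(nPrimary),
                   nLipid = as.integer(nLipid),
                   nUnknown = as.integer(nUnknown),
                   baselineLogMean = baselineLogMean,
                   baselineLogSd = baselineLogSd,
                   tissueOffsetSd = tissueOffsetSd, noiseSd = noiseSd,
                   nuisanceLoadingSd = nuisanceLoadingSd,
                   nuisanceScoreSd = nuisanceScoreSd, zeroRate = zeroRate,
                   mticJitterSd = mticJitterSd, effects = effects),
              class = "simConfig")
}

#' Specify a planted differential-abundance effect
#'
#' @param featureIds character, features carrying the effect.
#' @param scope which populations carry it: \code{"shared_cave"}
#'   (Pachon + Tinaja), \code{"pachon_only"}, \code{"tinaja_only"},
#'   \code{"surface_only"}.
#' @param axis \code{"feeding_state"} (shift only in \code{states}) or
#'   \code{"population_baseline"} (shift in every state).
#' @param magnitude effect size in z-units of the measurement noise.
#' @param states affected feeding states (required for the
#'   \code{feeding_state} axis).
#' @return A list of class \code{"plantedEffect"}.
#' @export
plantedEffect <- function(featureIds,
                          scope = c("shared_cave", "pachon_only",
                                    "tinaja_only", "surface_only"),
                          axis = c("feeding_state",
                                   "population_baseline"),
                          magnitude, states = NULL) {
    scope <- match.arg(scope)
    axis <- match.arg(axis)
    if (!is.finite(magnitude)) stop("magnitude must be finite")
    if (axis == "feeding_state") {
        if (is.null(states)) stop("feeding_state effects need 'states'")
        if (!all(states %in% .STATES)) stop("unknown feeding state")
    }
    structure(list(featureIds = as.character(featureIds), scope = scope,
                   axis = axis, magnitude = magnitude, states = states),
              class = "plantedEffect")
}

.scopePopulations <- function(scope)
    switch(scope, shared_cave = c("Pachon", "Tinaja"),
           pachon_only = "Pachon", tinaja_only = "Tinaja",
           surface_only = "Surface")

#' Simulate a synthetic metabolome with ground truth
#'
#' Draws a peak table and matching sample metadata from the generative
#' model described in [simConfig()], deterministically for a given seed.
#' Returns the realized effects, nuisance scores and zeroed cells as
#' ground truth for recovery scoring.
#'
#' @param config a [simConfig()] list.
#' @param seed integer RNG seed.
#' @return List with \code{set} (a [MetabolomeSet-class] with populated
#'   \code{colData}), \code{meta} (the metadata \code{data.frame}) and
#'   \code{truth} (effects, per-sample nuisance scores, zeroed cells,
#'   config and seed).
#' @export
#' @examples
#' sim <- simulateMetabolome(simConfig(nPrimary = 20, nLipid = 0,
#'                                     nUnknown = 5), seed = 1)
#' sim$set
simulateMetabolome <- function(config = simConfig(), seed = 1L) {
    stopifnot(inherits(config, "simConfig"))
    old <- .saveSeed(); on.exit(.restoreSeed(old))
    set.seed(as.integer(seed))
    cf <- config
    featIds <- c(sprintf("M%03d", seq_len(cf$nPrimary)),
                 sprintf("L%03d", seq_len(cf$nLipid)),
                 sprintf("U%03d", seq_len(cf$nUnknown)))
    nFeat <- length(featIds)
    identified <- c(rep(TRUE, cf$nPrimary + cf$nLipid),
                    rep(FALSE, cf$nUnknown))
    broad <- c("Carbohydrates/CCM", "Amino acids", "Fatty acids",
               "Nucleotides", "Miscellaneous/secondary")
    lipidClasses <- c("TG", "PC", "PE", "CE", "FFA", "SM", "Cer")
    category <- c(sample(broad, cf$nPrimary, replace = TRUE),
                  sample(lipidClasses, cf$nLipid, replace = TRUE),
                  rep("unknown", cf$nUnknown))
    meta <- expand.grid(replicate = seq_len(cf$nReps),
                        feeding_state = cf$states, tissue = cf$tissues,
                        population = cf$populations,
                        stringsAsFactors = FALSE)
    meta$sample_id <- with(meta, paste(population, tissue, feeding_state,
                                       paste0("r", replicate), sep = "."))
    meta <- meta[, c("sample_id", "population", "tissue", "feeding_state",
                     "replicate")]
    nSamp <- nrow(meta)

    baseline <- stats::rnorm(nFeat, cf$baselineLogMean, cf$baselineLogSd)
    tissOff <- matrix(stats::rnorm(nFeat * length(cf$tissues), 0,
                                   cf$tissueOffsetSd),
                      nFeat, length(cf$tissues),
                      dimnames = list(featIds, cf$tissues))
    loading <- stats::rnorm(nFeat, 0, cf$nuisanceLoadingSd)
    score <- stats::rnorm(nSamp, 0, cf$nuisanceScoreSd)
    names(score) <- meta$sample_id

    lg <- matrix(baseline, nFeat, nSamp) +
        tissOff[, meta$tissue] +
        tcrossprod(loading, score) +
        matrix(stats::rnorm(nFeat * nSamp, 0, cf$noiseSd), nFeat, nSamp)
    dimnames(lg) <- list(featIds, meta$sample_id)

    for (eff in cf$effects) {
        if (!all(eff$featureIds %in% featIds))
            stop("planted effect names unknown features")
        pops <- .scopePopulations(eff$scope)
        cols <- meta$population %in% pops
        if (eff$axis == "feeding_state")
            cols <- cols & meta$feeding_state %in% eff$states
        lg[eff$featureIds, cols] <- lg[eff$featureIds, cols] +
            eff$magnitude * cf$noiseSd
    }

    intensities <- 10^lg

    ## zero-inflation: whole (feature, population x tissue) cells absent
    cellKey <- paste(meta$population, meta$tissue, sep = ".")
    cells <- unique(cellKey)
    grid <- expand.grid(feature = featIds, cell = cells,
                        stringsAsFactors = FALSE)
    nZero <- floor(cf$zeroRate * nrow(grid))
    zeroCells <- grid[sample.int(nrow(grid), nZero), , drop = FALSE]
    for (i in seq_len(nrow(zeroCells)))
        intensities[zeroCells$feature[i],
                    cellKey == zeroCells$cell[i]] <- 0

    ## per-sample mTIC jitter, multiplicative
    jitter <- 10^stats::rnorm(nSamp, 0, cf$mticJitterSd)
    intensities <- sweep(intensities, 2, jitter, "*")

    set <- MetabolomeSet(intensities, identified = identified,
                         category = category, sampleData = meta)
    truth <- list(effects = cf$effects, nuisanceScores = score,
                  zeroCells = zeroCells, mticJitter = jitter,
                  config = cf, seed = as.integer(seed))
    list(set = set, meta = meta, truth = truth)
}

#' Score pipeline flags against simulation ground truth
#'
#' Compares significance flags from feature tests with the planted-effect
#' membership recorded at simulation time, per effect scope/axis stratum
#' and overall. Sensitivity is the flagged fraction of features carrying a
#' planted effect, the false-positive rate is the flagged fraction of null
#' features, and precision is TP / (TP + FP) (NA when nothing is flagged).
#'
#' @param truth the \code{truth} element of [simulateMetabolome()].
#' @param results \code{data.frame} with \code{feature_id} and
#'   \code{p_value} (e.g. [runFeatureTests()] output).
#' @param alpha significance threshold (default 0.05).
#' @return \code{data.frame}, one row per stratum plus \code{"overall"}.
#' @export
recoveryReport <- function(truth, results, alpha = 0.05) {
    allFeat <- c(sprintf("M%03d", seq_len(truth$config$nPrimary)),
                 sprintf("L%03d", seq_len(truth$config$nLipid)),
                 sprintf("U%03d", seq_len(truth$config$nUnknown)))
    if (!all(results$feature_id %in% allFeat))
        stop("results refer to features outside the simulated universe")
    flagged <- unique(results$feature_id[results$p_value <= alpha])
    trueSets <- list()
    for (eff in truth$effects) {
        key <- paste(eff$scope, eff$axis, sep = "/")
        trueSets[[key]] <- union(trueSets[[key]], eff$featureIds)
    }
    trueAll <- unique(unlist(trueSets))
    tested <- unique(results$feature_id)
    nullFeat <- setdiff(tested, trueAll)
    strata <- c(names(trueSets), "overall")
    rows <- lapply(strata, function(st) {
        pos <- if (st == "overall") intersect(trueAll, tested)
               else intersect(trueSets[[st]], tested)
        tp <- length(intersect(pos, flagged))
        fp <- length(intersect(nullFeat, flagged))
        data.frame(stratum = st, n_true = length(pos),
                   n_null = length(nullFeat),
                   sensitivity = if (length(pos)) tp / length(pos) else NA,
                   fpr = if (length(nullFeat)) fp / length(nullFeat)
                         else NA,
                   precision = if (tp + fp > 0) tp / (tp + fp)
                               else NA_real_,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
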