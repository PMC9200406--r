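test_that("simulation is deterministic under a fixed seed", {
    cfg <- simConfig(nPrimary = 15, nLipid = 10, nUnknown = 5, nReps = 3)
    a <- simulateMetabolome(cfg, seed = 9)
    b <- simulateMetabolome(cfg, seed = 9)
    expect_identical(peaks(a$set), peaks(b$set))
    expect_identical(a$truth$nuisanceScores, b$truth$nuisanceScores)
    expect_identical(a$truth$zeroCells, b$truth$zeroCells)
    c <- simulateMetabolome(cfg, seed = 10)
    expect_false(identical(peaks(a$set), peaks(c$set)))
    ## and the caller's RNG stream is left untouched
    set.seed(123); before <- rnorm(1)
    set.seed(123); simulateMetabolome(cfg, seed = 9); after <- rnorm(1)
    expect_identical(before, after)
})

test_that("the degenerate no-variation config yields constant features", {
    cfg <- simConfig(nPrimary = 8, nLipid = 0, nUnknown = 0, nReps = 3,
                     tissues = "liver", states = c("Refed", "Fasted30"),
                     noiseSd = 0, nuisanceLoadingSd = 0, zeroRate = 0,
                     mticJitterSd = 0.1)
    sim <- simulateMetabolome(cfg, seed = 4)
    ## raw data vary only through the mTIC jitter; normalization within
    ## one population x tissue group removes it, so every feature is
    ## constant and flagged by the z-transform
    norm <- mticNormalize(sim$set, grouping = "global")
    cmp <- buildComparisons(sim$meta)[[1]]
    z <- logZTransform(norm, cmp)
    expect_setequal(z@constantFeatures, rownames(zscores(z)))
    expect_true(all(zscores(z) == 0))
})

test_that("design shape and annotations match the config", {
    cfg <- simConfig(nPrimary = 10, nLipid = 6, nUnknown = 4, nReps = 4,
                     tissues = c("liver", "brain"),
                     states = c("Refed", "Fasted30"))
    sim <- simulateMetabolome(cfg, seed = 1)
    expect_equal(dim(sim$set), c(20L, 3 * 2 * 2 * 4))
    expect_equal(sum(identifiedFeatures(sim$set)), 16)
    expect_equal(sum(featureCategories(sim$set) == "unknown"), 4)
    key <- with(sim$meta, paste(population, tissue, feeding_state,
                                replicate))
    expect_false(anyDuplicated(key) > 0)
    expect_error(simConfig(nReps = 2), "nReps")
    expect_error(simConfig(zeroRate = 1), "zeroRate")
    expect_error(simulateMetabolome(simConfig(
        effects = list(plantedEffect("nope", "shared_cave",
                                     "feeding_state", 1,
                                     states = "Fasted30"))), seed = 1),
        "unknown features")
})

test_that("realized noise matches the configured noise scale", {
    ## with no nuisance/effects/jitter, the within-cell log10 SD should
    ## estimate noiseSd; average over many (feature, cell) estimates
    cfg <- simConfig(nPrimary = 120, nLipid = 0, nUnknown = 0, nReps = 6,
                     tissues = "liver", states = c("Refed", "Fasted30"),
                     noiseSd = 0.25, nuisanceLoadingSd = 0, zeroRate = 0,
                     mticJitterSd = 0)
    sim <- simulateMetabolome(cfg, seed = 21)
    lg <- log10(peaks(sim$set))
    cell <- with(sim$meta, paste(population, feeding_state))
    sds <- unlist(lapply(unique(cell), function(cl)
        apply(lg[, cell == cl, drop = FALSE], 1, sd)))
    expect_lt(abs(mean(sds) - 0.25) / 0.25, 0.2)
})

test_that("planted fasting effects dominate the realized group
           differences in both cave populations", {
    ids <- sprintf("M%03d", 1:10)
    cfg <- simConfig(nPrimary = 60, nLipid = 0, nUnknown = 0,
                     tissues = "liver", states = c("Refed", "Fasted30"),
                     zeroRate = 0, nuisanceLoadingSd = 0.1,
                     effects = list(plantedEffect(
                         ids, "shared_cave", "feeding_state",
                         magnitude = 3, states = "Fasted30")))
    sim <- simulateMetabolome(cfg, seed = 31)
    lg <- log10(peaks(sim$set))
    meta <- sim$meta
    for (pop in c("Pachon", "Tinaja")) {
        fast <- meta$sample_id[meta$population == pop &
                               meta$feeding_state == "Fasted30"]
        refed <- meta$sample_id[meta$population == pop &
                                meta$feeding_state == "Refed"]
        d <- abs(rowMeans(lg[, fast]) - rowMeans(lg[, refed]))
        expect_setequal(names(sort(d, decreasing = TRUE))[1:10], ids)
    }
})

test_that("recovery report scores flags against truth per stratum", {
    truth <- list(
        config = simConfig(nPrimary = 10, nLipid = 0, nUnknown = 0),
        effects = list(plantedEffect(c("M001", "M002"), "shared_cave",
                                     "feeding_state", 2,
                                     states = "Fasted30")))
    res <- data.frame(feature_id = sprintf("M%03d", 1:10),
                      p_value = c(0.01, 0.2, rep(0.5, 8)))
    rep1 <- recoveryReport(truth, res)
    ov <- rep1[rep1$stratum == "overall", ]
    expect_equal(ov$sensitivity, 0.5)
    expect_equal(ov$fpr, 0)
    expect_equal(ov$precision, 1)

    ## perfect flags
    res2 <- res; res2$p_value <- c(0.01, 0.01, rep(0.5, 8))
    ov2 <- recoveryReport(truth, res2)
    expect_equal(ov2$sensitivity[ov2$stratum == "overall"], 1)
    expect_equal(ov2$precision[ov2$stratum == "overall"], 1)

    ## no flags: recall 0, precision undefined -> NA
    res3 <- res; res3$p_value <- rep(0.5, 10)
    ov3 <- recoveryReport(truth, res3)
    expect_equal(ov3$sensitivity[ov3$stratum == "overall"], 0)
    expect_true(is.na(ov3$precision[ov3$stratum == "overall"]))

    expect_error(recoveryReport(truth, data.frame(feature_id = "X9",
                                                  p_value = 0.1)),
                 "outside the simulated universe")
})

test_that("O-PLS filtering does not hurt DQ2 when a nuisance factor
           dominates", {
    ## paired seeds: same data analyzed with and without the filter
    diffs <- numeric(12)
    for (i in seq_along(diffs)) {
        cfg <- simConfig(nPrimary = 25, nLipid = 0, nUnknown = 0,
                         tissues = "liver",
                         states = c("Refed", "Fasted30"), zeroRate = 0,
                         noiseSd = 0.15, nuisanceLoadingSd = 0.6,
                         effects = list(plantedEffect(
                             sprintf("M%03d", 1:6), "shared_cave",
                             "feeding_state", 1.5, states = "Fasted30")))
        sim <- simulateMetabolome(cfg, seed = 300 + i)
        cmp <- buildComparisons(sim$meta)[["liver.Pachon.Fasted30-vs-Refed"]]
        z <- logZTransform(mticNormalize(sim$set), cmp)
        X <- t(zscores(z))
        y <- comparisonLabels(cmp)
        dFilt <- dq2Score(y, cvPredict(X, y, nOrth = 1))$dq2
        dRaw <- dq2Score(y, cvPredict(X, y, nOrth = 0))$dq2
        diffs[i] <- dFilt - dRaw
    }
    expect_gte(mean(diffs), 0)
})
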