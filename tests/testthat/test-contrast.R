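# A small balanced dataset for contrast building: 3 populations x 1
# tissue x 2 states x nReps, with an optional per-population log10 shift
# applied to chosen features in the fasted state.
makeContrastSim <- function(nReps = 6, nFeatures = 20, seed = 1,
                            shift = 0, shiftFeatures = character(0),
                            shiftPops = c("Pachon", "Tinaja"),
                            noiseSd = 0.25) {
    eff <- list()
    if (shift != 0 && length(shiftFeatures)) {
        scope <- if (setequal(shiftPops, c("Pachon", "Tinaja")))
            "shared_cave"
        else if (identical(shiftPops, "Pachon")) "pachon_only"
        else if (identical(shiftPops, "Tinaja")) "tinaja_only"
        else "surface_only"
        eff <- list(plantedEffect(shiftFeatures, scope, "feeding_state",
                                  magnitude = shift,
                                  states = "Fasted30"))
    }
    simulateMetabolome(
        simConfig(nReps = nReps, tissues = "liver",
                  states = c("Refed", "Fasted30"),
                  nPrimary = nFeatures, nLipid = 0, nUnknown = 0,
                  zeroRate = 0, noiseSd = noiseSd, effects = eff),
        seed = seed)
}

test_that("identical populations give an identically zero contrast", {
    ## feed the builder one dataset, then overwrite so P, T, S columns
    ## are element-wise equal for every replicate/state
    sim <- makeContrastSim(nReps = 3, nFeatures = 5, seed = 2)
    m <- peaks(sim$set)
    meta <- sim$meta
    surf <- meta$sample_id[meta$population == "Surface"]
    for (pop in c("Pachon", "Tinaja")) {
        ids <- meta$sample_id[meta$population == pop]
        key <- sub("^[^.]+", "", ids)               # .tissue.state.rep
        m[, ids] <- m[, paste0("Surface", key)]
    }
    set <- attachSampleMeta(MetabolomeSet(m), meta)
    ct <- buildContrast(set, "liver", c("Refed", "Fasted30"))
    expect_lt(max(abs(ct@values)), 1e-9)
    expect_equal(sort(unique(ct@labels)), c(-1, 1))
    expect_equal(ncol(ct@values), 6)
})

test_that("a cave-only fasted shift appears as a between-class gap", {
    sim <- makeContrastSim(nFeatures = 10, seed = 5, shift = 8,
                           shiftFeatures = sprintf("M%03d", 1:3),
                           noiseSd = 0.05)
    ct <- buildContrast(sim$set, "liver", c("Refed", "Fasted30"))
    gap <- rowMeans(ct@values[, ct@labels > 0]) -
        rowMeans(ct@values[, ct@labels < 0])
    expect_true(all(gap[1:3] > 2 * max(abs(gap[4:10]))))
})

test_that("unbalanced replicate counts are an error, not imputed", {
    sim <- makeContrastSim(nReps = 6, nFeatures = 5, seed = 3)
    keep <- sim$meta$sample_id != "Tinaja.liver.Fasted30.r6"
    set <- attachSampleMeta(
        MetabolomeSet(peaks(sim$set)[, keep]),
        sim$meta[keep, ])
    expect_error(buildContrast(set, "liver", c("Refed", "Fasted30")),
                 "unbalanced populations")
})

test_that("the contrast is symmetric in the two cave populations", {
    sim <- makeContrastSim(nFeatures = 12, seed = 7, shift = 2,
                           shiftFeatures = sprintf("M%03d", 1:4))
    ct1 <- buildContrast(sim$set, "liver", c("Refed", "Fasted30"))
    ## swap the Pachon and Tinaja columns wholesale and rebuild
    m <- peaks(sim$set)
    meta <- sim$meta
    pach <- meta$sample_id[meta$population == "Pachon"]
    tina <- meta$sample_id[meta$population == "Tinaja"]
    key <- sub("^[^.]+", "", pach)
    m2 <- m
    m2[, pach] <- m[, paste0("Tinaja", key)]
    m2[, paste0("Tinaja", key)] <- m[, pach]
    set2 <- attachSampleMeta(MetabolomeSet(m2), meta)
    ct2 <- buildContrast(set2, "liver", c("Refed", "Fasted30"))
    expect_equal(ct2@values, ct1@values, tolerance = 1e-10)

    r1 <- contrastTest(ct1)
    r2 <- contrastTest(ct2)
    expect_equal(r2$p_value, r1$p_value, tolerance = 1e-10)
    expect_equal(r2$direction, r1$direction)
})

test_that("shared-cave effects are detected 'up' and surface-only
           effects 'down'", {
    simUp <- makeContrastSim(nFeatures = 30, seed = 11, shift = 3,
                             shiftFeatures = sprintf("M%03d", 1:5))
    rUp <- contrastTest(buildContrast(simUp$set, "liver",
                                      c("Refed", "Fasted30")))
    hit <- rUp[rUp$feature_id %in% sprintf("M%03d", 1:5), ]
    expect_true(all(hit$direction == "up"))
    expect_true(any(hit$significant))

    simDown <- makeContrastSim(nFeatures = 30, seed = 11, shift = 3,
                               shiftFeatures = sprintf("M%03d", 1:5),
                               shiftPops = "Surface")
    rDown <- contrastTest(buildContrast(simDown$set, "liver",
                                        c("Refed", "Fasted30")))
    expect_true(all(rDown$direction[
        rDown$feature_id %in% sprintf("M%03d", 1:5)] == "down"))
})

test_that("a shared cave effect beats a single-population effect of the
           same size", {
    ## paired seeds: identical data apart from the effect scope
    pShared <- pSingle <- numeric(30)
    for (i in 1:30) {
        s <- makeContrastSim(nFeatures = 15, seed = 100 + i, shift = 1.5,
                             shiftFeatures = "M001")
        p <- makeContrastSim(nFeatures = 15, seed = 100 + i, shift = 1.5,
                             shiftFeatures = "M001",
                             shiftPops = "Pachon")
        pShared[i] <- contrastTest(buildContrast(
            s$set, "liver", c("Refed", "Fasted30")))$p_value[1]
        pSingle[i] <- contrastTest(buildContrast(
            p$set, "liver", c("Refed", "Fasted30")))$p_value[1]
    }
    expect_lt(median(pShared), median(pSingle))
})

test_that("pairing permutation is a diagnostic, not a different answer", {
    sim <- makeContrastSim(nFeatures = 10, seed = 13, shift = 2.5,
                           shiftFeatures = sprintf("M%03d", 1:3))
    r0 <- contrastTest(buildContrast(sim$set, "liver",
                                     c("Refed", "Fasted30")))
    rp <- contrastTest(buildContrast(sim$set, "liver",
                                     c("Refed", "Fasted30"),
                                     pairing = "permute", seed = 9))
    top0 <- r0$feature_id[order(r0$p_value)][1:3]
    topP <- rp$feature_id[order(rp$p_value)][1:3]
    expect_setequal(top0, topP)
})

test_that("top-k ranking matches a brute-force sort with deterministic
           tie-breaks", {
    set.seed(17)
    res <- data.frame(
        feature_id = sprintf("F%02d", 1:30),
        comparison_id = "c", slope = rnorm(30),
        slope_se = 1, z_stat = 0,
        p_value = sample(seq(0.001, 0.9, length.out = 30)),
        direction = "up", separation = FALSE, significant = FALSE,
        stringsAsFactors = FALSE)
    top <- topKTable(res, k = 20)
    brute <- res[order(res$p_value, -abs(res$slope), res$feature_id), ]
    expect_equal(top$feature_id, brute$feature_id[1:20])
    expect_equal(top$rank, 1:20)
    expect_equal(top$neg_log10_p, -log10(top$p_value))

    ## fewer than k: everything comes back
    expect_equal(nrow(topKTable(res[1:7, ], k = 20)), 7)

    ## ties on p: broken by |slope| then id, stable across shuffles
    tie <- res
    tie$p_value <- 0.5
    t1 <- topKTable(tie, k = 5)
    t2 <- topKTable(tie[sample(30), ], k = 5)
    expect_equal(t1$feature_id, t2$feature_id)
    expect_equal(t1$feature_id,
                 tie$feature_id[order(-abs(tie$slope),
                                      tie$feature_id)][1:5])
})
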