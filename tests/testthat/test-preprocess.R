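test_that("mTIC normalization reproduces the worked toy example", {
    m <- matrix(c(2, 3, 4, 6), 2,
                dimnames = list(c("F1", "F2"), c("A", "B")))
    res <- mticNormalize(MetabolomeSet(m), grouping = "global")
    expect_equal(unname(res@mticPerSample), c(5, 10))
    expect_equal(unname(res@mticReference), 7.5)
    expect_equal(unname(peaks(normalizedSet(res))),
                 matrix(c(3, 4.5, 3, 4.5), 2))

    ## equal mTIC across samples: normalization is the identity
    m2 <- matrix(c(2, 3, 1, 4), 2,
                 dimnames = list(c("F1", "F2"), c("A", "B")))
    res2 <- mticNormalize(MetabolomeSet(m2), grouping = "global")
    expect_equal(peaks(normalizedSet(res2)), peaks(MetabolomeSet(m2)))
})

test_that("unidentified peaks are excluded from mTIC but still scaled", {
    m <- matrix(c(2, 3, 100, 4, 6, 7), 3,
                dimnames = list(c("F1", "F2", "U1"), c("A", "B")))
    res <- mticNormalize(MetabolomeSet(m, identified = c(TRUE, TRUE,
                                                          FALSE)),
                         grouping = "global")
    expect_equal(unname(res@mticPerSample), c(5, 10))    # U1 not counted
    expect_equal(unname(peaks(normalizedSet(res))["U1", ]),
                 c(100 * 1.5, 7 * 0.75))                  # but scaled
    ## a sample with only unidentified signal has no defined mTIC
    bad <- MetabolomeSet(matrix(c(0, 0, 5, 1, 2, 3), 3,
                                dimnames = list(c("F1", "F2", "U1"),
                                                c("A", "B"))),
                         identified = c(TRUE, TRUE, FALSE))
    expect_error(mticNormalize(bad, grouping = "global"), "zero mTIC")
})

test_that("mTIC conservation and scale invariance hold on simulated data", {
    sim <- simulateMetabolome(simConfig(nPrimary = 30, nLipid = 10,
                                        nUnknown = 5, nReps = 3),
                              seed = 11)
    res <- mticNormalize(sim$set)
    norm <- peaks(normalizedSet(res))
    idf <- identifiedFeatures(sim$set)
    sums <- colSums(norm[idf, ])
    ref <- res@mticReference[res@groupOfSample]
    expect_lt(max(abs(sums - ref) / ref), 1e-9)

    ## multiplying one whole sample column by c > 0 leaves the normalized
    ## matrix unchanged up to its group reference (the reference mean
    ## itself absorbs the rescaling)
    m <- peaks(sim$set)
    m[, 3] <- m[, 3] * 7.3
    scaled <- attachSampleMeta(
        MetabolomeSet(m, identified = idf,
                      category = featureCategories(sim$set)), sim$meta)
    res2 <- mticNormalize(scaled)
    rel <- function(r) sweep(peaks(normalizedSet(r)), 2,
                             r@mticReference[r@groupOfSample], "/")
    expect_equal(rel(res2), rel(res), tolerance = 1e-12)
})

test_that("log10 z-scoring matches direct arithmetic and conventions", {
    m <- matrix(c(1, 10, 100, 1000), 1,
                dimnames = list("F1", paste0("S", 1:4)))
    cmp <- ComparisonDesign("c", "liver", c("S1", "S2"), c("S3", "S4"))
    z <- logZTransform(MetabolomeSet(m), cmp)
    expect_equal(unname(zscores(z)[1, ]),
                 c(-1.161895, -0.387298, 0.387298, 1.161895),
                 tolerance = 1e-6)

    ## constant feature: all-zero row, flagged
    mc <- matrix(c(5, 5, 5, 5, 1, 2, 4, 8), 2, byrow = TRUE,
                 dimnames = list(c("Fc", "Fv"), paste0("S", 1:4)))
    zc <- logZTransform(MetabolomeSet(mc), cmp)
    expect_equal(unname(zscores(zc)["Fc", ]), rep(0, 4))
    expect_equal(zc@constantFeatures, "Fc")

    ## zero replaced by half the smallest positive value of the feature
    mz <- matrix(c(0, 10, 100, 1000), 1,
                 dimnames = list("F1", paste0("S", 1:4)))
    zz <- logZTransform(MetabolomeSet(mz), cmp)
    byHand <- scale(log10(c(5, 10, 100, 1000)))[, 1]
    expect_equal(unname(zscores(zz)[1, ]), byHand, tolerance = 1e-12)

    expect_error(logZTransform(MetabolomeSet(mz[, 1:2, drop = FALSE]),
                               NULL), "fewer than 3")
})

test_that("z-score rows have mean 0 / sd 1 and absorb positive scaling", {
    sim <- simulateMetabolome(simConfig(nPrimary = 25, nLipid = 0,
                                        nUnknown = 0, nReps = 4,
                                        tissues = "liver", zeroRate = 0),
                              seed = 3)
    cmps <- buildComparisons(sim$meta)
    z <- zscores(logZTransform(sim$set, cmps[[1]]))
    expect_lt(max(abs(rowMeans(z))), 1e-9)
    expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-9)

    ## multiplying one feature by a positive constant leaves z unchanged
    m <- peaks(sim$set)
    m[3, ] <- m[3, ] * 42
    z2 <- zscores(logZTransform(
        attachSampleMeta(MetabolomeSet(m), sim$meta), cmps[[1]]))
    expect_equal(z2, z, tolerance = 1e-9)
})

test_that("category mapping uses subclass, then superclass, then fallback", {
    ann <- data.frame(
        feature_id = c("glc", "amp", "mys"),
        subclass = c("Monosaccharides", NA, "foo"),
        superclass = c(NA, "Nucleosides, nucleotides, and analogues",
                       "bar"))
    expect_warning(cats <- categorizeFeatures(ann), "Miscellaneous")
    expect_equal(unname(cats),
                 c("Carbohydrates/CCM", "Nucleotides",
                   "Miscellaneous/secondary"))
    expect_error(categorizeFeatures(ann, mapping = c(foo = "NotACat")),
                 "malformed mapping")
})

test_that("condition-factor formulas evaluate exactly as defined", {
    expect_equal(fishCondition(1, 1, 1, 1)$k_final, 100)
    expect_equal(fishCondition(10, 8, 3, 3)$delta_wt_pct, -25)
    expect_equal(fishCondition(2, 2, 2, 2)$k_final, 25)
    ## K is homogeneous: K(c m, c^(1/3) x) = K(m, x)
    c0 <- 3.7
    expect_equal(fishCondition(c0 * 2, c0 * 2, c0^(1/3) * 2,
                               c0^(1/3) * 2)$k_final,
                 fishCondition(2, 2, 2, 2)$k_final)
    ## denominators are the final measurements by default
    fc <- fishCondition(10, 8, 2, 2)
    expect_equal(fc$delta_k_pct, (fc$k_final - fc$k_initial) /
                                  fc$k_final * 100)
    expect_equal(fishCondition(10, 8, 2, 2,
                               denominator = "initial")$delta_wt_pct,
                 -20)
    expect_error(fishCondition(-1, 1, 1, 1), "positive")
})

test_that("normality router sends normal data to ANOVA and heavy tails to
           Kruskal-Wallis", {
    set.seed(42)
    gNorm <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30))
    r1 <- groupCompareRouter(gNorm)
    expect_equal(r1$route, "anova_tukey")
    expect_true(all(r1$pairwise$stars == "ns"))
    expect_gt(r1$omnibus_p, 0.05)

    set.seed(7)
    gHeavy <- list(a = rcauchy(50), b = rcauchy(50), c = rcauchy(50))
    r2 <- groupCompareRouter(gHeavy)
    expect_equal(r2$route, "kruskal_dunn")

    ## identical groups: every pairwise comparison is ns
    g0 <- list(a = c(1, 2, 3, 4, 5, 6, 7, 8),
               b = c(1, 2, 3, 4, 5, 6, 7, 8),
               c = c(1, 2, 3, 4, 5, 6, 7, 8))
    r3 <- groupCompareRouter(g0)
    expect_true(all(r3$pairwise$stars == "ns"))
    expect_error(groupCompareRouter(list(a = 1:2, b = 1:3)), "at least 3")
})

test_that("the D'Agostino-Pearson implementation agrees with an external
           oracle on reference data", {
    ## scipy.stats.normaltest oracle, frozen:
    ## x = 0.1 + (1:20 %% 7) gives K2 = 2.828790388709766,
    ## p = 0.24307258066992246  (computed independently once)
    x <- 0.1 + (1:20 %% 7)
    r <- dagostinoTest(x)
    expect_equal(unname(r$statistic), 2.828790388709766, tolerance = 1e-9)
    expect_equal(r$p.value, 0.24307258066992246, tolerance = 1e-9)
})

test_that("star coding follows the printed thresholds", {
    expect_equal(starCode(c(0.2, 0.05, 0.01, 0.001, 0.0001, 1e-6)),
                 c("ns", "*", "**", "***", "****", "****"))
})
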