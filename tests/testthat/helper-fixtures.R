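# Shared fixtures: small data builders and independent oracles.

# Write a small peak-table CSV and return its path.
writeToyPeakCsv <- function(lines, ext = ".csv") {
    f <- tempfile(fileext = ext)
    writeLines(lines, f)
    f
}

# Full factorial metadata data.frame without touching the readers.
makeFullMeta <- function(nReps = 6,
                         populations = populationLevels(),
                         tissues = tissueLevels(),
                         states = feedingStateLevels()) {
    g <- expand.grid(replicate = seq_len(nReps), feeding_state = states,
                     tissue = tissues, population = populations,
                     stringsAsFactors = FALSE)
    g$sample_id <- with(g, paste(population, tissue, feeding_state,
                                 g$replicate, sep = "."))
    g[, c("sample_id", "population", "tissue", "feeding_state",
          "replicate")]
}

# Unit vector orthogonal to the column span of `to` (QR projection, so
# the columns of `to` need not be mutually orthogonal).
orthogonalTo <- function(v, to) {
    Q <- qr.Q(qr(to))
    u <- v - Q %*% crossprod(Q, v)
    as.numeric(u / sqrt(sum(u^2)))
}

# Independent posterior-mode oracle for the Cauchy-prior logistic model:
# iteratively refined 2-D grid search of the exact log-posterior on the
# standardized-covariate scale, back-transformed to the original scale.
gridPosteriorMode <- function(x, y, scales = c(10, 2.5)) {
    sdx <- stats::sd(x)
    xs <- (x - mean(x)) / (2 * sdx)
    logpost <- function(a, b) {
        eta <- a + b * xs
        sum(y * eta - log1p(exp(eta))) +
            stats::dt(a / scales[1], 1, log = TRUE) - log(scales[1]) +
            stats::dt(b / scales[2], 1, log = TRUE) - log(scales[2])
    }
    ctr <- c(0, 0)
    width <- 20
    for (it in 1:9) {
        as <- seq(ctr[1] - width, ctr[1] + width, length.out = 41)
        bs <- seq(ctr[2] - width, ctr[2] + width, length.out = 41)
        g <- outer(as, bs, Vectorize(logpost))
        i <- which(g == max(g), arr.ind = TRUE)[1, ]
        ctr <- c(as[i[1]], bs[i[2]])
        width <- width / 8
    }
    c(intercept = ctr[1] - ctr[2] * mean(x) / (2 * sdx),
      slope = ctr[2] / (2 * sdx))
}

# Simulate one balanced two-class z-scored matrix (samples x features)
# with an optional mean shift on the first `nShift` features.
makeTwoClassMatrix <- function(nPerClass = 6, nFeatures = 20, shift = 0,
                               nShift = nFeatures, seed = 1) {
    set.seed(seed)
    y <- rep(c(1, -1), each = nPerClass)
    X <- matrix(rnorm(2 * nPerClass * nFeatures), 2 * nPerClass, nFeatures)
    if (shift != 0 && nShift > 0)
        X[y > 0, seq_len(nShift)] <- X[y > 0, seq_len(nShift)] + shift
    X <- scale(X)
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
    list(X = X, y = y)
}
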