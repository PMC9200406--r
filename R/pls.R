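## One-component PLS classification with cross-validated Q2/DQ2 and a
## permutation null. The internals run inside leave-one-out and
## permutation loops, so they stay plain-matrix and allocation-light.

.pls1Core <- function(X, y) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("all-zero X; PLS weight undefined")
    w <- w / nw
    t <- as.numeric(X %*% w)
    mt <- mean(t); my <- mean(y)
    tc <- t - mt
    sst <- sum(tc * tc)
    b <- if (sst == 0) 0 else sum(tc * (y - my)) / sst
    a <- my - b * mt
    list(w = as.numeric(w), b = b, intercept = a)
}

#' Fit a one-component PLS1 classifier
#'
#' Single latent component: weight \eqn{w \propto X^T y} (unit norm), score
#' \eqn{t = Xw}, then least-squares regression of \eqn{y} on \eqn{t} with
#' intercept. Predictions are \eqn{\hat y = a + b\,(x \cdot w)}.
#'
#' @param X numeric matrix, samples x features.
#' @param y numeric +1/-1 labels, both classes present.
#' @return List with \code{w} (unit weight vector), \code{b} (regression
#'   coefficient on the score), \code{intercept}, and \code{fitted}.
#' @export
pls1Fit <- function(X, y) {
    X <- as.matrix(X)
    y <- as.numeric(y)
    if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
    if (length(unique(sign(y))) < 2) stop("response is single-class")
    fit <- .pls1Core(X, y)
    fit$fitted <- as.numeric(fit$intercept + fit$b * (X %*% fit$w))
    fit
}

#' Predict from a PLS1 fit
#' @param fit result of [pls1Fit()].
#' @param newX matrix or vector of new samples.
#' @return numeric predictions.
#' @export
pls1Predict <- function(fit, newX) {
    if (is.null(dim(newX))) newX <- matrix(newX, nrow = 1)
    as.numeric(fit$intercept + fit$b * (newX %*% fit$w))
}

#' Cross-validated Q2 and discriminant (truncated) DQ2
#'
#' \deqn{Q^2 = 1 - \sum_k (y_k - \hat y_k)^2 / \sum_k (y_k - \bar y)^2.}
#' DQ2 is identical except each prediction is first clamped to
#' \eqn{[-1, 1]}: a correct prediction that overshoots its class label is
#' not penalized. Consequently DQ2 >= Q2 always, and both are <= 1.
#'
#' @param labels numeric +1/-1 class labels.
#' @param cvPredictions out-of-sample predictions, same length.
#' @return List with \code{q2} and \code{dq2}.
#' @export
#' @examples
#' dq2Score(c(-1, 1), c(-2, 2))   # q2 = 0, dq2 = 1
dq2Score <- function(labels, cvPredictions) {
    y <- as.numeric(labels)
    yhat <- as.numeric(cvPredictions)
    if (length(y) != length(yhat)) stop("length mismatch")
    if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1")
    tss <- sum((y - mean(y))^2)
    if (tss == 0) stop("all labels identical; Q2 undefined")
    q2 <- 1 - sum((y - yhat)^2) / tss
    ytrunc <- pmax(pmin(yhat, 1), -1)
    dq2 <- 1 - sum((y - ytrunc)^2) / tss
    list(q2 = q2, dq2 = dq2)
}

## Lean LOO core shared by cvPredict and the permutation loop: the O-PLS
## deflation is done in place, component by component, so no score/loading
## matrices are assembled inside folds.
.cvLoo <- function(X, y, nOrth) {
    n <- nrow(X)
    pred <- numeric(n)
    for (k in seq_len(n)) {
        ytr <- y[-k]
        if (!any(ytr > 0) || !any(ytr < 0))
            stop("training fold became single-class")
        Xtr <- X[-k, , drop = FALSE]
        xn <- X[k, ]
        j <- 0L
        while (j < nOrth) {
            comp <- .oplsComponent(Xtr, ytr)
            if (is.null(comp)) break
            Xtr <- Xtr - tcrossprod(comp$to, comp$po)
            xn <- xn - sum(xn * comp$wo) * comp$po
            j <- j + 1L
        }
        f <- .pls1Core(Xtr, ytr)
        pred[k] <- f$intercept + f$b * sum(xn * f$w)
    }
    pred
}

#' Out-of-sample predictions for the O-PLS + PLS1 pipeline
#'
#' Leave-one-out cross-validation: for every held-out sample the O-PLS
#' filter AND the PLS1 classifier are refit on the remaining samples, and
#' the held-out sample is projected through the training model (orthogonal
#' components subtracted with training weights, then scored). Refitting
#' the filter inside the fold avoids information leakage from the held-out
#' label.
#'
#' @param X numeric matrix, samples x features (z-scored upstream).
#' @param y numeric +1/-1 labels, >= 2 samples per class.
#' @param nOrth orthogonal components removed inside each fold (default 1).
#' @return Numeric vector of leave-one-out predictions.
#' @export
cvPredict <- function(X, y, nOrth = 1L) {
    X <- as.matrix(X)
    y <- as.numeric(y)
    if (min(table(sign(y))) < 2) stop("need >= 2 samples per class")
    .cvLoo(X, y, as.integer(nOrth))
}

#' Permutation significance of the cross-validated DQ2
#'
#' Computes the observed DQ2 by leave-one-out cross-validation of the full
#' O-PLS + PLS1 pipeline, then rebuilds the null by shuffling the class
#' labels \code{nPerm} times and recomputing DQ2 each time (the filter and
#' classifier are refit from scratch per permutation). A normal
#' distribution is fitted to the permuted DQ2 values by sample mean and SD;
#' significance is the two-tailed survival function
#' \eqn{p = 2\,\Phi(-|z|)} of \eqn{z = (DQ2_{obs} - \mu_{perm})/\sigma_{perm}},
#' clamped to [0, 1]. If the permutation SD is zero the result is
#' degenerate and p = 1 is reported with a warning.
#'
#' @param X numeric matrix, samples x features.
#' @param y numeric +1/-1 labels.
#' @param nPerm number of label permutations (>= 100; default 1000).
#' @param seed integer RNG seed, recorded in the result.
#' @param nOrth orthogonal components (default 1).
#' @return A [Dq2Result-class].
#' @export
permutationSignificance <- function(X, y, nPerm = 1000L, seed = 1L,
                                    nOrth = 1L) {
    X <- as.matrix(X)
    y <- as.numeric(y)
    nPerm <- as.integer(nPerm)
    if (nPerm < 100) stop("nPerm must be >= 100")
    nOrth <- as.integer(nOrth)
    pred <- cvPredict(X, y, nOrth)
    obs <- dq2Score(y, pred)
    permDq2 <- numeric(nPerm)
    old <- .saveSeed()
    on.exit(.restoreSeed(old))
    set.seed(as.integer(seed))
    for (i in seq_len(nPerm)) {
        yp <- sample(y)
        permDq2[i] <- dq2Score(yp, .cvLoo(X, yp, nOrth))$dq2
    }
    mu <- mean(permDq2)
    sdv <- stats::sd(permDq2)
    if (sdv == 0) {
        warning("degenerate permutation null (SD = 0); p set to 1")
        z <- 0
        p <- 1
    } else {
        z <- (obs$dq2 - mu) / sdv
        p <- min(1, max(0, 2 * stats::pnorm(-abs(z))))
    }
    methods::new("Dq2Result", q2 = obs$q2, dq2 = obs$dq2,
                 cvPredictions = pred, labels = y, permDq2 = permDq2,
                 permMean = mu, permSd = sdv, z = z, pValue = p,
                 nPerm = nPerm, seed = as.integer(seed))
}

.saveSeed <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.restoreSeed <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}
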