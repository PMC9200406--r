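#' Bayesian logistic regression with Cauchy priors
#'
#' Fits \eqn{P(y = 1) = \mathrm{logit}^{-1}(a + b x)} by posterior mode
#' under independent Cauchy priors: scale 2.5 on the slope of the
#' standardized covariate and scale 10 on the intercept — the
#' weakly-informative default under which no typical change in input
#' shifts the response probability from 0.01 to 0.50 or from 0.50 to 0.99.
#' The mode is found by EM-augmented iteratively reweighted least squares,
#' treating the Cauchy (t with 1 df) prior as a scale mixture of normals;
#' the slope therefore stays finite even under complete separation, where
#' the maximum-likelihood estimate diverges.
#'
#' The covariate is centered and rescaled to SD 0.5 internally before
#' fitting (coefficients are reported back on the original scale), so the
#' slope prior applies per two standard deviations of the input. Standard
#' errors come from the curvature of the penalized objective at the mode
#' (observed information plus the EM normal approximation of the prior);
#' p-values are two-sided Wald tests, matching the summary behavior of
#' classical weakly-informative GLM fits rather than a posterior tail
#' probability.
#'
#' @param x numeric covariate, one value per sample; must vary.
#' @param y 0/1 (or logical) class labels, both classes present.
#' @param priorScaleSlope Cauchy scale for the slope on the standardized
#'   covariate (default 2.5).
#' @param priorScaleIntercept Cauchy scale for the intercept (default 10).
#' @param standardize center and rescale the covariate internally
#'   (default TRUE).
#' @param maxIter,tol IRLS-EM iteration cap (100) and relative change
#'   tolerance of the penalized deviance (1e-8).
#' @return A list: \code{intercept}, \code{slope}, \code{slope_se},
#'   \code{z_stat}, \code{p_value}, \code{converged}, \code{n_iter},
#'   \code{separation_detected}, and the prior scales used.
#' @export
#' @examples
#' ## complete separation: the MLE diverges, the posterior mode does not
#' bayesLogisticFit(c(-1, -1, -1, 1, 1, 1), c(0, 0, 0, 1, 1, 1))$slope
bayesLogisticFit <- function(x, y, priorScaleSlope = 2.5,
                             priorScaleIntercept = 10,
                             standardize = TRUE, maxIter = 100L,
                             tol = 1e-8) {
    x <- as.numeric(x)
    y <- as.numeric(y)
    if (any(!y %in% c(0, 1))) stop("y must be 0/1")
    if (length(unique(y)) < 2) stop("both classes must be present")
    sdx <- stats::sd(x)
    if (!is.finite(sdx) || sdx == 0) stop("x is constant")
    if (standardize) {
        cx <- mean(x)
        sc <- 2 * sdx
        xs <- (x - cx) / sc
    } else {
        cx <- 0; sc <- 1; xs <- x
    }
    X <- cbind(1, xs)
    s <- c(priorScaleIntercept, priorScaleSlope)

    ## separation screen: does unpenalized IRLS run away?
    mle <- suppressWarnings(
        stats::glm.fit(X, y, family = stats::binomial()))
    sep <- !mle$converged || abs(mle$coefficients[2]) > 10

    beta <- c(stats::qlogis(mean(y)), 0)
    objective <- function(b) {
        eta <- as.numeric(X %*% b)
        sum(y * eta - log1p(exp(eta))) +
            sum(stats::dt(b / s, df = 1, log = TRUE) - log(s))
    }
    obj <- objective(beta)
    converged <- FALSE
    iter <- 0L
    lambda <- 2 / (s^2 + beta^2)
    while (iter < maxIter) {
        iter <- iter + 1L
        eta <- as.numeric(X %*% beta)
        mu <- stats::plogis(eta)
        mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
        w <- mu * (1 - mu)
        zw <- eta + (y - mu) / w
        ## E-step for the t(1) prior: E[1/sigma_j^2 | beta_j]
        lambda <- 2 / (s^2 + beta^2)
        A <- crossprod(X, X * w) + diag(lambda)
        beta <- as.numeric(solve(A, crossprod(X, w * zw)))
        objNew <- objective(beta)
        if (abs(objNew - obj) < tol * (abs(obj) + tol)) {
            obj <- objNew
            converged <- TRUE
            break
        }
        obj <- objNew
    }
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    w <- w * (1 - w)
    H <- crossprod(X, X * w) + diag(2 / (s^2 + beta^2))
    se <- sqrt(diag(solve(H)))
    slope <- beta[2] / sc
    slopeSe <- se[2] / sc
    zStat <- beta[2] / se[2]
    list(intercept = beta[1] - beta[2] * cx / sc,
         slope = slope, slope_se = slopeSe, z_stat = zStat,
         p_value = min(1, max(.Machine$double.xmin,
                              2 * stats::pnorm(-abs(zStat)))),
         converged = converged, n_iter = iter,
         prior_scale_slope = priorScaleSlope,
         prior_scale_intercept = priorScaleIntercept,
         separation_detected = isTRUE(sep))
}

## shared result-row builder
.featureRow <- function(featureId, comparisonId, fit, alpha) {
    data.frame(feature_id = featureId, comparison_id = comparisonId,
               slope = fit$slope, slope_se = fit$slope_se,
               z_stat = fit$z_stat, p_value = fit$p_value,
               direction = if (fit$slope >= 0) "up" else "down",
               separation = fit$separation_detected,
               significant = fit$p_value <= alpha,
               stringsAsFactors = FALSE)
}

.emptyFeatureTable <- function() {
    data.frame(feature_id = character(0), comparison_id = character(0),
               slope = numeric(0), slope_se = numeric(0),
               z_stat = numeric(0), p_value = numeric(0),
               direction = character(0), separation = logical(0),
               significant = logical(0), stringsAsFactors = FALSE)
}

#' Per-feature Bayesian logistic tests for one comparison
#'
#' Applies the O-PLS filter once to the full comparison matrix (samples x
#' features, labels +1/-1 from the comparison design), then fits one
#' single-covariate Bayesian logistic regression per feature, using the
#' feature's filtered column as covariate and group membership as response.
#' By design no multiple-testing correction is applied: the conservative
#' Cauchy prior already shrinks implausible effects, so marginal p-values
#' are reported as-is. Benjamini-Hochberg adjustment is available behind
#' \code{bhFdr = TRUE} for sensitivity analyses.
#'
#' @param z a [ZScoreMatrix-class] computed for this comparison (features x
#'   samples, columns in \code{comparisonSamples(comparison)} order).
#' @param comparison the [ComparisonDesign-class].
#' @param nOrth O-PLS components removed (default 1).
#' @param alpha significance threshold for the \code{significant} flag.
#' @param bhFdr apply Benjamini-Hochberg to the p-values (default FALSE).
#' @param priorScaleSlope,priorScaleIntercept prior scales passed through
#'   to [bayesLogisticFit()].
#' @return \code{data.frame}, one row per feature: slope, SE, z, p,
#'   direction (\code{up} = higher in the +1 group), separation flag,
#'   significance. Per-feature failures are recorded in the
#'   \code{"failures"} attribute, never fatal.
#' @export
runFeatureTests <- function(z, comparison, nOrth = 1L, alpha = 0.05,
                            bhFdr = FALSE, priorScaleSlope = 2.5,
                            priorScaleIntercept = 10) {
    stopifnot(methods::is(z, "ZScoreMatrix"),
              methods::is(comparison, "ComparisonDesign"))
    ids <- comparisonSamples(comparison)
    zm <- zscores(z)
    if (!all(ids %in% colnames(zm)))
        stop("comparison samples missing from z-matrix")
    X <- t(zm[, ids, drop = FALSE])
    if (ncol(X) == 0)
        return(structure(.emptyFeatureTable(), failures = character(0)))
    y <- comparisonLabels(comparison)
    Xf <- .oplsCore(X, as.numeric(y), as.integer(nOrth))$X
    y01 <- as.numeric(y > 0)
    failures <- character()
    rows <- vector("list", ncol(Xf))
    for (j in seq_len(ncol(Xf))) {
        fid <- colnames(X)[j]
        fit <- tryCatch(
            bayesLogisticFit(Xf[, j], y01,
                             priorScaleSlope = priorScaleSlope,
                             priorScaleIntercept = priorScaleIntercept),
            error = function(e) {
                failures[[length(failures) + 1]] <<-
                    paste0(fid, ": ", conditionMessage(e))
                NULL
            })
        if (!is.null(fit))
            rows[[j]] <- .featureRow(fid, comparison@comparisonId, fit,
                                     alpha)
    }
    res <- do.call(rbind, rows)
    if (is.null(res)) res <- .emptyFeatureTable()
    if (bhFdr && nrow(res)) {
        res$p_value <- stats::p.adjust(res$p_value, "BH")
        res$significant <- res$p_value <= alpha
    }
    rownames(res) <- NULL
    structure(res, failures = failures)
}

#' Class-level tests: aggregate members, then test the aggregate
#'
#' For lipid categories, classes, and saturation groups the covariate is
#' the mean O-PLS-filtered z-score of the class's member features per
#' sample (aggregation rule: arithmetic mean; \code{aggregate = "sum"} and
#' \code{"pc1"} are available as sensitivity alternatives). The same
#' Bayesian logistic machinery as the per-feature tests is then applied to
#' the aggregate. Classes with fewer than two member features present are
#' skipped (recorded in the \code{"skipped"} attribute).
#'
#' @param z a [ZScoreMatrix-class] for the comparison.
#' @param comparison the [ComparisonDesign-class].
#' @param classes named character vector: feature id -> class label.
#' @param nOrth,alpha,bhFdr as in [runFeatureTests()].
#' @param aggregate \code{"mean"} (default), \code{"sum"} or \code{"pc1"}.
#' @return \code{data.frame}, one row per class (class name in
#'   \code{feature_id}).
#' @export
classLevelTests <- function(z, comparison, classes, nOrth = 1L,
                            alpha = 0.05, bhFdr = FALSE,
                            aggregate = c("mean", "sum", "pc1")) {
    aggregate <- match.arg(aggregate)
    stopifnot(methods::is(z, "ZScoreMatrix"))
    ids <- comparisonSamples(comparison)
    zm <- zscores(z)
    X <- t(zm[, ids, drop = FALSE])
    y <- comparisonLabels(comparison)
    Xf <- .oplsCore(X, as.numeric(y), as.integer(nOrth))$X
    colnames(Xf) <- colnames(X)
    y01 <- as.numeric(y > 0)
    skipped <- character()
    rows <- list()
    for (cl in unique(classes[!is.na(classes)])) {
        members <- intersect(names(classes)[classes == cl], colnames(Xf))
        if (length(members) < 2) {
            skipped <- c(skipped, cl)
            next
        }
        sub <- Xf[, members, drop = FALSE]
        cov <- switch(aggregate,
            mean = rowMeans(sub),
            sum = rowSums(sub),
            pc1 = {
                sv <- svd(scale(sub, scale = FALSE), nu = 1, nv = 0)
                as.numeric(sv$u[, 1] * sv$d[1])
            })
        fit <- tryCatch(bayesLogisticFit(cov, y01),
                        error = function(e) NULL)
        if (!is.null(fit))
            rows[[cl]] <- .featureRow(cl, comparison@comparisonId, fit,
                                      alpha)
    }
    res <- do.call(rbind, rows)
    if (is.null(res)) res <- .emptyFeatureTable()
    if (bhFdr && nrow(res)) {
        res$p_value <- stats::p.adjust(res$p_value, "BH")
        res$significant <- res$p_value <= alpha
    }
    rownames(res) <- NULL
    structure(res, skipped = skipped)
}

#' Saturation class from double-bond count
#'
#' Maps free fatty acid double-bond counts to saturation classes:
#' 0 -> SFA (saturated), 1 -> MUFA (monounsaturated), >= 2 -> PUFA
#' (polyunsaturated).
#'
#' @param doubleBonds integer vector of double-bond counts.
#' @return character vector of classes.
#' @export
saturationClass <- function(doubleBonds) {
    db <- as.integer(doubleBonds)
    if (any(is.na(db) | db < 0)) stop("double-bond counts must be >= 0")
    ifelse(db == 0, "SFA", ifelse(db == 1, "MUFA", "PUFA"))
}
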