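#' Fish body-condition metrics
#'
#' Computes percent weight change, Fulton's condition factor (K) before and
#' after a feeding regimen, and percent K change:
#' \deqn{\Delta Wt\% = (m_f - m_i)/m_f \times 100,\quad
#'       K = (m/x^3) \times 100,\quad
#'       \Delta K\% = (K_f - K_i)/K_f \times 100,}
#' with mass \eqn{m} in grams and standard length \eqn{x} in centimeters.
#' Note the percent-change denominators are the FINAL mass and K values;
#' this unconventional convention is kept deliberately (switch with
#' \code{denominator = "initial"} for the textbook definition).
#'
#' @param mass_initial_g,mass_final_g masses in grams, > 0.
#' @param length_initial_cm,length_final_cm standard lengths in cm, > 0.
#' @param denominator \code{"final"} (default) or \code{"initial"}: which
#'   measurement divides the percent changes.
#' @return A list with \code{delta_wt_pct}, \code{k_initial},
#'   \code{k_final}, \code{delta_k_pct} and the inputs.
#' @export
#' @examples
#' fishCondition(1, 1, 1, 1)$k_final          # 100
#' fishCondition(10, 8, 3, 3)$delta_wt_pct    # -25
fishCondition <- function(mass_initial_g, mass_final_g,
                          length_initial_cm, length_final_cm,
                          denominator = c("final", "initial")) {
    denominator <- match.arg(denominator)
    vals <- c(mass_initial_g, mass_final_g, length_initial_cm,
              length_final_cm)
    if (any(!is.finite(vals)) || any(vals <= 0))
        stop("all masses and lengths must be positive")
    kFactor <- function(m, x) (m / x^3) * 100
    ki <- kFactor(mass_initial_g, length_initial_cm)
    kf <- kFactor(mass_final_g, length_final_cm)
    pct <- function(final, initial) {
        den <- if (denominator == "final") final else initial
        (final - initial) / den * 100
    }
    list(mass_initial_g = mass_initial_g, mass_final_g = mass_final_g,
         length_initial_cm = length_initial_cm,
         length_final_cm = length_final_cm,
         delta_wt_pct = pct(mass_final_g, mass_initial_g),
         k_initial = ki, k_final = kf,
         delta_k_pct = pct(kf, ki))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' The K-squared statistic combines transformed sample skewness and
#' kurtosis (D'Agostino, Belanger & D'Agostino Jr., 1990) and is referred
#' to a chi-squared distribution with 2 degrees of freedom. Requires
#' n >= 8 for the kurtosis transform to be defined.
#'
#' @param x numeric vector, n >= 8.
#' @return \code{htest}-like list with \code{statistic} and \code{p.value}.
#' @export
dagostinoTest <- function(x) {
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
    m <- mean(x)
    m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
    g1 <- m3 / m2^1.5
    g2 <- m4 / m2^2 - 3
    ## skewness transform (D'Agostino 1970)
    Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
    b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
        ((n - 2) * (n + 5) * (n + 7) * (n + 9))
    W2 <- -1 + sqrt(2 * (b2 - 1))
    d <- 1 / sqrt(log(sqrt(W2)))
    a <- sqrt(2 / (W2 - 1))
    Zs <- d * log(Y / a + sqrt((Y / a)^2 + 1))
    ## kurtosis transform (Anscombe & Glynn 1983)
    Eb2 <- 3 * (n - 1) / (n + 1)
    Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
    xk <- (g2 + 3 - Eb2) / sqrt(Vb2)
    beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
        sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
    A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
    Zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
        sqrt(2 / (9 * A))
    K2 <- Zs^2 + Zk^2
    list(statistic = c(K2 = K2),
         p.value = stats::pchisq(K2, df = 2, lower.tail = FALSE),
         method = "D'Agostino-Pearson omnibus normality test")
}

#' Dunn's rank-based multiple comparisons
#'
#' Post-hoc pairwise z-tests on the pooled ranks following a
#' Kruskal-Wallis test, with the standard tie correction and Bonferroni
#' adjustment of the two-sided p-values across all pairs.
#'
#' @param values numeric vector of pooled observations.
#' @param groups factor/character of the same length.
#' @return \code{data.frame} with one row per pair: \code{group1},
#'   \code{group2}, \code{z}, \code{p_unadjusted}, \code{p_adjusted}.
#' @export
dunnTest <- function(values, groups) {
    groups <- as.factor(groups)
    N <- length(values)
    r <- rank(values)
    tie <- table(r)
    tieCorr <- sum(tie^3 - tie) / (12 * (N - 1))
    rbar <- tapply(r, groups, mean)
    n <- tapply(r, groups, length)
    lev <- levels(groups)
    pairs <- utils::combn(lev, 2, simplify = FALSE)
    res <- do.call(rbind, lapply(pairs, function(pr) {
        se <- sqrt((N * (N + 1) / 12 - tieCorr) *
                   (1 / n[pr[1]] + 1 / n[pr[2]]))
        z <- (rbar[pr[1]] - rbar[pr[2]]) / se
        data.frame(group1 = pr[1], group2 = pr[2], z = as.numeric(z),
                   p_unadjusted = 2 * stats::pnorm(-abs(as.numeric(z))),
                   stringsAsFactors = FALSE)
    }))
    res$p_adjusted <- pmin(1, res$p_unadjusted * nrow(res))
    rownames(res) <- NULL
    res
}

#' Star-code a p-value
#'
#' \code{ns} (p > 0.05), \code{*} (<= 0.05), \code{**} (<= 0.01),
#' \code{***} (<= 0.001), \code{****} (<= 0.0001).
#'
#' @param p numeric vector of p-values.
#' @return character vector of star codes.
#' @export
starCode <- function(p) {
    cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
        labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

#' Normality-routed group comparison
#'
#' Compares two or more groups the way aquaculture condition data are
#' usually analyzed: the pooled within-group residuals are screened with
#' four normality tests (D'Agostino-Pearson, Shapiro-Wilk,
#' Lilliefors-corrected Kolmogorov-Smirnov, Anderson-Darling) at
#' \code{alpha}; if at least three of the four pass, groups are compared by
#' one-way ANOVA with Tukey's HSD, otherwise by Kruskal-Wallis with Dunn's
#' post-hoc correction. Pairwise results carry star-coded significance.
#'
#' @param groups named list of numeric vectors, each of length >= 3
#'   (>= 8 for the D'Agostino-Pearson screen).
#' @param alpha significance level for both the normality screen and the
#'   star coding (default 0.05).
#' @return A list: \code{route} (\code{"anova_tukey"} or
#'   \code{"kruskal_dunn"}), \code{normality} (per-test p-values and
#'   pass/fail), \code{omnibus_p}, and \code{pairwise}
#'   (\code{data.frame} with adjusted p and stars).
#' @export
groupCompareRouter <- function(groups, alpha = 0.05) {
    if (is.null(names(groups)))
        names(groups) <- paste0("group", seq_along(groups))
    if (length(groups) < 2) stop("need at least two groups")
    if (any(vapply(groups, length, integer(1)) < 3))
        stop("each group needs at least 3 values")
    values <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                  levels = names(groups))
    resid <- values - stats::ave(values, fac)
    normP <- c(
        dagostino_pearson = dagostinoTest(resid)$p.value,
        shapiro_wilk = stats::shapiro.test(resid)$p.value,
        kolmogorov_smirnov = nortest::lillie.test(resid)$p.value,
        anderson_darling = nortest::ad.test(resid)$p.value)
    passed <- normP > alpha
    route <- if (sum(passed) >= 3) "anova_tukey" else "kruskal_dunn"
    if (route == "anova_tukey") {
        fit <- stats::aov(values ~ fac)
        omnibus <- summary(fit)[[1]][["Pr(>F)"]][1]
        tk <- stats::TukeyHSD(fit)$fac
        pw <- data.frame(
            group1 = sub("-.*", "", rownames(tk)),
            group2 = sub(".*-", "", rownames(tk)),
            estimate = tk[, "diff"], p_adjusted = tk[, "p adj"],
            stringsAsFactors = FALSE)
    } else {
        omnibus <- stats::kruskal.test(values, fac)$p.value
        dn <- dunnTest(values, fac)
        pw <- data.frame(group1 = dn$group1, group2 = dn$group2,
                         estimate = dn$z, p_adjusted = dn$p_adjusted,
                         stringsAsFactors = FALSE)
    }
    pw$stars <- starCode(pw$p_adjusted)
    rownames(pw) <- NULL
    list(route = route,
         normality = data.frame(test = names(normP), p = as.numeric(normP),
                                passed = as.logical(passed),
                                stringsAsFactors = FALSE),
         omnibus_p = omnibus, pairwise = pw, alpha = alpha)
}
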