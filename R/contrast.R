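#' ContrastSet: parallel-adaptation pseudo-samples
#'
#' Holds per-feature vectors \eqn{x = (P + T)/2 - S} built from
#' within-population z-scores of Pachon (P), Tinaja (T) and Surface (S)
#' samples for one tissue and one feeding-state pair, with the
#' feeding-state label of each pseudo-sample. Typically 12 pseudo-samples:
#' 6 per state.
#'
#' @slot values numeric matrix, features x pseudo-samples.
#' @slot labels numeric +1/-1 per pseudo-sample (+1 = the later, more
#'   fasted state of the pair).
#' @slot tissue character scalar.
#' @slot statePair character length-2, (earlier, later) state.
#' @export
setClass("ContrastSet",
    representation(values = "matrix", labels = "numeric",
                   tissue = "character", statePair = "character"))

setValidity("ContrastSet", function(object) {
    if (ncol(object@values) != length(object@labels))
        return("values/labels length mismatch")
    if (length(unique(sign(object@labels))) < 2)
        return("both feeding-state classes must be present")
    TRUE
})

setMethod("show", "ContrastSet", function(object) {
    cat("ContrastSet:", nrow(object@values), "features x",
        ncol(object@values), "pseudo-samples;", object@tissue, ";",
        paste(object@statePair, collapse = " vs "), "\n")
    invisible(NULL)
})

.popSamples <- function(meta, pop, tissue, statePair) {
    sel <- meta$population == pop & meta$tissue == tissue &
        meta$feeding_state %in% statePair
    meta[sel, , drop = FALSE]
}

#' Build the parallel-adaptation contrast x = (P + T)/2 - S
#'
#' For one tissue and one feeding-state pair, z-scores each population's
#' samples within that population (log10, half-minimum zero replacement,
#' across its typically 12 samples), pairs replicate k of Pachon with
#' replicate k of Tinaja and Surface by sorted replicate id within each
#' state, and forms \eqn{x_k = (P_k + T_k)/2 - S_k} per feature. The
#' resulting pseudo-samples keep their feeding-state labels (+1 for the
#' later, more-fasted state).
#'
#' Replicate counts per state must match across the three populations;
#' no imputation is attempted. Fish are not biologically paired, so the
#' pairing is an arbitrary but exchangeable bookkeeping device;
#' \code{pairing = "permute"} re-draws the Tinaja and Surface pairing at
#' random (given \code{seed}) as a stability diagnostic.
#'
#' @param x a [MetabolomeSet-class] or [MticNormalization-class] with
#'   population/tissue/feeding_state/replicate in \code{colData}.
#' @param tissue tissue to use.
#' @param statePair character length-2; order is normalized to canonical
#'   feeding-state order (earlier, later).
#' @param categorySubset optional category restriction.
#' @param pairing \code{"sorted"} (default) or \code{"permute"}.
#' @param seed RNG seed for \code{pairing = "permute"}.
#' @return A [ContrastSet-class].
#' @export
buildContrast <- function(x, tissue, statePair = c("Refed", "Fasted30"),
                          categorySubset = NULL,
                          pairing = c("sorted", "permute"), seed = 1L) {
    pairing <- match.arg(pairing)
    if (methods::is(x, "MticNormalization")) x <- normalizedSet(x)
    stopifnot(methods::is(x, "MetabolomeSet"))
    meta <- as.data.frame(SummarizedExperiment::colData(x))
    statePair <- .STATES[.STATES %in% statePair]
    if (length(statePair) != 2) stop("statePair must name two states")
    pops <- c(Pachon = "Pachon", Tinaja = "Tinaja", Surface = "Surface")
    sub <- lapply(pops, .popSamples, meta = meta, tissue = tissue,
                  statePair = statePair)
    counts <- vapply(sub, function(m)
        c(sum(m$feeding_state == statePair[1]),
          sum(m$feeding_state == statePair[2])), numeric(2))
    if (any(counts == 0)) stop("missing population/state cell in ", tissue)
    if (any(counts[1, ] != counts[1, 1]) ||
        any(counts[2, ] != counts[2, 1]))
        stop("unbalanced populations: replicate counts differ across ",
             "Pachon/Tinaja/Surface")
    ## per-population z-scores over that population's samples
    zmats <- lapply(pops, function(p) {
        m <- sub[[p]]
        pos <- m$sample_id[m$feeding_state == statePair[2]]
        neg <- m$sample_id[m$feeding_state == statePair[1]]
        cmp <- ComparisonDesign(paste(tissue, p, sep = "."), tissue,
                                pos, neg, "state_within_population")
        logZTransform(x, cmp, categorySubset = categorySubset)
    })
    ## order each population's columns by (state, replicate)
    ordered <- lapply(pops, function(p) {
        m <- sub[[p]]
        ids <- unlist(lapply(statePair, function(st) {
            mm <- m[m$feeding_state == st, , drop = FALSE]
            mm$sample_id[order(mm$replicate)]
        }))
        zscores(zmats[[p]])[, ids, drop = FALSE]
    })
    if (pairing == "permute") {
        old <- .saveSeed(); on.exit(.restoreSeed(old))
        set.seed(as.integer(seed))
        nPer <- counts[, 1]
        shuffle <- function(mat) {
            idx <- c(sample(seq_len(nPer[1])),
                     nPer[1] + sample(seq_len(nPer[2])))
            mat[, idx, drop = FALSE]
        }
        ordered$Tinaja <- shuffle(ordered$Tinaja)
        ordered$Surface <- shuffle(ordered$Surface)
    }
    feats <- Reduce(intersect, lapply(ordered, rownames))
    if (!length(feats)) stop("no features shared across populations")
    zP <- ordered$Pachon[feats, , drop = FALSE]
    zT <- ordered$Tinaja[feats, , drop = FALSE]
    zS <- ordered$Surface[feats, , drop = FALSE]
    vals <- (zP + zT) / 2 - zS
    labels <- rep(c(-1, 1), counts[, 1])
    colnames(vals) <- paste0(rep(statePair, counts[, 1]), ".rep",
                             unlist(lapply(counts[, 1], seq_len)))
    methods::new("ContrastSet", values = vals, labels = labels,
                 tissue = tissue, statePair = statePair)
}

#' Bayesian logistic tests on the parallel-adaptation contrast
#'
#' O-PLS-filters the pseudo-sample matrix against the feeding-state labels
#' and fits one single-covariate Bayesian logistic regression per feature
#' on the filtered \eqn{x = (P + T)/2 - S} values. \code{direction = "up"}
#' means the feature is increased in both cave populations in the
#' more-fasted state relative to surface.
#'
#' @param contrast a [ContrastSet-class].
#' @param nOrth O-PLS components (default 1).
#' @param alpha significance threshold (default 0.05).
#' @param priorScaleSlope,priorScaleIntercept prior scales for
#'   [bayesLogisticFit()].
#' @return \code{data.frame} with feature_id, comparison_id, tissue,
#'   state_pair, slope, SE, z, p, direction, separation, significance.
#' @export
contrastTest <- function(contrast, nOrth = 1L, alpha = 0.05,
                         priorScaleSlope = 2.5,
                         priorScaleIntercept = 10) {
    stopifnot(methods::is(contrast, "ContrastSet"))
    X <- t(contrast@values)
    y <- contrast@labels
    Xf <- .oplsCore(X, y, as.integer(nOrth))$X
    y01 <- as.numeric(y > 0)
    cid <- paste0(contrast@tissue, ".parallel.",
                  contrast@statePair[2], "-vs-", contrast@statePair[1])
    rows <- lapply(seq_len(ncol(Xf)), function(j) {
        fit <- tryCatch(
            bayesLogisticFit(Xf[, j], y01,
                             priorScaleSlope = priorScaleSlope,
                             priorScaleIntercept = priorScaleIntercept),
            error = function(e) NULL)
        if (is.null(fit)) return(NULL)
        .featureRow(colnames(X)[j], cid, fit, alpha)
    })
    res <- do.call(rbind, rows)
    res$tissue <- contrast@tissue
    res$state_pair <- paste(contrast@statePair, collapse = "/")
    rownames(res) <- NULL
    res
}

#' Top-k table of the most significant features
#'
#' Ranks test results by ascending p-value (ties broken by descending
#' |slope|, then by feature id) and keeps the \code{k} most significant
#' regardless of direction, per tissue when a \code{tissue} column is
#' present. A \code{neg_log10_p} column is attached for heatmap rendering.
#'
#' @param results \code{data.frame} from [contrastTest()] or
#'   [runFeatureTests()].
#' @param k rows to keep per tissue (default 20).
#' @return Ranked \code{data.frame}.
#' @export
topKTable <- function(results, k = 20L) {
    if (!nrow(results)) stop("results are empty")
    rankOne <- function(df) {
        ord <- order(df$p_value, -abs(df$slope), df$feature_id)
        out <- df[ord[seq_len(min(k, nrow(df)))], , drop = FALSE]
        out$rank <- seq_len(nrow(out))
        out
    }
    if ("tissue" %in% names(results)) {
        parts <- split(results, results$tissue)
        out <- do.call(rbind, lapply(parts, rankOne))
    } else {
        out <- rankOne(results)
    }
    out$neg_log10_p <- -log10(out$p_value)
    rownames(out) <- NULL
    out
}
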