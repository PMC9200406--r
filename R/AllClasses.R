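#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

## Canonical factor levels. The order within each vector also fixes which
## group of a pairwise comparison receives the +1 label: the LATER level is
## group_pos (Pachon > Tinaja > Surface; Fasted30 > Fasted4 > Refed), so the
## sign of every reported coefficient is reproducible.
.POPULATIONS <- c("Surface", "Tinaja", "Pachon")
.TISSUES <- c("liver", "muscle", "brain")
.STATES <- c("Refed", "Fasted4", "Fasted30")

#' Canonical factor levels
#'
#' Accessors for the fixed population, tissue and feeding-state level sets
#' used throughout the package. The ordering determines the +1/-1 label
#' assignment in pairwise comparisons: the later level of a pair is always
#' the positive class.
#'
#' @return A character vector of levels.
#' @export
#' @examples
#' populationLevels()
populationLevels <- function() .POPULATIONS

#' @rdname populationLevels
#' @export
tissueLevels <- function() .TISSUES

#' @rdname populationLevels
#' @export
feedingStateLevels <- function() .STATES

#' MetabolomeSet: a peak-height table with feature annotation
#'
#' A \linkS4class{SummarizedExperiment} holding a features x samples matrix
#' of non-negative instrument peak heights in the assay \code{"peaks"}.
#' Per-feature annotation lives in \code{rowData}: \code{identified}
#' (logical; whether the feature maps to a known compound) and
#' \code{category} (broad metabolite category, lipid class, or
#' \code{"unknown"}). Sample factors (population, tissue, feeding state,
#' replicate, optional biometrics) live in \code{colData}.
#'
#' Absent measurements are encoded as intensity 0; \code{NA} values are
#' rejected by the validity method so that missingness decisions are made
#' explicitly upstream.
#'
#' @export
setClass("MetabolomeSet", contains = "SummarizedExperiment")

.validMetabolomeSet <- function(object) {
    msg <- character()
    if (!"peaks" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'peaks' is required")
    else {
        x <- SummarizedExperiment::assay(object, "peaks")
        if (anyNA(x))
            msg <- c(msg, "NA intensities forbidden; encode absence as 0")
        else if (any(x < 0))
            msg <- c(msg, "negative intensity")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate feature id")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample id")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("identified", "category") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain 'identified' and 'category'")
    else if (!is.logical(rd$identified) || anyNA(rd$identified))
        msg <- c(msg, "'identified' must be logical without NA")
    if (length(msg)) msg else TRUE
}
setValidity("MetabolomeSet", .validMetabolomeSet)

#' Construct a MetabolomeSet
#'
#' @param peaks numeric matrix, features x samples, non-negative, no NA.
#'   Row and column names are the feature and sample ids.
#' @param identified logical per feature; defaults to all \code{TRUE}.
#' @param category character per feature; defaults to \code{"unknown"}.
#' @param sampleData optional \code{data.frame}/\code{DataFrame} of sample
#'   metadata (as returned by [readSampleMeta()]); matched to columns by
#'   \code{sample_id} and stored in \code{colData}.
#' @return A validated [MetabolomeSet-class] object.
#' @export
#' @examples
#' m <- matrix(c(1, 3, 0, 2, 4, 5), nrow = 3,
#'             dimnames = list(paste0("F", 1:3), c("S1", "S2")))
#' MetabolomeSet(m)
MetabolomeSet <- function(peaks, identified = NULL, category = NULL,
                          sampleData = NULL) {
    peaks <- as.matrix(peaks)
    storage.mode(peaks) <- "double"
    if (is.null(rownames(peaks)))
        rownames(peaks) <- paste0("F", seq_len(nrow(peaks)))
    if (is.null(colnames(peaks)))
        colnames(peaks) <- paste0("S", seq_len(ncol(peaks)))
    if (is.null(identified)) identified <- rep(TRUE, nrow(peaks))
    if (is.null(category)) category <- rep("unknown", nrow(peaks))
    rd <- S4Vectors::DataFrame(identified = as.logical(identified),
                               category = as.character(category),
                               row.names = rownames(peaks))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(peaks = peaks), rowData = rd)
    obj <- methods::new("MetabolomeSet", se)
    if (!is.null(sampleData))
        obj <- attachSampleMeta(obj, sampleData)
    methods::validObject(obj)
    obj
}

#' @describeIn MetabolomeSet extract the peak-height matrix.
#' @param object,x a \code{MetabolomeSet}.
#' @export
peaks <- function(x) SummarizedExperiment::assay(x, "peaks")

#' @describeIn MetabolomeSet logical identification flags per feature.
#' @export
identifiedFeatures <- function(x) SummarizedExperiment::rowData(x)$identified

#' @describeIn MetabolomeSet category labels per feature.
#' @export
featureCategories <- function(x) SummarizedExperiment::rowData(x)$category

setMethod("show", "MetabolomeSet", function(object) {
    cat("MetabolomeSet:", nrow(object), "features x", ncol(object),
        "samples\n")
    cat("  identified:", sum(identifiedFeatures(object)), "| categories:",
        length(unique(featureCategories(object))), "\n")
    if (ncol(SummarizedExperiment::colData(object)) > 0)
        cat("  colData:",
            paste(colnames(SummarizedExperiment::colData(object)),
                  collapse = ", "), "\n")
    invisible(NULL)
})

#' ComparisonDesign: a binary contrast within one tissue
#'
#' Two disjoint groups of sample ids labelled +1 (\code{groupPos}) and -1
#' (\code{groupNeg}), with an axis recording whether the contrast compares
#' populations within a feeding state, feeding states within a population,
#' or the parallel-adaptation pseudo-samples.
#'
#' @slot comparisonId character scalar, unique identifier.
#' @slot tissue character scalar.
#' @slot groupPos,groupNeg character vectors of sample ids.
#' @slot axis one of \code{"population_within_state"},
#'   \code{"state_within_population"}, \code{"parallel_contrast"}.
#' @export
setClass("ComparisonDesign",
    representation(comparisonId = "character", tissue = "character",
                   groupPos = "character", groupNeg = "character",
                   axis = "character"))

setValidity("ComparisonDesign", function(object) {
    msg <- character()
    if (length(intersect(object@groupPos, object@groupNeg)))
        msg <- c(msg, "groupPos and groupNeg overlap")
    if (!length(object@groupPos) || !length(object@groupNeg))
        msg <- c(msg, "both groups must be non-empty")
    ax <- c("population_within_state", "state_within_population",
            "parallel_contrast")
    if (!object@axis %in% ax)
        msg <- c(msg, "unknown axis")
    if (length(msg)) msg else TRUE
})

#' @rdname ComparisonDesign-class
#' @param comparisonId,tissue,groupPos,groupNeg,axis see slots.
#' @export
ComparisonDesign <- function(comparisonId, tissue, groupPos, groupNeg,
                             axis = "population_within_state") {
    methods::new("ComparisonDesign", comparisonId = comparisonId,
                 tissue = tissue, groupPos = as.character(groupPos),
                 groupNeg = as.character(groupNeg), axis = axis)
}

setMethod("show", "ComparisonDesign", function(object) {
    cat("ComparisonDesign", object@comparisonId, "[", object@axis, "]\n")
    cat("  tissue:", object@tissue, "|", length(object@groupPos), "vs",
        length(object@groupNeg), "samples\n")
    invisible(NULL)
})

#' @describeIn ComparisonDesign-class all sample ids, positive group first.
#' @param object a \code{ComparisonDesign}.
#' @export
comparisonSamples <- function(object)
    c(object@groupPos, object@groupNeg)

#' @describeIn ComparisonDesign-class +1/-1 labels aligned with
#'   \code{comparisonSamples()}.
#' @export
comparisonLabels <- function(object) {
    y <- c(rep(1, length(object@groupPos)), rep(-1, length(object@groupNeg)))
    names(y) <- comparisonSamples(object)
    y
}

#' MticNormalization: result of identified-peak total ion current scaling
#'
#' @slot normalized the scaled [MetabolomeSet-class].
#' @slot mticPerSample named numeric, the identified-peak sum per sample
#'   before scaling.
#' @slot mticReference named numeric, the group-average mTIC each sample was
#'   scaled to (one value per normalization group).
#' @slot groupOfSample named character mapping sample id to its group.
#' @slot grouping \code{"population_x_tissue"} or \code{"global"}.
#' @export
setClass("MticNormalization",
    representation(normalized = "MetabolomeSet", mticPerSample = "numeric",
                   mticReference = "numeric", groupOfSample = "character",
                   grouping = "character"))

setMethod("show", "MticNormalization", function(object) {
    cat("MticNormalization (", object@grouping, "): ",
        ncol(object@normalized), " samples, ",
        length(object@mticReference), " reference group(s)\n", sep = "")
    invisible(NULL)
})

#' @describeIn MticNormalization-class the normalized MetabolomeSet.
#' @param object a \code{MticNormalization}.
#' @export
normalizedSet <- function(object) object@normalized

#' ZScoreMatrix: per-feature z-scores of log10 intensities
#'
#' Rows are features, columns the samples of one scoring group (typically
#' one comparison). Rows constant within the group are set to all-zero and
#' flagged; features with no positive intensity in the group are dropped.
#'
#' @slot z numeric matrix, features x samples.
#' @slot constantFeatures character, ids of flagged constant features.
#' @slot droppedFeatures character, ids dropped as all-zero.
#' @slot logBase numeric, base of the log transform (10).
#' @slot zeroRule character, the zero-replacement rule applied.
#' @slot grouping character, description of the scoring group.
#' @export
setClass("ZScoreMatrix",
    representation(z = "matrix", constantFeatures = "character",
                   droppedFeatures = "character", logBase = "numeric",
                   zeroRule = "character", grouping = "character"))

setMethod("show", "ZScoreMatrix", function(object) {
    cat("ZScoreMatrix:", nrow(object@z), "features x", ncol(object@z),
        "samples (", object@grouping, ")\n")
    if (length(object@constantFeatures))
        cat("  constant features:", length(object@constantFeatures), "\n")
    if (length(object@droppedFeatures))
        cat("  dropped all-zero features:",
            length(object@droppedFeatures), "\n")
    invisible(NULL)
})

#' @describeIn ZScoreMatrix-class the z-score matrix.
#' @param object a \code{ZScoreMatrix}.
#' @export
zscores <- function(object) object@z

#' OplsModel: an orthogonal signal correction fit
#'
#' Filters from a samples x features matrix the structured variation
#' orthogonal to a binary response. \code{Xfiltered + tOrth %*% t(pOrth)}
#' reconstructs the input, each orthogonal score vector is exactly
#' orthogonal to the response, and each orthogonal loading is orthogonal to
#' the predictive weight vector.
#'
#' @slot Xfiltered numeric matrix, samples x features.
#' @slot tOrth numeric matrix, samples x nOrthEffective orthogonal scores.
#' @slot pOrth numeric matrix, features x nOrthEffective orthogonal loadings.
#' @slot wOrth numeric matrix, features x nOrthEffective orthogonal weights
#'   (needed to project new samples).
#' @slot w numeric, predictive weight vector (unit length).
#' @slot nOrth integer, requested component count.
#' @slot nOrthEffective integer, components actually removed.
#' @export
setClass("OplsModel",
    representation(Xfiltered = "matrix", tOrth = "matrix", pOrth = "matrix",
                   wOrth = "matrix", w = "numeric", nOrth = "integer",
                   nOrthEffective = "integer"))

setMethod("show", "OplsModel", function(object) {
    cat("OplsModel:", nrow(object@Xfiltered), "samples x",
        ncol(object@Xfiltered), "features;",
        object@nOrthEffective, "orthogonal component(s) removed\n")
    invisible(NULL)
})

#' @describeIn OplsModel-class the filtered matrix.
#' @param object an \code{OplsModel}.
#' @export
filteredMatrix <- function(object) object@Xfiltered

#' Dq2Result: cross-validated discriminant Q2 with permutation significance
#'
#' @slot q2,dq2 numeric, cross-validated Q2 and truncated (discriminant) Q2.
#' @slot cvPredictions numeric, out-of-sample prediction per sample.
#' @slot labels numeric, the +1/-1 class labels.
#' @slot permDq2 numeric, DQ2 under label permutation (the null).
#' @slot permMean,permSd,z,pValue numeric, the fitted-normal summary of the
#'   null and the two-tailed significance of the observed DQ2.
#' @slot nPerm,seed integer, permutation count and RNG seed used.
#' @export
setClass("Dq2Result",
    representation(q2 = "numeric", dq2 = "numeric",
                   cvPredictions = "numeric", labels = "numeric",
                   permDq2 = "numeric", permMean = "numeric",
                   permSd = "numeric", z = "numeric", pValue = "numeric",
                   nPerm = "integer", seed = "integer"))

setMethod("show", "Dq2Result", function(object) {
    cat(sprintf("Dq2Result: Q2 = %.4f, DQ2 = %.4f", object@q2, object@dq2))
    if (length(object@permDq2))
        cat(sprintf(", z = %.3f, p = %.4g (n_perm = %d)",
                    object@z, object@pValue, object@nPerm))
    cat("\n")
    invisible(NULL)
})
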