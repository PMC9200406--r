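#' Log10 z-score transform within a comparison
#'
#' Restricts a peak table to the samples of one comparison (and optionally
#' one category), replaces zeros by half the smallest positive intensity of
#' the same feature within the comparison, takes log10, and z-scores each
#' feature across the comparison's samples using the sample standard
#' deviation (n - 1 denominator). Features constant within the comparison
#' are set to all-zero and flagged; features with no positive value are
#' dropped with a warning.
#'
#' @param x a [MetabolomeSet-class] or [MticNormalization-class].
#' @param comparison a [ComparisonDesign-class]; its samples must exist in
#'   \code{x}. If \code{NULL}, all samples are used (one scoring group).
#' @param categorySubset optional category name; restricts features.
#' @return A [ZScoreMatrix-class] with samples ordered as
#'   \code{comparisonSamples(comparison)}.
#' @export
#' @examples
#' m <- matrix(c(1, 10, 100, 1000), 1, dimnames = list("F1", paste0("S", 1:4)))
#' cmp <- ComparisonDesign("c", "liver", c("S1", "S2"), c("S3", "S4"))
#' zscores(logZTransform(MetabolomeSet(m), cmp))
logZTransform <- function(x, comparison = NULL, categorySubset = NULL) {
    if (methods::is(x, "MticNormalization")) x <- normalizedSet(x)
    stopifnot(methods::is(x, "MetabolomeSet"))
    if (is.null(comparison)) {
        ids <- colnames(x)
        grouping <- "all samples"
    } else {
        ids <- comparisonSamples(comparison)
        grouping <- comparison@comparisonId
        if (!all(ids %in% colnames(x)))
            stop("comparison samples missing from table: ",
                 paste(setdiff(ids, colnames(x)), collapse = ", "))
    }
    if (length(ids) < 3)
        stop("fewer than 3 samples in the scoring group; SD unstable")
    mat <- peaks(x)[, ids, drop = FALSE]
    if (!is.null(categorySubset)) {
        keep <- featureCategories(x) %in% categorySubset
        if (!any(keep)) stop("no features in category ",
                             paste(categorySubset, collapse = ","))
        mat <- mat[keep, , drop = FALSE]
    }
    allZero <- rowSums(mat > 0) == 0
    if (any(allZero))
        warning(sum(allZero), " feature(s) all-zero in group; dropped")
    dropped <- rownames(mat)[allZero]
    mat <- mat[!allZero, , drop = FALSE]
    ## half-minimum imputation, per feature within the group
    for (i in which(rowSums(mat == 0) > 0)) {
        half <- min(mat[i, mat[i, ] > 0]) / 2
        mat[i, mat[i, ] == 0] <- half
    }
    lg <- log10(mat)
    mu <- rowMeans(lg)
    sd <- apply(lg, 1, stats::sd)
    const <- sd < .Machine$double.eps^0.5 * pmax(1, abs(mu))
    z <- (lg - mu) / ifelse(const, 1, sd)
    z[const, ] <- 0
    methods::new("ZScoreMatrix", z = z,
                 constantFeatures = rownames(mat)[const],
                 droppedFeatures = dropped, logBase = 10,
                 zeroRule = "half-min", grouping = grouping)
}

#' Map feature annotations to broad metabolite categories
#'
#' Assigns each feature to one of the five broad categories used for
#' category-wise scoring — carbohydrates and central carbon metabolites,
#' amino acids, fatty acids, nucleotides, miscellaneous/secondary — from
#' its HMDB-style subclass (falling back to the superclass when the
#' subclass is absent or unmapped). Terms with no mapping entry fall back
#' to \code{"Miscellaneous/secondary"} with a warning.
#'
#' @param annotations \code{data.frame} with columns \code{feature_id} and
#'   \code{subclass} and/or \code{superclass}.
#' @param mapping named character vector \code{term -> category}, or the
#'   path of a YAML file of the same shape. Defaults to the mapping shipped
#'   in \code{inst/extdata/category_map.yaml}. Matching is
#'   case-insensitive.
#' @return Named character vector of categories, one per feature.
#' @export
categorizeFeatures <- function(annotations, mapping = NULL) {
    cats <- c("Carbohydrates/CCM", "Amino acids", "Fatty acids",
              "Nucleotides", "Miscellaneous/secondary")
    if (is.null(mapping))
        mapping <- system.file("extdata", "category_map.yaml",
                               package = "cavemet")
    if (is.character(mapping) && length(mapping) == 1 &&
        file.exists(mapping)) {
        mapping <- tryCatch(unlist(yaml::read_yaml(mapping)),
                            error = function(e)
                                stop("malformed mapping file: ",
                                     conditionMessage(e)))
    }
    if (is.null(names(mapping)) || !all(mapping %in% cats))
        stop("malformed mapping: must be named term -> category, ",
             "categories one of: ", paste(cats, collapse = "; "))
    names(mapping) <- tolower(names(mapping))
    lookup <- function(term) {
        if (is.na(term) || !nzchar(term)) return(NA_character_)
        unname(mapping[tolower(term)])
    }
    sub <- if ("subclass" %in% names(annotations))
        annotations$subclass else rep(NA_character_, nrow(annotations))
    sup <- if ("superclass" %in% names(annotations))
        annotations$superclass else rep(NA_character_, nrow(annotations))
    out <- vapply(seq_len(nrow(annotations)), function(i) {
        hit <- lookup(sub[i])
        if (is.na(hit)) hit <- lookup(sup[i])
        hit
    }, character(1))
    unmapped <- is.na(out)
    if (any(unmapped))
        warning(sum(unmapped), " feature(s) without mapping entry ",
                "assigned to Miscellaneous/secondary")
    out[unmapped] <- "Miscellaneous/secondary"
    stats::setNames(out, annotations$feature_id)
}
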