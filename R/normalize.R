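#' mTIC normalization of peak heights
#'
#' Scales each sample so that the sum of its identified peak heights (its
#' mTIC) equals the average mTIC of its normalization group:
#' \deqn{y_{ij} = (x_{ij} / mTIC_j) \times \bar{mTIC}.}
#' The mTIC denominator sums only identified features, so unidentified
#' (potentially artifactual) peaks do not influence the scale factor, but
#' every feature of a sample, identified or not, is multiplied by it.
#'
#' With \code{grouping = "population_x_tissue"} (the default) the reference
#' \eqn{\bar{mTIC}} is the mean mTIC of the sample's population-by-tissue
#' group, regardless of feeding state; \code{"global"} uses one reference
#' over all samples.
#'
#' @param x a [MetabolomeSet-class]. For \code{"population_x_tissue"} its
#'   \code{colData} must carry \code{population} and \code{tissue}.
#' @param grouping \code{"population_x_tissue"} or \code{"global"}.
#' @return A [MticNormalization-class] holding the scaled set, the per-sample
#'   mTIC values and the per-group references.
#' @export
#' @examples
#' m <- matrix(c(2, 3, 4, 6), 2, dimnames = list(c("F1","F2"), c("A","B")))
#' res <- mticNormalize(MetabolomeSet(m), grouping = "global")
#' peaks(normalizedSet(res))   # both samples scaled to mTIC 7.5
mticNormalize <- function(x, grouping = c("population_x_tissue", "global")) {
    grouping <- match.arg(grouping)
    stopifnot(methods::is(x, "MetabolomeSet"))
    mat <- peaks(x)
    idf <- identifiedFeatures(x)
    if (!any(idf)) stop("no identified features; mTIC undefined")
    mtic <- colSums(mat[idf, , drop = FALSE])
    if (any(mtic <= 0))
        stop("zero mTIC: sample(s) with no identified signal: ",
             paste(colnames(mat)[mtic <= 0], collapse = ", "))
    cd <- SummarizedExperiment::colData(x)
    if (grouping == "population_x_tissue") {
        if (!all(c("population", "tissue") %in% colnames(cd)))
            stop("population_x_tissue grouping needs population and tissue ",
                 "in colData; use grouping = 'global' otherwise")
        grp <- paste(cd$population, cd$tissue, sep = ".")
    } else {
        grp <- rep("all", ncol(mat))
    }
    names(grp) <- colnames(mat)
    ref <- tapply(mtic, grp, mean)
    ref <- ref[unique(grp)]             # drop unused-level NAs, keep order
    scale <- as.numeric(ref[grp]) / mtic
    norm <- sweep(mat, 2, scale, "*")
    out <- x
    SummarizedExperiment::assay(out, "peaks") <- norm
    methods::new("MticNormalization", normalized = out,
                 mticPerSample = mtic,
                 mticReference = stats::setNames(as.numeric(ref),
                                                 names(ref)),
                 groupOfSample = grp, grouping = grouping)
}
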