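#' PCA scores for cluster inspection
#'
#' SVD-based principal component analysis of a z-score matrix (features x
#' samples; rows are centered by construction). Scores are returned per
#' sample with the explained-variance fraction per component. The sign of
#' each component is fixed by making the largest-magnitude element of its
#' loading vector positive, so score plots are reproducible across runs.
#'
#' @param z a [ZScoreMatrix-class] or plain features x samples matrix with
#'   centered rows.
#' @param nComponents components to return (default 2). If the matrix rank
#'   is lower, the available components are returned with a warning.
#' @return List with \code{scores} (samples x k), \code{loadings}
#'   (features x k) and \code{explainedVariance} (fractions over the full
#'   spectrum).
#' @export
pcaScores <- function(z, nComponents = 2L) {
    mat <- if (methods::is(z, "ZScoreMatrix")) zscores(z) else as.matrix(z)
    X <- t(mat)
    if (nrow(X) < nComponents + 1)
        stop("need at least nComponents + 1 samples")
    sv <- svd(X)
    tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
    rank <- sum(sv$d > tol)
    k <- min(nComponents, rank)
    if (k < nComponents)
        warning("rank ", rank, " < requested ", nComponents,
                " components; returning ", k)
    flip <- vapply(seq_len(k), function(j) {
        v <- sv$v[, j]
        sign(v[which.max(abs(v))])
    }, numeric(1))
    scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, "*")
    loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, "*")
    rownames(scores) <- rownames(X)
    rownames(loadings) <- colnames(X)
    colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
    list(scores = scores, loadings = loadings,
         explainedVariance = sv$d^2 / sum(sv$d^2))
}

#' Run the full analysis pipeline
#'
#' Orchestrates normalize -> per-comparison z-scoring -> per-feature
#' Bayesian logistic tests -> category-wise O-PLS/PLS DQ2 classification
#' with permutation significance -> parallel-adaptation contrast tests ->
#' top-k tables, writing TSV outputs and a machine-readable JSON summary.
#' Re-running with an identical config reproduces identical result tables
#' (output file hashes are part of the summary; no timestamps are
#' embedded).
#'
#' @param config a list with entries:
#'   \describe{
#'     \item{sim}{a [simConfig()] to simulate inputs, or \code{NULL} to
#'       read from \code{peakTablePath}/\code{sampleMetaPath}.}
#'     \item{peakTablePath, sampleMetaPath}{input files when
#'       \code{sim} is \code{NULL}.}
#'     \item{seed}{master seed; drives simulation and, via fixed offsets,
#'       every permutation test (default 1).}
#'     \item{outDir}{output directory (required).}
#'     \item{mticGrouping}{\code{"population_x_tissue"} or
#'       \code{"global"}.}
#'     \item{nOrth, nPerm, alpha, k}{O-PLS components (1), permutations
#'       per classification (200), significance level (0.05), top-table
#'       size (20).}
#'     \item{classify}{run the DQ2 classification stage (default TRUE).}
#'     \item{classifyCategories}{categories to classify; default the five
#'       broad primary-metabolite categories present.}
#'   }
#' @return Invisibly, a list: \code{summary} (also written as
#'   \code{summary.json}), \code{comparisons}, \code{featureTests},
#'   \code{classification}, \code{contrastTests}, \code{topTables},
#'   \code{paths}.
#' @export
runPipeline <- function(config) {
    cfg <- config
    if (is.null(cfg$outDir)) stop("[config] outDir is required")
    cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
    cfg$nOrth <- if (is.null(cfg$nOrth)) 1L else as.integer(cfg$nOrth)
    cfg$nPerm <- if (is.null(cfg$nPerm)) 200L else as.integer(cfg$nPerm)
    cfg$alpha <- if (is.null(cfg$alpha)) 0.05 else cfg$alpha
    cfg$k <- if (is.null(cfg$k)) 20L else as.integer(cfg$k)
    cfg$classify <- if (is.null(cfg$classify)) TRUE else cfg$classify
    cfg$mticGrouping <- if (is.null(cfg$mticGrouping))
        "population_x_tissue" else cfg$mticGrouping

    ## ---- load or simulate -------------------------------------------
    inputDigests <- list()
    if (!is.null(cfg$sim)) {
        sim <- simulateMetabolome(cfg$sim, seed = cfg$seed)
        set <- sim$set
        meta <- sim$meta
        truth <- sim$truth
    } else {
        for (p in c(cfg$peakTablePath, cfg$sampleMetaPath))
            if (is.null(p) || !file.exists(p))
                stop("[input] missing input path: ",
                     if (is.null(p)) "(unset)" else p)
        set <- readPeakTable(cfg$peakTablePath)
        meta <- readSampleMeta(cfg$sampleMetaPath)
        set <- attachSampleMeta(set, meta)
        truth <- NULL
        inputDigests <- list(
            peak_table = unname(tools::md5sum(cfg$peakTablePath)),
            sample_meta = unname(tools::md5sum(cfg$sampleMetaPath)))
    }
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)

    ## ---- normalize and enumerate comparisons ------------------------
    norm <- tryCatch(mticNormalize(set, grouping = cfg$mticGrouping),
                     error = function(e)
                         stop("[normalize] ", conditionMessage(e)))
    comparisons <- buildComparisons(meta)

    ## ---- per-feature tests ------------------------------------------
    featureTests <- do.call(rbind, lapply(comparisons, function(cmp) {
        z <- suppressWarnings(logZTransform(norm, cmp))
        runFeatureTests(z, cmp, nOrth = cfg$nOrth, alpha = cfg$alpha)
    }))
    rownames(featureTests) <- NULL

    ## ---- category-wise DQ2 classification ---------------------------
    classification <- NULL
    if (isTRUE(cfg$classify)) {
        broad <- c("Carbohydrates/CCM", "Amino acids", "Fatty acids",
                   "Nucleotides", "Miscellaneous/secondary")
        cats <- cfg$classifyCategories
        if (is.null(cats))
            cats <- intersect(broad, featureCategories(set))
        stateCmps <- Filter(function(c) c@axis == "state_within_population",
                            comparisons)
        rows <- list()
        i <- 0L
        for (cmp in stateCmps) for (ct in cats) {
            i <- i + 1L
            z <- tryCatch(
                suppressWarnings(logZTransform(norm, cmp,
                                               categorySubset = ct)),
                error = function(e) NULL)
            if (is.null(z) || nrow(zscores(z)) < 2) next
            dq <- permutationSignificance(
                t(zscores(z)), comparisonLabels(cmp),
                nPerm = cfg$nPerm, seed = cfg$seed + i,
                nOrth = cfg$nOrth)
            rows[[length(rows) + 1L]] <- data.frame(
                comparison_id = cmp@comparisonId, category = ct,
                n_features = nrow(zscores(z)), q2 = dq@q2, dq2 = dq@dq2,
                z = dq@z, p_value = dq@pValue, n_perm = dq@nPerm,
                stringsAsFactors = FALSE)
        }
        classification <- do.call(rbind, rows)
    }

    ## ---- parallel-adaptation contrasts ------------------------------
    statePairs <- list(c("Refed", "Fasted30"), c("Fasted4", "Fasted30"),
                       c("Refed", "Fasted4"))
    tissues <- intersect(.TISSUES, unique(as.character(meta$tissue)))
    contrastTests <- NULL
    topTables <- list()
    canContrast <- all(.POPULATIONS %in% meta$population)
    if (canContrast) {
        for (sp in statePairs) {
            if (!all(sp %in% meta$feeding_state)) next
            res <- do.call(rbind, lapply(tissues, function(tis) {
                ct <- tryCatch(suppressWarnings(
                    buildContrast(norm, tis, statePair = sp)),
                    error = function(e) NULL)
                if (is.null(ct)) return(NULL)
                contrastTest(ct, nOrth = cfg$nOrth, alpha = cfg$alpha)
            }))
            if (is.null(res)) next
            contrastTests <- rbind(contrastTests, res)
            topTables[[paste(sp, collapse = "-")]] <-
                topKTable(res, k = cfg$k)
        }
    }

    ## ---- write outputs ----------------------------------------------
    wtsv <- function(df, name) {
        p <- file.path(cfg$outDir, name)
        utils::write.table(df, p, sep = "\t", row.names = FALSE,
                           quote = FALSE)
        p
    }
    paths <- character()
    paths["feature_tests"] <- wtsv(featureTests, "feature_tests.tsv")
    if (!is.null(classification))
        paths["classification"] <- wtsv(classification,
                                        "classification.tsv")
    if (!is.null(contrastTests)) {
        paths["contrast_tests"] <- wtsv(contrastTests,
                                        "contrast_tests.tsv")
        for (nm in names(topTables))
            paths[paste0("top_", nm)] <-
                wtsv(topTables[[nm]], paste0("top_contrast_", nm, ".tsv"))
    }
    summary <- list(
        seed = cfg$seed,
        n_samples = ncol(set), n_features = nrow(set),
        n_comparisons = length(comparisons),
        n_feature_tests = nrow(featureTests),
        n_significant = sum(featureTests$significant),
        n_classifications = if (is.null(classification)) 0L
                            else nrow(classification),
        n_contrast_tests = if (is.null(contrastTests)) 0L
                           else nrow(contrastTests),
        top_tables = lapply(topTables, function(tt)
            list(n_rows = nrow(tt), tissues = unique(tt$tissue))),
        mtic_grouping = cfg$mticGrouping, n_perm = cfg$nPerm,
        n_orth = cfg$nOrth, alpha = cfg$alpha,
        input_digests = inputDigests,
        output_digests = lapply(as.list(paths),
                                function(p) unname(tools::md5sum(p))))
    jsonlite::write_json(summary,
                         file.path(cfg$outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(summary = summary, comparisons = comparisons,
                   featureTests = featureTests,
                   classification = classification,
                   contrastTests = contrastTests, topTables = topTables,
                   truth = truth, norm = norm, paths = paths))
}
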