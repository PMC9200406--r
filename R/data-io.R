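## Delimited-text readers/writers for peak tables and sample metadata.
## The on-disk schema is fixed: features as rows, one column per sample,
## a leading feature_id column, optional 'identified' and 'category'
## annotation columns. Delimiter is taken from the file extension
## (.csv -> comma, .tsv/.txt -> tab) unless overridden.

.detectDelim <- function(path, delim = NULL) {
    if (!is.null(delim)) return(delim)
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a peak-height table
#'
#' Reads a delimited text file with a \code{feature_id} column, optional
#' \code{identified} (logical) and \code{category} columns, and one numeric
#' column per sample. Unparseable numeric cells are an error, never silently
#' zeroed; absent measurements must be encoded as 0.
#'
#' @param path file path to a CSV/TSV table.
#' @param delim optional delimiter override; default inferred from the
#'   extension (\code{.csv} comma, otherwise tab).
#' @return A [MetabolomeSet-class].
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("feature_id,S1,S2", "F1,1,2", "F2,3,4"), f)
#' readPeakTable(f)
readPeakTable <- function(path, delim = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    delim <- .detectDelim(path, delim)
    header <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
    if (anyDuplicated(header))
        stop("duplicate sample id in header: ",
             paste(unique(header[duplicated(header)]), collapse = ", "))
    df <- utils::read.table(path, sep = delim, header = TRUE,
                            colClasses = "character", check.names = FALSE,
                            quote = "\"", comment.char = "",
                            stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    if (!"feature_id" %in% names(df))
        stop("peak table must contain a 'feature_id' column")
    fid <- df$feature_id
    if (anyDuplicated(fid))
        stop("duplicate feature id: ",
             paste(unique(fid[duplicated(fid)]), collapse = ", "))
    ann <- intersect(c("identified", "category"), names(df))
    samp <- setdiff(names(df), c("feature_id", ann))
    if (!length(samp)) stop("peak table contains no sample columns")
    num <- suppressWarnings(
        vapply(df[samp], as.numeric, numeric(nrow(df))))
    num <- matrix(num, nrow = nrow(df),
                  dimnames = list(fid, samp))
    bad <- is.na(num) & !is.na(df[samp])
    if (any(bad)) {
        i <- which(bad, arr.ind = TRUE)[1, ]
        stop("unparseable numeric cell at feature '", fid[i[1]],
             "', sample '", samp[i[2]], "'")
    }
    if (anyNA(num)) stop("NA intensities forbidden; encode absence as 0")
    if (any(num < 0)) stop("negative intensity")
    identified <- if ("identified" %in% ann)
        .parseLogical(df$identified) else rep(TRUE, nrow(df))
    category <- if ("category" %in% ann) df$category
                else rep("unknown", nrow(df))
    MetabolomeSet(num, identified = identified, category = category)
}

.parseLogical <- function(x) {
    out <- rep(NA, length(x))
    out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
    out[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
    if (anyNA(out)) stop("unparseable 'identified' flag: ",
                         x[which(is.na(out))[1]])
    out
}

#' Write a peak table
#'
#' Inverse of [readPeakTable()]: writes the peaks assay plus the
#' \code{identified} and \code{category} annotation columns. Reading the
#' file back yields a value-identical \code{MetabolomeSet} up to float
#' formatting.
#'
#' @param x a [MetabolomeSet-class].
#' @param path output path; delimiter from the extension.
#' @param delim optional delimiter override.
#' @return Invisibly, \code{path}.
#' @export
writePeakTable <- function(x, path, delim = NULL) {
    delim <- .detectDelim(path, delim)
    df <- data.frame(feature_id = rownames(x),
                     identified = identifiedFeatures(x),
                     category = featureCategories(x),
                     as.data.frame(peaks(x), check.names = FALSE),
                     check.names = FALSE)
    utils::write.table(df, path, sep = delim, row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

.matchLevel <- function(x, levels, what) {
    i <- match(tolower(x), tolower(levels))
    if (anyNA(i))
        stop("unknown ", what, ": ",
             paste(unique(x[is.na(i)]), collapse = ", "))
    levels[i]
}

#' Read sample metadata
#'
#' Reads a delimited table with columns \code{sample_id}, \code{population},
#' \code{tissue}, \code{feeding_state}, \code{replicate} and optional
#' \code{mass_g}, \code{length_cm}. Factor levels are validated
#' case-insensitively against [populationLevels()], [tissueLevels()] and
#' [feedingStateLevels()]; the design tuple (population, tissue,
#' feeding_state, replicate) must be unique.
#'
#' @param path file path.
#' @param delim optional delimiter override.
#' @return A \code{data.frame} with validated factor columns.
#' @export
readSampleMeta <- function(path, delim = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    delim <- .detectDelim(path, delim)
    df <- utils::read.table(path, sep = delim, header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            fileEncoding = "UTF-8")
    req <- c("sample_id", "population", "tissue", "feeding_state",
             "replicate")
    miss <- setdiff(req, names(df))
    if (length(miss))
        stop("metadata missing column(s): ", paste(miss, collapse = ", "))
    out <- data.frame(
        sample_id = as.character(df$sample_id),
        population = factor(.matchLevel(df$population, .POPULATIONS,
                                        "population"), levels = .POPULATIONS),
        tissue = factor(.matchLevel(df$tissue, .TISSUES, "tissue"),
                        levels = .TISSUES),
        feeding_state = factor(.matchLevel(df$feeding_state, .STATES,
                                           "feeding state"),
                               levels = .STATES),
        replicate = as.integer(df$replicate),
        stringsAsFactors = FALSE)
    for (opt in c("mass_g", "length_cm"))
        if (opt %in% names(df)) {
            v <- as.numeric(df[[opt]])
            if (any(!is.na(v) & v <= 0)) stop("non-positive ", opt)
            out[[opt]] <- v
        }
    if (anyDuplicated(out$sample_id)) stop("duplicate sample id")
    if (any(is.na(out$replicate) | out$replicate < 1))
        stop("replicate must be a positive integer")
    key <- paste(out$population, out$tissue, out$feeding_state,
                 out$replicate)
    if (anyDuplicated(key))
        stop("duplicate design cell: ", key[duplicated(key)][1])
    out
}

#' Attach sample metadata to a MetabolomeSet
#'
#' Checks that metadata sample ids and peak-table columns match one-to-one,
#' reorders metadata to the column order, and stores it in \code{colData}.
#'
#' @param x a [MetabolomeSet-class].
#' @param meta a metadata \code{data.frame} as from [readSampleMeta()].
#' @return \code{x} with populated \code{colData}.
#' @export
attachSampleMeta <- function(x, meta) {
    meta <- as.data.frame(meta)
    if (!setequal(meta$sample_id, colnames(x)) ||
        nrow(meta) != ncol(x))
        stop("sample ids in metadata and peak table do not match 1:1")
    meta <- meta[match(colnames(x), meta$sample_id), , drop = FALSE]
    rownames(meta) <- meta$sample_id
    SummarizedExperiment::colData(x) <- S4Vectors::DataFrame(meta)
    methods::validObject(x)
    x
}

#' Enumerate all pairwise comparisons of a factorial design
#'
#' For each tissue present, emits every pairwise population comparison
#' within each feeding state (\code{axis = "population_within_state"}) and
#' every pairwise feeding-state comparison within each population
#' (\code{axis = "state_within_population"}). The later level in the
#' canonical order (Pachon > Tinaja > Surface; Fasted30 > Fasted4 > Refed)
#' is always the +1 group. Tissue cells lacking one side of a pair are
#' skipped (recorded in the \code{"skipped"} attribute).
#'
#' @param meta metadata \code{data.frame} from [readSampleMeta()] or
#'   [simulateMetabolome()].
#' @return A list of [ComparisonDesign-class] objects, named by
#'   \code{comparisonId}.
#' @export
buildComparisons <- function(meta) {
    meta <- as.data.frame(meta)
    out <- list()
    skipped <- character()
    ids <- function(tis, pop = NULL, st = NULL) {
        sel <- meta$tissue == tis
        if (!is.null(pop)) sel <- sel & meta$population == pop
        if (!is.null(st)) sel <- sel & meta$feeding_state == st
        meta$sample_id[sel]
    }
    for (tis in intersect(.TISSUES, unique(as.character(meta$tissue)))) {
        ## populations within each feeding state
        for (st in .STATES) {
            pops <- .POPULATIONS[vapply(.POPULATIONS, function(p)
                length(ids(tis, pop = p, st = st)) > 0, logical(1))]
            for (pair in .pairsOf(pops)) {
                ## pair[2] is later in canonical order -> +1 group
                id <- paste(tis, st, paste0(pair[2], "-vs-", pair[1]),
                            sep = ".")
                out[[id]] <- ComparisonDesign(
                    id, tis,
                    groupPos = ids(tis, pop = pair[2], st = st),
                    groupNeg = ids(tis, pop = pair[1], st = st),
                    axis = "population_within_state")
            }
            if (length(pops) < 2 && length(pops) > 0)
                skipped <- c(skipped, paste(tis, st, "population pair"))
        }
        ## feeding states within each population
        for (pop in .POPULATIONS) {
            sts <- .STATES[vapply(.STATES, function(s)
                length(ids(tis, pop = pop, st = s)) > 0, logical(1))]
            for (pair in .pairsOf(sts)) {
                id <- paste(tis, pop, paste0(pair[2], "-vs-", pair[1]),
                            sep = ".")
                out[[id]] <- ComparisonDesign(
                    id, tis,
                    groupPos = ids(tis, pop = pop, st = pair[2]),
                    groupNeg = ids(tis, pop = pop, st = pair[1]),
                    axis = "state_within_population")
            }
            if (length(sts) < 2 && length(sts) > 0)
                skipped <- c(skipped, paste(tis, pop, "state pair"))
        }
    }
    attr(out, "skipped") <- skipped
    out
}

## all unordered pairs of a level vector, each pair in canonical order
.pairsOf <- function(levels) {
    if (length(levels) < 2) return(list())
    idx <- utils::combn(length(levels), 2, simplify = FALSE)
    lapply(idx, function(ij) levels[ij])
}
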