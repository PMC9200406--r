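## O-PLS orthogonal signal correction, single-response NIPALS form.
## The internal core works on plain matrices (it sits inside the
## cross-validation and permutation loops); oplsFilter() is the exported,
## validated S4 surface.

`%||%` <- function(a, b) if (is.null(a)) b else a

## One pass: returns NULL when no orthogonal variation remains.
.oplsComponent <- function(X, y, tol = 1e-12) {
    w <- crossprod(X, y)                     # features x 1
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(NULL)
    w <- w / nw
    t <- X %*% w
    p <- crossprod(X, t) / sum(t * t)
    wo <- p - as.numeric(crossprod(w, p)) * w
    if (sqrt(sum(wo^2)) < tol * sqrt(sum(p^2))) return(NULL)
    wo <- wo / sqrt(sum(wo^2))
    to <- X %*% wo
    po <- crossprod(X, to) / sum(to * to)
    list(w = as.numeric(w), wo = as.numeric(wo), to = as.numeric(to),
         po = as.numeric(po))
}

## Full filter on plain matrices.
.oplsCore <- function(X, y, nOrth = 1L) {
    nFeat <- ncol(X)
    tos <- vector("list", nOrth)
    pos <- vector("list", nOrth)
    wos <- vector("list", nOrth)
    w <- rep(0, nFeat)
    k <- 0L
    while (k < nOrth) {
        comp <- .oplsComponent(X, y)
        if (is.null(comp)) break
        k <- k + 1L
        X <- X - tcrossprod(comp$to, comp$po)
        tos[[k]] <- comp$to
        pos[[k]] <- comp$po
        wos[[k]] <- comp$wo
        w <- comp$w
    }
    tO <- matrix(unlist(tos[seq_len(k)], use.names = FALSE) %||%
                 numeric(0), nrow(X), k)
    pO <- matrix(unlist(pos[seq_len(k)], use.names = FALSE) %||%
                 numeric(0), nFeat, k)
    wO <- matrix(unlist(wos[seq_len(k)], use.names = FALSE) %||%
                 numeric(0), nFeat, k)
    if (k == 0L) {
        ## nothing orthogonal removed; still report the predictive weight
        w0 <- crossprod(X, y)
        if (sqrt(sum(w0^2)) > 0) w <- as.numeric(w0 / sqrt(sum(w0^2)))
    }
    list(X = X, tOrth = tO, pOrth = pO, wOrth = wO, w = w,
         nOrthEffective = k)
}

#' O-PLS filtering of a feature matrix against a binary response
#'
#' Removes from a samples x features matrix the structured variation
#' orthogonal to a +1/-1 response. Per component (NIPALS, single response):
#' the predictive weight \eqn{w \propto X^T y} (unit norm), scores
#' \eqn{t = Xw}, loadings \eqn{p = X^T t/(t^T t)}; the orthogonal weight
#' \eqn{w_o = p - (w^T p) w} normalized, orthogonal scores
#' \eqn{t_o = X w_o}, loadings \eqn{p_o = X^T t_o/(t_o^T t_o)}; then
#' \eqn{X \leftarrow X - t_o p_o^T}. Each \eqn{t_o} is exactly orthogonal
#' to \eqn{y}, and the filtered matrix plus
#' \eqn{\sum t_o p_o^T} reconstructs the input.
#'
#' Input columns are expected centered (z-scored upstream); no re-centering
#' is performed between components. If no orthogonal variation exists
#' (e.g. \eqn{X} is exactly rank-one along the predictive direction) the
#' input is returned unchanged with \code{nOrthEffective = 0}.
#'
#' @param X numeric matrix, samples x features (>= 4 samples).
#' @param y numeric +1/-1 labels, both classes present.
#' @param nOrth number of orthogonal components to remove (default 1).
#' @return An [OplsModel-class].
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(48), 8, 6)
#' X <- scale(X, scale = FALSE)
#' y <- rep(c(1, -1), each = 4)
#' fit <- oplsFilter(X, y)
#' max(abs(X - (filteredMatrix(fit) + fit@tOrth %*% t(fit@pOrth))))
oplsFilter <- function(X, y, nOrth = 1L) {
    X <- as.matrix(X)
    y <- as.numeric(y)
    if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
    if (nrow(X) < 4) stop("need at least 4 samples")
    if (length(unique(sign(y))) < 2)
        stop("response is single-class; O-PLS undefined")
    nOrth <- as.integer(nOrth)
    if (nOrth < 1) stop("nOrth must be a positive integer")
    core <- .oplsCore(X, y, nOrth)
    methods::new("OplsModel", Xfiltered = core$X,
                 tOrth = core$tOrth, pOrth = core$pOrth,
                 wOrth = core$wOrth, w = core$w, nOrth = nOrth,
                 nOrthEffective = as.integer(core$nOrthEffective))
}

#' Apply a fitted O-PLS filter to new samples
#'
#' Projects new rows onto the stored orthogonal weights and subtracts the
#' corresponding orthogonal variation, component by component, exactly as
#' the training pass did. Used to filter a held-out sample through a model
#' fitted on the training fold.
#'
#' @param model an [OplsModel-class].
#' @param newX numeric matrix (or vector for one sample), features in the
#'   training order.
#' @return Filtered matrix of the same shape as \code{newX}.
#' @export
oplsApply <- function(model, newX) {
    if (is.null(dim(newX))) newX <- matrix(newX, nrow = 1)
    k <- model@nOrthEffective
    if (k == 0) return(newX)
    for (j in seq_len(k)) {
        to <- newX %*% model@wOrth[, j]
        newX <- newX - tcrossprod(to, model@pOrth[, j])
    }
    newX
}
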