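#' Preprocess training matrices for the joint embedding
#'
#' Applies the training-time column transform to the raw peptide-count
#' matrix P' and RNA Z-score matrix R': columns with zero variance are
#' removed, the remaining columns are centered by their mean, and each
#' centered column is scaled to unit Euclidean norm. All statistics
#' (column means over the full raw vocabulary, kept-column masks, and
#' centered-column norms) are retained so query profiles can be
#' transformed identically at prediction time and decoded back to the
#' raw scale.
#'
#' @param Praw numeric matrix, RBPs x peptide templates (raw counts).
#' @param Rraw numeric matrix, RBPs x RNA 7-mers (raw Z-scores); must
#'   have identical rownames in identical order to \code{Praw}.
#' @return a list with elements \code{P}, \code{R} (preprocessed blocks),
#'   \code{keepP}, \code{keepR} (logical masks over raw columns),
#'   \code{muP}, \code{muR} (raw column means), \code{normP},
#'   \code{normR} (centered-column norms of kept columns),
#'   \code{colsP}, \code{colsR} (raw column names) and \code{rowIds}.
#' @export
preprocessTraining <- function(Praw, Rraw) {
    stopifnot(is.matrix(Praw), is.matrix(Rraw))
    if (is.null(rownames(Praw)) || is.null(rownames(Rraw)) ||
        !identical(rownames(Praw), rownames(Rraw)))
        stop("'Praw' and 'Rraw' must have identical row ids in ",
             "identical order")
    if (nrow(Praw) < 2L)
        stop("at least 2 training rows are required")
    if (is.null(colnames(Praw)) || is.null(colnames(Rraw)))
        stop("both matrices must have column names")

    prepBlock <- function(X, label) {
        mu <- colMeans(X)
        rng <- apply(X, 2L, range)
        keep <- rng[1L, ] < rng[2L, ]           # exact zero-variance drop
        if (!any(keep))
            stop("all ", label, " columns have zero variance")
        Xc <- sweep(X[, keep, drop = FALSE], 2L, mu[keep], "-")
        nrm <- sqrt(colSums(Xc^2))
        list(X = sweep(Xc, 2L, nrm, "/"), keep = keep, mu = mu, norm = nrm)
    }
    p <- prepBlock(Praw, "peptide")
    r <- prepBlock(Rraw, "RNA")
    list(P = p$X, R = r$X,
         keepP = p$keep, keepR = r$keep,
         muP = p$mu, muR = r$mu,
         normP = p$norm, normR = r$norm,
         colsP = colnames(Praw), colsR = colnames(Rraw),
         rowIds = rownames(Praw))
}
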