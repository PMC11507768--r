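#' Choose the embedding dimension from the RNA block
#'
#' Runs an SVD of the preprocessed RNA block R alone and returns the
#' smallest rank d at which every training row is reconstructed with a
#' Pearson correlation of at least \code{pccMin} by the rank-d
#' approximation. This mirrors how the published training run arrived at
#' its retained dimension (a 0.95 floor).
#'
#' @param R preprocessed RNA matrix (rows = training RBPs).
#' @param pccMin minimum per-row reconstruction PCC, in (0, 1].
#' @return integer dimension d; if the floor is never reached the rank of
#'   R is returned with a warning.
#' @export
selectDimension <- function(R, pccMin = 0.95) {
    stopifnot(is.matrix(R))
    .assertScalarNumeric(pccMin, "pccMin", lower = 0, upper = 1,
                         openLower = TRUE)
    sv <- svd(R)
    tol <- max(dim(R)) * .Machine$double.eps * sv$d[1L]
    rnk <- sum(sv$d > tol)
    if (rnk == 0L) stop("R is a zero matrix")
    recon <- matrix(0, nrow(R), ncol(R))
    for (d in seq_len(rnk)) {
        recon <- recon + sv$d[d] * tcrossprod(sv$u[, d], sv$v[, d])
        pcc <- .rowPcc(R, recon)
        # rows with no variance cannot be scored; treat as reconstructed
        if (all(is.na(pcc) | pcc >= pccMin)) return(d)
    }
    warning("minimum reconstruction PCC of ", pccMin,
            " not reached at full rank; returning rank(R) = ", rnk)
    rnk
}

#' Fit the joint protein-ligand embedding
#'
#' Computes the SVD of the column-wise concatenation [P R] of the
#' preprocessed peptide and RNA blocks, scores every component by its
#' contribution to the variance of the RNA block,
#' \eqn{s_i = \sigma_i^2 \|v_{R,i}\|^2}, and retains the top \code{d}
#' components by that score (rather than by singular value, as plain
#' PCA would). Ties are broken by original singular-value order. The
#' sign of each retained component is fixed so that the entry of largest
#' magnitude in its right singular vector is positive, making the fit
#' deterministic across platforms. The training embeddings are
#' \eqn{W = U' \Sigma'}.
#'
#' @param tm preprocessed training data from [preprocessTraining()].
#' @param d number of components to retain (at most the rank of [P R]).
#' @param gamma RBF width of the local decoder kernel.
#' @param nbhThreshold e-sim cutoff defining the decoding neighborhood.
#' @param confCutoff e-dist below which queries are flagged confident.
#' @param Rraw optional raw RNA matrix for local decoding; reconstructed
#'   from the stored statistics when omitted.
#' @return a fitted [JPLEModel-class].
#' @seealso [jple()] for the one-call wrapper, [proteinQuery()],
#'   [rnaQuery()].
#' @export
fitJoint <- function(tm, d, gamma = 25, nbhThreshold = 0.01,
                     confCutoff = 0.127, Rraw = NULL) {
    stopifnot(is.list(tm), is.matrix(tm$P), is.matrix(tm$R))
    J <- cbind(tm$P, tm$R)
    p <- ncol(tm$P)
    sv <- svd(J)
    tol <- max(dim(J)) * .Machine$double.eps * sv$d[1L]
    rnk <- sum(sv$d > tol)
    d <- as.integer(d)
    if (d < 1L || d > rnk)
        stop("'d' must be between 1 and rank([P R]) = ", rnk)

    vR2 <- colSums(sv$v[-seq_len(p), seq_len(rnk), drop = FALSE]^2)
    scores <- sv$d[seq_len(rnk)]^2 * vR2
    keep <- order(-scores, seq_len(rnk))[seq_len(d)]

    U <- sv$u[, keep, drop = FALSE]
    V <- sv$v[, keep, drop = FALSE]
    S <- sv$d[keep]
    for (j in seq_len(d)) {           # deterministic sign convention
        m <- which.max(abs(V[, j]))
        if (V[m, j] < 0) {
            V[, j] <- -V[, j]
            U[, j] <- -U[, j]
        }
    }
    W <- sweep(U, 2L, S, "*")
    rownames(W) <- tm$rowIds

    if (is.null(Rraw)) {
        Rraw <- matrix(rep(tm$muR, each = length(tm$rowIds)),
                       nrow = length(tm$rowIds),
                       dimnames = list(tm$rowIds, tm$colsR))
        Rraw[, tm$keepR] <- sweep(
            sweep(tm$R, 2L, tm$normR, "*"), 2L,
            tm$muR[tm$keepR], "+")
    } else {
        stopifnot(identical(rownames(Rraw), tm$rowIds),
                  identical(colnames(Rraw), tm$colsR))
    }

    Vp <- V[seq_len(p), , drop = FALSE]
    Vr <- V[-seq_len(p), , drop = FALSE]
    rownames(Vp) <- colnames(tm$P)
    rownames(Vr) <- colnames(tm$R)

    new("JPLEModel",
        Vp = Vp, Vr = Vr, singularValues = S, W = W, d = d,
        scores = scores, gamma = gamma, nbhThreshold = nbhThreshold,
        confCutoff = confCutoff,
        prep = tm[c("keepP", "keepR", "muP", "muR", "normP", "normR",
                    "colsP", "colsR", "rowIds")],
        Rraw = Rraw, version = .MODEL_VERSION)
}

#' Fit a JPLE model from raw training matrices
#'
#' Convenience wrapper: preprocesses the raw peptide-count and RNA
#' Z-score matrices, selects the embedding dimension from the RNA block
#' (unless fixed by the caller), and fits the joint embedding.
#'
#' @param Praw,Rraw raw training matrices (identical row order).
#' @param d embedding dimension; chosen with [selectDimension()] when
#'   \code{NULL}.
#' @param pccMin per-row reconstruction floor for dimension selection.
#' @inheritParams fitJoint
#' @return a fitted [JPLEModel-class].
#' @examples
#' set.seed(1)
#' P <- matrix(rpois(200, 1), 10, dimnames = list(paste0("r", 1:10),
#'                                                paste0("t", 1:20)))
#' R <- matrix(rnorm(100), 10, dimnames = list(paste0("r", 1:10),
#'                                             paste0("k", 1:10)))
#' jple(P, R, d = 3)
#' @export
jple <- function(Praw, Rraw, d = NULL, pccMin = 0.95, gamma = 25,
                 nbhThreshold = 0.01, confCutoff = 0.127) {
    tm <- preprocessTraining(Praw, Rraw)
    if (is.null(d)) d <- selectDimension(tm$R, pccMin = pccMin)
    fitJoint(tm, d, gamma = gamma, nbhThreshold = nbhThreshold,
             confCutoff = confCutoff, Rraw = Rraw)
}
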