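#' Standardize a cohort of reconstructed peptide profiles
#'
#' Reconstructed peptide profiles from a cohort of RNA queries (for
#' example a leave-one-out cross-validation over all measured RBPs) are
#' stacked row-wise and standardized column-wise: each template column
#' is centered by its mean and divided by its (population) standard
#' deviation. Constant columns are set to zero with a warning. Residue
#' importance scores are computed from rows of the standardized matrix,
#' so they depend on the cohort the standardization was run over.
#'
#' @param x numeric matrix of reconstructed peptide profiles (rows =
#'   RBPs, columns = gapped 5-mer templates), at least 2 rows.
#' @return the standardized matrix.
#' @export
standardizeReconstructions <- function(x) {
    stopifnot(is.matrix(x))
    if (nrow(x) < 2L)
        stop("standardization needs at least 2 reconstructions; ",
             "pass the unstandardized profile explicitly to skip it")
    mu <- colMeans(x)
    sd_ <- sqrt(colMeans(sweep(x, 2L, mu, "-")^2))
    const <- sd_ == 0
    if (any(const)) {
        warning(sum(const), " constant column(s) set to 0")
        sd_[const] <- 1
    }
    out <- sweep(sweep(x, 2L, mu, "-"), 2L, sd_, "/")
    out[, const] <- 0
    out
}

#' Residue importance scores from a reconstructed peptide profile
#'
#' Distributes the values of a reconstructed peptide profile p* over the
#' residues of an RNA-binding region: every gapped 5-mer template with a
#' positive occurrence count c in the RBR contributes its profile value
#' divided by c at each of its occurrences, and each occurrence adds
#' that per-occurrence value to all five residue positions it covers
#' (including the wildcard position). A residue's score is the sum over
#' all covering occurrences of all templates; residues in no 5-residue
#' window score zero.
#'
#' @param pStar named numeric vector, a (typically standardized) row of
#'   reconstructed peptide-profile values; templates absent from
#'   \code{pStar} contribute zero.
#' @param rbr the [RBR-class] to score.
#' @return a [ResidueImportance-class].
#' @export
residueImportance <- function(pStar, rbr) {
    stopifnot(is(rbr, "RBR"), is.numeric(pStar))
    if (is.null(names(pStar)))
        stop("'pStar' must be a named vector of template values")
    counts <- table(.templateInstances(rbr))

    segLens <- nchar(rbr@segments)
    scores <- numeric(sum(segLens))
    offset <- 0L
    for (s in seq_along(rbr@segments)) {
        seg <- rbr@segments[s]
        n <- segLens[s]
        if (n >= 5L) {
            for (i in seq_len(n - 4L)) {
                win <- substr(seg, i, i + 4L)
                if (grepl("X", win, fixed = TRUE)) next
                v <- 0
                for (tpl in .windowTemplates(win)) {
                    pv <- pStar[tpl]
                    if (!is.na(pv))
                        v <- v + pv / as.numeric(counts[[tpl]])
                }
                idx <- offset + i:(i + 4L)
                scores[idx] <- scores[idx] + v
            }
        }
        offset <- offset + n
    }
    positions <- unlist(lapply(seq_along(rbr@segments), function(s)
        seq.int(rbr@segStart[s], rbr@segEnd[s])), use.names = FALSE)
    new("ResidueImportance", rbr = rbr, scores = scores,
        positions = as.integer(positions))
}

#' Evaluate an importance track against interface labels
#'
#' Computes the area under the ROC curve (rank-based, ties averaged) and
#' the area under the precision-recall curve (step-interpolated
#' precision) of a per-residue score track against binary RNA-contact
#' labels (1 = residue within contact distance of the RNA).
#'
#' @param scores numeric vector of per-residue scores, or a
#'   [ResidueImportance-class].
#' @param labels binary vector (0/1 or logical) of the same length;
#'   both classes must be present.
#' @return named numeric vector \code{c(auroc = ..., aupr = ...)}.
#' @export
interfaceMetrics <- function(scores, labels) {
    if (is(scores, "ResidueImportance")) scores <- scores@scores
    labels <- as.integer(labels)
    if (length(labels) != length(scores))
        stop("'labels' must match 'scores' in length")
    if (!all(labels %in% c(0L, 1L)))
        stop("'labels' must be binary")
    n1 <- sum(labels == 1L)
    n0 <- sum(labels == 0L)
    if (n1 == 0L || n0 == 0L)
        stop("both classes must be present in 'labels'")

    r <- rank(scores)                     # ties averaged
    auroc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

    ord <- order(scores, decreasing = TRUE)
    lab <- labels[ord]
    sc <- scores[ord]
    # evaluate at thresholds between distinct score values
    cut <- which(diff(sc) != 0)
    kk <- c(cut, length(sc))
    tp <- cumsum(lab)[kk]
    prec <- tp / kk
    rec <- tp / n1
    # step interpolation: precision at recall r is the max precision
    # attained at any recall >= r
    iprec <- rev(cummax(rev(prec)))
    aupr <- sum(diff(c(0, rec)) * iprec)
    c(auroc = auroc, aupr = aupr)
}
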