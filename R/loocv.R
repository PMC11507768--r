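#' Leave-one-out RNA-query reconstructions
#'
#' For each training RBP in turn, fits the embedding on all remaining
#' RBPs and reconstructs the held-out peptide profile from its RNA
#' profile via an RNA query. The stacked reconstructions form the
#' cohort matrix that [standardizeReconstructions()] expects before
#' residue importance scoring.
#'
#' @param Praw,Rraw raw training matrices (identical row order);
#'   for RNA queries \code{Praw} is ideally homolog-augmented
#'   ([buildAugmentedProfiles()]).
#' @param d embedding dimension; selected per fold from the RNA block
#'   when \code{NULL}.
#' @param pccMin reconstruction floor for per-fold dimension selection.
#' @param ... passed on to [fitJoint()].
#' @return numeric matrix (RBPs x raw peptide templates) of
#'   reconstructed profiles p*.
#' @export
loocvRnaReconstructions <- function(Praw, Rraw, d = NULL,
                                    pccMin = 0.95, ...) {
    stopifnot(is.matrix(Praw), is.matrix(Rraw),
              identical(rownames(Praw), rownames(Rraw)))
    n <- nrow(Praw)
    out <- matrix(NA_real_, n, ncol(Praw),
                  dimnames = dimnames(Praw))
    for (i in seq_len(n)) {
        tm <- preprocessTraining(Praw[-i, , drop = FALSE],
                                 Rraw[-i, , drop = FALSE])
        di <- if (is.null(d)) selectDimension(tm$R, pccMin = pccMin)
              else min(d, nrow(Praw) - 1L)
        model <- fitJoint(tm, di, Rraw = Rraw[-i, , drop = FALSE], ...)
        q <- rnaQuery(Rraw[i, ], model)
        rec <- reconstruction(q)
        out[i, ] <- rec[colnames(Praw)]
    }
    out
}
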