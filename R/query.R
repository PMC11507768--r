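## Encoders, decoders and query drivers.

# Transform a raw query profile (named vector) with the stored training
# statistics: align to the raw training vocabulary, mask dropped
# columns, subtract column means, divide by centered-column norms.
.prepQuery <- function(raw, model, block = c("peptide", "rna")) {
    block <- match.arg(block)
    cols <- if (block == "peptide") model@prep$colsP else model@prep$colsR
    keep <- if (block == "peptide") model@prep$keepP else model@prep$keepR
    mu <- if (block == "peptide") model@prep$muP else model@prep$muR
    nrm <- if (block == "peptide") model@prep$normP else model@prep$normR
    if (is.null(names(raw)))
        stop("query profile must be a named vector")
    unseen <- setdiff(names(raw), cols)
    if (length(unseen) == length(raw))
        stop("query profile shares no features with the training ",
             block, " vocabulary")
    if (length(unseen))
        warning(length(unseen), " query feature(s) absent from the ",
                "training vocabulary were ignored")
    full <- numeric(length(cols))
    names(full) <- cols
    known <- intersect(names(raw), cols)
    full[known] <- raw[known]
    (full[keep] - mu[keep]) / nrm
}

# Minimum-norm least-squares solve of A w ~= b via SVD; tolerant of
# rank-deficient A (small fixtures can violate full column rank).
.lsSolve <- function(A, b) {
    sv <- svd(A)
    tol <- max(dim(A)) * .Machine$double.eps * sv$d[1L]
    pos <- sv$d > tol
    if (!any(pos)) return(numeric(ncol(A)))
    as.vector(sv$v[, pos, drop = FALSE] %*%
        (crossprod(sv$u[, pos, drop = FALSE], b) / sv$d[pos]))
}

#' Embed a query profile into the JPLE latent space
#'
#' A protein query deconvolves a raw peptide profile against the peptide
#' block of the retained singular vectors; an RNA query does the same
#' with the RNA block. The embedding is the (minimum-norm) ordinary
#' least-squares solution of \eqn{V_{block} w \approx x} for the
#' preprocessed query vector x. Features absent from the training
#' vocabulary are ignored with a warning.
#'
#' @param raw named numeric vector: peptide template counts
#'   (\code{embedProtein}) or RNA 7-mer Z-scores (\code{embedRNA}).
#' @param model a fitted [JPLEModel-class].
#' @return numeric embedding of length \code{modelDim(model)}, with a
#'   \code{"source"} attribute.
#' @export
embedProtein <- function(raw, model) {
    stopifnot(is(model, "JPLEModel"))
    x <- .prepQuery(raw, model, "peptide")
    structure(.lsSolve(model@Vp, x), source = "protein")
}

#' @rdname embedProtein
#' @export
embedRNA <- function(raw, model) {
    stopifnot(is(model, "JPLEModel"))
    x <- .prepQuery(raw, model, "rna")
    structure(.lsSolve(model@Vr, x), source = "rna")
}

#' Embedding distance and similarity
#'
#' The e-dist between two embeddings is one minus their cosine
#' similarity (range [0, 2]); the e-sim is its RBF transform
#' \eqn{\exp(-\gamma\,\epsilon^2)}. A zero embedding has undefined
#' cosine; its e-dist is defined as 1 (neutral) with a warning.
#'
#' @param w1,w2 numeric embeddings of equal length.
#' @return \code{eDist}: a number in [0, 2].
#' @examples
#' eDist(c(1, 0), c(0, 1))   # orthogonal: 1
#' eSim(0.2)                 # exp(-1)
#' @export
eDist <- function(w1, w2) {
    if (length(w1) != length(w2))
        stop("embedding dimensions differ: ", length(w1), " vs ",
             length(w2))
    n1 <- sqrt(sum(w1^2))
    n2 <- sqrt(sum(w2^2))
    if (n1 == 0 || n2 == 0) {
        warning("e-dist of a zero embedding is defined as 1")
        return(1)
    }
    min(max(1 - sum(w1 * w2) / (n1 * n2), 0), 2)
}

#' @rdname eDist
#' @param edist e-dist value(s).
#' @param gamma RBF width (the fitted models default to 25).
#' @export
eSim <- function(edist, gamma = 25) exp(-gamma * edist^2)

# e-dists of one embedding against all training embeddings.
.edistsToTraining <- function(w, model) {
    W <- model@W
    nw <- sqrt(sum(w^2))
    nW <- sqrt(rowSums(W^2))
    if (nw == 0) {
        warning("e-dist of a zero embedding is defined as 1")
        d <- rep(1, nrow(W))
    } else {
        d <- 1 - as.vector(W %*% w) / (nW * nw)
        d[nW == 0] <- 1
        d <- pmin(pmax(d, 0), 2)
    }
    names(d) <- rownames(W)
    d
}

#' Decode an embedding back to a raw-scale profile
#'
#' Global decoding is the linear map back through the retained singular
#' vectors: \eqn{x = V_{block} w} on the preprocessed scale, then
#' un-scaled by the stored column norms and re-centered by the stored
#' column means, so the result is directly comparable to measured
#' profiles. Columns dropped as zero-variance are reported at their
#' training column mean.
#'
#' @param w numeric embedding.
#' @param model a fitted [JPLEModel-class].
#' @param block \code{"rna"} to reconstruct an RNA 7-mer profile,
#'   \code{"peptide"} for a peptide profile.
#' @return named numeric vector over the full raw column vocabulary.
#' @export
decodeGlobal <- function(w, model, block = c("rna", "peptide")) {
    block <- match.arg(block)
    stopifnot(is(model, "JPLEModel"), length(w) == model@d)
    if (block == "rna") {
        V <- model@Vr; keep <- model@prep$keepR
        mu <- model@prep$muR; nrm <- model@prep$normR
        cols <- model@prep$colsR
    } else {
        V <- model@Vp; keep <- model@prep$keepP
        mu <- model@prep$muP; nrm <- model@prep$normP
        cols <- model@prep$colsP
    }
    out <- mu
    names(out) <- cols
    out[keep] <- as.vector(V %*% w) * nrm + mu[keep]
    out
}

#' Kernel-weighted local decoding of an RNA profile
#'
#' Local decoding reconstructs the RNA-binding profile as the e-sim
#' weighted average of the raw training profiles in the neighborhood
#' \eqn{N = \{i : \exp(-\gamma\,\epsilon_i^2) \ge t\}} (default
#' \eqn{t = 0.01}, i.e. training RBPs within e-dist
#' \eqn{\sqrt{\ln(1/t)/\gamma}}). With an empty neighborhood the
#' reconstruction is the zero vector and the result is flagged
#' non-confident.
#'
#' @inheritParams decodeGlobal
#' @return list with \code{reconstruction} (named numeric),
#'   \code{edists}, \code{esims}, \code{neighborhood} (character ids)
#'   and \code{empty} (logical).
#' @export
decodeLocal <- function(w, model) {
    stopifnot(is(model, "JPLEModel"), length(w) == model@d)
    ed <- .edistsToTraining(w, model)
    es <- eSim(ed, model@gamma)
    nbh <- names(es)[es >= model@nbhThreshold]
    if (length(nbh)) {
        wts <- es[nbh] / sum(es[nbh])
        rec <- as.vector(crossprod(model@Rraw[nbh, , drop = FALSE], wts))
        names(rec) <- colnames(model@Rraw)
    } else {
        rec <- structure(numeric(ncol(model@Rraw)),
                         names = colnames(model@Rraw))
    }
    list(reconstruction = rec, edists = ed, esims = es,
         neighborhood = nbh, empty = length(nbh) == 0L)
}

#' Query a JPLE model with a peptide profile
#'
#' Embeds the query peptide profile, measures e-dists to all training
#' RBPs, and reconstructs the RNA-binding profile with the requested
#' decoder (kernel-weighted local decoding by default; global linear
#' decoding as the alternative). The query is flagged confident when the
#' smallest e-dist falls below the model's confidence cutoff.
#'
#' @param raw named numeric vector of peptide template counts, e.g. from
#'   [peptideProfile()].
#' @param model a fitted [JPLEModel-class].
#' @param decoder \code{"local"} (default) or \code{"global"}.
#' @return a [JPLEQuery-class] with the reconstructed RNA profile.
#' @export
proteinQuery <- function(raw, model, decoder = c("local", "global")) {
    decoder <- match.arg(decoder)
    w <- embedProtein(raw, model)
    if (decoder == "local") {
        loc <- decodeLocal(w, model)
        rec <- loc$reconstruction
        ed <- loc$edists; es <- loc$esims; nbh <- loc$neighborhood
        conf <- !loc$empty && min(ed) < model@confCutoff
    } else {
        ed <- .edistsToTraining(w, model)
        es <- eSim(ed, model@gamma)
        nbh <- names(es)[es >= model@nbhThreshold]
        rec <- decodeGlobal(w, model, "rna")
        conf <- min(ed) < model@confCutoff
    }
    new("JPLEQuery", embedding = as.numeric(w), source = "protein",
        decoder = decoder, edists = ed, esims = es, neighborhood = nbh,
        reconstruction = rec, minEdist = min(ed), confident = conf)
}

#' Query a JPLE model with an RNA-binding profile
#'
#' Embeds the query RNA 7-mer profile through the RNA block of the
#' retained singular vectors and reconstructs the peptide profile with
#' global decoding; the reconstructed values represent the relative
#' contribution of each gapped peptide template to the queried RNA
#' specificity. For this query direction the model is best fitted on
#' homolog-augmented peptide profiles (see [buildAugmentedProfiles()]).
#'
#' @param raw named numeric vector of RNA 7-mer Z-scores.
#' @param model a fitted [JPLEModel-class].
#' @return a [JPLEQuery-class] whose reconstruction is the peptide
#'   profile p*.
#' @export
rnaQuery <- function(raw, model) {
    w <- embedRNA(raw, model)
    ed <- .edistsToTraining(w, model)
    es <- eSim(ed, model@gamma)
    nbh <- names(es)[es >= model@nbhThreshold]
    rec <- decodeGlobal(w, model, "peptide")
    new("JPLEQuery", embedding = as.numeric(w), source = "rna",
        decoder = "global", edists = ed, esims = es, neighborhood = nbh,
        reconstruction = rec, minEdist = min(ed),
        confident = min(ed) < model@confCutoff)
}
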