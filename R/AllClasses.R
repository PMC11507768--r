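#' @import methods
NULL

#' RNA-binding region of a protein
#'
#' An RNA-binding region (RBR) is the part of an RNA-binding protein that
#' spans all of its RNA-binding domains (RBDs), each extended by a short
#' flank of residues to capture linkers and termini. Overlapping or
#' adjacent extended domains are merged, so an RBR is an ordered set of
#' non-overlapping segments of the parent protein sequence.
#'
#' @slot proteinId single string, identifier of the parent protein.
#' @slot segments character vector of amino-acid segment sequences, in
#'   order of occurrence along the protein.
#' @slot segStart,segEnd integer vectors, 1-based inclusive coordinates of
#'   each segment on the parent protein.
#' @slot domainClasses character vector, comma-separated classes of the
#'   RBDs merged into each segment (e.g. \code{"RRM"} or \code{"RRM,RRM"}).
#'
#' @seealso [buildRBR()], [peptideProfile()]
#' @exportClass RBR
setClass("RBR",
    representation(
        proteinId = "character",
        segments = "character",
        segStart = "integer",
        segEnd = "integer",
        domainClasses = "character"
    )
)

setValidity("RBR", function(object) {
    msg <- NULL
    n <- length(object@segments)
    if (length(object@proteinId) != 1L)
        msg <- c(msg, "'proteinId' must be a single string")
    if (length(object@segStart) != n || length(object@segEnd) != n ||
        length(object@domainClasses) != n)
        msg <- c(msg, "segment slots must have equal length")
    if (n > 0L) {
        if (any(nchar(object@segments) !=
                object@segEnd - object@segStart + 1L))
            msg <- c(msg, "segment lengths disagree with coordinates")
        if (n > 1L && any(diff(object@segStart) <= 0L))
            msg <- c(msg, "segments must be ordered by start")
        if (n > 1L &&
            any(object@segStart[-1L] <= object@segEnd[-n]))
            msg <- c(msg, "segments must not overlap")
    }
    if (is.null(msg)) TRUE else msg
})

#' Fitted joint protein-ligand embedding model
#'
#' Container for a fitted JPLE model: the retained singular system of the
#' joint [P R] matrix (split into the peptide block \code{Vp} and the RNA
#' block \code{Vr}), the training embeddings \code{W = U' S'}, the
#' per-component variance scores used for axis selection, the decoder
#' parameters, and all preprocessing statistics needed to transform query
#' profiles at prediction time.
#'
#' @slot Vp numeric matrix (kept peptide columns x d), peptide block of the
#'   retained right singular vectors.
#' @slot Vr numeric matrix (kept RNA columns x d), RNA block of the
#'   retained right singular vectors.
#' @slot singularValues numeric vector of the d retained singular values,
#'   in retained (score-ranked) order.
#' @slot W numeric matrix (n training RBPs x d) of training embeddings.
#' @slot d integer, the retained embedding dimension.
#' @slot scores numeric vector over all components (original singular-value
#'   order) of the variance contribution to the RNA block,
#'   \eqn{s_i = \sigma_i^2 \|v_{R,i}\|^2}.
#' @slot gamma RBF kernel width used to convert e-dists to e-sims.
#' @slot nbhThreshold minimum e-sim for a training RBP to enter the local
#'   decoding neighborhood.
#' @slot confCutoff e-dist below which a query is flagged confident.
#' @slot prep list of preprocessing statistics (column means, kept-column
#'   masks, centered-column norms for both blocks).
#' @slot Rraw numeric matrix of the raw (unpreprocessed) training RNA
#'   profiles, used by the local decoder.
#' @slot version format version tag of the container.
#'
#' @seealso [jple()], [fitJoint()], [proteinQuery()], [rnaQuery()]
#' @exportClass JPLEModel
setClass("JPLEModel",
    representation(
        Vp = "matrix",
        Vr = "matrix",
        singularValues = "numeric",
        W = "matrix",
        d = "integer",
        scores = "numeric",
        gamma = "numeric",
        nbhThreshold = "numeric",
        confCutoff = "numeric",
        prep = "list",
        Rraw = "matrix",
        version = "character"
    )
)

setValidity("JPLEModel", function(object) {
    msg <- NULL
    d <- object@d
    if (ncol(object@Vp) != d || ncol(object@Vr) != d ||
        ncol(object@W) != d || length(object@singularValues) != d)
        msg <- c(msg, "embedding dimension disagrees between slots")
    V <- rbind(object@Vp, object@Vr)
    if (d > 0L) {
        G <- crossprod(V)
        if (max(abs(G - diag(d))) > 1e-8)
            msg <- c(msg, "stacked [Vp; Vr] columns are not orthonormal")
    }
    if (object@gamma <= 0)
        msg <- c(msg, "'gamma' must be positive")
    if (is.null(msg)) TRUE else msg
})

#' Result of a JPLE protein or RNA query
#'
#' @slot embedding numeric d-vector, the least-squares embedding of the
#'   query profile in the model's latent space.
#' @slot source either \code{"protein"} or \code{"rna"}, the block the
#'   query was encoded from.
#' @slot decoder decoder used for the reconstruction (\code{"local"} or
#'   \code{"global"}).
#' @slot edists named numeric vector of e-dists (cosine distances in
#'   embedding space) to every training RBP.
#' @slot esims named numeric vector of RBF-transformed e-dists,
#'   \eqn{\exp(-\gamma \epsilon^2)}.
#' @slot neighborhood ids of training RBPs with e-sim at or above the
#'   neighborhood threshold.
#' @slot reconstruction named numeric vector: the reconstructed RNA 7-mer
#'   profile (protein query) or reconstructed peptide profile (RNA query),
#'   on the raw measurement scale.
#' @slot minEdist smallest e-dist to any training RBP.
#' @slot confident logical, \code{TRUE} when \code{minEdist} is below the
#'   model's confidence cutoff (and the reconstruction is non-degenerate).
#'
#' @seealso [proteinQuery()], [rnaQuery()]
#' @exportClass JPLEQuery
setClass("JPLEQuery",
    representation(
        embedding = "numeric",
        source = "character",
        decoder = "character",
        edists = "numeric",
        esims = "numeric",
        neighborhood = "character",
        reconstruction = "numeric",
        minEdist = "numeric",
        confident = "logical"
    )
)

setValidity("JPLEQuery", function(object) {
    msg <- NULL
    if (!object@source %in% c("protein", "rna"))
        msg <- c(msg, "'source' must be 'protein' or 'rna'")
    if (length(object@edists) != length(object@esims))
        msg <- c(msg, "'edists' and 'esims' must have equal length")
    if (!all(is.finite(object@embedding)))
        msg <- c(msg, "embedding entries must be finite")
    if (is.null(msg)) TRUE else msg
})

#' Per-residue importance track over an RNA-binding region
#'
#' Residue importance scores (RIS) assign to every residue of an RBR the
#' summed, occurrence-normalized values of the reconstructed peptide
#' profile entries whose gapped 5-mer templates cover that residue.
#' Residues covered by no 5-residue window have score zero.
#'
#' @slot rbr the [RBR-class] the scores refer to.
#' @slot scores numeric vector, one score per RBR residue (concatenated
#'   over segments).
#' @slot positions integer vector of 1-based positions on the parent
#'   protein, parallel to \code{scores}.
#'
#' @seealso [residueImportance()], [interfaceMetrics()]
#' @exportClass ResidueImportance
setClass("ResidueImportance",
    representation(
        rbr = "RBR",
        scores = "numeric",
        positions = "integer"
    )
)

setValidity("ResidueImportance", function(object) {
    msg <- NULL
    n <- sum(nchar(object@rbr@segments))
    if (length(object@scores) != n)
        msg <- c(msg, "'scores' must have one entry per RBR residue")
    if (length(object@positions) != n)
        msg <- c(msg, "'positions' must have one entry per RBR residue")
    if (is.null(msg)) TRUE else msg
})

#' Simulated RNAcompete-style probe array
#'
#' Holds designed single-stranded RNA probe sequences together with one
#' measured intensity column per sample (protein extract).
#'
#' @slot probeIds character vector of unique probe identifiers.
#' @slot sequences character vector of RNA probe sequences (ACGU).
#' @slot intensities numeric matrix, probes x samples, finite.
#'
#' @seealso [genProbeArray()], [quantifyRNAcompete()]
#' @exportClass ProbeArray
setClass("ProbeArray",
    representation(
        probeIds = "character",
        sequences = "character",
        intensities = "matrix"
    )
)

setValidity("ProbeArray", function(object) {
    msg <- NULL
    n <- length(object@probeIds)
    if (anyDuplicated(object@probeIds))
        msg <- c(msg, "probe ids must be unique")
    if (length(object@sequences) != n || nrow(object@intensities) != n)
        msg <- c(msg, "probe ids, sequences and intensity rows must align")
    if (n > 0L && any(nchar(object@sequences) < 7L))
        msg <- c(msg, "every probe sequence must be at least 7 nt long")
    if (n > 0L && !all(is.finite(object@intensities)))
        msg <- c(msg, "intensities must be finite")
    if (is.null(msg)) TRUE else msg
})
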