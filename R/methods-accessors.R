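#' @rdname JPLEQuery-class
#' @aliases embedding,JPLEQuery-method
setMethod("embedding", "JPLEQuery", function(x) x@embedding)

#' @rdname JPLEQuery-class
setMethod("edists", "JPLEQuery", function(x) x@edists)

#' @rdname JPLEQuery-class
setMethod("esims", "JPLEQuery", function(x) x@esims)

#' @rdname JPLEQuery-class
setMethod("neighborhood", "JPLEQuery", function(x) x@neighborhood)

#' @rdname JPLEQuery-class
setMethod("reconstruction", "JPLEQuery", function(x) x@reconstruction)

#' @rdname JPLEQuery-class
setMethod("minEdist", "JPLEQuery", function(x) x@minEdist)

#' @rdname JPLEQuery-class
setMethod("isConfident", "JPLEQuery", function(x) x@confident)

#' @rdname JPLEModel-class
setMethod("trainingEmbeddings", "JPLEModel", function(x) x@W)

#' @rdname JPLEModel-class
setMethod("modelDim", "JPLEModel", function(x) x@d)

#' @rdname JPLEModel-class
setMethod("componentScores", "JPLEModel", function(x) x@scores)

#' @rdname RBR-class
setMethod("rbrSequence", "RBR",
    function(x) paste(x@segments, collapse = ""))

#' @rdname ResidueImportance-class
setMethod("risScores", "ResidueImportance", function(x) {
    out <- x@scores
    names(out) <- x@positions
    out
})

#' @rdname ResidueImportance-class
#' @return \code{risTrack} returns a data.frame with one row per RBR
#'   residue: protein id, 1-based residue position, residue and score.
setMethod("risTrack", "ResidueImportance", function(x) {
    data.frame(
        protein_id = x@rbr@proteinId,
        position = x@positions,
        residue = strsplit(rbrSequence(x@rbr), "")[[1L]],
        score = x@scores,
        stringsAsFactors = FALSE
    )
})

setMethod("show", "RBR", function(object) {
    cat("RBR for protein", object@proteinId, "\n")
    cat(sprintf("  %d segment(s), %d residues total\n",
        length(object@segments), sum(nchar(object@segments))))
    for (i in seq_along(object@segments))
        cat(sprintf("  [%d] %d-%d (%s)\n", i, object@segStart[i],
            object@segEnd[i], object@domainClasses[i]))
})

setMethod("show", "JPLEModel", function(object) {
    cat("JPLEModel\n")
    cat(sprintf("  training RBPs : %d\n", nrow(object@W)))
    cat(sprintf("  peptide block : %d kept / %d raw columns\n",
        nrow(object@Vp), length(object@prep$colsP)))
    cat(sprintf("  RNA block     : %d kept / %d raw columns\n",
        nrow(object@Vr), length(object@prep$colsR)))
    cat(sprintf("  dimension d   : %d\n", object@d))
    cat(sprintf(
        "  decoder       : gamma=%g, e-sim threshold=%g, e-dist cutoff=%g\n",
        object@gamma, object@nbhThreshold, object@confCutoff))
})

setMethod("show", "JPLEQuery", function(object) {
    cat(sprintf("JPLEQuery (%s query, %s decoding)\n",
        object@source, object@decoder))
    cat(sprintf("  min e-dist    : %.4f (%s)\n", object@minEdist,
        if (object@confident) "confident" else "not confident"))
    cat(sprintf("  neighborhood  : %d training RBP(s)\n",
        length(object@neighborhood)))
    cat(sprintf("  reconstruction: %d features\n",
        length(object@reconstruction)))
})

setMethod("show", "ResidueImportance", function(object) {
    cat("ResidueImportance for", object@rbr@proteinId, "\n")
    cat(sprintf("  %d residues, score range [%.3g, %.3g]\n",
        length(object@scores), min(object@scores), max(object@scores)))
})

setMethod("show", "ProbeArray", function(object) {
    cat(sprintf("ProbeArray: %d probes x %d sample(s), probe length %d-%d\n",
        length(object@probeIds), ncol(object@intensities),
        min(nchar(object@sequences)), max(nchar(object@sequences))))
})
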