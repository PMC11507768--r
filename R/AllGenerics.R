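#' @rdname JPLEQuery-class
#' @param object,x a [JPLEQuery-class], [JPLEModel-class],
#'   [ResidueImportance-class] or [RBR-class] object, as appropriate.
#' @export
setGeneric("embedding", function(x) standardGeneric("embedding"))

#' @rdname JPLEQuery-class
#' @export
setGeneric("edists", function(x) standardGeneric("edists"))

#' @rdname JPLEQuery-class
#' @export
setGeneric("esims", function(x) standardGeneric("esims"))

#' @rdname JPLEQuery-class
#' @export
setGeneric("neighborhood", function(x) standardGeneric("neighborhood"))

#' @rdname JPLEQuery-class
#' @export
setGeneric("reconstruction", function(x) standardGeneric("reconstruction"))

#' @rdname JPLEQuery-class
#' @export
setGeneric("minEdist", function(x) standardGeneric("minEdist"))

#' @rdname JPLEQuery-class
#' @export
setGeneric("isConfident", function(x) standardGeneric("isConfident"))

#' @rdname JPLEModel-class
#' @export
setGeneric("trainingEmbeddings",
    function(x) standardGeneric("trainingEmbeddings"))

#' @rdname JPLEModel-class
#' @export
setGeneric("modelDim", function(x) standardGeneric("modelDim"))

#' @rdname JPLEModel-class
#' @export
setGeneric("componentScores", function(x) standardGeneric("componentScores"))

#' @rdname RBR-class
#' @export
setGeneric("rbrSequence", function(x) standardGeneric("rbrSequence"))

#' @rdname ResidueImportance-class
#' @export
setGeneric("risScores", function(x) standardGeneric("risScores"))

#' @rdname ResidueImportance-class
#' @export
setGeneric("risTrack", function(x) standardGeneric("risTrack"))
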