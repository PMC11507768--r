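#' Enumerate the RNA 7-mer vocabulary
#'
#' Returns all 7-mers over the RNA alphabet \{A, C, G, U\} in
#' lexicographic order. The standard RNA-binding profile vocabulary
#' excludes the two 7-mers corresponding to the SapI/BspQI restriction
#' site used during array construction (printed in the DNA alphabet as
#' GCTCTTC and CGAGAAG, transliterated here to RNA), leaving 16,382 of
#' the 16,384 possible 7-mers.
#'
#' @param excludeRestriction drop the two restriction-site 7-mers
#'   (default \code{TRUE}).
#' @return character vector of 7-mer strings, lexicographically ordered.
#' @examples
#' length(enumerate7mers(FALSE))  # 16384
#' length(enumerate7mers(TRUE))   # 16382
#' @export
enumerate7mers <- function(excludeRestriction = TRUE) {
    km <- do.call(paste0,
        rev(expand.grid(rep(list(.RNA4), 7L),
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)))
    if (excludeRestriction)
        km <- setdiff(km, chartr("T", "U", .RESTRICTION_DNA))
    km
}

# The five gapped templates of one 5-residue window: the wildcard 'X'
# placed at each position in turn.
.windowTemplates <- function(window) {
    vapply(1:5, function(i) {
        s <- window
        substr(s, i, i) <- "X"
        s
    }, character(1L))
}

# All gapped 5-mer template instances of an RBR, one entry per
# (window, wildcard position). Windows never span segment boundaries and
# windows containing an unknown residue ('X') are skipped.
.templateInstances <- function(rbr) {
    out <- character(0L)
    for (seg in rbr@segments) {
        n <- nchar(seg)
        if (n < 5L) next
        starts <- seq_len(n - 4L)
        windows <- substring(seg, starts, starts + 4L)
        windows <- windows[!grepl("X", windows, fixed = TRUE)]
        if (!length(windows)) next
        out <- c(out, unlist(lapply(windows, .windowTemplates)))
    }
    out
}

#' Gapped peptide profile of an RNA-binding region
#'
#' Counts all gapped 5-mer peptide templates (four specified residues and
#' one wildcard, written \code{X}) over the 5-residue windows of an RBR.
#' Every window contributes five templates, one per wildcard placement;
#' windows never span segment boundaries, and windows containing an
#' unknown residue (\code{X} in the input sequence) are skipped because
#' they carry no usable evidence.
#'
#' On an input free of unknown residues the total count equals
#' \code{5 * sum(pmax(0, segment_length - 4))}.
#'
#' @param rbr an [RBR-class] as returned by [buildRBR()].
#' @return named integer vector of template counts (templates observed in
#'   this RBR only; absent templates are implicitly zero).
#' @seealso [peptideProfileMatrix()] to assemble profiles over a common
#'   vocabulary.
#' @examples
#' rbr <- buildRBR("MAAAAAK", "p1",
#'                 data.frame(domain_class = "RRM", start = 2, end = 6),
#'                 flank = 0)
#' peptideProfile(rbr)
#' @export
peptideProfile <- function(rbr) {
    stopifnot(is(rbr, "RBR"))
    inst <- .templateInstances(rbr)
    if (!length(inst)) {
        warning("empty peptide profile for protein '", rbr@proteinId,
                "': no 'X'-free 5-residue window in any segment")
        return(structure(integer(0L), names = character(0L)))
    }
    tab <- table(inst)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    counts[order(names(counts))]
}

#' Assemble peptide profiles into a count matrix
#'
#' Builds the training matrix P' from a list of per-protein peptide
#' profiles, over the union of all observed templates (or a caller-fixed
#' vocabulary).
#'
#' @param profiles named list of profiles from [peptideProfile()].
#' @param vocabulary optional character vector fixing the column set and
#'   order; templates outside it are dropped.
#' @return numeric matrix, proteins x templates.
#' @export
peptideProfileMatrix <- function(profiles, vocabulary = NULL) {
    stopifnot(is.list(profiles), length(profiles) > 0L)
    if (is.null(names(profiles)) || anyDuplicated(names(profiles)))
        stop("'profiles' must have unique names")
    if (is.null(vocabulary))
        vocabulary <- sort(unique(unlist(lapply(profiles, names),
                                         use.names = FALSE)))
    out <- matrix(0, nrow = length(profiles), ncol = length(vocabulary),
                  dimnames = list(names(profiles), vocabulary))
    for (i in seq_along(profiles)) {
        p <- profiles[[i]]
        p <- p[names(p) %in% vocabulary]
        if (length(p)) out[i, names(p)] <- p
    }
    out
}
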