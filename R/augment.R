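#' Homolog-augmented peptide profiles
#'
#' For RNA queries the peptide representation of each training RBP is
#' enriched with the peptides of its close homologs (the callers is
#' expected to restrict homologs to a sensible identity band, e.g.
#' 50-99\% to any measured RBP, using [rbrSid()]). Homologs are supplied
#' as a gapped alignment block per training RBP. At every alignment
#' start position the distinct 5-mer peptides observed across homologs
#' each contribute their five gapped templates, and the position's
#' contribution is divided by the number of distinct peptides observed
#' there, so redundant homologs do not inflate the profile: a single
#' homolog identical to the training RBR reproduces its unaugmented
#' profile exactly. Windows never span gap columns (a gapped window is
#' not a real peptide).
#'
#' @param rbrs named list of training [RBR-class] objects.
#' @param alignments named list (same names) of character vectors; each
#'   vector holds the gapped homolog sequences of one training RBP, all
#'   of equal width. An empty vector falls back to the RBP's own
#'   unaugmented profile with a warning.
#' @param vocabulary optional template vocabulary fixing the columns of
#'   the returned matrix.
#' @return numeric matrix P+ (RBPs x templates), ready to replace the
#'   raw peptide block in [jple()].
#' @export
buildAugmentedProfiles <- function(rbrs, alignments, vocabulary = NULL) {
    stopifnot(is.list(rbrs), is.list(alignments))
    if (!identical(sort(names(rbrs)), sort(names(alignments))))
        stop("'rbrs' and 'alignments' must share the same names")
    profiles <- lapply(names(rbrs), function(id) {
        aln <- alignments[[id]]
        if (!length(aln)) {
            warning("no homologs for '", id,
                    "': using its own peptide profile")
            p <- peptideProfile(rbrs[[id]])
            return(p)
        }
        .augmentedProfile(aln)
    })
    names(profiles) <- names(rbrs)
    peptideProfileMatrix(profiles, vocabulary = vocabulary)
}

# Accumulate gapped 5-mer templates over an alignment block: per start
# column, distinct peptides each weighted by 1 / (number of distinct
# peptides at that column).
.augmentedProfile <- function(aln) {
    width <- unique(nchar(aln))
    if (length(width) != 1L)
        stop("alignment rows must have equal width")
    acc <- new.env(parent = emptyenv())
    for (j in seq_len(width - 4L)) {
        block <- substring(aln, j, j + 4L)
        ok <- !grepl("-", block, fixed = TRUE) &
              !grepl("X", block, fixed = TRUE) &
              nchar(block) == 5L
        peps <- unique(block[ok])
        if (!length(peps)) next
        wgt <- 1 / length(peps)
        for (pep in peps) {
            for (tpl in .windowTemplates(pep)) {
                prev <- if (exists(tpl, envir = acc, inherits = FALSE))
                    get(tpl, envir = acc) else 0
                assign(tpl, prev + wgt, envir = acc)
            }
        }
    }
    nm <- ls(acc)
    out <- vapply(nm, get, numeric(1L), envir = acc)
    names(out) <- nm
    out[order(names(out))]
}
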