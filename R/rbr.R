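#' Build the RNA-binding region of a protein
#'
#' Extends each annotated RNA-binding domain by a fixed flank of residues
#' on both sides (default 15, capturing linkers and termini), clips the
#' extended intervals to the sequence bounds, and merges overlapping or
#' adjacent intervals into segments. The resulting [RBR-class] is the
#' substrate for peptide-profile featurization and residue importance
#' scoring.
#'
#' @param sequence amino-acid sequence of the protein (single string,
#'   upper case, 20 canonical residues plus \code{X}).
#' @param proteinId identifier of the protein.
#' @param domains data.frame with columns \code{domain_class},
#'   \code{start}, \code{end} (1-based inclusive), as returned by
#'   [readDomainTable()] (rows for this protein only).
#' @param flank non-negative integer, residues added on each side of each
#'   domain.
#' @return an [RBR-class] object.
#' @examples
#' buildRBR(strrep("A", 100), "p1",
#'          data.frame(domain_class = "RRM", start = 40, end = 60))
#' @export
buildRBR <- function(sequence, proteinId, domains, flank = 15L) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    .validAASeq(sequence)
    .assertScalarNumeric(flank, "flank", lower = 0)
    if (is.null(domains) || nrow(domains) == 0L)
        stop("no RBDs for protein '", proteinId, "'")
    len <- nchar(sequence)
    if (any(domains$start < 1L) || any(domains$end > len) ||
        any(domains$start > domains$end))
        stop("domain coordinates out of bounds for protein '",
             proteinId, "'")
    ext <- IRanges::IRanges(
        start = pmax(1L, domains$start - as.integer(flank)),
        end = pmin(len, domains$end + as.integer(flank))
    )
    merged <- IRanges::reduce(ext)
    hits <- IRanges::findOverlaps(ext, merged)
    classes <- vapply(seq_along(merged), function(i) {
        paste(domains$domain_class[S4Vectors::queryHits(hits)[
            S4Vectors::subjectHits(hits) == i]], collapse = ",")
    }, character(1L))
    new("RBR",
        proteinId = as.character(proteinId),
        segments = substring(sequence, IRanges::start(merged),
                             IRanges::end(merged)),
        segStart = IRanges::start(merged),
        segEnd = IRanges::end(merged),
        domainClasses = classes)
}

# Per-domain subsequences (domain plus flank, clipped, NOT merged) --
# the units aligned by the pairwise sequence-identity machinery.
.domainSequences <- function(sequence, domains, flank = 15L) {
    len <- nchar(sequence)
    ord <- order(domains$start)
    domains <- domains[ord, , drop = FALSE]
    s <- pmax(1L, domains$start - as.integer(flank))
    e <- pmin(len, domains$end + as.integer(flank))
    list(seqs = substring(sequence, s, e),
         classes = as.character(domains$domain_class))
}
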