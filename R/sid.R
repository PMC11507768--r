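#' Global pairwise alignment and amino-acid sequence identity
#'
#' Aligns two amino-acid sequences with Needleman-Wunsch (BLOSUM62,
#' affine gaps: opening 11, extension 1 per residue) and reports the
#' sequence identity. The default identity denominator is the full
#' alignment length including gap columns (conservative); the
#' alternative \code{"shorter"} divides by the shorter input length, the
#' convention sometimes used when contrasting families of unequal
#' domain counts.
#'
#' @param a,b amino-acid sequences (single strings).
#' @param denominator \code{"alignment"} (default) or \code{"shorter"}.
#' @return list with \code{alignedA}, \code{alignedB} (gapped strings),
#'   \code{score} (alignment score) and \code{identity} (fraction in
#'   [0, 1]).
#' @export
nwIdentity <- function(a, b, denominator = c("alignment", "shorter")) {
    denominator <- match.arg(denominator)
    stopifnot(is.character(a), length(a) == 1L, nzchar(a),
              is.character(b), length(b) == 1L, nzchar(b))
    .validAASeq(a, "a"); .validAASeq(b, "b")
    pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        substitutionMatrix = "BLOSUM62",
        gapOpening = 11, gapExtension = 1, type = "global")
    alnA <- as.character(Biostrings::alignedPattern(pa))
    alnB <- as.character(Biostrings::alignedSubject(pa))
    chA <- strsplit(alnA, "")[[1L]]
    chB <- strsplit(alnB, "")[[1L]]
    matches <- sum(chA == chB & chA != "-")
    den <- switch(denominator,
        alignment = nchar(alnA),
        shorter = min(nchar(a), nchar(b)))
    list(alignedA = alnA, alignedB = alnB,
         score = Biostrings::score(pa), identity = matches / den)
}

#' Domain-aware sequence identity between two RNA-binding regions
#'
#' Aligns two RBRs domain by domain: each RBD (with flanks) of one
#' protein is aligned to an RBD of the other with [nwIdentity()]. With
#' equal domain counts, corresponding domains are paired in order and
#' the mean per-pair identity is returned. With unequal counts, all
#' contiguous placements of the shorter architecture onto the longer one
#' are enumerated (adjacent domains stay adjacent, accounting for domain
#' duplications and deletions), and the placement with the maximal mean
#' identity wins. A placement is only admissible when the paired domain
#' classes match.
#'
#' @param seqA,seqB full protein sequences.
#' @param domainsA,domainsB data.frames with columns
#'   \code{domain_class}, \code{start}, \code{end}.
#' @param flank residues added around each domain before alignment.
#' @param denominator passed to [nwIdentity()].
#' @return sequence identity in [0, 1].
#' @export
rbrSid <- function(seqA, domainsA, seqB, domainsB, flank = 15L,
                   denominator = c("alignment", "shorter")) {
    denominator <- match.arg(denominator)
    da <- .domainSequences(seqA, domainsA, flank)
    db <- .domainSequences(seqB, domainsB, flank)
    if (length(da$seqs) == 0L || length(db$seqs) == 0L)
        stop("both proteins need at least one annotated RBD")
    if (length(da$seqs) > length(db$seqs)) {
        tmp <- da; da <- db; db <- tmp
    }
    nA <- length(da$seqs)
    nB <- length(db$seqs)
    best <- -Inf
    for (s in 0:(nB - nA)) {
        idx <- seq_len(nA) + s
        if (!all(da$classes == db$classes[idx])) next
        ids <- vapply(seq_len(nA), function(i)
            nwIdentity(da$seqs[i], db$seqs[idx[i]],
                       denominator = denominator)$identity,
            numeric(1L))
        best <- max(best, mean(ids))
    }
    if (!is.finite(best))
        stop("no placement with compatible domain classes")
    best
}

#' Homology-transfer baseline for RNA specificity (the 70\% rule)
#'
#' Assigns to a query protein the RNA-binding profile of the reference
#' RBP with the highest domain-aware amino-acid sequence identity
#' ([rbrSid()]). The inference is flagged confident when that identity
#' reaches \code{minSid} (default 0.70, the classical transfer
#' threshold); the identity doubles as the confidence score.
#'
#' @param querySeq,queryDomains query protein sequence and RBD table.
#' @param references list of reference entries, each a list with
#'   elements \code{sequence}, \code{domains} and \code{profile} (and
#'   optionally \code{id}).
#' @param minSid identity threshold for a confident transfer.
#' @param flank residues added around each domain before alignment.
#' @return list with \code{profile}, \code{sid}, \code{confident} and
#'   \code{reference} (index or id of the chosen reference).
#' @export
inferBySid <- function(querySeq, queryDomains, references,
                       minSid = 0.70, flank = 15L) {
    stopifnot(is.list(references), length(references) > 0L)
    .assertScalarNumeric(minSid, "minSid", lower = 0, upper = 1)
    sids <- vapply(references, function(ref)
        rbrSid(querySeq, queryDomains, ref$sequence, ref$domains,
               flank = flank), numeric(1L))
    bestIdx <- which.max(sids)
    if (sum(sids >= sids[bestIdx] - 1e-12) > 1L)
        warning("tied best sequence identity; keeping the first ",
                "reference in list order")
    ref <- references[[bestIdx]]
    list(profile = ref$profile, sid = sids[bestIdx],
         confident = sids[bestIdx] >= minSid,
         reference = if (!is.null(ref$id)) ref$id else bestIdx)
}

#' Pairwise identities from a multiple sequence alignment
#'
#' For every pair of rows in a gapped MSA block, counts the columns
#' where both rows carry the same residue (gap positions never match)
#' and divides by the alignment length. Returns a symmetric matrix with
#' unit diagonal.
#'
#' @param msa named character vector of equal-length gapped sequences.
#' @return numeric identity matrix.
#' @export
msaSid <- function(msa) {
    stopifnot(is.character(msa), length(msa) >= 2L)
    width <- unique(nchar(msa))
    if (length(width) != 1L)
        stop("MSA rows must have equal length")
    chars <- do.call(rbind, strsplit(msa, ""))
    n <- length(msa)
    out <- diag(1, n)
    for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
            m <- sum(chars[i, ] == chars[j, ] & chars[i, ] != "-")
            out[i, j] <- out[j, i] <- m / width
        }
    }
    dimnames(out) <- list(names(msa), names(msa))
    out
}
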