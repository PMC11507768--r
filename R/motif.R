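#' Call specifically bound 7-mers
#'
#' A 7-mer is called specifically bound when its Z-score corresponds to
#' an upper-tail standard-normal p-value passing a Bonferroni-corrected
#' Z-test at the requested family-wise error rate (default 1\% over the
#' whole vocabulary).
#'
#' @param profile named numeric vector of Z-transformed 7-mer scores.
#' @param fwer family-wise error rate, in (0, 1).
#' @return character vector of called 7-mers (possibly empty).
#' @export
specific7mers <- function(profile, fwer = 0.01) {
    .assertScalarNumeric(fwer, "fwer", lower = 0, upper = 1,
                         openLower = TRUE, openUpper = TRUE)
    if (is.null(names(profile)))
        stop("'profile' must be a named vector of 7-mer Z-scores")
    p <- stats::pnorm(profile, lower.tail = FALSE)
    names(profile)[p <= fwer / length(profile)]
}

# Consensus base of a count column; ties resolved in A < C < G < U order.
.consensus <- function(counts) .RNA4[apply(counts, 2L, which.max)]

#' Position frequency matrix from the top-scoring 7-mers
#'
#' Builds a PFM by aligning the \code{topN} highest-scoring 7-mers
#' without gaps: the top 7-mer seeds the alignment, and each further
#' 7-mer (in rank order) is placed at the ungapped offset (within +/- 6,
#' any overlap of at least one column) that maximizes identity to the
#' running consensus; offset ties prefer the smaller absolute offset,
#' then the negative one. Count columns are normalized by their
#' coverage, i.e. the number of placed 7-mers overlapping each column.
#'
#' @param profile named numeric vector of 7-mer scores.
#' @param topN number of top 7-mers aligned (default 10).
#' @return 4 x width numeric matrix (rows A, C, G, U) whose columns sum
#'   to 1, with a \code{"support"} attribute giving per-column coverage.
#' @seealso [psamFromPfm()], [writeMemePfm()]
#' @export
pfmFromTopKmers <- function(profile, topN = 10L) {
    .assertScalarNumeric(topN, "topN", lower = 1)
    if (is.null(names(profile)))
        stop("'profile' must be a named vector of 7-mer scores")
    topN <- min(as.integer(topN), length(profile))
    top <- names(profile)[order(-profile)][seq_len(topN)]

    # columns indexed relative to the seed's first base (position 1)
    counts <- matrix(0, 4L, 7L, dimnames = list(.RNA4, NULL))
    origin <- 1L    # alignment column of matrix column 1
    addKmer <- function(counts, origin, kmer, offset) {
        colIdx <- offset + 1:7          # alignment columns of this kmer
        lo <- min(colIdx, origin)
        hi <- max(colIdx, origin + ncol(counts) - 1L)
        if (lo < origin || hi > origin + ncol(counts) - 1L) {
            wider <- matrix(0, 4L, hi - lo + 1L,
                            dimnames = list(.RNA4, NULL))
            wider[, (origin - lo + 1L):(origin - lo + ncol(counts))] <-
                counts
            counts <- wider
            origin <- lo
        }
        bases <- strsplit(kmer, "")[[1L]]
        for (k in 1:7)
            counts[bases[k], colIdx[k] - origin + 1L] <-
                counts[bases[k], colIdx[k] - origin + 1L] + 1
        list(counts = counts, origin = origin)
    }

    st <- addKmer(counts, origin, top[1L], 0L)
    if (topN > 1L) {
        for (kmer in top[-1L]) {
            cons <- .consensus(st$counts)
            consCols <- st$origin + seq_len(ncol(st$counts)) - 1L
            bases <- strsplit(kmer, "")[[1L]]
            best <- NULL
            for (off in -6:6) {
                cols <- off + 1:7
                ov <- match(cols, consCols)
                sel <- !is.na(ov)
                if (!any(sel)) next
                ident <- sum(bases[sel] == cons[ov[sel]])
                cand <- c(ident = ident, absOff = abs(off), off = off)
                if (is.null(best) ||
                    cand["ident"] > best["ident"] ||
                    (cand["ident"] == best["ident"] &&
                     (cand["absOff"] < best["absOff"] ||
                      (cand["absOff"] == best["absOff"] &&
                       cand["off"] < best["off"]))))
                    best <- cand
            }
            st <- addKmer(st$counts, st$origin, kmer, as.integer(best["off"]))
        }
    }
    support <- colSums(st$counts)
    pfm <- sweep(st$counts, 2L, support, "/")
    attr(pfm, "support") <- as.integer(support)
    pfm
}

#' Position-specific affinity matrix from a PFM
#'
#' Rescales every PFM column so that its maximum entry is exactly 1,
#' turning frequencies into relative affinities whose best possible
#' match scores 1 per position.
#'
#' @param pfm a PFM as returned by [pfmFromTopKmers()].
#' @return 4 x width matrix with per-column maximum 1.
#' @export
psamFromPfm <- function(pfm) {
    stopifnot(is.matrix(pfm), nrow(pfm) == 4L)
    mx <- apply(pfm, 2L, max)
    if (any(mx == 0))
        stop("PFM column(s) are all zero: ",
             paste(which(mx == 0), collapse = ", "))
    out <- sweep(pfm, 2L, mx, "/")
    attr(out, "support") <- NULL
    out
}

#' Binding score of a PSAM on an RNA sequence
#'
#' Slides the PSAM over the sequence; the score of each position is the
#' product of the matching affinity entries along the motif. Because
#' PSAM columns are max-normalized, the maximum possible position score
#' is 1, and the binding score of the sequence is the sum of all
#' position scores exceeding \code{thresholdFrac} of that maximum.
#'
#' @param psam a PSAM from [psamFromPfm()].
#' @param sequence RNA string (T is transliterated to U).
#' @param thresholdFrac fraction of the maximum position score below
#'   which windows are ignored (default 0.1).
#' @return single numeric binding score (0 when the sequence is shorter
#'   than the motif, with a warning).
#' @export
scanBindingScore <- function(psam, sequence, thresholdFrac = 0.1) {
    stopifnot(is.matrix(psam), nrow(psam) == 4L)
    .assertScalarNumeric(thresholdFrac, "thresholdFrac", lower = 0,
                         upper = 1)
    sequence <- chartr("T", "U", toupper(sequence))
    W <- ncol(psam)
    L <- nchar(sequence)
    if (L < W) {
        warning("sequence shorter than the motif: binding score 0")
        return(0)
    }
    rows <- match(strsplit(sequence, "")[[1L]], .RNA4)
    if (anyNA(rows))
        stop("sequence contains non-ACGU characters")
    npos <- L - W + 1L
    s <- rep(1, npos)
    for (j in seq_len(W))
        s <- s * psam[cbind(rows[seq_len(npos) + j - 1L], j)]
    sum(s[s > thresholdFrac])
}
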