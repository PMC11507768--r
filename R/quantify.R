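#' Construct a probe array
#'
#' @param probeIds unique probe identifiers.
#' @param sequences RNA probe sequences (ACGU, length >= 7; T is
#'   transliterated to U).
#' @param intensities numeric matrix or vector of measured intensities,
#'   one row per probe and one column per sample.
#' @return a [ProbeArray-class].
#' @export
probeArray <- function(probeIds, sequences, intensities) {
    if (is.null(dim(intensities)))
        intensities <- matrix(intensities, ncol = 1L,
                              dimnames = list(NULL, "sample1"))
    sequences <- chartr("T", "U", toupper(sequences))
    new("ProbeArray", probeIds = as.character(probeIds),
        sequences = sequences, intensities = intensities)
}

# Long table of (kmer, probe index) pairs for all 7-mer occurrences; a
# probe containing a 7-mer several times is counted once.
.kmerProbePairs <- function(sequences) {
    lens <- nchar(sequences)
    nWin <- pmax(0L, lens - 6L)
    probe <- rep.int(seq_along(sequences), nWin)
    start <- sequence(nWin)
    dt <- data.table::data.table(
        kmer = substring(sequences[probe], start, start + 6L),
        probe = probe)
    unique(dt, by = c("kmer", "probe"))
}

#' Quantify probe intensities into a 7-mer Z-score profile
#'
#' Implements the RNAcompete quantification pipeline on a probe array:
#' (1) intensities are centered and variance-normalized per sample
#' (columns) and then, when several samples are present, per probe
#' (rows), controlling for RNA and protein concentration effects; (2)
#' for each 7-mer of the vocabulary, the normalized intensities of the
#' probes containing it are collected, the top and bottom 2.5\% are
#' discarded (\code{ceiling(0.025 n)} from each tail, deterministic
#' ties), and the mean of the inner 95\% is taken; (3) the 7-mer means
#' are Z-transformed to mean 0 and standard deviation 1 (population
#' denominator).
#'
#' With a single sample the per-probe normalization step is skipped (it
#' would annihilate a single column); per-probe effects then remain as
#' noise that the trimmed mean and the probe count must average out.
#'
#' 7-mers contained in no probe are assigned the minimum observed score
#' before the Z-transform, with a warning.
#'
#' @param array a [ProbeArray-class].
#' @param sample column index or name of the sample to quantify.
#' @param kmers the 7-mer vocabulary (defaults to the standard 16,382).
#' @return named numeric vector of Z-scores over \code{kmers}.
#' @export
quantifyRNAcompete <- function(array, sample = 1L,
                               kmers = enumerate7mers(TRUE)) {
    stopifnot(is(array, "ProbeArray"))
    I <- array@intensities
    if (is.character(sample)) sample <- match(sample, colnames(I))
    if (is.na(sample) || sample < 1L || sample > ncol(I))
        stop("sample not found in probe array")

    sds <- apply(I, 2L, stats::sd)
    if (any(sds == 0))
        stop("degenerate probe array: zero intensity variance in ",
             "sample(s) ", paste(which(sds == 0), collapse = ", "))
    I <- scale(I)                                     # per sample
    if (ncol(I) >= 2L) {                              # then per probe
        rm_ <- rowMeans(I)
        rsd <- sqrt(rowSums((I - rm_)^2) / (ncol(I) - 1L))
        I <- (I - rm_) / ifelse(rsd == 0, 1, rsd)
        I[rsd == 0, ] <- 0
    }
    x <- I[, sample]

    pairs <- .kmerProbePairs(array@sequences)
    pairs <- pairs[pairs$kmer %in% kmers]
    val <- NULL  # NSE placate
    pairs[, val := x[probe]]
    trimmedMean <- function(v) {
        n <- length(v)
        k <- ceiling(0.025 * n)
        if (n - 2L * k < 1L) return(mean(v))
        mean(sort(v, method = "radix")[(k + 1L):(n - k)])
    }
    agg <- pairs[, list(score = trimmedMean(val)), by = "kmer"]
    means <- structure(rep(NA_real_, length(kmers)), names = kmers)
    means[agg$kmer] <- agg$score

    miss <- is.na(means)
    if (any(miss)) {
        shown <- utils::head(names(means)[miss], 10L)
        warning(sum(miss), " 7-mer(s) contained in no probe were set ",
                "to the minimum score: ", paste(shown, collapse = ", "),
                if (sum(miss) > 10L) ", ..." else "")
        means[miss] <- min(means, na.rm = TRUE)
    }
    s <- .popSd(means)
    if (s == 0)
        stop("degenerate quantification: all 7-mer scores identical")
    (means - mean(means)) / s
}
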