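## Readers and writers for the formats the pipeline consumes and emits:
## protein FASTA, domain-annotation tables, k-mer matrices, MEME motifs,
## and the serialized model container. Coordinates are 1-based inclusive
## in all files; the single conversion to internal representations
## happens here.

.MODEL_VERSION <- "jple-model-1"

#' Read protein sequences from FASTA
#'
#' Sequences are upper-cased and trailing stop characters (\code{*}) are
#' stripped. Identifiers are the first whitespace-delimited token of each
#' header and must be unique.
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @return named character vector of protein sequences.
#' @export
readProteinFasta <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    aa <- Biostrings::readBStringSet(path)
    if (length(aa) == 0L) stop("empty FASTA file: ", path)
    ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1L), 1L)
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate sequence id(s) in ", path, ": ",
             paste(dup, collapse = ", "))
    seqs <- toupper(gsub("*", "", as.character(aa), fixed = TRUE))
    if (any(!nzchar(seqs)))
        stop("empty sequence(s): ",
             paste(ids[!nzchar(seqs)], collapse = ", "))
    for (i in seq_along(seqs)) .validAASeq(seqs[i], name = ids[i])
    names(seqs) <- ids
    seqs
}

#' Read an RNA-binding-domain annotation table
#'
#' Expects a tab-separated file with a header row and columns
#' \code{protein_id}, \code{domain_class}, \code{start}, \code{end}
#' (1-based inclusive). Domain classes other than RRM and KH are kept but
#' downgraded to \code{"other"} with a warning.
#'
#' @param path path to the TSV file.
#' @return data.frame with the four validated columns.
#' @export
readDomainTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("protein_id", "domain_class", "start", "end")
    missing <- setdiff(need, colnames(df))
    if (length(missing))
        stop("domain table is missing column(s): ",
             paste(missing, collapse = ", "))
    df <- df[, need]
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
    bad <- which(is.na(df$start) | is.na(df$end) | df$start < 1L |
                 df$start > df$end)
    if (length(bad))
        stop("invalid domain coordinates (start > end or non-positive) ",
             "at row(s): ", paste(bad, collapse = ", "))
    unknown <- !df$domain_class %in% c("RRM", "KH", "other")
    if (any(unknown)) {
        warning("unknown domain class(es) set to 'other': ",
                paste(unique(df$domain_class[unknown]), collapse = ", "))
        df$domain_class[unknown] <- "other"
    }
    df
}

#' Read / write a k-mer matrix
#'
#' A k-mer matrix is a TSV whose first column holds row identifiers
#' (RBPs or constructs) and whose remaining columns are labelled by k-mer
#' strings -- the on-disk form of both peptide-profile matrices (P') and
#' RNA 7-mer Z-score matrices (R').
#'
#' @param path path of the TSV file.
#' @return \code{readKmerMatrix} returns a numeric matrix with row and
#'   column names.
#' @export
readKmerMatrix <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = "character", fill = FALSE)
    if (ncol(dt) < 2L) stop("k-mer matrix needs an id column plus ",
                            "at least one k-mer column: ", path)
    ids <- dt[[1L]]
    kmers <- colnames(dt)[-1L]
    if (anyDuplicated(ids))
        stop("duplicate row id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (anyDuplicated(kmers))
        stop("duplicate k-mer column(s): ",
             paste(unique(kmers[duplicated(kmers)]), collapse = ", "))
    vals <- suppressWarnings(
        vapply(kmers, function(k) as.numeric(dt[[k]]), numeric(nrow(dt))))
    vals <- matrix(vals, nrow = nrow(dt),
                   dimnames = list(ids, kmers))
    if (anyNA(vals)) {
        idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
        stop("non-numeric value at row '", ids[idx[1L]], "', column '",
             kmers[idx[2L]], "' in ", path)
    }
    vals
}

#' @rdname readKmerMatrix
#' @param x numeric matrix with row and column names.
#' @param idColumn name for the identifier column written first.
#' @export
writeKmerMatrix <- function(x, path, idColumn = "id") {
    stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
    dt <- data.table::data.table(rownames(x))
    data.table::setnames(dt, idColumn)
    dt <- cbind(dt, data.table::as.data.table(x))
    data.table::fwrite(dt, path, sep = "\t")
    invisible(path)
}

#' Write a position frequency matrix in MEME minimal format
#'
#' @param pfm numeric matrix, 4 rows named A, C, G, U, one column per
#'   motif position; every column must sum to 1 within 1e-6.
#' @param path output file.
#' @param name motif name written to the MEME header.
#' @param nsites number of contributing sites recorded in the header.
#' @export
writeMemePfm <- function(pfm, path, name = "motif1", nsites = 10L) {
    stopifnot(is.matrix(pfm), nrow(pfm) == 4L)
    if (!identical(rownames(pfm), .RNA4))
        stop("'pfm' rows must be named A, C, G, U")
    sums <- colSums(pfm)
    if (any(abs(sums - 1) > 1e-6))
        stop("PFM column(s) do not sum to 1: ",
             paste(which(abs(sums - 1) > 1e-6), collapse = ", "))
    lines <- c(
        "MEME version 4", "",
        "ALPHABET= ACGU", "",
        "strands: +", "",
        "Background letter frequencies",
        "A 0.25 C 0.25 G 0.25 U 0.25", "",
        paste("MOTIF", name),
        sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                ncol(pfm), as.integer(nsites)),
        apply(pfm, 2L, function(col) paste(sprintf("%.6f", col),
                                           collapse = " "))
    )
    writeLines(lines, path)
    invisible(path)
}

#' Save / load a fitted JPLE model
#'
#' The container is a single serialized keyed bundle holding every model
#' slot plus a format version tag; a load after save reproduces all
#' arrays bit-exactly.
#'
#' @param model a fitted [JPLEModel-class].
#' @param path file path for the container.
#' @export
saveModel <- function(model, path) {
    stopifnot(is(model, "JPLEModel"))
    payload <- list(
        version = .MODEL_VERSION,
        Vp = model@Vp, Vr = model@Vr,
        singularValues = model@singularValues,
        W = model@W, d = model@d, scores = model@scores,
        gamma = model@gamma, nbhThreshold = model@nbhThreshold,
        confCutoff = model@confCutoff,
        prep = model@prep, Rraw = model@Rraw
    )
    saveRDS(payload, path, version = 3L)
    invisible(path)
}

#' @rdname saveModel
#' @return \code{loadModel} returns the restored [JPLEModel-class].
#' @export
loadModel <- function(path) {
    if (!file.exists(path)) stop("model file not found: ", path)
    payload <- tryCatch(readRDS(path), error = function(e)
        stop("cannot read model container '", path,
             "' (corrupt or truncated): ", conditionMessage(e),
             call. = FALSE))
    if (!is.list(payload) || is.null(payload$version))
        stop("not a jple model container: ", path)
    if (!identical(payload$version, .MODEL_VERSION))
        stop("model container version '", payload$version,
             "' is not supported by this build (expected '",
             .MODEL_VERSION, "')")
    new("JPLEModel",
        Vp = payload$Vp, Vr = payload$Vr,
        singularValues = payload$singularValues,
        W = payload$W, d = payload$d, scores = payload$scores,
        gamma = payload$gamma, nbhThreshold = payload$nbhThreshold,
        confCutoff = payload$confCutoff,
        prep = payload$prep, Rraw = payload$Rraw,
        version = payload$version)
}
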