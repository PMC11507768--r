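## Independent oracles used by the tests. These deliberately share no
## code with the package implementation.

# Quadratic-space affine-gap global alignment score (Gotoh). Gap of
# length L costs open + L * ext, matching the scoring convention of the
# aligner under test.
gotohScore <- function(a, b, mat, open = 11, ext = 1) {
    A <- strsplit(a, "")[[1L]]
    B <- strsplit(b, "")[[1L]]
    n <- length(A); m <- length(B)
    NEG <- -1e18
    M <- matrix(NEG, n + 1L, m + 1L)
    X <- matrix(NEG, n + 1L, m + 1L)  # A residue over gap in B
    Y <- matrix(NEG, n + 1L, m + 1L)  # B residue over gap in A
    M[1L, 1L] <- 0
    for (i in seq_len(n)) X[i + 1L, 1L] <- -(open + i * ext)
    for (j in seq_len(m)) Y[1L, j + 1L] <- -(open + j * ext)
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            s <- mat[A[i], B[j]]
            M[i + 1L, j + 1L] <-
                max(M[i, j], X[i, j], Y[i, j]) + s
            X[i + 1L, j + 1L] <- max(
                M[i, j + 1L] - (open + ext),
                X[i, j + 1L] - ext,
                Y[i, j + 1L] - (open + ext))
            Y[i + 1L, j + 1L] <- max(
                M[i + 1L, j] - (open + ext),
                Y[i + 1L, j] - ext,
                X[i + 1L, j] - (open + ext))
        }
    }
    max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

# Score of a given (gapped) alignment under the same convention.
alignmentScore <- function(alnA, alnB, mat, open = 11, ext = 1) {
    A <- strsplit(alnA, "")[[1L]]
    B <- strsplit(alnB, "")[[1L]]
    stopifnot(length(A) == length(B))
    sc <- 0
    inGapA <- FALSE; inGapB <- FALSE
    for (k in seq_along(A)) {
        if (A[k] == "-") {
            sc <- sc - ext - if (inGapA) 0 else open
            inGapA <- TRUE; inGapB <- FALSE
        } else if (B[k] == "-") {
            sc <- sc - ext - if (inGapB) 0 else open
            inGapB <- TRUE; inGapA <- FALSE
        } else {
            sc <- sc + mat[A[k], B[k]]
            inGapA <- FALSE; inGapB <- FALSE
        }
    }
    sc
}

# Dense least-squares oracle for the encoders (normal equations with a
# pseudo-inverse fallback).
lstsqOracle <- function(A, b) {
    G <- crossprod(A)
    rhs <- crossprod(A, b)
    sol <- try(solve(G, rhs), silent = TRUE)
    if (inherits(sol, "try-error")) {
        sv <- svd(G)
        pos <- sv$d > max(sv$d) * 1e-12
        sol <- sv$v[, pos] %*% ((t(sv$u[, pos]) %*% rhs) / sv$d[pos])
    }
    as.vector(sol)
}

randomAA <- function(n, len) {
    aa <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")
    vapply(seq_len(n), function(i)
        paste(sample(aa, len, replace = TRUE), collapse = ""),
        character(1L))
}
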