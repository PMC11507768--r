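## Internal helpers shared across modules.

.datatable.aware <- TRUE

# 20 canonical amino acids; 'X' marks an unknown residue on input and the
# wildcard position in peptide templates.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.RNA4 <- c("A", "C", "G", "U")

# The assay vector printed in the array design is DNA; transliterated to
# the RNA alphabet where profiles live.
.RESTRICTION_DNA <- c("GCTCTTC", "CGAGAAG")

.popSd <- function(x) sqrt(mean((x - mean(x))^2))

.assertScalarNumeric <- function(x, name, lower = -Inf, upper = Inf,
                                 openLower = FALSE, openUpper = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop("'", name, "' must be a single finite number", call. = FALSE)
    lowOk <- if (openLower) x > lower else x >= lower
    highOk <- if (openUpper) x < upper else x <= upper
    if (!lowOk || !highOk)
        stop("'", name, "' out of range ", if (openLower) "(" else "[",
             lower, ", ", upper, if (openUpper) ")" else "]", call. = FALSE)
    invisible(x)
}

.validAASeq <- function(x, name = "sequence", allowX = TRUE) {
    alphabet <- if (allowX) c(.AA20, "X") else .AA20
    bad <- setdiff(unique(strsplit(x, "")[[1L]]), alphabet)
    if (length(bad))
        stop("invalid residue(s) in ", name, ": ",
             paste(bad, collapse = ", "), call. = FALSE)
    invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators do not perturb user code.
.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (!is.null(old))
                assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(seed)
    }
    force(expr)
}

# Pearson correlation between corresponding rows of two matrices.
.rowPcc <- function(A, B) {
    A <- A - rowMeans(A)
    B <- B - rowMeans(B)
    num <- rowSums(A * B)
    den <- sqrt(rowSums(A^2) * rowSums(B^2))
    out <- num / den
    out[den == 0] <- NA_real_
    out
}
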