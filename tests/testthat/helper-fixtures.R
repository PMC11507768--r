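## Shared fixtures, memoized so expensive objects are built once per
## test run.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(key, builder) {
    if (!exists(key, envir = .fixtureCache, inherits = FALSE))
        assign(key, builder(), envir = .fixtureCache)
    get(key, envir = .fixtureCache)
}

# Small random training pair with named rows/columns.
randomTraining <- function(n = 10L, p = 20L, r = 15L, seed = 7L) {
    set.seed(seed)
    P <- matrix(rpois(n * p, 2), n, p,
                dimnames = list(sprintf("rbp%02d", seq_len(n)),
                                sprintf("tpl%03d", seq_len(p))))
    R <- matrix(rnorm(n * r), n, r,
                dimnames = list(sprintf("rbp%02d", seq_len(n)),
                                sprintf("kmer%03d", seq_len(r))))
    list(P = P, R = R)
}

# Minimal hand-built model whose local decoder can be controlled
# exactly: d = 2, three mutually remote training embeddings.
toyLocalModel <- function(W, Rraw, gamma = 25, nbhThreshold = 0.01) {
    d <- ncol(W)
    p <- d          # peptide block carries the identity basis
    r <- ncol(Rraw)
    Vp <- diag(d)
    rownames(Vp) <- sprintf("t%d", seq_len(p))
    Vr <- matrix(0, r, d, dimnames = list(colnames(Rraw), NULL))
    new("JPLEModel",
        Vp = Vp, Vr = Vr, singularValues = rep(1, d), W = W,
        d = as.integer(d), scores = rep(1, d), gamma = gamma,
        nbhThreshold = nbhThreshold, confCutoff = 0.127,
        prep = list(
            keepP = rep(TRUE, p), keepR = rep(TRUE, r),
            muP = structure(numeric(p), names = rownames(Vp)),
            muR = structure(numeric(r), names = colnames(Rraw)),
            normP = rep(1, p), normR = rep(1, r),
            colsP = rownames(Vp), colsR = colnames(Rraw),
            rowIds = rownames(W)),
        Rraw = Rraw, version = "jple-model-1")
}

# The planted benchmark used for recovery tests: 12 families x 5
# members (60 proteins), planted templates, noise sd 0.1.
plantedBenchmark <- function() {
    memoFixture("plantedBenchmark", function() {
        fx <- genFamilies(12L, 5L, seed = 2024L)
        pm <- plantedModel(fx, nInformative = 3L, latentRank = 10L,
                           noiseSd = 0.1, seed = 2025L)
        R <- genProfiles(fx, pm)
        rbrs <- lapply(names(fx$proteins), function(id)
            buildRBR(fx$proteins[[id]], id,
                     fx$domains[fx$domains$protein_id == id, ]))
        names(rbrs) <- names(fx$proteins)
        profs <- lapply(rbrs, peptideProfile)
        P <- peptideProfileMatrix(profs)
        list(fx = fx, pm = pm, R = R, P = P, rbrs = rbrs,
             profiles = profs)
    })
}

# Noise-free diverse panel for RNA-query and residue-importance
# recovery: many small families, four unrelated families per
# specificity group, so interface templates recur across backgrounds.
plantedBenchmarkNoiseless <- function() {
    memoFixture("plantedBenchmarkNoiseless", function() {
        fx <- genFamilies(24L, 2L, seed = 501L, bands = c(0.9),
                          groupSize = 4L)
        pm <- plantedModel(fx, latentRank = 8L, noiseSd = 0,
                           seed = 502L)
        R <- genProfiles(fx, pm)
        rbrs <- lapply(names(fx$proteins), function(id)
            buildRBR(fx$proteins[[id]], id,
                     fx$domains[fx$domains$protein_id == id, ]))
        names(rbrs) <- names(fx$proteins)
        profs <- lapply(rbrs, peptideProfile)
        P <- peptideProfileMatrix(profs)
        list(fx = fx, pm = pm, R = R, P = P, rbrs = rbrs,
             model = jple(P, R))
    })
}

# The gapped templates that are deterministically co-present with a
# conserved interface peptide: windows overlapping the block by four
# residues with the wildcard masking the single variable position.
companionTemplates <- function(peptides) {
    unique(c(paste0("X", substr(peptides, 1L, 4L)),
             paste0(substr(peptides, 2L, 5L), "X")))
}

plantedBenchmarkModel <- function() {
    memoFixture("plantedBenchmarkModel", function() {
        bm <- plantedBenchmark()
        jple(bm$P, bm$R)
    })
}

# Deterministic toy RBR: the whole sequence as one segment.
toyRBR <- function(sequence, proteinId = "toy", domainClass = "RRM") {
    buildRBR(sequence, proteinId,
             data.frame(domain_class = domainClass, start = 1L,
                        end = nchar(sequence)),
             flank = 0L)
}
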