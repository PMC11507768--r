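test_that("preprocessing drops zero-variance columns and scales the rest", {
    P <- matrix(c(1, 1, 1,
                  0, 2, 1,
                  2, 0, 4), 3, 3,
                dimnames = list(c("a", "b", "c"), c("t1", "t2", "t3")))
    R <- matrix(c(0, 2, 1, 1, 0, 3), 3, 2,
                dimnames = list(c("a", "b", "c"), c("k1", "k2")))
    tm <- preprocessTraining(P, R)
    expect_false(tm$keepP[["t1"]])            # constant column dropped
    expect_true(all(abs(colMeans(tm$P)) < 1e-10))
    expect_true(all(abs(colSums(tm$P^2) - 1) < 1e-10))
    expect_true(all(abs(colSums(tm$R^2) - 1) < 1e-10))

    # closed form: column (0, 2) centers to (-1, 1), norm sqrt(2)
    P2 <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "t1"))
    R2 <- matrix(c(1, 5), 2, 1, dimnames = list(c("a", "b"), "k1"))
    tm2 <- preprocessTraining(P2, R2)
    expect_equal(unname(tm2$P[, 1L]), c(-1, 1) / sqrt(2))

    expect_error(preprocessTraining(P[1L, , drop = FALSE],
                                    R[1L, , drop = FALSE]),
                 "at least 2")
    Pc <- matrix(1, 3, 2, dimnames = list(c("a","b","c"), c("t1","t2")))
    expect_error(preprocessTraining(Pc, R), "zero variance")

    tr <- randomTraining(n = 10L, p = 20L, r = 15L, seed = 3L)
    tm3 <- preprocessTraining(tr$P, tr$R)
    expect_lt(max(abs(colMeans(tm3$P))), 1e-10)
    expect_lt(max(abs(colSums(tm3$P^2) - 1)), 1e-10)
})

test_that("dimension selection matches a brute-force scan", {
    set.seed(31)
    # exact low rank: reconstruction is perfect at the rank
    U <- matrix(rnorm(20 * 3), 20)
    V <- matrix(rnorm(30 * 3), 30)
    R <- U %*% t(V)
    expect_equal(selectDimension(R, 0.95), 3L)

    # pccMin = 1 on a full-rank matrix forces full rank (exactness to
    # machine precision triggers the documented fallback warning)
    Rf <- matrix(rnorm(8 * 12), 8)
    expect_equal(suppressWarnings(selectDimension(Rf, 1.0)), 8L)

    # signal + small noise: agree with an independent scan over d
    Rn <- U %*% t(V) + matrix(rnorm(20 * 30, sd = 0.05), 20)
    got <- selectDimension(Rn, 0.95)
    sv <- svd(Rn)
    scan <- NA_integer_
    for (d in seq_along(sv$d)) {
        rec <- sv$u[, 1:d, drop = FALSE] %*%
            (sv$d[1:d] * t(sv$v[, 1:d, drop = FALSE]))
        pcc <- vapply(seq_len(nrow(Rn)), function(i)
            cor(Rn[i, ], rec[i, ]), numeric(1))
        if (all(pcc >= 0.95)) { scan <- d; break }
    }
    expect_equal(got, scan)

    expect_error(selectDimension(Rn, 0), "pccMin")
    expect_error(selectDimension(Rn, 1.5), "pccMin")
})

test_that("joint fit scores components by RNA variance and conserves it", {
    # P all-noise, R rank-1: the retained axis carries R's variance
    set.seed(32)
    n <- 12L
    P <- matrix(rnorm(n * 5), n,
                dimnames = list(sprintf("r%02d", 1:n),
                                sprintf("t%02d", 1:5)))
    u <- rnorm(n)
    R <- outer(u, rnorm(40)) +
        matrix(rnorm(n * 40, sd = 1e-3), n)
    dimnames(R) <- list(rownames(P), sprintf("k%d", 1:40))
    tm <- preprocessTraining(P, R)
    m1 <- fitJoint(tm, 1L)
    varR <- sum(tm$R^2)
    expect_gt(max(componentScores(m1)) / varR, 0.99)
    # and that component is the retained one
    expect_equal(m1@singularValues,
                 svd(cbind(tm$P, tm$R))$d[which.max(componentScores(m1))])

    # variance conservation over all components
    expect_lt(abs(sum(componentScores(m1)) - varR), 1e-8)

    # monotone ranking of retained vs dropped scores
    tr <- randomTraining(n = 10L, p = 20L, r = 15L, seed = 5L)
    tm2 <- preprocessTraining(tr$P, tr$R)
    m4 <- fitJoint(tm2, 4L)
    retained <- sort(componentScores(m4), decreasing = TRUE)[1:4]
    expect_equal(sort(m4@singularValues^2 *
                      colSums(m4@Vr^2), decreasing = TRUE),
                 unname(retained), tolerance = 1e-8)

    # orthonormality of the stacked retained axes
    V <- rbind(m4@Vp, m4@Vr)
    expect_lt(max(abs(crossprod(V) - diag(4L))), 1e-8)

    expect_error(fitJoint(tm2, 50L), "rank")
})

test_that("full-rank models reproduce training rows exactly", {
    tr <- randomTraining(n = 8L, p = 14L, r = 10L, seed = 6L)
    tm <- preprocessTraining(tr$P, tr$R)
    rnk <- sum(svd(cbind(tm$P, tm$R))$d > 1e-10)
    m <- fitJoint(tm, rnk, Rraw = tr$R)
    for (i in c(1L, 5L)) {
        w <- trainingEmbeddings(m)[i, ]
        expect_lt(max(abs(decodeGlobal(w, m, "rna") - tr$R[i, ])), 1e-8)
        expect_lt(max(abs(decodeGlobal(w, m, "peptide") - tr$P[i, ])),
                  1e-8)
    }
    # truncated model: reconstruction error equals the SVD residual
    d <- rnk - 3L
    mt <- fitJoint(tm, d, Rraw = tr$R)
    J <- cbind(tm$P, tm$R)
    sv <- svd(J)
    keep <- order(-(sv$d^2 *
        colSums(sv$v[-(1:ncol(tm$P)), , drop = FALSE]^2)))[1:d]
    resid <- J - sv$u[, keep, drop = FALSE] %*%
        (sv$d[keep] * t(sv$v[, keep, drop = FALSE]))
    w1 <- trainingEmbeddings(mt)[1L, ]
    recon <- decodeGlobal(w1, mt, "rna")
    residRna <- resid[1L, -(1:ncol(tm$P))] * tm$normR
    expect_equal(unname(tr$R[1L, tm$keepR] - recon[tm$keepR]),
                 unname(residRna), tolerance = 1e-8)
})

test_that("encoders agree with a dense least-squares oracle", {
    tr <- randomTraining(n = 12L, p = 25L, r = 18L, seed = 8L)
    m <- jple(tr$P, tr$R, d = 6L)
    tm <- preprocessTraining(tr$P, tr$R)
    for (i in c(2L, 9L)) {
        wp <- embedProtein(tr$P[i, ], m)
        expect_equal(as.numeric(wp), lstsqOracle(m@Vp, tm$P[i, ]),
                     tolerance = 1e-8)
        wr <- embedRNA(tr$R[i, ], m)
        expect_equal(as.numeric(wr), lstsqOracle(m@Vr, tm$R[i, ]),
                     tolerance = 1e-8)
    }
    # a query equal to the stored column means preprocesses to zero
    w0 <- embedProtein(m@prep$muP, m)
    expect_equal(as.numeric(w0), numeric(modelDim(m)))

    # unseen features are ignored with a warning
    q <- c(tr$P[1L, ], ZZZZZ = 5)
    expect_warning(wq <- embedProtein(q, m), "ignored")
    expect_equal(as.numeric(wq), as.numeric(embedProtein(tr$P[1L, ], m)))

    expect_error(embedProtein(c(ZZZZZ = 1), m), "no features")
})

test_that("e-dist is a cosine distance with defined degenerate cases", {
    expect_equal(eDist(c(1, 2, 3), c(1, 2, 3)), 0)
    expect_equal(eDist(c(1, 0), c(0, 1)), 1)
    expect_equal(eDist(c(1, 1), c(-1, -1)), 2)
    expect_error(eDist(c(1, 2), c(1, 2, 3)), "dimension")
    expect_warning(d0 <- eDist(c(0, 0), c(1, 2)), "zero embedding")
    expect_equal(d0, 1)
})

test_that("the RBF kernel and neighborhood boundary have closed forms", {
    expect_equal(eSim(0.2, gamma = 25), exp(-1), tolerance = 1e-12)
    boundary <- sqrt(log(100) / 25)
    expect_equal(eSim(boundary, 25), 0.01, tolerance = 1e-12)
    expect_lt(eSim(boundary + 1e-9, 25), 0.01)
    expect_gt(eSim(boundary - 1e-9, 25), 0.01)
})

test_that("the local decoder averages neighborhood profiles by e-sim", {
    W <- rbind(a = c(1, 0), b = c(0, 1), c = c(-1, 0))
    Rraw <- rbind(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
    colnames(Rraw) <- c("k1", "k2", "k3")
    m <- toyLocalModel(W, Rraw)

    # single neighbor: exact profile
    loc <- decodeLocal(c(1, 0), m)
    expect_equal(loc$reconstruction, Rraw["a", ])
    expect_equal(loc$neighborhood, "a")

    # two neighbors at equal e-dist: unweighted mean
    locEq <- decodeLocal(c(1, 1) / sqrt(2), m)
    expect_setequal(locEq$neighborhood, c("a", "b"))
    expect_equal(locEq$reconstruction,
                 (Rraw["a", ] + Rraw["b", ]) / 2)

    # weights over the neighborhood sum to one
    wts <- locEq$esims[locEq$neighborhood] /
        sum(locEq$esims[locEq$neighborhood])
    expect_equal(sum(wts), 1)

    # empty neighborhood: (0, -1) is at e-dist >= 1 from all three
    # training embeddings, beyond the 0.01 e-sim boundary
    locEmpty <- decodeLocal(c(0, -1), m)
    expect_length(locEmpty$neighborhood, 0L)
    expect_true(locEmpty$empty)
    expect_true(all(locEmpty$reconstruction == 0))
})

test_that("protein queries retrieve themselves and flag confidence", {
    bm <- plantedBenchmark()
    m <- plantedBenchmarkModel()
    id <- rownames(bm$P)[1L]
    q <- proteinQuery(bm$profiles[[id]], m)
    expect_lt(minEdist(q), 0.05)
    expect_true(isConfident(q))
    expect_equal(names(which.min(edists(q))), id)
    expect_gt(cor(reconstruction(q), bm$R[id, ]), 0.9)

    # an unrelated random sequence is rejected as non-confident
    set.seed(41)
    junk <- peptideProfile(toyRBR(randomAA(1, 120L), "junk"))
    qj <- suppressWarnings(proteinQuery(junk, m))
    expect_false(isConfident(qj))
    expect_gt(minEdist(qj), 0.127)

    # global and local decoding agree inside a dense neighborhood
    qg <- proteinQuery(bm$profiles[[id]], m, decoder = "global")
    expect_gt(cor(reconstruction(qg), reconstruction(q)), 0.8)
})

test_that("RNA queries reconstruct informative peptide profiles", {
    tr <- randomTraining(n = 9L, p = 16L, r = 12L, seed = 44L)
    tm <- preprocessTraining(tr$P, tr$R)
    rnk <- sum(svd(cbind(tm$P, tm$R))$d > 1e-10)
    m <- fitJoint(tm, rnk, Rraw = tr$R)
    q <- rnaQuery(tr$R[3L, ], m)
    expect_gt(cor(reconstruction(q), tr$P[3L, ]), 0.9)

    # a zero embedding decodes to the column means
    expect_equal(decodeGlobal(numeric(modelDim(m)), m, "peptide"),
                 m@prep$muP)

    # planted-truth recovery: top reconstructed templates are the
    # informative ones (noise-free fixture). The truth set includes
    # the flank-companion templates that are exactly collinear with
    # each conserved block (wildcard masking the one variable
    # position of a 4-residue-overlap window): no linear model can
    # separate them from the planted templates.
    bm0 <- plantedBenchmarkNoiseless()
    m0 <- bm0$model
    for (fam in c("1", "2")) {
        id <- sprintf("fam%02d_m01", as.integer(fam))
        peps <- bm0$pm$peptides[[fam]]
        truth <- intersect(
            unique(c(bm0$pm$templatesByFamily[[fam]],
                     companionTemplates(peps))),
            colnames(bm0$P))
        q0 <- rnaQuery(bm0$R[id, ], m0)
        ps <- reconstruction(q0)
        top <- names(sort(ps, decreasing = TRUE))[seq_along(truth)]
        expect_gte(mean(truth %in% top), 0.8)
    }
})
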