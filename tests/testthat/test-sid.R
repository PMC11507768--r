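test_that("pairwise alignment identity matches the affine-gap oracle", {
    suppressMessages(Biostrings::pairwiseAlignment)  # warm namespace
    data(BLOSUM62, package = "Biostrings", envir = environment())

    idSame <- nwIdentity("MKVLAT", "MKVLAT")
    expect_equal(idSame$identity, 1.0)

    idNone <- nwIdentity("AAAA", "CCCC")
    expect_equal(idNone$identity, 0)

    set.seed(71)
    for (i in 1:10) {
        a <- randomAA(1, 30L)
        b <- randomAA(1, 30L)
        res <- nwIdentity(a, b)
        # score optimality against the independent DP oracle
        expect_equal(res$score, gotohScore(a, b, BLOSUM62),
                     tolerance = 1e-9)
        # returned alignment is consistent: it de-gaps to the inputs,
        # realizes the optimal score, and its identity is the stated
        # match fraction
        expect_equal(gsub("-", "", res$alignedA), a)
        expect_equal(gsub("-", "", res$alignedB), b)
        expect_equal(alignmentScore(res$alignedA, res$alignedB, BLOSUM62),
                     res$score, tolerance = 1e-9)
        chA <- strsplit(res$alignedA, "")[[1]]
        chB <- strsplit(res$alignedB, "")[[1]]
        expect_equal(res$identity,
                     sum(chA == chB & chA != "-") / length(chA))
    }

    # shorter-sequence denominator
    short <- nwIdentity("MKVLATGR", "MKVL", denominator = "shorter")
    expect_equal(short$identity,
                 {
                     chA <- strsplit(short$alignedA, "")[[1]]
                     chB <- strsplit(short$alignedB, "")[[1]]
                     sum(chA == chB & chA != "-") / 4
                 })

    expect_error(nwIdentity("MKB2", "MKV"), "invalid residue")
})

test_that("domain-aware RBR identity handles unequal architectures", {
    set.seed(72)
    d1 <- randomAA(1, 50L)
    d2 <- randomAA(1, 50L)
    d3 <- randomAA(1, 50L)
    gap <- randomAA(1, 20L)

    seqAB <- paste0(d1, gap, d2)
    domAB <- data.frame(domain_class = c("RRM", "RRM"),
                        start = c(1L, 71L), end = c(50L, 120L))
    # identical two-domain proteins
    expect_equal(rbrSid(seqAB, domAB, seqAB, domAB, flank = 0L), 1.0)

    # 2-domain vs 3-domain: the correct contiguous placement wins
    seq3 <- paste0(d3, gap, d1, gap, d2)
    dom3 <- data.frame(domain_class = c("RRM", "RRM", "RRM"),
                       start = c(1L, 71L, 141L),
                       end = c(50L, 120L, 190L))
    sid <- rbrSid(seqAB, domAB, seq3, dom3, flank = 0L)
    expect_equal(sid, 1.0)     # placement (2, 3) matches exactly

    # oracle: enumerate both placements by hand
    place1 <- mean(c(nwIdentity(d1, d3)$identity,
                     nwIdentity(d2, d1)$identity))
    place2 <- mean(c(nwIdentity(d1, d1)$identity,
                     nwIdentity(d2, d2)$identity))
    expect_equal(sid, max(place1, place2))

    # symmetry
    expect_equal(rbrSid(seq3, dom3, seqAB, domAB, flank = 0L), sid)

    # unrelated single-domain proteins score near zero
    lowSid <- rbrSid(d1, data.frame(domain_class = "KH", start = 1L,
                                    end = 50L),
                     d2, data.frame(domain_class = "KH", start = 1L,
                                    end = 50L), flank = 0L)
    expect_lt(lowSid, 0.3)

    # incompatible classes at every placement
    expect_error(rbrSid(d1, data.frame(domain_class = "KH", start = 1L,
                                       end = 50L),
                        d2, data.frame(domain_class = "RRM", start = 1L,
                                       end = 50L), flank = 0L),
                 "compatible|placement")
})

test_that("the 70% rule transfers the closest measured profile", {
    set.seed(73)
    base <- randomAA(1, 80L)
    mutate <- function(s, rate) {
        aa <- c("A","C","D","E","F","G","H","I","K","L",
                "M","N","P","Q","R","S","T","V","W","Y")
        ch <- strsplit(s, "")[[1]]
        hit <- runif(length(ch)) < rate
        ch[hit] <- vapply(ch[hit], function(x)
            sample(setdiff(aa, x), 1), character(1))
        paste(ch, collapse = "")
    }
    dom <- data.frame(domain_class = "RRM", start = 1L, end = 80L)
    refs <- list(
        list(id = "near", sequence = mutate(base, 0.1), domains = dom,
             profile = c(k1 = 1, k2 = 0)),
        list(id = "mid", sequence = mutate(base, 0.4), domains = dom,
             profile = c(k1 = 0, k2 = 1)),
        list(id = "far", sequence = mutate(base, 0.7), domains = dom,
             profile = c(k1 = -1, k2 = -1)))

    hit <- inferBySid(base, dom, refs, flank = 0L)
    expect_equal(hit$reference, "near")
    expect_equal(hit$profile, c(k1 = 1, k2 = 0))
    expect_true(hit$confident)       # ~90% identity

    # identical query: sid 1, confident
    self <- inferBySid(refs[[1]]$sequence, dom, refs[1], flank = 0L)
    expect_equal(self$sid, 1.0)
    expect_true(self$confident)

    # a 50%-identity best hit is returned but not confident
    lowRefs <- list(list(id = "weak", sequence = mutate(base, 0.5),
                         domains = dom, profile = c(k1 = 9)))
    low <- inferBySid(base, dom, lowRefs, flank = 0L)
    expect_false(low$confident)
    expect_equal(low$profile, c(k1 = 9))
})

test_that("MSA identities use the stated denominator convention", {
    m <- msaSid(c(a = "ACDE", b = "ACDE"))
    expect_equal(unname(m["a", "b"]), 1.0)

    m2 <- msaSid(c(a = "AC-E", b = "ACDE"))
    expect_equal(unname(m2[1L, 2L]), 3 / 4)

    m3 <- msaSid(c(a = "AC--", b = "--DE"))
    expect_equal(unname(m3[1L, 2L]), 0)

    expect_true(isSymmetric(msaSid(c(a = "ACDE", b = "AADE",
                                     c = "AC-E"))))
    expect_error(msaSid(c("ACDE", "ACD")), "equal length")
})

test_that("realized family identities land in their declared bands", {
    fx <- genFamilies(2L, 3L, seed = 99L, bands = c(0.9, 0.6))
    ids <- names(fx$proteins)
    fam1 <- ids[fx$family == 1L]
    founder <- fam1[fx$isFounder[fam1]]
    m2 <- fam1[!fx$isFounder[fam1]][1L]   # targeted 0.9
    got <- nwIdentity(fx$proteins[[founder]], fx$proteins[[m2]])$identity
    expect_lt(abs(got - 0.9), 0.05)

    # cross-family identity is unrelated-low
    other <- ids[fx$family == 2L][1L]
    cross <- nwIdentity(fx$proteins[[founder]],
                        fx$proteins[[other]])$identity
    expect_lt(cross, 0.3)
})
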