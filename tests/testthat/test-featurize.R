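test_that("7-mer vocabulary has the documented size and order", {
    all7 <- enumerate7mers(excludeRestriction = FALSE)
    std <- enumerate7mers(excludeRestriction = TRUE)
    expect_length(all7, 16384L)
    expect_length(std, 16382L)
    expect_identical(all7[1L], "AAAAAAA")
    expect_identical(all7, sort(all7))
    expect_setdiff <- setdiff(all7, std)
    expect_setequal(expect_setdiff, c("GCUCUUC", "CGAGAAG"))
})

test_that("RBR construction extends, clips and merges domain intervals", {
    seq100 <- strrep("A", 100L)
    one <- buildRBR(seq100, "p", data.frame(domain_class = "RRM",
                                            start = 40L, end = 60L))
    expect_equal(one@segStart, 25L)
    expect_equal(one@segEnd, 75L)

    # interval-merge: two domains whose flanks touch collapse into one
    two <- buildRBR(seq100, "p",
        data.frame(domain_class = c("RRM", "RRM"),
                   start = c(10L, 30L), end = c(20L, 40L)))
    expect_length(two@segments, 1L)
    expect_equal(two@segStart, 1L)
    expect_equal(two@segEnd, 55L)

    clip <- buildRBR(seq100, "p", data.frame(domain_class = "KH",
                                             start = 1L, end = 5L))
    expect_equal(clip@segStart, 1L)
    expect_equal(clip@segEnd, 20L)

    expect_error(buildRBR(seq100, "p",
                          data.frame(domain_class = character(0),
                                     start = integer(0), end = integer(0))),
                 "no RBDs")

    far <- buildRBR(seq100, "p",
        data.frame(domain_class = c("RRM", "KH"),
                   start = c(5L, 70L), end = c(15L, 80L)))
    expect_length(far@segments, 2L)
})

test_that("peptide profiles count gapped templates window by window", {
    p1 <- peptideProfile(toyRBR("AAAAA"))
    expect_setequal(names(p1),
                    c("XAAAA", "AXAAA", "AAXAA", "AAAXA", "AAAAX"))
    expect_true(all(p1 == 1L))

    p2 <- peptideProfile(toyRBR("AAAAAA"))
    expect_true(all(p2 == 2L))
    expect_setequal(names(p2), names(p1))

    expect_warning(p3 <- peptideProfile(toyRBR("ACDE")), "empty")
    expect_length(p3, 0L)

    # windows containing unknown residues contribute nothing
    pX <- peptideProfile(toyRBR("ACDEXACDEF"))
    expect_equal(sum(pX), 5L)  # only "ACDEF" yields a window
})

test_that("profile total equals 5 x number of windows on X-free input", {
    set.seed(11)
    for (rep in 1:5) {
        segs <- randomAA(2, sample(6:30, 1))
        seqn <- paste0(segs[1], segs[2])
        rbr <- buildRBR(seqn, "p",
            data.frame(domain_class = c("RRM", "RRM"),
                       start = c(1L, nchar(segs[1]) + 1L),
                       end = c(nchar(segs[1]), nchar(seqn))),
            flank = 0L)
        # flank 0 with adjacent domains merges into one segment
        expWindows <- sum(pmax(0L, nchar(rbr@segments) - 4L))
        expect_equal(sum(peptideProfile(rbr)), 5L * expWindows)
    }
})

test_that("profile matrices align profiles over a shared vocabulary", {
    profs <- list(a = c(XAAAA = 2L, AXAAA = 1L),
                  b = c(AXAAA = 3L, CXDEF = 1L))
    M <- peptideProfileMatrix(profs)
    expect_equal(dim(M), c(2L, 3L))
    expect_equal(M["a", "AXAAA"], 1)
    expect_equal(M["b", "XAAAA"], 0)
    expect_equal(colnames(M), sort(colnames(M)))

    Mv <- peptideProfileMatrix(profs, vocabulary = c("AXAAA", "ZZZZZ"))
    expect_equal(colnames(Mv), c("AXAAA", "ZZZZZ"))
    expect_equal(unname(Mv[, "ZZZZZ"]), c(0, 0))
})

test_that("homolog augmentation normalizes by distinct peptides per position", {
    rbr <- toyRBR("ACDEFGH")
    own <- peptideProfile(rbr)

    # one homolog identical to the RBR reproduces the plain profile
    P1 <- buildAugmentedProfiles(list(x = rbr),
                                 list(x = "ACDEFGH"))
    expect_equal(P1["x", names(own)], as.numeric(own),
                 ignore_attr = TRUE)

    # two identical homologs: identical row (distinct-peptide norm)
    P2 <- buildAugmentedProfiles(list(x = rbr),
                                 list(x = c("ACDEFGH", "ACDEFGH")))
    expect_equal(P2["x", ], P1["x", ])

    # two homologs differing at one position split the weight
    P3 <- buildAugmentedProfiles(list(x = rbr),
                                 list(x = c("ACDEFGH", "ACDEFGY")))
    expect_equal(unname(P3["x", "XCDEF"]), 1)       # shared window
    expect_equal(unname(P3["x", "DEFGX"]), 1)       # wildcard hides the diff
    expect_equal(unname(P3["x", "XEFGH"]), 0.5)     # split between G/Y forms
    expect_equal(unname(P3["x", "XEFGY"]), 0.5)

    # gap columns break windows
    P4 <- buildAugmentedProfiles(list(x = rbr),
                                 list(x = "ACD-EFGH"))
    expect_equal(sum(P4["x", ]), 0)

    expect_warning(
        P5 <- buildAugmentedProfiles(list(x = rbr), list(x = character(0))),
        "no homologs")
    expect_equal(P5["x", names(own)], as.numeric(own),
                 ignore_attr = TRUE)
})
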