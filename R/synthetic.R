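## Synthetic benchmark generators: protein families with planted
## domains, a planted peptide-template -> RNA-specificity model, and
## simulated probe arrays. Every generator takes an explicit seed and
## is deterministic given it; the caller's RNG stream is left intact.

#' Generate synthetic RBP families
#'
#' Draws founder proteins with one or two planted RNA-binding domains
#' (alternating KH single-domain and RRM-RRM architectures) and derives
#' family members by seeded point substitutions targeting a ladder of
#' sequence identities, so realized pairwise identities span high
#' (> 0.9), intermediate (0.5-0.7) and -- across unpaired families --
#' unrelated (< 0.3) bands. With four or more families, the second
#' half of the families reuses the conserved interface blocks of the
#' first half (convergent interfaces), so each such pair forms one
#' specificity group while remaining below the homology band overall.
#'
#' Every family carries six conserved 5-residue blocks inside its
#' first domain; these are the family's specificity-determining sites.
#' They receive a deterministic substitution budget of a quarter of
#' their proportional share -- purifying selection on the RNA-binding
#' interface -- allocated one substitution per drifted block, so
#' interface divergence grows as a step-wise monotone function of the
#' identity band. The background substitution rate is compensated so
#' the realized full-length identity still tracks the requested band.
#'
#' @param nFamilies number of unrelated families.
#' @param members proteins per family (the founder plus
#'   \code{members - 1} mutants).
#' @param seed integer seed; output is deterministic given it.
#' @param bands target identities of the mutant ladder, recycled over
#'   mutants.
#' @param groupSize number of unrelated families sharing each
#'   specificity group (convergent interfaces); 1 disables sharing.
#' @return list with \code{proteins} (named character vector),
#'   \code{domains} (data.frame: protein_id, domain_class, start, end),
#'   \code{family} (named integer), \code{isFounder} (named logical),
#'   \code{targetIdentity} (named numeric, NA for founders),
#'   \code{conservedStarts} (per family, founder coordinates of the
#'   conserved 5-mer blocks), \code{specGroup} (per family, the
#'   specificity group it belongs to) and \code{seed}.
#' @export
genFamilies <- function(nFamilies, members, seed,
                        bands = c(0.95, 0.9, 0.8, 0.5),
                        groupSize = 2L) {
    stopifnot(nFamilies >= 1L, members >= 1L, groupSize >= 1L)
    consFactor <- 0.25                   # relative rate at conserved sites
    .withSeed(seed, {
        proteins <- character(0L)
        domains <- list()
        family <- integer(0L)
        isFounder <- logical(0L)
        targetId <- numeric(0L)
        conservedStarts <- list()
        specGroup <- integer(nFamilies)
        for (f in seq_len(nFamilies)) {
            twoDomains <- f %% 2L == 0L
            domLen <- 60L
            nFlank <- 10L
            linker <- 15L
            len <- nFlank + domLen + nFlank +
                if (twoDomains) linker + domLen else 0L
            founder <- paste(sample(.AA20, len, replace = TRUE),
                             collapse = "")
            if (twoDomains) {
                dstart <- c(nFlank + 1L, nFlank + domLen + linker + 1L)
                dclass <- c("RRM", "RRM")
            } else {
                dstart <- nFlank + 1L
                dclass <- "KH"
            }
            dend <- dstart + domLen - 1L
            consStart <- dstart[1L] + c(2L, 12L, 22L, 32L, 42L, 52L)
            consPos <- as.vector(outer(0:4, consStart, "+"))
            conservedStarts[[f]] <- consStart
            nCons <- length(consPos)
            # convergent interfaces: beyond the first
            # ceiling(nFamilies / groupSize) families, each family
            # reuses the conserved-block peptides of a group-founder
            # family, so unrelated proteins can share a specificity
            # group -- as real RBP motifs recur across unrelated
            # families -- while staying below the homology band
            # elsewhere
            nGroups <- max(1L, ceiling(nFamilies / groupSize))
            partner <- if (nFamilies >= 4L && f > nGroups)
                ((f - 1L) %% nGroups) + 1L else f
            if (partner != f) {
                chars <- strsplit(founder, "")[[1L]]
                twin <- strsplit(proteins[[
                    sprintf("fam%02d_m01", partner)]], "")[[1L]]
                chars[consPos] <- twin[consPos]
                founder <- paste(chars, collapse = "")
            }
            specGroup[f] <- partner
            for (m in seq_len(members)) {
                id <- sprintf("fam%02d_m%02d", f, m)
                if (m == 1L) {
                    seqm <- founder
                    tgt <- NA_real_
                } else {
                    tgt <- bands[(m - 2L) %% length(bands) + 1L]
                    # fixed interface-divergence budget: the conserved
                    # blocks receive a deterministic number of
                    # substitutions (a quarter of their proportional
                    # share, one per drifted block), the rest of the
                    # sequence mutates at the compensated background
                    # rate, so the realized full-length identity
                    # tracks the requested band while specificity
                    # divergence grows monotonically with it
                    consMut <- min(nCons,
                        ceiling(consFactor * (1 - tgt) * nCons))
                    blocksHit <- sample(seq_along(consStart),
                        min(consMut, length(consStart)))
                    consHit <- vapply(blocksHit, function(bb)
                        consStart[bb] + sample(0:4, 1L), integer(1L))
                    extra <- consMut - length(consHit)
                    if (extra > 0L)
                        consHit <- c(consHit,
                            sample(setdiff(consPos, consHit), extra))
                    rateBg <- max(0, (1 - tgt) * len - consMut) /
                        (len - nCons)
                    chars <- strsplit(founder, "")[[1L]]
                    hit <- logical(len)
                    hit[setdiff(seq_len(len), consPos)] <-
                        stats::runif(len - nCons) < rateBg
                    hit[consHit] <- TRUE
                    chars[hit] <- vapply(chars[hit], function(aa)
                        sample(setdiff(.AA20, aa), 1L), character(1L))
                    seqm <- paste(chars, collapse = "")
                }
                proteins[id] <- seqm
                family[id] <- f
                isFounder[id] <- m == 1L
                targetId[id] <- tgt
                domains[[id]] <- data.frame(
                    protein_id = id, domain_class = dclass,
                    start = dstart, end = dend,
                    stringsAsFactors = FALSE)
            }
        }
        list(proteins = proteins,
             domains = do.call(rbind, c(domains, make.row.names = FALSE)),
             family = family, isFounder = isFounder,
             targetIdentity = targetId,
             conservedStarts = conservedStarts,
             specGroup = specGroup, seed = seed)
    })
}

#' Plant a peptide-template to RNA-specificity model on a fixture
#'
#' Selects, for every family, a set of informative 5-mer peptides
#' sitting on the fixture's conserved blocks; their gapped templates
#' carry additive effect vectors over the RNA 7-mer vocabulary, drawn
#' from a family-specific low-rank motif basis. A protein's true RNA
#' profile is the count-weighted sum of the effects of the informative
#' templates present in its RNA-binding region.
#'
#' Family members whose conserved blocks acquired substitutions carry
#' variant peptides at those blocks; each variant is assigned its own
#' effect vector correlated at \code{drift} with the ancestral block
#' effect, so RNA specificity diverges gradually -- not
#' catastrophically -- with interface divergence, emulating
#' neofunctionalization after interface mutations. The linear,
#' additive construction matches the linearity of the embedding model,
#' so recovery failures point at implementation bugs rather than model
#' mismatch.
#'
#' @param fixture a family fixture from [genFamilies()].
#' @param nInformative informative peptides (conserved blocks) used
#'   per family.
#' @param latentRank rank of the per-family effect basis.
#' @param noiseSd standard deviation of the Gaussian noise added to
#'   profiles (on the pre-Z-transform scale where planted effects have
#'   roughly unit variance).
#' @param drift correlation between the effect of a mutated interface
#'   peptide and its ancestral block effect, in [0, 1].
#' @param seed integer seed.
#' @return planted model: list with \code{effects} (templates x 7-mers
#'   matrix), \code{peptides} (per family), \code{templatesByFamily},
#'   \code{kmers}, \code{latentRank}, \code{noiseSd}, \code{drift},
#'   \code{seed}.
#' @export
plantedModel <- function(fixture, nInformative = 6L, latentRank = 10L,
                         noiseSd = 0.1, drift = 0.75,
                         seed = fixture$seed + 1L) {
    stopifnot(latentRank >= 1L, nInformative >= 1L, noiseSd >= 0,
              drift >= 0, drift <= 1)
    kmers <- enumerate7mers(TRUE)
    .withSeed(seed, {
        founders <- names(fixture$proteins)[fixture$isFounder]
        peptides <- list()
        blockStarts <- list()
        for (id in founders) {
            f <- fixture$family[[id]]
            dom <- fixture$domains[fixture$domains$protein_id == id, ]
            # informative peptides sit on the fixture's conserved
            # blocks when present, else are spaced along domain 1
            starts <- if (!is.null(fixture$conservedStarts))
                fixture$conservedStarts[[f]]
            else
                round(seq(dom$start[1L] + 2L, dom$end[1L] - 6L,
                          length.out = nInformative))
            starts <- starts[seq_len(min(nInformative, length(starts)))]
            blockStarts[[as.character(f)]] <- starts
            peptides[[as.character(f)]] <-
                substring(fixture$proteins[[id]], starts, starts + 4L)
        }
        tplByFam <- lapply(peptides, function(peps)
            unique(unlist(lapply(peps, .windowTemplates))))
        # Base index matrix of the 7-mer vocabulary, reused for all
        # basis vectors.
        baseIdx <- do.call(cbind, lapply(1:7, function(j)
            match(substring(kmers, j, j), .RNA4)))
        # A motif-like basis vector: the energy of each 7-mer under
        # random mono-, di- and tri-nucleotide weights. Such energies
        # are shift-coherent -- a 7-mer and its single-base shifts
        # score similarly -- emulating the composition- and
        # repeat-driven preferences (poly-U, GU-repeats, AU-rich)
        # typical of RRM and KH domains, and keeping the planted
        # signal recoverable from overlapping probe windows.
        motifEnergy <- function() {
            w1 <- stats::rnorm(4L, sd = 0.5)
            w2 <- array(stats::rnorm(16L), c(4L, 4L))
            w3 <- array(stats::rnorm(64L, sd = 1.5), c(4L, 4L, 4L))
            w4 <- array(stats::rnorm(256L, sd = 2), c(4L, 4L, 4L, 4L))
            e <- numeric(length(kmers))
            for (j in 1:7) e <- e + w1[baseIdx[, j]]
            for (j in 1:6) e <- e + w2[baseIdx[, c(j, j + 1L)]]
            for (j in 1:5) e <- e + w3[baseIdx[, c(j, j + 1L, j + 2L)]]
            for (j in 1:4) e <- e + w4[baseIdx[, c(j, j + 1L, j + 2L,
                                                   j + 3L)]]
            e / stats::sd(e) + stats::rnorm(length(kmers), sd = 0.05)
        }
        # Each specificity group (families sharing convergent
        # interface blocks) draws its effects from an independent
        # low-rank motif basis, so unrelated groups have uncorrelated
        # specificities while the informative templates recur across
        # unrelated sequence backgrounds. Every realized variant of a
        # conserved block (the founder's peptide plus any mutated
        # forms observed in family members) receives an effect vector;
        # variant effects correlate with the ancestral block effect at
        # `drift`. A template generated by several variants (wildcard
        # masking the mutated position) carries the mean of their
        # effects.
        effectAcc <- new.env(parent = emptyenv())
        addEffect <- function(tpl, e) {
            prev <- if (exists(tpl, envir = effectAcc, inherits = FALSE))
                get(tpl, envir = effectAcc) else list(n = 0L, sum = 0)
            assign(tpl, list(n = prev$n + 1L, sum = prev$sum + e),
                   envir = effectAcc)
        }
        fams <- as.integer(names(tplByFam))
        groupOf <- if (!is.null(fixture$specGroup))
            fixture$specGroup else fams
        for (g in sort(unique(groupOf[fams]))) {
            B <- do.call(rbind, replicate(latentRank, motifEnergy(),
                                          simplify = FALSE))
            groupFams <- fams[groupOf[fams] == g]
            nBlocks <- length(blockStarts[[as.character(groupFams[1L])]])
            for (b in seq_len(nBlocks)) {
                aAnc <- stats::rnorm(latentRank,
                                     sd = 1 / sqrt(latentRank))
                for (f in sort(groupFams)) {
                    fc <- as.character(f)
                    members <- names(fixture$proteins)[
                        fixture$family == f]
                    obs <- substring(fixture$proteins[members],
                                     blockStarts[[fc]][b],
                                     blockStarts[[fc]][b] + 4L)
                    founderPep <- peptides[[fc]][b]
                    variants <- c(founderPep,
                                  sort(setdiff(unique(obs), founderPep)))
                    for (v in variants) {
                        aV <- if (v == founderPep) aAnc
                        else drift * aAnc + sqrt(1 - drift^2) *
                            stats::rnorm(latentRank,
                                         sd = 1 / sqrt(latentRank))
                        effV <- as.vector(crossprod(aV, B))
                        for (tpl in .windowTemplates(v))
                            addEffect(tpl, effV)
                    }
                }
            }
        }
        templates <- sort(ls(effectAcc))
        effects <- do.call(rbind, lapply(templates, function(tpl) {
            acc <- get(tpl, envir = effectAcc)
            acc$sum / acc$n
        }))
        dimnames(effects) <- list(templates, kmers)
        list(effects = effects, peptides = peptides,
             templatesByFamily = tplByFam, kmers = kmers,
             latentRank = latentRank, noiseSd = noiseSd,
             drift = drift, seed = seed)
    })
}

#' Generate planted RNA-binding profiles for a fixture
#'
#' Computes every protein's true 7-mer profile under a planted model
#' (count-weighted sum of its informative-template effects), adds
#' Gaussian noise of the model's \code{noiseSd}, and Z-transforms each
#' profile to mean 0 and unit (population) standard deviation.
#'
#' @param fixture a family fixture from [genFamilies()].
#' @param model a planted model from [plantedModel()].
#' @param flank flank width used when building RBRs.
#' @return numeric matrix, proteins x 7-mers (the raw R' matrix).
#' @export
genProfiles <- function(fixture, model, flank = 15L) {
    ids <- names(fixture$proteins)
    kmers <- model$kmers
    templates <- rownames(model$effects)
    .withSeed(model$seed + 1L, {
        R <- matrix(0, length(ids), length(kmers),
                    dimnames = list(ids, kmers))
        for (i in seq_along(ids)) {
            id <- ids[i]
            rbr <- buildRBR(fixture$proteins[[id]], id,
                fixture$domains[fixture$domains$protein_id == id, ],
                flank = flank)
            prof <- peptideProfile(rbr)
            cnt <- structure(numeric(length(templates)),
                             names = templates)
            hit <- intersect(names(prof), templates)
            cnt[hit] <- prof[hit]
            r <- as.vector(cnt %*% model$effects)
            if (model$noiseSd > 0)
                r <- r + stats::rnorm(length(r), sd = model$noiseSd)
            s <- .popSd(r)
            R[i, ] <- if (s == 0) r else (r - mean(r)) / s
        }
        R
    })
}

#' Simulate an RNAcompete-style probe array
#'
#' Draws random single-stranded RNA probes and computes, for each probe
#' and each profile, an intensity equal to the sum of the affinities
#' (softmax-scaled Z-scores, \eqn{a_k = e^{z_k/4}}, giving a dynamic
#' range of roughly two orders of magnitude over the observed Z range)
#' of all 7-mers the probe contains, plus a shared lognormal per-probe effect (emulating
#' probe-level abundance artifacts, which the per-probe normalization
#' step of [quantifyRNAcompete()] removes when several samples are
#' present) and Gaussian measurement noise scaled so the probe-level
#' signal-to-noise ratio equals \code{snr}.
#'
#' @param profile named numeric vector of 7-mer Z-scores, or a matrix
#'   with one column per sample (7-mers x samples).
#' @param nProbes number of probes; the published assay uses ~241,000.
#' @param probeLen probe length in nucleotides (default 40).
#' @param seed integer seed.
#' @param snr probe-level signal-to-noise ratio of the Gaussian noise.
#' @return a [ProbeArray-class] with one intensity column per sample.
#' @export
genProbeArray <- function(profile, nProbes = 241000L, probeLen = 40L,
                          seed, snr = 3) {
    if (is.null(dim(profile)))
        profile <- matrix(profile, ncol = 1L,
                          dimnames = list(names(profile), "sample1"))
    stopifnot(nProbes >= 1000L, probeLen >= 7L, snr > 0,
              !is.null(rownames(profile)))
    .withSeed(seed, {
        chars <- matrix(sample(.RNA4, nProbes * probeLen, replace = TRUE),
                        nrow = nProbes)
        seqs <- do.call(paste0, as.data.frame(chars,
                                              stringsAsFactors = FALSE))
        nWin <- probeLen - 6L
        probe <- rep.int(seq_len(nProbes), rep.int(nWin, nProbes))
        start <- rep.int(seq_len(nWin), nProbes)
        km <- substring(seqs[probe], start, start + 6L)
        aff <- exp(profile / 4)
        intens <- matrix(0, nProbes, ncol(profile),
                         dimnames = list(NULL, colnames(profile)))
        dt <- data.table::data.table(probe = probe)
        ki <- match(km, rownames(profile))
        ok <- !is.na(ki)                # 7-mers outside the vocabulary
        sigSd <- numeric(ncol(profile))
        for (s in seq_len(ncol(profile))) {
            a <- numeric(length(ki))
            a[ok] <- aff[ki[ok], s]
            data.table::set(dt, j = "av", value = a)
            sig <- dt[, list(v = sum(av)), by = "probe"]$v
            sigSd[s] <- stats::sd(sig)
            intens[, s] <- sig
        }
        sp <- max(mean(sigSd), .Machine$double.eps)
        pe <- stats::rlnorm(nProbes, 0, 0.5)
        pe <- pe * (sp / 3) / stats::sd(pe)
        noise <- matrix(stats::rnorm(nProbes * ncol(profile),
                                     sd = sp / snr),
                        nProbes, ncol(profile))
        intens <- intens + pe + noise
        probeArray(sprintf("probe%07d", seq_len(nProbes)), seqs, intens)
    })
}
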