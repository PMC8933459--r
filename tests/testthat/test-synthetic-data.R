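test_that("genome generation is deterministic and places GATC motifs at the configured density", {
    cfg <- smallConfig()
    g1 <- simulateGenome(cfg)$genome
    g2 <- simulateGenome(cfg)$genome
    expect_identical(as.character(g1), as.character(g2))

    # motif counts by direct scan vs Poisson expectation (3 SD)
    counts <- Biostrings::vcountPattern("GATC", g1)
    for (i in seq_along(counts)) {
        L <- cfg@chromLengths[[i]]
        expected <- L / cfg@gatcSpacingMean
        expect_lt(abs(counts[i] - expected), 3 * sqrt(expected) + 1)
    }

    # degenerate spacing: no motif fits, one fragment per chromosome
    cfgBig <- simConfig(chromLengths = c(chrA = 1e6), rdnaUnitLength = 0,
                        gatcSpacingMean = 1e12, domainLayout = GRanges(),
                        seed = 3)
    gBig <- simulateGenome(cfgBig)
    expect_equal(sum(Biostrings::vcountPattern("GATC", gBig$genome)), 0)
    expect_length(fragments(buildGatcFragments(gBig$genome)), 1L)
})

test_that("rDNA unit is appended to the last chromosome and recorded", {
    sim <- smallSim()
    rd <- rdnaInterval(sim$truth)
    expect_equal(as.character(seqnames(rd)), "chrB")
    expect_equal(start(rd), 10e6 + 1)
    expect_equal(end(rd), 10e6 + 2e4)
    expect_error(simConfig(chromLengths = c(chrA = 1e4),
                           rdnaUnitLength = 1e6),
                 "shorter than rdnaUnitLength")
})

test_that("DamID simulation recovers the configured enrichment", {
    sim <- smallSim()
    # null model: enrichment 1 gives genome-wide mean ratio near 0
    trNull <- ratioTrackFor(sim$truth, sim$map, seed = 11, depth = 2e6,
                            enrichment = 1)
    b <- bins(trNull)
    expect_lt(abs(mean(b$score[!b$mask])), 0.05)

    # enrichment 4: in-NAD minus out-of-NAD mean ratio = log2(4) +- 0.1
    tr <- ratioTrackFor(sim$truth, sim$map, seed = 12, depth = 2e6,
                        enrichment = 4)
    b <- bins(tr)
    mids <- resize(b, 1, fix = "center")
    inNad <- overlapsAny(mids, nadTruth(sim$truth))
    ok <- !b$mask
    diff <- mean(b$score[ok & inNad]) - mean(b$score[ok & !inNad])
    expect_lt(abs(diff - 2), 0.1)
})

test_that("DamID counts approach Poisson as dispersion vanishes", {
    # equal-length fragments so counts are iid at fixed depth
    unit <- paste0(randomGatcFreeDna(496), "GATC")
    seqs <- Biostrings::DNAStringSet(c(chrP = paste(
        rep(unit, 2000), collapse = "")))
    map <- buildGatcFragments(seqs)
    cfg <- simConfig(chromLengths = c(chrP = 1e6), rdnaUnitLength = 0,
                     domainLayout = GRanges(), seed = 9)
    truth <- simulateGenome(cfg)$truth
    dd <- simulateDamid(truth, map, depth = 1e6, enrichment = 1,
                        dispersion = 0, seed = 21)
    cnt <- fragmentCounts(dd$dam)
    # interior fragments share one mean; variance/mean ~ 1
    inner <- cnt[-c(1L, length(cnt))]
    expect_lt(abs(var(inner) / mean(inner) - 1), 0.1)
    # and with dispersion 0.5 the counts are overdispersed
    dd2 <- simulateDamid(truth, map, depth = 1e6, enrichment = 1,
                         dispersion = 0.5, seed = 21)
    inner2 <- fragmentCounts(dd2$dam)[-c(1L, 2000L)]
    expect_gt(var(inner2) / mean(inner2), 2)
})

test_that("Hi-C pairs follow the configured distance decay", {
    sim <- smallSim()
    pr <- simulateHicPairs(sim$truth, nPairs = 2e5, alpha = 1,
                           rdnaBoost = 1, q1Boost = 1, compBoost = 1,
                           rdnaFraction = 0, seed = 31)
    cis <- pr[pr$chr1 == pr$chr2, ]
    s <- abs(cis$pos2 - cis$pos1)
    s <- s[s >= 2000 & s <= 5e6]
    # log-log regression of counts in log-spaced distance bins
    brk <- exp(seq(log(2000), log(5e6), length.out = 25))
    h <- hist(s, breaks = brk, plot = FALSE)
    dens <- h$counts / diff(brk)
    keep <- h$counts > 20
    fit <- lm(log(dens[keep]) ~ log(h$mids[keep]))
    expect_lt(abs(unname(coef(fit)[2]) + 1), 0.1)
})

test_that("rDNA-anchored pairs are boosted into planted NADs", {
    sim <- smallSim()
    pr <- simulateHicPairs(sim$truth, nPairs = 2e5, rdnaBoost = 5,
                           q1Boost = 1, compBoost = 1,
                           rdnaFraction = 0.3, seed = 32)
    rd <- rdnaInterval(sim$truth)
    in1 <- pr$chr1 == as.character(seqnames(rd)) &
        pr$pos1 >= start(rd) - 1 & pr$pos1 < end(rd)
    anchored <- pr[in1, ]
    other <- GRanges(anchored$chr2, IRanges(anchored$pos2 + 1, width = 1))
    nad <- nadTruth(sim$truth)
    nadBp <- sum(width(nad))
    totBp <- sum(seqlengths(sim$truth@seqinfo)) - width(rd)
    inNad <- overlapsAny(other, nad)
    rateRatio <- (sum(inNad) / nadBp) / (sum(!inNad) / (totBp - nadBp))
    expect_lt(abs(rateRatio - 5) / 5, 0.2)

    expect_error(simulateHicPairs(sim$truth, nPairs = 0), "> 0")
})

test_that("ChIP tracks reflect per-layer means", {
    sim <- smallSim()
    marks <- list(
        flat = c("NAD-only" = 2, "NAD/LAD" = 2, "LAD-only" = 2,
                 "iNAD/iLAD" = 2),
        H3K9me2 = c("NAD-only" = 2, "NAD/LAD" = 4, "LAD-only" = 2,
                    "iNAD/iLAD" = 1),
        zero = c("NAD-only" = 0, "NAD/LAD" = 0, "LAD-only" = 0,
                 "iNAD/iLAD" = 0))
    trk <- simulateChipTracks(sim$truth, marks = marks, binSize = 500,
                              seed = 41)
    part <- classifyLayers(nadTruth(sim$truth), ladTruth(sim$truth))
    grp <- function(track, lv) {
        mids <- resize(track, 1, fix = "center")
        track$score[overlapsAny(mids, layerSet(part, lv))]
    }
    # equal means: no significant difference between layers
    p <- t.test(grp(trk$flat, "NAD/LAD"), grp(trk$flat, "LAD-only"))$p.value
    expect_gt(p, 0.01)
    # 2x mark recovered within 10%
    ratio <- mean(grp(trk$H3K9me2, "NAD/LAD")) /
        mean(grp(trk$H3K9me2, "LAD-only"))
    expect_lt(abs(ratio - 2) / 2, 0.1)
    # zero-mean mark yields an all-zero track
    expect_true(all(trk$zero$score == 0))
    # missing layer mean errors
    expect_error(simulateChipTracks(sim$truth,
                                    marks = list(bad = c("NAD-only" = 1)),
                                    binSize = 500, seed = 1),
                 "missing label mean")
})

test_that("expression simulation gives layer-mean RPKM and is deterministic", {
    sim <- smallSim()
    ex1 <- simulateExpression(sim$truth, nGenes = 3000, seed = 51)
    ex2 <- simulateExpression(sim$truth, nGenes = 3000, seed = 51)
    expect_identical(ex1$counts, ex2$counts)

    tab <- computeRpkm(ex1$counts, ex1$genes$exonLength, ex1$libSize,
                       geneIds = ex1$genes$gene_id)
    mids <- resize(ex1$genes, 1, fix = "center")
    inNadOnly <- overlapsAny(
        mids, layerSet(classifyLayers(nadTruth(sim$truth),
                                      ladTruth(sim$truth)), "NAD-only"))
    # layer mean RPKM 0.2 -> at least 70% of those genes below 1
    expect_gte(mean(tab$rpkm[inNadOnly] < 1), 0.7)
    expect_error(simulateExpression(sim$truth, nGenes = 0), "> 0")
})
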