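## Indicator track of a domain set over a genome (1 inside, 0 outside).
indicatorTrack <- function(domains, sl) {
    gr <- sort(c(granges(domains),
                 GenomicRanges::setdiff(
                     GRanges(names(sl), IRanges(1, sl),
                             seqlengths = sl), domains)))
    gr$score <- as.numeric(overlapsAny(gr, domains))
    seqlengths(gr) <- sl
    gr
}

test_that("border profiles form the ideal step on the indicator track", {
    sl <- c(chrP = 1e7)
    doms <- GRanges("chrP", IRanges(c(2e6 + 1, 6e6 + 1), c(4e6, 8e6)),
                    seqlengths = sl)
    trk <- indicatorTrack(doms, sl)
    bp <- borderProfile(trk, doms, flank = 5e5, binWidth = 1e5)
    # interior (positive positions) at 1, exterior at 0
    inside <- bp$positions > 0
    expect_equal(unname(bp$meanCurve[inside]), rep(1, sum(inside)))
    expect_equal(unname(bp$meanCurve[!inside]), rep(0, sum(!inside)))
    expect_equal(bp$dropped, 0)

    # constant track gives a flat curve
    flat <- trk; flat$score <- 3.5
    bpF <- borderProfile(flat, doms, flank = 5e5, binWidth = 1e5)
    expect_equal(unname(bpF$meanCurve), rep(3.5, 10))

    # boundaries without full flanks are dropped and counted
    domsEdge <- GRanges("chrP", IRanges(c(1e5, 2e6 + 1), c(3e5, 4e6)),
                        seqlengths = sl)
    bpE <- borderProfile(indicatorTrack(domsEdge, sl), domsEdge,
                         flank = 5e5, binWidth = 1e5)
    expect_equal(bpE$dropped, 2)  # both flanks of the edge domain

    # curves invariant to the input's domain order
    bpR <- borderProfile(trk, rev(doms), flank = 5e5, binWidth = 1e5)
    expect_equal(bpR$meanCurve, bp$meanCurve)

    expect_error(borderProfile(trk, GRanges("chrP", IRanges(1, 1e5),
                                            seqlengths = sl),
                               flank = 5e6, binWidth = 1e5),
                 "no boundary")
})

test_that("per-domain signal means recover simulated layer levels", {
    sl <- c(chrP = 1e6)
    doms <- GRanges("chrP", IRanges(c(1, 5e5 + 1), c(2e5, 8e5)),
                    seqlengths = sl)
    flat <- GRanges("chrP", IRanges(1, 1e6), score = 2.2,
                    seqlengths = sl)
    ds <- domainSignal(flat, doms)
    expect_equal(ds$perDomain$mean, c(2.2, 2.2))
    # empty domain set gives an empty summary
    expect_equal(nrow(domainSignal(flat, GRanges())$perDomain), 0L)

    # two layers with simulated means 1 and 2 recovered within 5%
    sim <- smallSim()
    marks <- list(m = c("NAD-only" = 1, "NAD/LAD" = 2, "LAD-only" = 1,
                        "iNAD/iLAD" = 1))
    trk <- simulateChipTracks(sim$truth, marks = marks, binSize = 500,
                              seed = 81)$m
    part <- classifyLayers(nadTruth(sim$truth), ladTruth(sim$truth))
    m1 <- domainSignal(trk, layerSet(part, "NAD-only"))$summary[["mean"]]
    m2 <- domainSignal(trk, layerSet(part, "NAD/LAD"))$summary[["mean"]]
    expect_lt(abs(m1 - 1), 0.05)
    expect_lt(abs(m2 - 2), 0.1)
})

test_that("binned fold changes are normalized and antisymmetric", {
    sl <- c(chrP = 1e6)
    mkCov <- function(scores, width = 1e4) {
        GRanges("chrP", IRanges(seq(1, 1e6, by = width), width = width),
                score = scores, seqlengths = sl)
    }
    set.seed(9)
    base <- rpois(100, 50)
    a <- mkCov(base)
    # identical conditions: zero everywhere
    fc0 <- binnedFoldChange(a, a, binSize = 2e4)
    expect_equal(fc0$track$score, rep(0, 50))
    # doubling one condition globally changes nothing (normalization)
    fc1 <- binnedFoldChange(mkCov(2 * base), a, binSize = 2e4)
    expect_equal(fc1$track$score, rep(0, 50), tolerance = 1e-12)
    # antisymmetry under condition swap
    b <- mkCov(rpois(100, 50))
    fAB <- binnedFoldChange(a, b, binSize = 2e4)
    fBA <- binnedFoldChange(b, a, binSize = 2e4)
    expect_equal(fAB$track$score, -fBA$track$score, tolerance = 1e-12)
    # a doubled bin stands out by ~1 at small pseudocount
    dbl <- base; dbl[11:12] <- 2 * dbl[11:12]  # bin 6 of 2e4
    fD <- binnedFoldChange(mkCov(dbl), a, binSize = 2e4,
                           pseudocount = 1e-6)
    expect_equal(fD$track$score[6],
                 log2(2 * sum(base) / sum(dbl)), tolerance = 0.01)
    expect_error(binnedFoldChange(a, b, binSize = 0), "> 0")
})

test_that("per-layer boundary fold profiles localize a planted flank signal", {
    sl <- c(chrP = 2e7)
    nad <- GRanges("chrP", IRanges(5e6 + 1, 7e6), seqlengths = sl)
    lad <- GRanges("chrP", IRanges(12e6 + 1, 14e6), seqlengths = sl)
    part <- classifyLayers(nad, lad)
    # fold change elevated only in the 400-kb flanks of the NAD-only
    # domain
    flanks <- GRanges("chrP", IRanges(c(5e6 - 4e5 + 1, 7e6 + 1),
                                      c(5e6, 7e6 + 4e5)),
                      seqlengths = sl)
    fc <- indicatorTrack(flanks, sl)
    prof <- borderFoldProfile(fc, part, flank = 5e5, binWidth = 1e5)
    nadCurve <- prof[["NAD-only"]]$meanCurve
    ladCurve <- prof[["LAD-only"]]$meanCurve
    outer <- prof[["NAD-only"]]$positions < 0
    expect_gt(mean(nadCurve[outer]), 0.7)
    expect_equal(unname(ladCurve), rep(0, 10))
    # zero fold change gives flat zero curves for every layer
    zero <- fc; zero$score <- 0
    profZ <- borderFoldProfile(zero, part, flank = 5e5, binWidth = 1e5)
    for (lv in c("NAD-only", "LAD-only"))
        expect_equal(unname(profZ[[lv]]$meanCurve), rep(0, 10))
})

test_that("RPKM follows the closed form with a strict expression cutoff", {
    t1 <- computeRpkm(10, 1000, 1e7)
    expect_equal(t1$rpkm, 1.0)
    expect_equal(t1$class, "low")       # exactly 1 is low
    t2 <- computeRpkm(500, 2000, 25e6)
    expect_equal(t2$rpkm, 10.0)
    expect_equal(t2$class, "expressed")
    t3 <- computeRpkm(0, 1000, 1e7)
    expect_equal(t3$rpkm, 0)
    expect_equal(t3$class, "low")
    expect_error(computeRpkm(5, 0, 1e7), "length")
    # linear in counts, inverse-linear in library size
    expect_equal(computeRpkm(40, 1000, 1e7)$rpkm,
                 4 * computeRpkm(10, 1000, 1e7)$rpkm)
    expect_equal(computeRpkm(10, 1000, 2e7)$rpkm,
                 computeRpkm(10, 1000, 1e7)$rpkm / 2)
})

test_that("gene membership uses the half-open midpoint rule", {
    expect_equal(nrow(genesInDomains(GRanges(), GRanges())), 0L)
    sl <- c(chrP = 1e6)
    # gene [101, 300] 1-based -> 0-based [100, 300): midpoint0 = 200
    gene <- GRanges("chrP", IRanges(101, 300), gene_id = "g1",
                    seqlengths = sl)
    domStart <- GRanges("chrP", IRanges(201, 400), seqlengths = sl)
    expect_true(genesInDomains(gene, domStart)$member)  # mid on start
    domAfter <- GRanges("chrP", IRanges(202, 400), seqlengths = sl)
    expect_false(genesInDomains(gene, domAfter)$member)

    # planted low-expression fraction in the NAD layer recovered
    sim <- smallSim()
    ex <- simulateExpression(sim$truth, nGenes = 4000, seed = 91)
    tab <- computeRpkm(ex$counts, ex$genes$exonLength, ex$libSize,
                       geneIds = ex$genes$gene_id)
    nadLayer <- layerSet(classifyLayers(nadTruth(sim$truth),
                                        ladTruth(sim$truth)), "NAD-only")
    mem <- genesInDomains(ex$genes, nadLayer, expression = tab)
    lowFrac <- mean(mem$class[mem$member] == "low")
    # mean RPKM 0.2 -> Poisson P(count gives RPKM <= 1) ~ 0.98
    expect_gt(lowFrac, 0.9)
})
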