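## Minimal index: one 100-kb chromosome with a 10-kb terminal rDNA unit.
toyIndex <- function() genomeIndex(c(chrR = 110000), "chrR:100001-110000")

test_that("rDNA unit appending preserves coordinates and records the interval", {
    genome <- Biostrings::DNAStringSet(c(chrX = randomGatcFreeDna(5000),
                                         chrY = randomGatcFreeDna(3000)))
    unit <- Biostrings::DNAStringSet(c(rdna = randomGatcFreeDna(800)))
    res <- appendRdna(genome, unit, "chrY")
    expect_equal(unname(Biostrings::width(res$genome)), c(5000, 3800))
    rd <- rdnaInterval(res$index)
    expect_equal(start(rd), 3001)
    expect_equal(end(rd), 3800)
    # pre-existing sequence (hence all features on it) unchanged
    expect_equal(as.character(Biostrings::subseq(res$genome[["chrY"]],
                                                 1, 3000)),
                 as.character(genome[["chrY"]]))
    # duplicate append refused unless forced
    expect_error(appendRdna(res$genome, unit, "chrY"), "already terminal")
    res2 <- appendRdna(res$genome, unit, "chrY", force = TRUE)
    expect_equal(unname(Biostrings::width(res2$genome)[2]), 4600)
    expect_error(appendRdna(genome, Biostrings::DNAStringSet("")), "empty")
})

test_that("Knight-Ruiz balancing equalizes row sums", {
    # 2x2 case solvable by hand: x = (1/sqrt(3), 1/sqrt(3))
    A <- matrix(c(2, 1, 1, 2), 2)
    kb <- krBalance(A, minNonzeroFrac = 0)
    expect_equal(kb$x, rep(1 / sqrt(3), 2), tolerance = 1e-8)
    expect_equal(rowSums(kb$balanced), c(1, 1), tolerance = 1e-8)

    # random positive symmetric 200x200: CV of row sums < 1e-6
    set.seed(19)
    M <- matrix(runif(200 * 200, 0.1, 2), 200)
    M <- (M + t(M)) / 2
    kb2 <- krBalance(M)
    rs <- rowSums(kb2$balanced)
    expect_lt(sd(rs) / mean(rs), 1e-6)

    # permutation invariance (up to the same permutation)
    p <- sample(200)
    kb3 <- krBalance(M[p, p])
    expect_equal(kb3$x, kb2$x[p], tolerance = 1e-6)

    expect_error(krBalance(matrix(c(1, 2, 5, 1), 2)), "symmetric")
    z <- krBalance(matrix(0, 4, 4))
    expect_true(all(z$masked))
})

test_that("low-coverage rows are masked before balancing", {
    set.seed(7)
    M <- matrix(runif(50 * 50, 0.5, 2), 50)
    M <- (M + t(M)) / 2
    M[10, ] <- 0; M[, 10] <- 0
    M[10, 11] <- M[11, 10] <- 1  # 1 nonzero of 50 -> below 10%
    kb <- krBalance(M)
    expect_true(kb$masked[10])
    expect_false(any(kb$masked[-10]))
    rs <- rowSums(kb$balanced[-10, -10])
    expect_lt(sd(rs) / mean(rs), 1e-6)
})

test_that("pair classification follows the exactly-one-end rule", {
    idx <- toyIndex()
    pairs <- data.frame(
        readID = sprintf("r%d", 1:6),
        chr1 = "chrR",
        pos1 = c(100500, 100600, 100700, 1000, 100800, 105000),
        chr2 = "chrR",
        pos2 = c(4999, 5000, 12345, 2000, 101000, 50),
        strand1 = "+", strand2 = "-")
    # r1-r3: rDNA-anchored to bins 0/5000/10000; r4 both outside;
    # r5 both inside; r6 anchored
    ct <- extractRdnaContacts(pairs, idx, binSize = 5000)
    b <- bins(ct)
    expect_equal(start(b), c(1L, 1L, 5001L, 10001L)[-2])
    expect_equal(unname(b$rawCount), c(2, 1, 1))  # bin 0 gets r1 and r6
    tl <- tallies(ct)
    expect_equal(unname(tl["retained"]), 4)
    expect_equal(unname(tl["bothInside"]), 1)
    expect_equal(unname(tl["bothOutside"]), 1)
    # conservation
    expect_equal(sum(tl[c("retained", "bothInside", "bothOutside",
                          "malformed")]), nrow(pairs))
})

test_that("malformed pair lines are skipped with a tally", {
    idx <- toyIndex()
    f <- tempfile(fileext = ".pairs")
    writeLines(c("# comment",
                 "r1\tchrR\t100500\tchrR\t4999\t+\t-",
                 "r2\tchrR\tnotanumber\tchrR\t10\t+\t-",
                 "r3\tchrR\t100600",
                 "r4\tchrElse\t5\tchrR\t100700\t+\t+"), f)
    expect_warning(ct <- extractRdnaContacts(f, idx, binSize = 5000),
                   "malformed")
    tl <- tallies(ct)
    expect_equal(unname(tl["malformed"]), 3)
    expect_equal(unname(tl["retained"]), 1)
    unlink(f)
})

test_that("blacklist filtering removes overlapping bins", {
    idx <- toyIndex()
    pairs <- data.frame(chr1 = "chrR", pos1 = c(100500, 100600, 100700),
                        chr2 = "chrR", pos2 = c(1000, 7000, 12000))
    ct <- extractRdnaContacts(pairs, idx, binSize = 5000)
    expect_length(bins(ct), 3L)
    # empty blacklist: unchanged
    ct0 <- filterBlacklist(ct, GRanges())
    expect_length(bins(ct0), 3L)
    # [4000,6000) 0-based overlaps bins [0,5000) and [5000,10000)
    bl <- GRanges("chrR", IRanges(4001, 6000))
    ct1 <- filterBlacklist(ct, bl)
    expect_equal(start(bins(ct1)), 10001L)
    expect_equal(unname(tallies(ct1)["blacklisted"]), 2)
    # whole-genome blacklist empties the table
    ct2 <- filterBlacklist(ct, GRanges("chrR", IRanges(1, 110000)))
    expect_length(bins(ct2), 0L)
})

test_that("replicate-common contacts intersect presence and average scores", {
    idx <- toyIndex()
    mk <- function(pos2, scores, rep) {
        ct <- extractRdnaContacts(
            data.frame(chr1 = "chrR", pos1 = 100500 + seq_along(pos2),
                       chr2 = "chrR", pos2 = pos2),
            idx, binSize = 5000, replicate = rep)
        ct@bins$score <- scores
        ct
    }
    r1 <- mk(c(1000), 2, "r1")
    r2 <- mk(c(1200), 4, "r2")
    r3 <- mk(c(1400), 6, "r3")
    cc <- commonContacts(list(r1, r2, r3))
    expect_length(bins(cc), 1L)
    expect_equal(bins(cc)$score, 4.0)
    # identical tables reproduce themselves
    cc2 <- commonContacts(list(r1, r1))
    expect_equal(bins(cc2)$score, bins(r1)$score)
    # disjoint tables give an empty result
    r4 <- mk(c(22000), 1, "r4")
    expect_length(bins(commonContacts(list(r1, r4))), 0L)
    # inconsistent binning errors
    r5 <- extractRdnaContacts(
        data.frame(chr1 = "chrR", pos1 = 100500, chr2 = "chrR",
                   pos2 = 1000), idx, binSize = 10000)
    expect_error(commonContacts(list(r1, r5)), "inconsistent")
})

test_that("quintile proportions are normalized and detect uniformity", {
    idx <- genomeIndex(c(chrQ = 50e6, chrTiny = 2e4),
                       rdna = GRanges("chrTiny", IRanges(10001, 20000),
                                      seqlengths = c(chrQ = 50e6,
                                                     chrTiny = 2e4)))
    set.seed(3)
    # 10,000 uniform unique contact bins on chrQ
    starts <- sample(seq(0, 50e6 - 5000, by = 5000), 10000)
    gr <- GRanges("chrQ", IRanges(starts + 1, starts + 5000),
                  rawCount = 1, score = 1,
                  seqlengths = c(chrQ = 50e6, chrTiny = 2e4))
    ct <- new("ContactTable", bins = sort(gr), binSize = 5000,
              replicate = "u",
              tallies = c(retained = 10000, bothInside = 0,
                          bothOutside = 0, malformed = 0,
                          blacklisted = 0))
    expect_warning(qd <- quintileDistribution(ct, idx), "excluded")
    expect_equal(sum(qd$perChromosome["chrQ", ]), 1.0)
    expect_true(all(abs(qd$perChromosome["chrQ", ] - 0.2) < 0.02))

    # all contacts in the first fifth
    gr1 <- GRanges("chrQ", IRanges(c(1, 5001), width = 5000),
                   rawCount = 1, score = 1,
                   seqlengths = c(chrQ = 50e6, chrTiny = 2e4))
    ct1 <- new("ContactTable", bins = gr1, binSize = 5000,
               replicate = "u", tallies = c(retained = 2))
    suppressWarnings(qd1 <- quintileDistribution(ct1, idx))
    expect_equal(unname(qd1$perChromosome["chrQ", ]), c(1, 0, 0, 0, 0))
})

test_that("per-chromosome summaries count unique bins", {
    idx <- toyIndex()
    # duplicate raw pairs into one bin remain one unique contact
    pairs <- data.frame(chr1 = "chrR", pos1 = c(100500, 100600),
                        chr2 = "chrR", pos2 = c(1000, 1200))
    ct <- extractRdnaContacts(pairs, idx, binSize = 5000)
    s <- perChromosomeSummary(ct)
    expect_equal(s$uniqueContacts, 1L)
    expect_equal(s$totalRaw, 2)
})

test_that("rDNA-targeted simulation concentrates contacts where planted", {
    # NADs only on the rDNA-carrying chromosome -> it ranks first
    lay <- data.frame(chrom = "chrB",
                      start = c(1e6, 4e6, 7e6),
                      end = c(3e6, 6e6, 9e6),
                      label = "NAD-only")
    cfg <- simConfig(chromLengths = c(chrA = 10e6, chrB = 10e6),
                     rdnaUnitLength = 2e4, domainLayout = lay,
                     compartmentPeriod = 1e6, seed = 13)
    sim <- simulateGenome(cfg)
    pr <- simulateHicPairs(sim$truth, nPairs = 1e5, rdnaBoost = 10,
                           q1Boost = 1, compBoost = 1,
                           rdnaFraction = 0.4, seed = 14)
    idx <- genomeIndex(seqlengths(sim$truth@seqinfo),
                       rdnaInterval(sim$truth))
    ct <- extractRdnaContacts(pr, idx, binSize = 5000)
    s <- perChromosomeSummary(ct)
    expect_equal(s$chrom[which.max(s$uniqueContacts)], "chrB")
})
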