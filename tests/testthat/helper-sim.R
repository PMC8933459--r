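## Shared fixtures, generated once per test run.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(Biostrings)
})

## Small two-chromosome simulation with all three planted labels.
smallLayout <- function() {
    data.frame(
        chrom = rep(c("chrA", "chrB"), each = 4),
        start = c(1e6, 3e6, 5e6, 7.5e6, 1.2e6, 3.2e6, 5.2e6, 7.7e6),
        end   = c(2e6, 4e6, 6e6, 8.5e6, 2.2e6, 4.2e6, 6.2e6, 8.7e6),
        label = rep(c("NAD-only", "NAD/LAD", "LAD-only", "NAD-only"), 2))
}

smallConfig <- function(...) {
    simConfig(chromLengths = c(chrA = 10e6, chrB = 10e6),
              rdnaUnitLength = 2e4,
              domainLayout = smallLayout(),
              compartmentPeriod = 1e6,
              damidDepth = 5e5,
              hicNPairs = 2e5,
              seed = 42L, ...)
}

.simCache <- new.env(parent = emptyenv())

## Memoized small genome + fragment map shared across test files.
smallSim <- function() {
    if (is.null(.simCache$small)) {
        sim <- simulateGenome(smallConfig())
        sim$map <- buildGatcFragments(sim$genome)
        .simCache$small <- sim
    }
    .simCache$small
}

## Memoized full-scale (3 x 30 Mb) genome for the acceptance suite.
fullSim <- function(layout = NULL) {
    key <- if (is.null(layout)) "default" else attr(layout, "key")
    if (is.null(key)) key <- "custom"
    slot <- paste0("full_", key)
    if (is.null(.simCache[[slot]])) {
        cfg <- if (is.null(layout)) simConfig(seed = 7L)
               else simConfig(domainLayout = layout, seed = 7L)
        sim <- simulateGenome(cfg)
        .simCache[[slot]] <- sim
    }
    .simCache[[slot]]
}

fullMap <- function() {
    if (is.null(.simCache$fullMap))
        .simCache$fullMap <- buildGatcFragments(fullSim()$genome)
    .simCache$fullMap
}

## DamID -> binned ratio track for one replicate.
ratioTrackFor <- function(truth, map, seed, depth = NULL,
                          enrichment = NULL) {
    args <- list(truth = truth, map = map, seed = seed)
    if (!is.null(depth)) args$depth <- depth
    if (!is.null(enrichment)) args$enrichment <- enrichment
    dd <- do.call(simulateDamid, args)
    binTrack(damidRatio(dd$nols, dd$dam))
}

## bp-level Jaccard index between two interval sets.
bpJaccard <- function(a, b) {
    a <- reduce(if (is(a, "DomainSet")) domains(a) else a)
    b <- reduce(if (is(b, "DomainSet")) domains(b) else b)
    i <- sum(width(GenomicRanges::intersect(a, b, ignore.strand = TRUE)))
    u <- sum(width(GenomicRanges::union(a, b, ignore.strand = TRUE)))
    i / u
}

## Random GATC-free DNA for hand-built sequences.
randomGatcFreeDna <- function(n) {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    gsub("GATC", "GATA", s, fixed = TRUE)
}

## FragmentCounts with given counts on a map (for closed-form tests).
manualCounts <- function(map, counts) {
    new("FragmentCounts", map = map, counts = as.integer(counts),
        skipped = c(unknownChrom = 0, outOfBounds = 0))
}
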