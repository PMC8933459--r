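#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators: toy genome
#' geometry, planted NAD/LAD domain layout, compartment checkerboard,
#' DamID depth/enrichment/dispersion, Hi-C pair counts and boosts, and
#' state-dependent ChIP and expression means. The defaults describe the
#' desk-scale study conditions used throughout the package's tests:
#' three 30-Mb chromosomes carrying 24 planted Mb-scale domains, a 45-kb
#' rRNA gene unit appended to the last chromosome, 2M DamID reads per
#' sample with 4-fold nucleolar enrichment, and distance-decaying Hi-C
#' pairs with 5-fold rDNA-anchored enrichment into planted NADs.
#'
#' @param chromLengths Named vector of chromosome lengths in bp.
#' @param gatcSpacingMean Mean spacing between planted GATC motifs (bp).
#' @param rdnaUnitLength Length of the rRNA gene unit appended to the
#'   last chromosome (bp).
#' @param domainLayout `GRanges` (1-based) or data.frame with 0-based
#'   half-open `chrom`,`start`,`end`,`label` columns giving the planted
#'   architecture; labels from [layerLevels()] (or "none"). `NULL` uses a
#'   default alternating layout with eight 1.2-Mb domains per chromosome.
#' @param compartmentPeriod A/B checkerboard block size (bp).
#' @param damidDepth Total reads per DamID sample.
#' @param damidEnrichment Fold enrichment of the nucleolar-targeted Dam
#'   sample inside planted NADs.
#' @param damidDispersion Negative-binomial dispersion of fragment
#'   counts (0 = Poisson).
#' @param hicNPairs Number of simulated Hi-C pairs.
#' @param hicDecayAlpha Exponent of the contact-probability decay
#'   P(s) ~ s^-alpha.
#' @param hicRdnaBoost Fold oversampling of rDNA-anchored pairs into
#'   planted NAD bins.
#' @param hicQuintile1Boost Fold oversampling of rDNA-anchored pairs
#'   into the centromere-proximal first fifth of each chromosome.
#' @param hicCompartmentBoost Fold oversampling of same-compartment cis
#'   pairs (checkerboard strength).
#' @param hicRdnaFraction Fraction of simulated pairs that are
#'   rDNA-anchored.
#' @param chipStateMeans Named list: mark -> named vector of mean signal
#'   per layer (all four [layerLevels()]).
#' @param exprStateMeans Named vector of mean RPKM per layer.
#' @param exprLibSize Library size used to convert RPKM to counts.
#' @param seed Integer master seed; all generators derive their streams
#'   from it.
#' @return A validated [SimConfig-class].
#' @export
#' @examples
#' cfg <- simConfig(chromLengths = c(chrA = 5e6, chrB = 5e6), seed = 11)
#' cfg
simConfig <- function(chromLengths = c(chr1 = 30e6, chr2 = 30e6,
                                       chr3 = 30e6),
                      gatcSpacingMean = 500,
                      rdnaUnitLength = 45000,
                      domainLayout = NULL,
                      compartmentPeriod = 2e6,
                      damidDepth = 2e6,
                      damidEnrichment = 4,
                      damidDispersion = 0.2,
                      hicNPairs = 1e6,
                      hicDecayAlpha = 1,
                      hicRdnaBoost = 5,
                      hicQuintile1Boost = 2,
                      hicCompartmentBoost = 2,
                      hicRdnaFraction = 0.1,
                      chipStateMeans = list(
                          H3K9me2 = c("NAD-only" = 2, "NAD/LAD" = 4,
                                      "LAD-only" = 2, "iNAD/iLAD" = 1),
                          H3K9me3 = c("NAD-only" = 3, "NAD/LAD" = 3,
                                      "LAD-only" = 2, "iNAD/iLAD" = 1)),
                      exprStateMeans = c("NAD-only" = 0.2, "NAD/LAD" = 0.2,
                                         "LAD-only" = 0.5,
                                         "iNAD/iLAD" = 5),
                      exprLibSize = 2e7,
                      seed = 1L) {
    if (is.null(domainLayout))
        domainLayout <- .defaultLayout(chromLengths)
    if (is.data.frame(domainLayout)) {
        domainLayout <- GRanges(domainLayout$chrom,
                                IRanges(domainLayout$start + 1,
                                        domainLayout$end),
                                label = domainLayout$label)
    }
    if (is.null(domainLayout$label) && length(domainLayout))
        stop("domainLayout needs a 'label' column")
    if (any(chromLengths < rdnaUnitLength))
        stop("invalid config: chromosome shorter than rdnaUnitLength")
    new("SimConfig",
        chromLengths = chromLengths,
        gatcSpacingMean = gatcSpacingMean,
        rdnaUnitLength = rdnaUnitLength,
        domainLayout = domainLayout,
        compartmentPeriod = compartmentPeriod,
        damidDepth = damidDepth,
        damidEnrichment = damidEnrichment,
        damidDispersion = damidDispersion,
        hicNPairs = hicNPairs,
        hicDecayAlpha = hicDecayAlpha,
        hicRdnaBoost = hicRdnaBoost,
        hicQuintile1Boost = hicQuintile1Boost,
        hicCompartmentBoost = hicCompartmentBoost,
        hicRdnaFraction = hicRdnaFraction,
        chipStateMeans = chipStateMeans,
        exprStateMeans = exprStateMeans,
        exprLibSize = exprLibSize,
        seed = as.integer(seed))
}

## Alternating Mb-scale domains: eight 1.2-Mb blocks per chromosome,
## labels cycling through NAD-only / NAD-LAD / LAD-only.
.defaultLayout <- function(chromLengths) {
    labs <- c("NAD-only", "NAD/LAD", "LAD-only")
    rows <- lapply(names(chromLengths), function(chr) {
        L <- chromLengths[[chr]]
        n <- max(0L, min(8L, floor((L - 2e6) / 3.5e6)))
        if (n == 0L) return(NULL)
        starts <- 2e6 + (seq_len(n) - 1) * 3.5e6
        data.frame(chrom = chr, start = starts, end = starts + 1.2e6,
                   label = rep_len(labs, n))
    })
    df <- do.call(rbind, rows)
    if (is.null(df)) return(GRanges())
    GRanges(df$chrom, IRanges(df$start + 1, df$end), label = df$label)
}

## Random DNA guaranteed free of the GATC motif.
.gatcFreeSequence <- function(n) {
    s <- rawToChar(sample(as.raw(c(65L, 67L, 71L, 84L)), n,
                          replace = TRUE))
    # GATC occurrences cannot overlap and GATC -> GATA cannot create a
    # new occurrence, so one pass removes them all
    gsub("GATC", "GATA", s, fixed = TRUE)
}

## Motif start positions (1-based) from a Poisson process with mean
## spacing `spacing`, overlapping placements rejected.
.motifStarts <- function(L, spacing) {
    if (L < 8L) return(integer(0))
    gaps <- rexp(ceiling(L / spacing * 1.5) + 100, rate = 1 / spacing)
    while (sum(gaps) < L)
        gaps <- c(gaps, rexp(1000, rate = 1 / spacing))
    pos <- floor(cumsum(gaps)) + 1
    pos <- pos[pos <= L - 3]
    repeat {
        bad <- which(diff(pos) < 4L) + 1L
        if (!length(bad)) break
        pos <- pos[-bad]
    }
    as.integer(pos)
}

#' Simulate a toy genome with planted architecture
#'
#' Generates a GATC-free random genome, plants GATC motifs as a Poisson
#' process with the configured mean spacing, appends an rRNA gene unit
#' to the end of the last chromosome (mirroring the rDNA-appended
#' reference used for anchor extraction), and records the planted
#' NAD/LAD intervals and A/B compartment checkerboard as ground truth.
#'
#' @param config A [SimConfig-class].
#' @param outdir Optional directory; when given, writes `genome.fa`,
#'   `chrom.sizes`, and BED files of the planted truth.
#' @return A list with elements `genome` (a
#'   [Biostrings::DNAStringSet]) and `truth` (a [SimTruth-class]).
#' @export
#' @examples
#' cfg <- simConfig(chromLengths = c(chrT = 2e6), rdnaUnitLength = 10000,
#'                  seed = 3)
#' sim <- simulateGenome(cfg)
#' sim$truth
simulateGenome <- function(config, outdir = NULL) {
    validObject(config)
    cl <- config@chromLengths
    lastChr <- names(cl)[length(cl)]
    .withSeed(.subSeed(config@seed, 101), {
        seqs <- lapply(names(cl), function(chr) {
            L <- as.integer(cl[[chr]])
            s <- .gatcFreeSequence(L)
            pos <- .motifStarts(L, config@gatcSpacingMean)
            if (length(pos)) {
                r <- charToRaw(s)
                idx <- rep(pos, each = 4L) + rep(0:3, length(pos))
                r[idx] <- rep(charToRaw("GATC"), length(pos))
                s <- rawToChar(r)
            }
            if (chr == lastChr && config@rdnaUnitLength > 0)
                s <- paste0(s, .gatcFreeSequence(
                    as.integer(config@rdnaUnitLength)))
            s
        })
        genome <- Biostrings::DNAStringSet(unlist(seqs))
        names(genome) <- names(cl)
    })
    finalLen <- cl
    finalLen[lastChr] <- finalLen[lastChr] + config@rdnaUnitLength
    si <- Seqinfo(names(finalLen), seqlengths = finalLen)

    rdna <- if (config@rdnaUnitLength > 0) {
        GRanges(lastChr, IRanges(cl[[lastChr]] + 1, finalLen[[lastChr]]),
                seqinfo = si)
    } else GRanges(seqinfo = si)

    lay <- config@domainLayout
    seqlevels(lay) <- seqlevels(si)
    seqinfo(lay) <- si
    nad <- reduce(lay[lay$label %in% c("NAD-only", "NAD/LAD")])
    lad <- reduce(lay[lay$label %in% c("NAD/LAD", "LAD-only")])

    comp <- .checkerboard(si, config@compartmentPeriod)

    truth <- new("SimTruth", nadTruth = nad, ladTruth = lad,
                 compartmentTruth = comp, rdna = rdna, seqinfo = si,
                 config = config)
    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        Biostrings::writeXStringSet(genome, file.path(outdir, "genome.fa"))
        write.table(data.frame(names(finalLen), finalLen),
                    file.path(outdir, "chrom.sizes"), sep = "\t",
                    quote = FALSE, row.names = FALSE, col.names = FALSE)
        rtracklayer::export(nad, file.path(outdir, "nad_truth.bed"))
        rtracklayer::export(lad, file.path(outdir, "lad_truth.bed"))
    }
    list(genome = genome, truth = truth)
}

## Alternating A/B blocks of the configured period on every chromosome.
.checkerboard <- function(si, period) {
    sl <- seqlengths(si)
    rows <- do.call(rbind, lapply(names(sl), function(chr) {
        starts <- seq(1, sl[[chr]], by = period)
        data.frame(chr = chr, start = starts,
                   end = pmin(starts + period - 1, sl[[chr]]),
                   state = ifelse(seq_along(starts) %% 2L == 1L,
                                  "A", "B"))
    }))
    gr <- GRanges(rows$chr, IRanges(rows$start, rows$end), seqinfo = si)
    gr$state <- rows$state
    sort(gr)
}

#' Simulate DamID fragment counts
#'
#' Draws negative-binomial read counts per GATC fragment for the free
#' Dam control and the nucleolar-targeted sample. Control means are
#' proportional to fragment length; the nucleolar sample multiplies the
#' mean of every fragment whose midpoint lies inside a planted NAD by
#' the configured fold enrichment, then renormalizes so both libraries
#' have the configured expected depth.
#'
#' @param truth A [SimTruth-class].
#' @param map A [GatcFragmentMap-class] built from the simulated genome.
#' @param depth,enrichment,dispersion Override the corresponding
#'   `SimConfig` values.
#' @param seed Integer seed for this draw (replicates use different
#'   seeds); defaults to a stream derived from the config seed.
#' @return List with `nols` and `dam`, both [FragmentCounts-class].
#' @export
simulateDamid <- function(truth, map,
                          depth = truthConfig(truth)@damidDepth,
                          enrichment = truthConfig(truth)@damidEnrichment,
                          dispersion = truthConfig(truth)@damidDispersion,
                          seed = .subSeed(truthConfig(truth)@seed, 202)) {
    stopifnot(is(truth, "SimTruth"), is(map, "GatcFragmentMap"))
    fr <- map@fragments
    if (length(fr) == 0L) stop("empty fragment map")
    mids <- GRanges(seqnames(fr),
                    IRanges(start(fr) + floor((width(fr) - 1) / 2),
                            width = 1))
    inNad <- overlapsAny(mids, truth@nadTruth)
    w <- as.numeric(width(fr))
    muDam <- depth * w / sum(w)
    wN <- w * ifelse(inNad, enrichment, 1)
    muNols <- depth * wN / sum(wN)
    .withSeed(seed, {
        draw <- function(mu) {
            if (dispersion <= 0) rpois(length(mu), mu)
            else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
        }
        nols <- draw(muNols)
        dam <- draw(muDam)
    })
    mk <- function(x) new("FragmentCounts", map = map,
                          counts = as.integer(x),
                          skipped = c(unknownChrom = 0, outOfBounds = 0))
    list(nols = mk(nols), dam = mk(dam))
}

#' Simulate Hi-C pairs
#'
#' Generates 7-column pairs records (readID chr1 pos1 chr2 pos2 strand1
#' strand2; positions 0-based). Background cis pairs follow the
#' distance decay P(s) ~ s^-alpha, with same-compartment pairs of the
#' planted checkerboard oversampled by the compartment boost
#' (rejection sampling). A configured fraction of pairs is anchored in
#' the rDNA interval, with the distal end drawn from per-bin weights
#' boosted inside planted NADs and inside the centromere-proximal first
#' fifth of each chromosome.
#'
#' @param truth A [SimTruth-class].
#' @param nPairs,alpha,rdnaBoost,q1Boost,compBoost,rdnaFraction Override
#'   the corresponding `SimConfig` values.
#' @param seed Integer seed.
#' @param path Optional file path; when given the pairs are written as
#'   tab text and the path returned invisibly.
#' @param weightBin Bin size used to discretize the rDNA-target weights.
#' @param sMin Minimum cis separation (bp).
#' @return A data.frame of pairs (or the path, invisibly).
#' @export
simulateHicPairs <- function(truth,
                             nPairs = truthConfig(truth)@hicNPairs,
                             alpha = truthConfig(truth)@hicDecayAlpha,
                             rdnaBoost = truthConfig(truth)@hicRdnaBoost,
                             q1Boost = truthConfig(truth)@hicQuintile1Boost,
                             compBoost =
                                 truthConfig(truth)@hicCompartmentBoost,
                             rdnaFraction =
                                 truthConfig(truth)@hicRdnaFraction,
                             seed = .subSeed(truthConfig(truth)@seed, 303),
                             path = NULL, weightBin = 1e5, sMin = 1000) {
    stopifnot(is(truth, "SimTruth"))
    if (nPairs <= 0) stop("hic_n_pairs must be > 0")
    sl <- seqlengths(truth@seqinfo)
    nR <- if (length(truth@rdna)) round(nPairs * rdnaFraction) else 0L
    nB <- nPairs - nR
    .withSeed(seed, {
        bg <- .simBackgroundPairs(truth, nB, alpha, compBoost, sl, sMin)
        rd <- .simRdnaPairs(truth, nR, rdnaBoost, q1Boost, sl, weightBin)
        df <- rbind(bg, rd)
        if (nrow(df)) {
            df <- df[sample.int(nrow(df)), , drop = FALSE]
            df <- data.frame(readID = sprintf("read%07d", seq_len(nrow(df))),
                             df, row.names = NULL)
            df$strand1 <- sample(c("+", "-"), nrow(df), replace = TRUE)
            df$strand2 <- sample(c("+", "-"), nrow(df), replace = TRUE)
        }
    })
    if (!is.null(path)) {
        write.table(df, path, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        return(invisible(path))
    }
    df
}

.simBackgroundPairs <- function(truth, n, alpha, compBoost, sl, sMin) {
    out <- vector("list", 0L)
    got <- 0L
    compState <- function(chr, pos0) {
        g <- GRanges(chr, IRanges(pos0 + 1, width = 1))
        hits <- findOverlaps(g, truth@compartmentTruth, select = "first")
        truth@compartmentTruth$state[hits]
    }
    while (got < n) {
        m <- min(5e5, ceiling((n - got) * compBoost * 1.3) + 1000)
        chr <- sample(names(sl), m, replace = TRUE, prob = sl)
        len <- sl[chr]
        pos1 <- floor(runif(m) * len)
        s <- round(.rPowerLaw(m, alpha, sMin, len))
        pos2 <- pos1 + sample(c(-1, 1), m, replace = TRUE) * s
        ok <- pos2 >= 0 & pos2 < len
        chr <- chr[ok]; pos1 <- pos1[ok]; pos2 <- pos2[ok]
        if (compBoost != 1 && length(chr)) {
            same <- compState(chr, pos1) == compState(chr, pos2)
            keep <- runif(length(chr)) < ifelse(same, 1, 1 / compBoost)
            chr <- chr[keep]; pos1 <- pos1[keep]; pos2 <- pos2[keep]
        }
        if (length(chr)) {
            take <- min(length(chr), n - got)
            out[[length(out) + 1L]] <-
                data.frame(chr1 = chr[seq_len(take)],
                           pos1 = pos1[seq_len(take)],
                           chr2 = chr[seq_len(take)],
                           pos2 = pos2[seq_len(take)])
            got <- got + take
        }
    }
    if (length(out)) do.call(rbind, out)
    else data.frame(chr1 = character(), pos1 = numeric(),
                    chr2 = character(), pos2 = numeric())
}

.simRdnaPairs <- function(truth, n, rdnaBoost, q1Boost, sl, weightBin) {
    if (n <= 0)
        return(data.frame(chr1 = character(), pos1 = numeric(),
                          chr2 = character(), pos2 = numeric()))
    tiles <- .tileBins(truth@seqinfo, weightBin)
    tiles <- tiles[!overlapsAny(tiles, truth@rdna)]
    mids <- GRanges(seqnames(tiles),
                    IRanges(start(tiles) + floor((width(tiles) - 1) / 2),
                            width = 1))
    w <- as.numeric(width(tiles))
    w <- w * ifelse(overlapsAny(mids, truth@nadTruth), rdnaBoost, 1)
    q1 <- (start(mids) - 1) < sl[as.character(seqnames(mids))] / 5
    w <- w * ifelse(q1, q1Boost, 1)
    pick <- sample.int(length(tiles), n, replace = TRUE, prob = w)
    pos2 <- start(tiles)[pick] - 1 + floor(runif(n) * width(tiles)[pick])
    rchr <- as.character(seqnames(truth@rdna))
    pos1 <- start(truth@rdna) - 1 + floor(runif(n) * width(truth@rdna))
    data.frame(chr1 = rchr, pos1 = pos1,
               chr2 = as.character(seqnames(tiles))[pick], pos2 = pos2)
}

#' Simulate ChIP coverage tracks
#'
#' Draws gamma-distributed per-bin signal (default 50-bp bins) around
#' the mean configured for the repressive layer each bin falls in.
#'
#' @param truth A [SimTruth-class].
#' @param marks Named list of per-layer means (defaults to the config's
#'   `chipStateMeans`).
#' @param binSize Bin width in bp.
#' @param shape Gamma shape parameter (mean / shape = scale).
#' @param seed Integer seed.
#' @param outdir Optional directory; one bedgraph per mark is written.
#' @return Named list of `GRanges` with a `score` column.
#' @export
simulateChipTracks <- function(truth,
                               marks = truthConfig(truth)@chipStateMeans,
                               binSize = 50, shape = 5,
                               seed = .subSeed(truthConfig(truth)@seed,
                                               404),
                               outdir = NULL) {
    stopifnot(is(truth, "SimTruth"))
    part <- classifyLayers(truth@nadTruth, truth@ladTruth)
    tiles <- .tileBins(truth@seqinfo, binSize)
    mids <- GRanges(seqnames(tiles),
                    IRanges(start(tiles) + floor((width(tiles) - 1) / 2),
                            width = 1))
    hit <- findOverlaps(mids, part@ranges, select = "first")
    layer <- as.character(part@ranges$layer)[hit]
    out <- list()
    .withSeed(seed, {
        for (mk in names(marks)) {
            mu <- marks[[mk]]
            if (!all(.LAYER_LEVELS %in% names(mu)))
                stop("missing label mean for mark ", mk)
            m <- unname(mu[layer])
            score <- numeric(length(tiles))
            pos <- m > 0
            score[pos] <- rgamma(sum(pos), shape = shape,
                                 rate = shape / m[pos])
            gr <- tiles
            gr$score <- score
            out[[mk]] <- gr
        }
    })
    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        for (mk in names(out))
            rtracklayer::export(out[[mk]],
                                file.path(outdir,
                                          paste0(mk, ".bedgraph")),
                                format = "bedGraph")
    }
    out
}

#' Simulate gene models and expression counts
#'
#' Places genes uniformly along the genome and draws Poisson exon read
#' counts whose expectation gives each gene the mean RPKM configured for
#' the layer containing its midpoint.
#'
#' @param truth A [SimTruth-class].
#' @param nGenes Number of genes to place.
#' @param libSize Library size (total mapped reads) used for the
#'   RPKM-to-count conversion.
#' @param exonLength Union-exon length per gene (bp).
#' @param geneLength Gene body length (bp).
#' @param seed Integer seed.
#' @param outdir Optional directory; writes a GTF-style gene model file
#'   and a tab-delimited count table.
#' @return List with `genes` (`GRanges` with `gene_id`, `exonLength`),
#'   `counts` (integer vector) and `libSize`.
#' @export
simulateExpression <- function(truth, nGenes,
                               libSize = truthConfig(truth)@exprLibSize,
                               exonLength = 2000, geneLength = 10000,
                               seed = .subSeed(truthConfig(truth)@seed,
                                               505),
                               outdir = NULL) {
    stopifnot(is(truth, "SimTruth"))
    if (nGenes <= 0) stop("n_genes must be > 0")
    sl <- seqlengths(truth@seqinfo)
    part <- classifyLayers(truth@nadTruth, truth@ladTruth)
    means <- truthConfig(truth)@exprStateMeans
    if (!all(.LAYER_LEVELS %in% names(means)))
        stop("exprStateMeans must name all four layers")
    .withSeed(seed, {
        chr <- sample(names(sl), nGenes, replace = TRUE, prob = sl)
        start0 <- floor(runif(nGenes) * (sl[chr] - geneLength))
        genes <- GRanges(chr, IRanges(start0 + 1, width = geneLength),
                         seqinfo = truth@seqinfo)
        genes$gene_id <- sprintf("gene%05d", seq_len(nGenes))
        genes$exonLength <- exonLength
        mids <- GRanges(seqnames(genes),
                        IRanges(start(genes) +
                                    floor((width(genes) - 1) / 2),
                                width = 1))
        hit <- findOverlaps(mids, part@ranges, select = "first")
        mu <- means[as.character(part@ranges$layer)[hit]] *
            (exonLength / 1e3) * (libSize / 1e6)
        counts <- rpois(nGenes, mu)
    })
    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        g <- genes
        g$type <- "gene"
        g$source <- "simulation"
        rtracklayer::export(g, file.path(outdir, "genes.gtf"),
                            format = "gtf")
        write.table(data.frame(gene_id = genes$gene_id, count = counts),
                    file.path(outdir, "exon_counts.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
    list(genes = genes, counts = as.integer(counts), libSize = libSize)
}
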