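#' Build the GATC fragment map
#'
#' Scans the genome for GATC motifs and cuts each chromosome at the
#' DpnI cleavage point between GA and TC (two bases into the motif).
#' The motif is palindromic, so a single forward-strand scan covers
#' both strands. The resulting fragments tile every chromosome exactly.
#'
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @return A [GatcFragmentMap-class].
#' @export
#' @examples
#' dna <- Biostrings::DNAStringSet(c(chrZ = "TTGATCAAGATCTT"))
#' fragments(buildGatcFragments(dna))  # [1,4], [5,10], [11,14]
buildGatcFragments <- function(genome) {
    if (is.character(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    stopifnot(is(genome, "DNAStringSet"))
    if (length(genome) == 0L || any(Biostrings::width(genome) == 0L))
        stop("empty sequence")
    names(genome) <- sub("\\s.*$", "", names(genome))
    sl <- setNames(Biostrings::width(genome), names(genome))
    si <- Seqinfo(names(sl), seqlengths = sl)
    hits <- Biostrings::vmatchPattern("GATC", genome)
    grl <- lapply(names(genome), function(chr) {
        L <- sl[[chr]]
        s1 <- Biostrings::startIndex(hits)[[match(chr, names(genome))]]
        if (is.null(s1)) s1 <- integer(0)
        # cleavage between positions s1+1 and s1+2 (GA | TC)
        cut <- sort(s1 + 1L)
        starts <- c(1L, cut + 1L)
        ends <- c(cut, L)
        GRanges(chr, IRanges(starts, ends), seqinfo = si)
    })
    fr <- sort(do.call(c, grl))
    new("GatcFragmentMap", fragments = fr)
}

#' Count reads per GATC fragment
#'
#' Assigns each read to the single fragment containing its 5'-most
#' genomic coordinate. Reads on unknown chromosomes are skipped with a
#' warning; reads outside chromosome bounds are rejected. Counted plus
#' skipped plus rejected always equals the number of input reads.
#'
#' @param reads A data.frame with columns `chrom`, `pos` (0-based 5'
#'   coordinate) and optionally `strand`, or a `GRanges` whose start is
#'   the 5' coordinate (1-based).
#' @param map A [GatcFragmentMap-class].
#' @return A [FragmentCounts-class].
#' @export
countReads <- function(reads, map) {
    stopifnot(is(map, "GatcFragmentMap"))
    fr <- map@fragments
    sl <- seqlengths(fr)
    if (is(reads, "GRanges")) {
        chrom <- as.character(seqnames(reads))
        pos1 <- ifelse(as.character(strand(reads)) == "-",
                       end(reads), start(reads))
    } else {
        stopifnot(all(c("chrom", "pos") %in% names(reads)))
        chrom <- as.character(reads$chrom)
        pos1 <- reads$pos + 1  # 0-based input
    }
    known <- chrom %in% names(sl)
    nUnknown <- sum(!known)
    if (nUnknown > 0)
        warning(nUnknown, " read(s) on unknown chromosomes skipped")
    chrom <- chrom[known]; pos1 <- pos1[known]
    inb <- pos1 >= 1 & pos1 <= sl[chrom]
    nOob <- sum(!inb)
    chrom <- chrom[inb]; pos1 <- pos1[inb]
    counts <- integer(length(fr))
    if (length(chrom)) {
        g <- GRanges(chrom, IRanges(pos1, width = 1), seqinfo = seqinfo(fr))
        hit <- findOverlaps(g, fr, select = "first")
        tab <- tabulate(hit, nbins = length(fr))
        counts <- as.integer(tab)
    }
    new("FragmentCounts", map = map, counts = counts,
        skipped = c(unknownChrom = nUnknown, outOfBounds = nOob))
}

#' Per-fragment log2 m6A ratio
#'
#' Library-size-normalized log2 ratio of the nucleolar-targeted sample
#' over the free Dam control:
#' `score_i = log2(((nols_i + psi)/N_nols) / ((dam_i + psi)/N_dam))`.
#' Fragments whose combined raw count falls below `minReads` are
#' masked.
#'
#' @param nols,dam [FragmentCounts-class] objects on the same fragment
#'   map.
#' @param pseudocount Pseudocount psi (> 0) added to raw counts.
#' @param minReads Mask floor: fragments with `nols + dam < minReads`
#'   are masked.
#' @return The fragment `GRanges` with `score` and `mask` metadata
#'   columns.
#' @export
damidRatio <- function(nols, dam, pseudocount = 1, minReads = 2) {
    stopifnot(is(nols, "FragmentCounts"), is(dam, "FragmentCounts"))
    if (pseudocount <= 0) stop("pseudocount must be > 0")
    if (!identical(granges(nols@map@fragments),
                   granges(dam@map@fragments)))
        stop("mismatched fragment maps")
    nN <- sum(as.numeric(nols@counts))
    nD <- sum(as.numeric(dam@counts))
    if (nN == 0 || nD == 0) stop("empty library")
    score <- log2(((nols@counts + pseudocount) / nN) /
                  ((dam@counts + pseudocount) / nD))
    gr <- granges(nols@map@fragments)
    gr$score <- score
    gr$mask <- (nols@counts + dam@counts) < minReads
    gr
}

#' Bin fragment scores into a ratio track
#'
#' Aggregates per-fragment scores into fixed-width bins (default 100
#' kb) as the length-weighted mean of overlapping fragment scores; a
#' fragment straddling two bins contributes to both in proportion to
#' the overlap. Bins with at least half their length covered by masked
#' fragments (or with no usable signal) are masked.
#'
#' @param fragmentScores `GRanges` with `score` and `mask` columns, as
#'   returned by [damidRatio()].
#' @param binSize Bin width in bp.
#' @return A [RatioTrack-class].
#' @export
binTrack <- function(fragmentScores, binSize = 1e5) {
    stopifnot(is(fragmentScores, "GRanges"))
    if (binSize <= 0) stop("bin_size must be > 0")
    if (is.null(fragmentScores$mask)) fragmentScores$mask <- FALSE
    bins <- .tileBins(seqinfo(fragmentScores), binSize)
    agg <- .weightedBinMeans(bins, fragmentScores, fragmentScores$score,
                             maskedSource = fragmentScores$mask)
    bins$score <- agg$mean
    bins$mask <- agg$maskedBp >= width(bins) / 2 | agg$weight == 0
    bins$score[bins$mask & !is.finite(bins$score)] <- NA_real_
    new("RatioTrack", bins = bins, binSize = binSize)
}

#' Correlation between two ratio tracks
#'
#' Pearson correlation over the bins unmasked in both tracks, the
#' replicate-agreement statistic of the DamID pipeline.
#'
#' @param a,b [RatioTrack-class] objects on identical bins.
#' @return List with `r` (Pearson correlation) and `n` (bins used).
#' @export
trackCorrelation <- function(a, b) {
    stopifnot(is(a, "RatioTrack"), is(b, "RatioTrack"))
    if (a@binSize != b@binSize ||
        !identical(granges(a@bins), granges(b@bins)))
        stop("tracks are not on the same binning")
    ok <- !a@bins$mask & !b@bins$mask
    if (sum(ok) < 3L) stop("fewer than 3 jointly unmasked bins")
    list(r = cor(a@bins$score[ok], b@bins$score[ok]), n = sum(ok))
}
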