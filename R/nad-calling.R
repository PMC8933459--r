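## Maximal runs of above-threshold bins within one chromosome.
## `above` is logical per bin (already FALSE at masked bins); returns a
## two-column matrix of run start/end indices.
.findRuns <- function(above, mergeGap = 0L) {
    r <- rle(above)
    if (mergeGap > 0L && length(r$lengths) > 2L) {
        # bridge short below-threshold gaps flanked by above-runs
        inner <- seq(2L, length(r$lengths) - 1L)
        bridge <- inner[!r$values[inner] & r$lengths[inner] <= mergeGap &
                        r$values[inner - 1L] & r$values[inner + 1L]]
        r$values[bridge] <- TRUE
        above <- inverse.rle(r)
        r <- rle(above)
    }
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values], end = ends[r$values])
}

#' Call NAD domains by quantile threshold with a permutation FDR
#'
#' Segments a binned log2 ratio track into candidate domains: the
#' threshold is the `minQuant` quantile of all unmasked scores,
#' candidates are maximal runs of consecutive unmasked above-threshold
#' bins, and each run is scored by its mean bin score. The null is
#' obtained by permuting the unmasked scores within each chromosome
#' `nShuffles` times and re-running the same detection; the FDR of a
#' run scoring `s` is the mean null count of runs scoring at least `s`
#' divided by the observed count, clamped to [0, 1]. Runs with
#' `FDR < fdrMax` are emitted with bin-resolution boundaries.
#'
#' @param track A [RatioTrack-class] with at least 100 unmasked bins.
#' @param fdrMax FDR threshold (default 0.01).
#' @param minQuant Quantile defining the score threshold (default
#'   0.70).
#' @param nShuffles Number of within-chromosome permutations.
#' @param seed Integer seed for the permutation null (required).
#' @param mergeGap Bridge below-threshold gaps of at most this many
#'   bins (default 0, no bridging).
#' @param label Label given to emitted domains.
#' @return A [DomainSet-class] with `score` (mean log2 ratio), `fdr`
#'   and `nbins` metadata.
#' @export
callPeaks <- function(track, fdrMax = 0.01, minQuant = 0.70,
                      nShuffles = 100, seed, mergeGap = 0L,
                      label = "NAD") {
    stopifnot(is(track, "RatioTrack"))
    if (missing(seed) || is.null(seed))
        stop("an explicit seed is required for the permutation null")
    b <- track@bins
    unm <- !b$mask
    if (sum(unm) < 100L)
        stop("track must have at least 100 unmasked bins")
    egr <- GRanges(seqinfo = seqinfo(b))
    mcols(egr) <- DataFrame(label = character(0), score = numeric(0),
                            fdr = numeric(0), nbins = integer(0))
    empty <- new("DomainSet", ranges = egr, binSize = track@binSize)
    if (sd(b$score[unm]) == 0) {
        warning("degenerate (constant) track: no peaks called")
        return(empty)
    }
    thr <- quantile(b$score[unm], minQuant, names = FALSE)
    chrom <- as.character(seqnames(b))
    byChrom <- split(seq_along(b), chrom)

    # runs are ranked for the FDR by their score sum (mean x length):
    # a permuted track scatters high bins into singleton runs whose
    # mean matches a genuine domain's, but whose sum cannot
    runScores <- function(score, mask) {
        out <- vector("list", length(byChrom))
        for (i in seq_along(byChrom)) {
            idx <- byChrom[[i]]
            above <- !mask[idx] & score[idx] >= thr
            runs <- .findRuns(above, mergeGap)
            if (nrow(runs)) {
                stat <- vapply(seq_len(nrow(runs)), function(k) {
                    j <- idx[runs[k, 1L]:runs[k, 2L]]
                    v <- score[j][!mask[j]]
                    c(mean(v), sum(v))
                }, numeric(2))
                out[[i]] <- data.frame(chromIdx = i,
                                       start = runs[, 1L],
                                       end = runs[, 2L],
                                       score = stat[1L, ],
                                       sum = stat[2L, ])
            }
        }
        do.call(rbind, out)
    }
    obs <- runScores(b$score, b$mask)
    if (is.null(obs) || nrow(obs) == 0L) return(empty)

    nullSums <- .withSeed(seed, {
        acc <- vector("list", nShuffles)
        for (s in seq_len(nShuffles)) {
            perm <- b$score
            for (idx in byChrom) {
                u <- idx[!b$mask[idx]]
                perm[u] <- perm[sample(u)]
            }
            r <- runScores(perm, b$mask)
            acc[[s]] <- if (is.null(r)) numeric(0) else r$sum
        }
        unlist(acc)
    })

    fdr <- vapply(obs$sum, function(s) {
        nullCount <- sum(nullSums >= s) / nShuffles
        obsCount <- sum(obs$sum >= s)
        min(1, nullCount / obsCount)
    }, numeric(1))

    keep <- fdr < fdrMax
    if (!any(keep)) return(empty)
    obs <- obs[keep, , drop = FALSE]
    fdr <- fdr[keep]
    chromNames <- names(byChrom)
    gr <- GRanges(chromNames[obs$chromIdx],
                  IRanges(start(b)[vapply(seq_len(nrow(obs)), function(k)
                              byChrom[[obs$chromIdx[k]]][obs$start[k]],
                              integer(1))],
                          end(b)[vapply(seq_len(nrow(obs)), function(k)
                              byChrom[[obs$chromIdx[k]]][obs$end[k]],
                              integer(1))]),
                  seqinfo = seqinfo(b))
    gr$label <- label
    gr$score <- obs$score
    gr$fdr <- fdr
    gr$nbins <- obs$end - obs$start + 1L
    new("DomainSet", ranges = sort(gr), binSize = track@binSize)
}

#' Intersect replicate domain calls
#'
#' Base-pair intersection of two domain sets; only regions significant
#' in both replicates survive. Intersection fragments shorter than one
#' analysis bin (by default) are dropped.
#'
#' @param a,b [DomainSet-class] objects with the same genome context.
#' @param minWidth Minimum retained fragment width in bp; defaults to
#'   the calling bin size of `a` (or 1 if unknown).
#' @param label Label for the combined set.
#' @return A [DomainSet-class].
#' @export
intersectReplicates <- function(a, b, minWidth = NULL, label = "NAD") {
    stopifnot(is(a, "DomainSet"), is(b, "DomainSet"))
    .checkSameGenome(a@ranges, b@ranges, "replicate domain sets")
    if (is.null(minWidth))
        minWidth <- if (is.na(a@binSize)) 1 else a@binSize
    gr <- GenomicRanges::intersect(.asRanges(a), .asRanges(b),
                                   ignore.strand = TRUE)
    gr <- gr[width(gr) >= minWidth]
    if (length(gr)) {
        gr$label <- label
        gr$score <- NA_real_
    }
    new("DomainSet", ranges = gr, binSize = a@binSize)
}

#' Summary statistics of a domain set
#'
#' Domain count, length distribution, genome coverage, and
#' per-chromosome coverage including the centromere-proximal first
#' fifth of each chromosome.
#'
#' @param d A [DomainSet-class] (or `GRanges` with seqlengths).
#' @return List with `count`, `minLength`, `medianLength`, `maxLength`,
#'   `totalBp`, `coverage`, and a `perChromosome` data.frame with
#'   columns `chrom`, `bp`, `coverage`, `q1Coverage`.
#' @export
domainStats <- function(d) {
    gr <- .asRanges(d)
    sl <- seqlengths(gr)
    if (length(gr) == 0L)
        return(list(count = 0L, minLength = 0, medianLength = 0,
                    maxLength = 0, totalBp = 0, coverage = 0,
                    perChromosome = data.frame(
                        chrom = character(0), bp = numeric(0),
                        coverage = numeric(0), q1Coverage = numeric(0))))
    w <- width(gr)
    perChrom <- do.call(rbind, lapply(names(sl)[!is.na(sl)],
                                      function(chr) {
        g <- gr[seqnames(gr) == chr]
        q1 <- GRanges(chr, IRanges(1, floor(sl[[chr]] / 5)))
        q1bp <- sum(width(GenomicRanges::intersect(
            g, q1, ignore.strand = TRUE)))
        data.frame(chrom = chr, bp = sum(width(g)),
                   coverage = sum(width(g)) / sl[[chr]],
                   q1Coverage = q1bp / floor(sl[[chr]] / 5))
    }))
    list(count = length(gr), minLength = min(w),
         medianLength = median(w), maxLength = max(w),
         totalBp = sum(as.numeric(w)),
         coverage = sum(as.numeric(w)) / sum(as.numeric(sl),
                                             na.rm = TRUE),
         perChromosome = perChrom)
}
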