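#' Boundary metaprofile of a signal track
#'
#' Averages a signal over domain boundaries. Every domain contributes
#' its two boundaries, both oriented so that the domain interior lies
#' on the positive side of the position axis (the left boundary is used
#' as-is, the right boundary is flipped). Boundaries whose full flanks
#' do not fit inside the chromosome are dropped and counted. Signal is
#' sampled as the length-weighted mean per position bin.
#'
#' @param track `GRanges` with a `score` column (bedgraph-style
#'   signal).
#' @param domains A [DomainSet-class] or `GRanges`.
#' @param flank Flank width on each side of the boundary (bp).
#' @param binWidth Position bin width (bp); `flank` must be a multiple.
#' @return List with `profile` (matrix boundaries x position bins),
#'   `positions` (bin centers relative to the boundary, interior
#'   positive), `meanCurve` (column means), and `dropped` (boundaries
#'   without full flanks).
#' @export
borderProfile <- function(track, domains, flank = 5e5,
                          binWidth = 1e4) {
    stopifnot(is(track, "GRanges"), !is.null(track$score))
    gr <- .asRanges(domains)
    if (flank %% binWidth != 0)
        stop("flank must be a multiple of binWidth")
    K <- as.integer(flank / binWidth)
    sl <- seqlengths(gr)
    if (all(is.na(sl))) sl <- seqlengths(track)
    # 0-based boundary coordinates; orientation +1 puts the interior
    # at increasing genomic coordinates
    b0 <- c(start(gr) - 1, end(gr))
    chrom <- rep(as.character(seqnames(gr)), 2L)
    orient <- rep(c(1L, -1L), each = length(gr))
    usable <- b0 - flank >= 0 & b0 + flank <= sl[chrom]
    usable[is.na(usable)] <- FALSE
    dropped <- sum(!usable)
    if (!any(usable)) stop("no boundary with full flanks")
    b0 <- b0[usable]; chrom <- chrom[usable]; orient <- orient[usable]
    nB <- length(b0)
    j <- seq(-K, K - 1L)            # position bin indices
    # genomic interval of position bin j at each boundary
    offs <- rep(j, times = nB)
    bAll <- rep(b0, each = 2L * K)
    oAll <- rep(orient, each = 2L * K)
    chrAll <- rep(chrom, each = 2L * K)
    lo <- ifelse(oAll == 1L, bAll + offs * binWidth,
                 bAll - (offs + 1L) * binWidth)
    binsGr <- GRanges(chrAll, IRanges(lo + 1, lo + binWidth))
    seqlevels(binsGr) <- names(sl)
    seqlengths(binsGr) <- sl
    agg <- .weightedBinMeans(binsGr, track, track$score)
    mat <- matrix(agg$mean, nrow = nB, ncol = 2L * K, byrow = TRUE)
    colnames(mat) <- sprintf("%+d", j)
    list(profile = mat,
         positions = (j + 0.5) * binWidth,
         meanCurve = colMeans(mat, na.rm = TRUE),
         dropped = dropped)
}

#' Per-domain signal aggregates
#'
#' Length-weighted mean signal per domain with a distribution summary
#' for box-plot-style comparison between layers.
#'
#' @param track `GRanges` with a `score` column.
#' @param domains A [DomainSet-class] or `GRanges`.
#' @return List with `perDomain` (data.frame chrom/start/end/mean) and
#'   `summary` (mean, median, quartiles across domains).
#' @export
domainSignal <- function(track, domains) {
    stopifnot(is(track, "GRanges"), !is.null(track$score))
    gr <- .asRanges(domains)
    if (length(gr) == 0L)
        return(list(perDomain = data.frame(chrom = character(0),
                                           start = integer(0),
                                           end = integer(0),
                                           mean = numeric(0)),
                    summary = c(mean = NA_real_, q25 = NA_real_,
                                median = NA_real_, q75 = NA_real_)))
    agg <- .weightedBinMeans(gr, track, track$score)
    per <- data.frame(chrom = as.character(seqnames(gr)),
                      start = start(gr), end = end(gr),
                      mean = agg$mean)
    m <- per$mean[is.finite(per$mean)]
    list(perDomain = per,
         summary = c(mean = mean(m),
                     q25 = quantile(m, 0.25, names = FALSE),
                     median = median(m),
                     q75 = quantile(m, 0.75, names = FALSE)))
}

#' Binned log2 fold change between two coverage tracks
#'
#' Sums read coverage of two conditions into fixed-width bins (default
#' 20 kb), normalizes each by its library size, and reports the
#' per-bin `log2((a_i/A + psi_a) / (b_i/B + psi_b))` where the
#' pseudocount corresponds to `pseudocount` reads pre-normalization
#' (`psi_a = pseudocount/A`), making the statistic antisymmetric under
#' condition swap and invariant to global scaling.
#'
#' @param condA,condB `GRanges` with a `score` column of read counts.
#' @param binSize Bin width in bp.
#' @param pseudocount Pseudocount in reads.
#' @return List with `track` (`GRanges` bins with `score` = log2 FC)
#'   and `scatter` (data.frame of normalized per-bin values).
#' @export
binnedFoldChange <- function(condA, condB, binSize = 2e4,
                             pseudocount = 1) {
    stopifnot(is(condA, "GRanges"), is(condB, "GRanges"))
    if (binSize <= 0) stop("bin size must be > 0")
    .checkSameGenome(condA, condB, "coverage tracks")
    bins <- .tileBins(seqinfo(condA), binSize)
    sumInto <- function(track) {
        hits <- findOverlaps(bins, track)
        ov <- width(pintersect(bins[queryHits(hits)],
                               track[subjectHits(hits)]))
        # reads apportioned by overlap fraction of the source interval
        contrib <- track$score[subjectHits(hits)] * ov /
            width(track)[subjectHits(hits)]
        out <- numeric(length(bins))
        if (length(hits)) {
            agg <- rowsum(contrib, queryHits(hits))
            out[as.integer(rownames(agg))] <- agg[, 1L]
        }
        out
    }
    a <- sumInto(condA); b <- sumInto(condB)
    A <- sum(a); B <- sum(b)
    if (A == 0 || B == 0) stop("empty coverage track")
    # one shared pseudocount on the normalized scale (pc reads at the
    # geometric-mean library) keeps the statistic antisymmetric and
    # exactly invariant to global scaling of either condition
    psi <- pseudocount / sqrt(A * B)
    fc <- log2((a / A + psi) / (b / B + psi))
    bins$score <- fc
    list(track = bins,
         scatter = data.frame(chrom = as.character(seqnames(bins)),
                              start = start(bins) - 1,
                              a = a / A, b = b / B, log2fc = fc))
}

#' Boundary fold-change profiles per layer
#'
#' Applies [borderProfile()] to a fold-change track at the boundaries
#' of each layer of a partition.
#'
#' @param fcTrack `GRanges` with a `score` column (e.g. the `track`
#'   element of [binnedFoldChange()]).
#' @param partition A [LayerPartition-class].
#' @param flank,binWidth Passed to [borderProfile()].
#' @param layers Which layers to profile (default all four).
#' @return Named list of [borderProfile()] results (NULL for layers
#'   with no usable boundary).
#' @export
borderFoldProfile <- function(fcTrack, partition, flank = 5e5,
                              binWidth = 1e4,
                              layers = layerLevels()) {
    stopifnot(is(partition, "LayerPartition"))
    out <- setNames(vector("list", length(layers)), layers)
    for (lv in layers) {
        gr <- layerSet(partition, lv)
        out[[lv]] <- tryCatch(
            borderProfile(fcTrack, gr, flank, binWidth),
            error = function(e) NULL)
    }
    out
}

#' RPKM expression table
#'
#' Reads per kilobase of union-exon model per million mapped reads:
#' `RPKM_g = count_g * 1e9 / (librarySize * length_g)`. A gene is
#' classed "expressed" if RPKM is strictly greater than 1, otherwise
#' "low" (RPKM exactly 1 is low).
#'
#' @param counts Integer vector of exon read counts.
#' @param exonLengths Union-exon lengths in bp (> 0).
#' @param librarySize Total mapped reads (> 0).
#' @param geneIds Optional gene identifiers.
#' @return data.frame with `gene_id`, `exonLength`, `count`, `rpkm`,
#'   `class`.
#' @export
#' @examples
#' computeRpkm(10, 1000, 1e7)   # RPKM 1, class "low"
#' computeRpkm(500, 2000, 25e6) # RPKM 10, class "expressed"
computeRpkm <- function(counts, exonLengths, librarySize,
                        geneIds = NULL) {
    exonLengths <- rep_len(exonLengths, length(counts))
    if (any(exonLengths <= 0)) stop("zero or negative exon length")
    if (librarySize <= 0) stop("library size must be > 0")
    if (any(counts < 0)) stop("negative counts")
    rpkm <- counts * 1e9 / (librarySize * exonLengths)
    if (is.null(geneIds))
        geneIds <- sprintf("gene%05d", seq_along(counts))
    data.frame(gene_id = geneIds, exonLength = exonLengths,
               count = counts, rpkm = rpkm,
               class = ifelse(rpkm > 1, "expressed", "low"))
}

#' Gene membership in domains
#'
#' Assigns genes to a domain set by the midpoint rule (half-open: a
#' midpoint exactly on a domain start is a member) and joins an
#' expression table when provided.
#'
#' @param genes `GRanges` of gene bodies with a `gene_id` column.
#' @param domains A [DomainSet-class] or `GRanges`.
#' @param expression Optional data.frame from [computeRpkm()], joined
#'   on `gene_id`.
#' @return data.frame with `gene_id`, `chrom`, `midpoint` (0-based),
#'   `member`, plus `rpkm` and `class` when expression is given.
#' @export
genesInDomains <- function(genes, domains, expression = NULL) {
    stopifnot(is(genes, "GRanges"))
    if (length(genes) == 0L) {
        out <- data.frame(gene_id = character(0), chrom = character(0),
                          midpoint = numeric(0), member = logical(0))
        return(out)
    }
    ids <- genes$gene_id
    if (is.null(ids)) ids <- sprintf("gene%05d", seq_along(genes))
    mids <- .geneMidpoints(genes)
    member <- overlapsAny(mids, .asRanges(domains),
                          ignore.strand = TRUE)
    out <- data.frame(gene_id = ids,
                      chrom = as.character(seqnames(genes)),
                      midpoint = start(mids) - 1,
                      member = member)
    if (!is.null(expression))
        out <- merge(out, expression[, c("gene_id", "rpkm", "class")],
                     by = "gene_id", sort = FALSE)
    out
}
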