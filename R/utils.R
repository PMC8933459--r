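## Internal helpers shared across modules.

## Error unless two objects share chromosome names and lengths.
.checkSameGenome <- function(a, b, what = "inputs") {
    sa <- seqlengths(a); sb <- seqlengths(b)
    common <- intersect(names(sa), names(sb))
    if (length(common) == 0L ||
        !identical(sa[common], sb[common]) ||
        !setequal(names(sa)[!is.na(sa)], names(sb)[!is.na(sb)]))
        stop(what, " have mismatched genome context (seqlengths differ)")
    invisible(TRUE)
}

## Fixed-width genome tiling; last tile per chromosome is clipped.
.tileBins <- function(si, binSize) {
    sl <- seqlengths(si)
    if (any(is.na(sl))) stop("seqlengths required for binning")
    tileGenome(sl, tilewidth = binSize, cut.last.tile.in.chrom = TRUE)
}

## GRanges from 0-based half-open coordinates.
.grFrom0 <- function(chrom, start0, end0, si = NULL, ...) {
    gr <- GRanges(chrom, IRanges(start0 + 1, end0), ...)
    if (!is.null(si)) seqinfo(gr) <- merge(seqinfo(gr), si)
    gr
}

## Inverse-CDF sampler for P(s) proportional to s^-alpha on [smin, smax].
.rPowerLaw <- function(n, alpha, smin, smax) {
    u <- runif(n)
    if (abs(alpha - 1) < 1e-12) {
        smin * (smax / smin)^u
    } else {
        a1 <- 1 - alpha
        (smin^a1 + u * (smax^a1 - smin^a1))^(1 / a1)
    }
}

## Length-weighted mean of interval scores over target bins.
## `values` and optional `masked` align with `source` ranges.
.weightedBinMeans <- function(targets, source, values, maskedSource = NULL) {
    hits <- findOverlaps(targets, source)
    qh <- queryHits(hits); sh <- subjectHits(hits)
    ov <- width(pintersect(targets[qh], source[sh]))
    n <- length(targets)
    keep <- rep(TRUE, length(sh))
    maskedBp <- numeric(n)
    if (!is.null(maskedSource)) {
        m <- maskedSource[sh]
        if (any(m)) {
            agg <- rowsum(ov[m], qh[m])
            maskedBp[as.integer(rownames(agg))] <- agg[, 1L]
        }
        keep <- !m
    }
    v <- values[sh]
    ok <- keep & !is.na(v)
    wsum <- rep(0, n); vsum <- rep(0, n)
    if (any(ok)) {
        agg <- rowsum(cbind(ov[ok], ov[ok] * v[ok]), qh[ok])
        idx <- as.integer(rownames(agg))
        wsum[idx] <- agg[, 1L]; vsum[idx] <- agg[, 2L]
    }
    list(mean = ifelse(wsum > 0, vsum / wsum, NA_real_),
         weight = wsum, maskedBp = maskedBp)
}

## Run a block of code under a fixed seed, restoring RNG state afterwards.
.withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
    force(code)
}

## Derive a stream-specific sub-seed that stays within 32-bit range.
.subSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

#' Construct a domain set
#'
#' Wraps labelled intervals into a [DomainSet-class], sorting and
#' validating them against the genome context carried by the ranges.
#'
#' @param ranges A `GRanges`; a `label` metadata column is added when
#'   absent.
#' @param label Default label applied when `ranges` has none.
#' @param score Optional per-interval scores.
#' @param binSize Analysis bin size the set derives from (NA if none).
#' @return A `DomainSet`.
#' @export
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000),
#'                              seqlengths = c(chr1 = 10000))
#' domainSet(gr, label = "NAD")
domainSet <- function(ranges, label = "domain", score = NA_real_,
                      binSize = NA_real_) {
    stopifnot(is(ranges, "GRanges"))
    gr <- sort(sortSeqlevels(ranges))
    if (is.null(gr$label)) gr$label <- rep(label, length(gr))
    if (is.null(gr$score)) gr$score <- rep(score, length(gr))
    mcols(gr) <- mcols(gr)[, c("label", "score"), drop = FALSE]
    new("DomainSet", ranges = gr, binSize = binSize)
}

## Total bp of a DomainSet / GRanges.
.domainBp <- function(x) {
    gr <- if (is(x, "DomainSet")) x@ranges else x
    sum(as.numeric(width(reduce(gr, ignore.strand = TRUE))))
}

## Coerce DomainSet-or-GRanges to plain reduced GRanges.
.asRanges <- function(x) {
    gr <- if (is(x, "DomainSet")) x@ranges else x
    reduce(granges(gr), ignore.strand = TRUE)
}
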