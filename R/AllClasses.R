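#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges granges mcols `mcols<-` seqnames start
#'   end width strand findOverlaps countOverlaps pintersect reduce gaps
#'   tileGenome shift resize
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom S4Vectors queryHits subjectHits metadata `metadata<-` Rle
#'   runValue DataFrame
#' @importFrom GenomeInfoDb seqinfo Seqinfo seqlengths seqlevels
#'   seqlevelsInUse `seqlevels<-` `seqinfo<-` keepSeqlevels sortSeqlevels
NULL

## The four mutually exclusive repressive layers of the genome.
.LAYER_LEVELS <- c("NAD-only", "NAD/LAD", "LAD-only", "iNAD/iLAD")

#' Layer level names
#'
#' The four bp-level layers the genome is partitioned into by
#' [classifyLayers()]: regions contacting only the nucleolus (NAD-only),
#' both nucleolus and lamina (NAD/LAD), only the lamina (LAD-only), or
#' neither (iNAD/iLAD).
#'
#' @return Character vector of the four layer names, in canonical order.
#' @export
layerLevels <- function() .LAYER_LEVELS

## ---------------------------------------------------------------------------
## Simulation configuration and planted truth
## ---------------------------------------------------------------------------

#' @rdname simConfig
#' @exportClass SimConfig
setClass("SimConfig", slots = c(
    chromLengths      = "numeric",
    gatcSpacingMean   = "numeric",
    rdnaUnitLength    = "numeric",
    domainLayout      = "GRanges",
    compartmentPeriod = "numeric",
    damidDepth        = "numeric",
    damidEnrichment   = "numeric",
    damidDispersion   = "numeric",
    hicNPairs         = "numeric",
    hicDecayAlpha     = "numeric",
    hicRdnaBoost      = "numeric",
    hicQuintile1Boost = "numeric",
    hicCompartmentBoost = "numeric",
    hicRdnaFraction   = "numeric",
    chipStateMeans    = "list",
    exprStateMeans    = "numeric",
    exprLibSize       = "numeric",
    seed              = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    cl <- object@chromLengths
    if (length(cl) == 0L || is.null(names(cl)) || any(!nzchar(names(cl))))
        msg <- c(msg, "chromLengths must be a named vector of lengths")
    if (any(cl <= 0)) msg <- c(msg, "all chromosome lengths must be > 0")
    if (object@gatcSpacingMean <= 0)
        msg <- c(msg, "gatcSpacingMean must be > 0")
    if (object@rdnaUnitLength < 0)
        msg <- c(msg, "rdnaUnitLength must be >= 0")
    folds <- c(object@damidEnrichment, object@hicRdnaBoost,
               object@hicQuintile1Boost, object@hicCompartmentBoost)
    if (any(folds <= 0)) msg <- c(msg, "all fold parameters must be > 0")
    if (object@hicRdnaFraction < 0 || object@hicRdnaFraction > 1)
        msg <- c(msg, "hicRdnaFraction must lie in [0, 1]")
    if (object@compartmentPeriod <= 0)
        msg <- c(msg, "compartmentPeriod must be > 0")
    lay <- object@domainLayout
    if (length(lay)) {
        if (is.null(lay$label) ||
            !all(lay$label %in% c(.LAYER_LEVELS, "none")))
            msg <- c(msg, "domainLayout labels must be layer names or 'none'")
        if (!all(as.character(seqnames(lay)) %in% names(cl)))
            msg <- c(msg, "domainLayout chromosomes missing from chromLengths")
        else if (any(end(lay) > cl[as.character(seqnames(lay))]))
            msg <- c(msg, "domainLayout intervals exceed chromosome bounds")
        red <- reduce(lay, drop.empty.ranges = TRUE)
        if (sum(width(red)) != sum(width(lay)))
            msg <- c(msg, "domainLayout intervals must be disjoint")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname simulateGenome
#' @exportClass SimTruth
setClass("SimTruth", slots = c(
    nadTruth         = "GRanges",
    ladTruth         = "GRanges",
    compartmentTruth = "GRanges",
    rdna             = "GRanges",
    seqinfo          = "Seqinfo",
    config           = "SimConfig"
))

setValidity("SimTruth", function(object) {
    msg <- character()
    if (length(object@rdna) > 1L)
        msg <- c(msg, "rdna must be empty or a single interval")
    if (length(object@rdna) == 1L) {
        chr <- as.character(seqnames(object@rdna))
        L <- seqlengths(object@seqinfo)[chr]
        if (is.na(L) || end(object@rdna) != L)
            msg <- c(msg, "rdna interval must terminate its chromosome")
    }
    if (length(object@compartmentTruth)) {
        covered <- sum(width(reduce(object@compartmentTruth)))
        if (covered != sum(seqlengths(object@seqinfo)))
            msg <- c(msg, "compartment labels must tile the genome")
    }
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DamID containers
## ---------------------------------------------------------------------------

#' GATC fragment map
#'
#' Ordered, chromosome-tiling restriction fragments delimited by DpnI
#' cleavage points (between GA and TC of each GATC motif). Built by
#' [buildGatcFragments()].
#'
#' @slot fragments A `GRanges` that tiles each chromosome exactly.
#' @exportClass GatcFragmentMap
setClass("GatcFragmentMap", slots = c(fragments = "GRanges"))

setValidity("GatcFragmentMap", function(object) {
    fr <- object@fragments
    if (length(fr) == 0L) return("fragment map is empty")
    sl <- seqlengths(fr)
    if (any(is.na(sl))) return("fragment map requires seqlengths")
    for (chr in seqlevelsInUse(fr)) {
        f <- fr[seqnames(fr) == chr]
        f <- f[order(start(f))]
        if (start(f)[1L] != 1L || end(f)[length(f)] != sl[[chr]])
            return(sprintf("fragments do not span chromosome %s", chr))
        if (length(f) > 1L &&
            any(start(f)[-1L] != end(f)[-length(f)] + 1L))
            return(sprintf("fragments on %s have gaps or overlaps", chr))
    }
    TRUE
})

#' Per-fragment read counts
#'
#' Read counts aligned to a [GatcFragmentMap-class], produced by
#' [countReads()] or [simulateDamid()].
#'
#' @slot map The fragment map the counts are indexed against.
#' @slot counts Non-negative integer counts, one per fragment.
#' @slot skipped Named tally of reads not counted (unknown chromosome,
#'   out of bounds).
#' @exportClass FragmentCounts
setClass("FragmentCounts", slots = c(
    map = "GatcFragmentMap", counts = "integer", skipped = "numeric"))

setValidity("FragmentCounts", function(object) {
    if (length(object@counts) != length(object@map@fragments))
        return("counts length must equal fragment count")
    if (any(object@counts < 0L)) return("counts must be non-negative")
    TRUE
})

#' Binned log2 m6A ratio track
#'
#' Per-bin log2 ratio of the nucleolar-targeted Dam sample over the free
#' Dam control, the DamID readout of nucleolar contact frequency. Bins
#' are constant width except at chromosome ends; bins with insufficient
#' read support are masked.
#'
#' @slot bins `GRanges` with metadata columns `score` (log2 ratio) and
#'   `mask` (`TRUE` where the score is unusable).
#' @slot binSize Bin width in bp.
#' @exportClass RatioTrack
setClass("RatioTrack", slots = c(bins = "GRanges", binSize = "numeric"))

setValidity("RatioTrack", function(object) {
    b <- object@bins
    if (!all(c("score", "mask") %in% names(mcols(b))))
        return("bins must carry 'score' and 'mask' columns")
    if (any(!is.finite(b$score[!b$mask])))
        return("unmasked scores must be finite")
    if (object@binSize <= 0) return("binSize must be > 0")
    TRUE
})

## ---------------------------------------------------------------------------
## Domain and layer containers
## ---------------------------------------------------------------------------

#' Labelled genomic domain set
#'
#' Sorted, non-overlapping labelled intervals with genome context
#' (sequence lengths), housing NADs, LADs, layers and cell-type-specific
#' sets.
#'
#' @slot ranges `GRanges` with metadata columns `label` and `score`;
#'   seqlengths define the genome context.
#' @slot binSize Analysis bin size the set was called at (NA if not
#'   applicable).
#' @exportClass DomainSet
setClass("DomainSet", slots = c(ranges = "GRanges", binSize = "numeric"))

setValidity("DomainSet", function(object) {
    gr <- object@ranges
    if (length(gr)) {
        if (is.null(gr$label)) return("ranges must carry a 'label' column")
        for (lab in unique(gr$label)) {
            g <- gr[gr$label == lab]
            if (sum(width(reduce(g))) != sum(width(g)))
                return(sprintf("intervals overlap within label '%s'", lab))
        }
        sl <- seqlengths(gr)
        present <- as.character(seqnames(gr))
        if (!any(is.na(sl[present])) && any(end(gr) > sl[present]))
            return("intervals exceed chromosome bounds")
    }
    TRUE
})

#' Genome layer partition
#'
#' The bp-exact partition of the genome into the four repressive layers
#' (see [layerLevels()]): the sets are mutually disjoint and their union
#' tiles every chromosome.
#'
#' @slot ranges `GRanges` with a `layer` factor column over
#'   [layerLevels()].
#' @exportClass LayerPartition
setClass("LayerPartition", slots = c(ranges = "GRanges"))

setValidity("LayerPartition", function(object) {
    gr <- object@ranges
    if (is.null(gr$layer)) return("ranges must carry a 'layer' column")
    if (!all(as.character(gr$layer) %in% .LAYER_LEVELS))
        return("unknown layer labels")
    sl <- seqlengths(gr)
    if (any(is.na(sl))) return("partition requires seqlengths")
    if (sum(width(reduce(gr))) != sum(width(gr)))
        return("layers overlap")
    if (sum(width(gr)) != sum(sl))
        return("layers do not tile the genome")
    TRUE
})

## ---------------------------------------------------------------------------
## Hi-C containers
## ---------------------------------------------------------------------------

#' Genome index with rDNA anchor
#'
#' Chromosome names/lengths of an rDNA-appended reference, with the
#' appended rRNA gene unit recorded as the terminal interval of its
#' chromosome.
#'
#' @slot seqinfo `Seqinfo` of the modified reference.
#' @slot rdna Single-interval `GRanges` marking the appended unit.
#' @exportClass GenomeIndex
setClass("GenomeIndex", slots = c(seqinfo = "Seqinfo", rdna = "GRanges"))

setValidity("GenomeIndex", function(object) {
    if (length(object@rdna) != 1L) return("rdna must be a single interval")
    chr <- as.character(seqnames(object@rdna))
    L <- seqlengths(object@seqinfo)[chr]
    if (is.na(L) || end(object@rdna) != L)
        return("rdna interval must be the terminal segment of its chromosome")
    TRUE
})

#' rDNA-anchored contact table
#'
#' Binned genomic bins contacted by the rDNA anchor, with raw pair
#' counts and (optionally balanced) normalized scores, plus conservation
#' tallies of the pair classification.
#'
#' @slot bins `GRanges` with `rawCount` and `score` columns, aligned to
#'   the bin-size grid.
#' @slot binSize Bin width in bp (default pipeline value 5000).
#' @slot replicate Replicate identifier.
#' @slot tallies Named counters: retained, bothInside, bothOutside,
#'   malformed, blacklisted.
#' @exportClass ContactTable
setClass("ContactTable", slots = c(
    bins = "GRanges", binSize = "numeric", replicate = "character",
    tallies = "numeric"))

setValidity("ContactTable", function(object) {
    b <- object@bins
    if (!all(c("rawCount", "score") %in% names(mcols(b))))
        return("bins must carry 'rawCount' and 'score' columns")
    if (any(b$rawCount < 0)) return("raw counts must be >= 0")
    if (any(!is.na(b$score) & b$score < 0))
        return("scores must be >= 0 where defined")
    if (length(b) && any((start(b) - 1L) %% object@binSize != 0))
        return("bins are not aligned to the bin-size grid")
    TRUE
})

#' Compartment eigenvector track
#'
#' Per-bin leading eigenvector of the distance-normalized contact
#' correlation matrix, oriented so positive values mark the A (active)
#' compartment and negative the B (repressive) compartment.
#'
#' @slot bins `GRanges` with `ev` and `mask` columns.
#' @slot binSize Bin width in bp.
#' @slot reference Name of the orientation reference used.
#' @exportClass EigenTrack
setClass("EigenTrack", slots = c(
    bins = "GRanges", binSize = "numeric", reference = "character"))

setValidity("EigenTrack", function(object) {
    b <- object@bins
    if (!all(c("ev", "mask") %in% names(mcols(b))))
        return("bins must carry 'ev' and 'mask' columns")
    if (any(!is.finite(b$ev[!b$mask])))
        return("unmasked eigenvector values must be finite")
    TRUE
})
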