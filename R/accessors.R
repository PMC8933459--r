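#' @rdname accessors
#' @export
setMethod("bins", "RatioTrack", function(x, ...) x@bins)

#' @rdname accessors
#' @export
setMethod("bins", "ContactTable", function(x, ...) x@bins)

#' @rdname accessors
#' @export
setMethod("bins", "EigenTrack", function(x, ...) x@bins)

#' @rdname accessors
#' @export
setMethod("binSize", "RatioTrack", function(x, ...) x@binSize)

#' @rdname accessors
#' @export
setMethod("binSize", "ContactTable", function(x, ...) x@binSize)

#' @rdname accessors
#' @export
setMethod("binSize", "EigenTrack", function(x, ...) x@binSize)

#' @rdname accessors
#' @export
setMethod("binSize", "DomainSet", function(x, ...) x@binSize)

#' @rdname accessors
#' @export
setMethod("domains", "DomainSet", function(x, ...) x@ranges)

#' @rdname accessors
#' @export
setMethod("domains", "LayerPartition", function(x, ...) x@ranges)

#' @rdname accessors
#' @param layer For `layerSet()`, one of [layerLevels()].
#' @export
setMethod("layerSet", "LayerPartition", function(x, layer, ...) {
    layer <- match.arg(layer, .LAYER_LEVELS)
    x@ranges[x@ranges$layer == layer]
})

#' @rdname accessors
#' @export
setMethod("tallies", "ContactTable", function(x, ...) x@tallies)

#' @rdname accessors
#' @export
setMethod("fragments", "GatcFragmentMap", function(x, ...) x@fragments)

#' @rdname accessors
#' @export
setMethod("fragments", "FragmentCounts", function(x, ...) x@map@fragments)

#' @rdname accessors
#' @export
setMethod("librarySize", "FragmentCounts",
          function(x, ...) sum(as.numeric(x@counts)))

#' @rdname accessors
#' @export
setMethod("rdnaInterval", "GenomeIndex", function(x, ...) x@rdna)

#' @rdname accessors
#' @export
setMethod("rdnaInterval", "SimTruth", function(x, ...) x@rdna)

#' Counts accessor
#' @param x A `FragmentCounts` object.
#' @return Integer vector of per-fragment read counts.
#' @export
fragmentCounts <- function(x) {
    stopifnot(is(x, "FragmentCounts"))
    x@counts
}

#' Planted-truth accessors
#'
#' Extract the planted NAD/LAD intervals, compartment labels and
#' configuration from a `SimTruth`.
#'
#' @param x A `SimTruth` object.
#' @return A `GRanges` (or `SimConfig` for `truthConfig`).
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
nadTruth <- function(x) { stopifnot(is(x, "SimTruth")); x@nadTruth }

#' @rdname truth-accessors
#' @export
ladTruth <- function(x) { stopifnot(is(x, "SimTruth")); x@ladTruth }

#' @rdname truth-accessors
#' @export
compartmentTruth <- function(x) {
    stopifnot(is(x, "SimTruth")); x@compartmentTruth
}

#' @rdname truth-accessors
#' @export
truthConfig <- function(x) { stopifnot(is(x, "SimTruth")); x@config }

setMethod("show", "SimConfig", function(object) {
    cl <- object@chromLengths
    cat("SimConfig:", length(cl), "chromosome(s),",
        sprintf("%.1f Mb total\n", sum(cl) / 1e6))
    cat("  GATC spacing ~", object@gatcSpacingMean, "bp; rDNA unit",
        object@rdnaUnitLength, "bp\n")
    cat("  planted domains:", length(object@domainLayout),
        "| compartment period:", object@compartmentPeriod, "bp\n")
    cat("  DamID: depth", object@damidDepth, "enrichment",
        object@damidEnrichment, "dispersion", object@damidDispersion, "\n")
    cat("  Hi-C:", object@hicNPairs, "pairs, alpha",
        object@hicDecayAlpha, ", rDNA boost", object@hicRdnaBoost, "\n")
    cat("  seed:", object@seed, "\n")
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth on", length(seqlengths(object@seqinfo)),
        "chromosome(s)\n")
    cat("  planted NADs:", length(object@nadTruth),
        "| planted LADs:", length(object@ladTruth), "\n")
    if (length(object@rdna))
        cat("  rDNA:", as.character(object@rdna), "\n")
})

setMethod("show", "GatcFragmentMap", function(object) {
    fr <- object@fragments
    cat("GatcFragmentMap:", length(fr), "fragments on",
        length(seqlevelsInUse(fr)), "chromosome(s); median width",
        median(width(fr)), "bp\n")
})

setMethod("show", "FragmentCounts", function(object) {
    cat("FragmentCounts:", length(object@counts), "fragments, library",
        sum(as.numeric(object@counts)), "reads")
    if (sum(object@skipped) > 0)
        cat(" (", sum(object@skipped), "skipped )")
    cat("\n")
})

setMethod("show", "RatioTrack", function(object) {
    b <- object@bins
    cat("RatioTrack:", length(b), "bins of", object@binSize, "bp;",
        sum(b$mask), "masked\n")
})

setMethod("show", "DomainSet", function(object) {
    gr <- object@ranges
    cat("DomainSet:", length(gr), "interval(s)")
    if (length(gr))
        cat(",", sprintf("%.2f Mb", sum(width(gr)) / 1e6), "total; labels:",
            paste(unique(gr$label), collapse = ", "))
    cat("\n")
})

setMethod("show", "LayerPartition", function(object) {
    gr <- object@ranges
    bp <- vapply(.LAYER_LEVELS, function(l)
        sum(width(gr[gr$layer == l])), numeric(1))
    cat("LayerPartition over", sprintf("%.2f Mb:\n", sum(bp) / 1e6))
    for (l in .LAYER_LEVELS)
        cat(sprintf("  %-10s %8.2f Mb (%5.1f%%)\n", l, bp[[l]] / 1e6,
                    100 * bp[[l]] / sum(bp)))
})

setMethod("show", "GenomeIndex", function(object) {
    cat("GenomeIndex:", length(seqlengths(object@seqinfo)),
        "chromosome(s); rDNA at", as.character(object@rdna), "\n")
})

setMethod("show", "ContactTable", function(object) {
    cat("ContactTable [", object@replicate, "]: ",
        length(object@bins), " contact bins of ", object@binSize,
        " bp\n", sep = "")
    if (length(object@tallies))
        cat("  tallies:", paste(names(object@tallies), object@tallies,
                                sep = "=", collapse = ", "), "\n")
})

setMethod("show", "EigenTrack", function(object) {
    b <- object@bins
    cat("EigenTrack:", length(b), "bins of", object@binSize, "bp;",
        sum(b$mask), "masked; oriented by", object@reference, "\n")
})
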