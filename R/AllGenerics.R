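#' @import methods
#' @importFrom stats cor quantile rnbinom rpois rgamma rexp runif median sd
#'   setNames var
#' @importFrom utils head tail read.table write.table
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the container classes: `bins()` returns
#' the per-bin [GenomicRanges::GRanges] backing a track or contact table,
#' `binSize()` its bin width in bp, `domains()` the interval set of a
#' `DomainSet`, `layerSet()` one named layer of a `LayerPartition`, and
#' `tallies()` the bookkeeping counters of a `ContactTable`.
#'
#' @param x An object of one of the package's container classes.
#' @param ... Additional arguments passed to methods.
#' @return `bins()`, `domains()` and `layerSet()` return a `GRanges`;
#'   `binSize()` a single numeric; `tallies()` a named numeric vector.
#' @name accessors
#' @aliases bins binSize domains layerSet tallies
#' @examples
#' cfg <- simConfig(chromLengths = c(chrT = 2e6), seed = 1)
#' sim <- simulateGenome(cfg)
#' frags <- buildGatcFragments(sim$genome)
#' head(fragments(frags))
NULL

#' @rdname accessors
#' @export
setGeneric("bins", function(x, ...) standardGeneric("bins"))

#' @rdname accessors
#' @export
setGeneric("binSize", function(x, ...) standardGeneric("binSize"))

#' @rdname accessors
#' @export
setGeneric("domains", function(x, ...) standardGeneric("domains"))

#' @rdname accessors
#' @export
setGeneric("layerSet", function(x, ...) standardGeneric("layerSet"))

#' @rdname accessors
#' @export
setGeneric("tallies", function(x, ...) standardGeneric("tallies"))

#' @rdname accessors
#' @export
setGeneric("fragments", function(x, ...) standardGeneric("fragments"))

#' @rdname accessors
#' @export
setGeneric("librarySize", function(x, ...) standardGeneric("librarySize"))

#' @rdname accessors
#' @export
setGeneric("rdnaInterval", function(x, ...) standardGeneric("rdnaInterval"))
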