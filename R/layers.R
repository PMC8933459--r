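#' Partition the genome into repressive layers
#'
#' Base-pair set algebra on NAD and LAD interval sets: NAD/LAD is their
#' intersection, NAD-only and LAD-only the respective differences, and
#' iNAD/iLAD the complement. The four layers are mutually disjoint and
#' tile the genome exactly.
#'
#' @param nads,lads [DomainSet-class] objects or `GRanges` with the
#'   same genome context (seqlengths required).
#' @return A [LayerPartition-class].
#' @export
#' @examples
#' sl <- c(chr1 = 200)
#' nad <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100),
#'                               seqlengths = sl)
#' lad <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150),
#'                               seqlengths = sl)
#' classifyLayers(nad, lad)
classifyLayers <- function(nads, lads) {
    n <- .asRanges(nads); l <- .asRanges(lads)
    if (length(n) && length(l)) .checkSameGenome(n, l, "NAD/LAD sets")
    si <- seqinfo(if (length(n)) n else l)
    if (any(is.na(seqlengths(si))))
        stop("genome context (seqlengths) required")
    seqlevels(n) <- seqlevels(si); seqinfo(n) <- si
    seqlevels(l) <- seqlevels(si); seqinfo(l) <- si
    both <- GenomicRanges::intersect(n, l, ignore.strand = TRUE)
    nadOnly <- GenomicRanges::setdiff(n, l, ignore.strand = TRUE)
    ladOnly <- GenomicRanges::setdiff(l, n, ignore.strand = TRUE)
    covered <- reduce(c(n, l), ignore.strand = TRUE)
    inert <- gaps(covered)
    inert <- inert[strand(inert) == "*"]
    tag <- function(gr, lab) {
        gr$layer <- rep(lab, length(gr))
        gr
    }
    all <- c(tag(nadOnly, "NAD-only"), tag(both, "NAD/LAD"),
             tag(ladOnly, "LAD-only"), tag(inert, "iNAD/iLAD"))
    all$layer <- factor(all$layer, levels = .LAYER_LEVELS)
    new("LayerPartition", ranges = sort(all))
}

#' Overlap fraction between two domain sets
#'
#' Percent of the base pairs of `a` covered by `b` (asymmetric: the
#' NAD-over-LAD and LAD-over-NAD fractions differ).
#'
#' @param a,b [DomainSet-class] objects or `GRanges`.
#' @return Single numeric percentage in [0, 100].
#' @export
overlapFraction <- function(a, b) {
    ga <- .asRanges(a); gb <- .asRanges(b)
    bpA <- .domainBp(ga)
    if (bpA == 0) stop("overlap fraction undefined for an empty set")
    ov <- sum(as.numeric(width(GenomicRanges::intersect(
        ga, gb, ignore.strand = TRUE))))
    100 * ov / bpA
}

#' Cell-type-specific and shared domains
#'
#' Splits two cell types' domain sets into pieces exclusive to each
#' (merged and filtered to a minimum length, suppressing slivers from
#' boundary jitter) and the shared intersection.
#'
#' @param d1,d2 [DomainSet-class] objects or `GRanges`.
#' @param minLen Minimum length (bp) of an exclusive piece; defaults to
#'   one analysis bin when `d1` carries a bin size, else 1.
#' @return List with `specific1`, `specific2`, `shared` (`GRanges`).
#' @export
cellSpecific <- function(d1, d2, minLen = NULL) {
    g1 <- .asRanges(d1); g2 <- .asRanges(d2)
    if (is.null(minLen))
        minLen <- if (is(d1, "DomainSet") && !is.na(d1@binSize))
            d1@binSize else 1
    sp1 <- GenomicRanges::setdiff(g1, g2, ignore.strand = TRUE)
    sp2 <- GenomicRanges::setdiff(g2, g1, ignore.strand = TRUE)
    list(specific1 = sp1[width(sp1) >= minLen],
         specific2 = sp2[width(sp2) >= minLen],
         shared = GenomicRanges::intersect(g1, g2,
                                           ignore.strand = TRUE))
}

#' Relocation fates of domain classes
#'
#' For each source domain class of one cell type, the fraction of its
#' base pairs landing in each repressive layer of the other cell type
#' (e.g. what fraction of ESC-specific NAD-only became iNAD/iLAD in
#' NPCs). Rows sum to 1.
#'
#' @param sources Named list of [DomainSet-class]/`GRanges` source
#'   classes (a single set is accepted and wrapped).
#' @param targetPartition A [LayerPartition-class] of the target cell
#'   type.
#' @return Matrix (source classes x four layers); empty source classes
#'   are omitted with a message.
#' @export
relocationFates <- function(sources, targetPartition) {
    stopifnot(is(targetPartition, "LayerPartition"))
    if (!is.list(sources)) sources <- list(source = sources)
    if (is.null(names(sources)))
        names(sources) <- paste0("class", seq_along(sources))
    rows <- list()
    for (nm in names(sources)) {
        gr <- .asRanges(sources[[nm]])
        tot <- .domainBp(gr)
        if (tot == 0) {
            message("source class '", nm, "' is empty; row omitted")
            next
        }
        rows[[nm]] <- vapply(.LAYER_LEVELS, function(lv) {
            sum(as.numeric(width(GenomicRanges::intersect(
                gr, layerSet(targetPartition, lv),
                ignore.strand = TRUE)))) / tot
        }, numeric(1))
    }
    if (!length(rows))
        return(matrix(numeric(0), 0, 4,
                      dimnames = list(NULL, .LAYER_LEVELS)))
    do.call(rbind, rows)
}

#' Annotate a domain set against a two-class track
#'
#' Fraction of a domain set's base pairs per annotation class (for
#' example early/late replication timing or A/B compartment calls);
#' unannotated bp is reported as "NA". Fractions sum to 1.
#'
#' @param d A [DomainSet-class] or `GRanges`.
#' @param annotation `GRanges` with a `class` (or `state`) metadata
#'   column.
#' @return Named numeric vector of fractions (including "NA").
#' @export
annotateFraction <- function(d, annotation) {
    gr <- .asRanges(d)
    tot <- .domainBp(gr)
    if (tot == 0) stop("empty domain set")
    cls <- annotation$class
    if (is.null(cls)) cls <- annotation$state
    if (is.null(cls)) stop("annotation needs a 'class' or 'state' column")
    cls <- as.character(cls)
    levels <- sort(unique(cls))
    frac <- vapply(levels, function(lv) {
        sum(as.numeric(width(GenomicRanges::intersect(
            gr, reduce(granges(annotation[cls == lv])),
            ignore.strand = TRUE)))) / tot
    }, numeric(1))
    covered <- sum(as.numeric(width(GenomicRanges::intersect(
        gr, reduce(granges(annotation)), ignore.strand = TRUE))))
    c(frac, "NA" = (tot - covered) / tot)
}

#' Gene density of a domain set
#'
#' Genes are assigned by their midpoint (avoiding double-counting of
#' boundary-straddling genes); density is genes per megabase of the
#' set.
#'
#' @param d A [DomainSet-class] or `GRanges`.
#' @param genes `GRanges` of gene bodies.
#' @return Genes per Mb (single numeric).
#' @export
geneDensity <- function(d, genes) {
    gr <- .asRanges(d)
    bp <- .domainBp(gr)
    if (bp == 0) stop("gene density undefined for an empty set")
    if (length(genes) == 0L) return(0)
    mids <- .geneMidpoints(genes)
    sum(overlapsAny(mids, gr, ignore.strand = TRUE)) / (bp / 1e6)
}

## Gene midpoints under the half-open convention: the 0-based midpoint
## floor((start0 + end0) / 2) expressed 1-based.
.geneMidpoints <- function(genes) {
    mid0 <- floor((start(genes) - 1 + end(genes)) / 2)
    GRanges(seqnames(genes), IRanges(mid0 + 1, width = 1),
            seqinfo = seqinfo(genes))
}
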