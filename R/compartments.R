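.SWITCH_LEVELS <- c("A to A", "B to B", "B to A", "A to B",
                    "B to b", "b to B", "A to a", "a to A")

#' Switch category names
#'
#' The eight compartment-switch categories produced by
#' [classifySwitch()]: stable (A to A, B to B), full switches (B to A,
#' A to B) and within-compartment strength changes (B to b, b to B,
#' A to a, a to A).
#'
#' @return Character vector of category names.
#' @export
switchLevels <- function() .SWITCH_LEVELS

#' A/B compartment eigenvector of a cis contact matrix
#'
#' Standard compartment construction: per chromosome, the observed
#' matrix is divided by the distance-stratified mean (observed over
#' expected), the Pearson correlation matrix of the O/E columns is
#' formed, and its leading eigenvector taken. The sign is oriented so
#' that correlation with a reference signal (e.g. gene density) is
#' positive; positive values then mark the A compartment, negative the
#' B compartment. Low-coverage bins and bins with degenerate O/E
#' columns are masked.
#'
#' @param mat Symmetric cis contact matrix (one chromosome) at the
#'   analysis bin size.
#' @param reference Numeric per-bin orientation signal, same length as
#'   `nrow(mat)`.
#' @param bins Optional `GRanges` of the matrix bins; when supplied an
#'   [EigenTrack-class] is returned instead of a list.
#' @param binSize Bin size recorded in the returned track.
#' @param minNonzeroFrac Mask bins whose matrix row has a smaller
#'   fraction of nonzero entries.
#' @param referenceName Label recorded as the orientation reference.
#' @return List with `ev` (eigenvector, NA at masked bins) and `mask`,
#'   or an [EigenTrack-class] when `bins` is given.
#' @export
compartmentEigenvector <- function(mat, reference, bins = NULL,
                                   binSize = 1e5,
                                   minNonzeroFrac = 0.1,
                                   referenceName = "reference") {
    stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
    n <- nrow(mat)
    stopifnot(length(reference) == n)
    keep <- rowMeans(mat > 0) >= minNonzeroFrac & rowSums(mat) > 0
    ev <- rep(NA_real_, n)
    if (sum(keep) >= 3L) {
        A <- mat[keep, keep, drop = FALSE]
        m <- nrow(A)
        # observed / expected by distance stratum
        d <- abs(row(A) - col(A))
        expByD <- vapply(0:(m - 1L), function(k) mean(A[d == k]),
                         numeric(1))
        E <- matrix(expByD[d + 1L], m, m)
        OE <- ifelse(E > 0, A / E, 0)
        # degenerate columns (zero variance) cannot be correlated
        sds <- apply(OE, 2L, sd)
        ok <- sds > 0
        if (sum(ok) >= 3L) {
            C <- suppressWarnings(cor(OE[, ok, drop = FALSE]))
            C[!is.finite(C)] <- 0
            eg <- eigen(C, symmetric = TRUE)
            v <- eg$vectors[, 1L]
            sub <- rep(NA_real_, m)
            sub[ok] <- v
            ev[keep] <- sub
        }
    } else {
        warning("chromosome is (nearly) all masked")
    }
    mask <- !is.finite(ev)
    if (!all(mask)) {
        r <- suppressWarnings(cor(ev[!mask], reference[!mask]))
        if (is.finite(r) && r < 0) ev <- -ev
    }
    ev[mask] <- NA_real_
    if (is.null(bins)) return(list(ev = ev, mask = mask))
    stopifnot(length(bins) == n)
    bins$ev <- ev
    bins$mask <- mask
    new("EigenTrack", bins = bins, binSize = binSize,
        reference = referenceName)
}

#' Classify compartment switches between two cell states
#'
#' Per-bin comparison of two eigenvector tracks. A sign change is a
#' full switch ("B to A" / "A to B"). Same-sign bins whose absolute
#' change reaches `deltaMin` are strength changes; under the default
#' `"weaker"` convention a lowercase letter denotes the weaker value
#' (closer to zero), so a B bin whose eigenvector rises toward zero is
#' "B to b" and one that strengthens is "b to B" (and symmetrically
#' "A to a" / "a to A"). The alternative `"decrease"` convention labels
#' the same-sign categories by the direction of the signed change
#' (lowercase marks a decrease from the first state), which mirrors
#' the weaker-convention labels. Changes below `deltaMin` are stable
#' ("A to A" / "B to B").
#'
#' @param ev1,ev2 [EigenTrack-class] objects (or numeric vectors) on
#'   the same bins; state 1 and state 2.
#' @param deltaMin Minimum |change| for a strength-change label
#'   (default 0: every same-sign change is labelled).
#' @param convention `"weaker"` (default) or `"decrease"`; see
#'   Details.
#' @return `GRanges` (or data.frame for vector input) with `category`
#'   (factor over [switchLevels()]), `dEv`, and `mask` columns.
#' @export
classifySwitch <- function(ev1, ev2, deltaMin = 0,
                           convention = c("weaker", "decrease")) {
    convention <- match.arg(convention)
    tracks <- is(ev1, "EigenTrack") && is(ev2, "EigenTrack")
    if (tracks) {
        if (!identical(granges(ev1@bins), granges(ev2@bins)))
            stop("eigenvector tracks are not on the same bins")
        v1 <- ev1@bins$ev; v2 <- ev2@bins$ev
        mask <- ev1@bins$mask | ev2@bins$mask
    } else {
        v1 <- as.numeric(ev1); v2 <- as.numeric(ev2)
        if (length(v1) != length(v2)) stop("bin mismatch")
        mask <- !is.finite(v1) | !is.finite(v2)
    }
    d <- v2 - v1
    cat <- rep(NA_character_, length(v1))
    ok <- !mask
    neg1 <- ok & v1 < 0; pos1 <- ok & v1 >= 0
    neg2 <- ok & v2 < 0; pos2 <- ok & v2 >= 0
    cat[neg1 & pos2] <- "B to A"
    cat[pos1 & neg2] <- "A to B"
    sameB <- neg1 & neg2
    sameA <- pos1 & pos2
    big <- abs(d) >= deltaMin & abs(d) > 0
    cat[sameB & !big] <- "B to B"
    cat[sameA & !big] <- "A to A"
    if (convention == "weaker") {
        # lowercase = weaker |ev|: B weakening (rising toward 0) = B to b
        cat[sameB & big & v2 > v1] <- "B to b"
        cat[sameB & big & v2 < v1] <- "b to B"
        cat[sameA & big & v2 < v1] <- "A to a"
        cat[sameA & big & v2 > v1] <- "a to A"
    } else {
        # signed-decrease convention: both "B to b" and "a to A" mark
        # a lower value in the second state
        cat[sameB & big & v2 < v1] <- "B to b"
        cat[sameB & big & v2 > v1] <- "b to B"
        cat[sameA & big & v2 > v1] <- "A to a"
        cat[sameA & big & v2 < v1] <- "a to A"
    }
    category <- factor(cat, levels = .SWITCH_LEVELS)
    if (tracks) {
        out <- granges(ev1@bins)
        out$category <- category
        out$dEv <- d
        out$mask <- mask
        metadata(out)$convention <- convention
        out
    } else {
        data.frame(category = category, dEv = d, mask = mask)
    }
}

#' Domain fractions by category
#'
#' Fraction of a domain set's base pairs overlapping bins of each
#' category. For an [EigenTrack-class] the categories are the A/B signs
#' (masked bins count as "NA"); for a switch call they are the eight
#' [switchLevels()]. Fractions over the exhaustive category set sum
#' to 1.
#'
#' @param domains A [DomainSet-class] or `GRanges`.
#' @param calls An [EigenTrack-class], or the `GRanges` returned by
#'   [classifySwitch()].
#' @return Named numeric vector of bp fractions (summing to 1).
#' @export
fractionByCategory <- function(domains, calls) {
    gr <- .asRanges(domains)
    if (.domainBp(gr) == 0) stop("empty domain set")
    if (is(calls, "EigenTrack")) {
        b <- calls@bins
        cats <- ifelse(b$mask, "NA", ifelse(b$ev >= 0, "A", "B"))
        levels <- c("A", "B", "NA")
    } else {
        b <- calls
        cats <- as.character(b$category)
        cats[is.na(cats)] <- "NA"
        levels <- c(.SWITCH_LEVELS, "NA")
    }
    tot <- .domainBp(gr)
    frac <- vapply(levels, function(lv) {
        sel <- b[cats == lv]
        if (length(sel) == 0L) return(0)
        sum(as.numeric(width(GenomicRanges::intersect(
            gr, reduce(granges(sel)), ignore.strand = TRUE)))) / tot
    }, numeric(1))
    # bp outside any call bin also lands in NA
    covered <- sum(as.numeric(width(GenomicRanges::intersect(
        gr, reduce(granges(b)), ignore.strand = TRUE))))
    frac["NA"] <- frac["NA"] + (tot - covered) / tot
    frac
}
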