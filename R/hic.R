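#' Append an rRNA gene unit to a reference chromosome
#'
#' Concatenates one rRNA gene unit to the end of the target chromosome
#' (the mouse reference lacks rDNA sequence, so Hi-C reads can only be
#' anchored after this modification) and records the appended interval.
#' All pre-existing coordinates are unchanged.
#'
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @param rdnaUnit A `DNAString`/`DNAStringSet` (first sequence used)
#'   or FASTA path with the rRNA gene unit.
#' @param targetChrom Chromosome to append to.
#' @param force Append even if the chromosome already ends with the
#'   unit (default FALSE: duplicate append is an error).
#' @return List with `genome` (modified `DNAStringSet`) and `index`
#'   (a [GenomeIndex-class] recording the rDNA interval).
#' @export
appendRdna <- function(genome, rdnaUnit, targetChrom, force = FALSE) {
    if (is.character(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    if (is.character(rdnaUnit))
        rdnaUnit <- Biostrings::readDNAStringSet(rdnaUnit)
    if (is(rdnaUnit, "DNAStringSet")) rdnaUnit <- rdnaUnit[[1L]]
    if (length(rdnaUnit) == 0L) stop("empty rDNA unit")
    if (!targetChrom %in% names(genome))
        stop("target chromosome '", targetChrom, "' not in genome")
    chrSeq <- genome[[targetChrom]]
    L <- length(chrSeq); U <- length(rdnaUnit)
    if (!force && L >= U &&
        as.character(Biostrings::subseq(chrSeq, L - U + 1L, L)) ==
        as.character(rdnaUnit))
        stop("rDNA unit already terminal on ", targetChrom,
             " (use force = TRUE to append again)")
    genome[[targetChrom]] <- Biostrings::xscat(chrSeq, rdnaUnit)
    sl <- setNames(Biostrings::width(genome), names(genome))
    si <- Seqinfo(names(sl), seqlengths = sl)
    rdna <- GRanges(targetChrom, IRanges(L + 1L, L + U), seqinfo = si)
    list(genome = genome,
         index = new("GenomeIndex", seqinfo = si, rdna = rdna))
}

#' Construct a genome index
#'
#' @param seqlengths Named vector of chromosome lengths.
#' @param rdna `GRanges` (single interval) or "chrom:start-end" string
#'   (1-based) locating the appended rRNA gene unit; it must terminate
#'   its chromosome.
#' @return A [GenomeIndex-class].
#' @export
genomeIndex <- function(seqlengths, rdna) {
    si <- Seqinfo(names(seqlengths), seqlengths = seqlengths)
    if (is.character(rdna)) {
        m <- regmatches(rdna,
                        regexec("^([^:]+):([0-9]+)-([0-9]+)$", rdna))[[1]]
        if (length(m) != 4L) stop("cannot parse rdna locus '", rdna, "'")
        rdna <- GRanges(m[2], IRanges(as.numeric(m[3]), as.numeric(m[4])))
    }
    seqlevels(rdna) <- seqlevels(si)
    seqinfo(rdna) <- si
    new("GenomeIndex", seqinfo = si, rdna = rdna)
}

## Knight-Ruiz inner-outer conjugate-gradient iteration; returns the
## positive scaling vector x with diag(x) A diag(x) doubly stochastic,
## or NULL if the iteration stalls.
.krSolve <- function(A, tol = 1e-10, delta = 0.1, Delta = 3,
                     maxOuter = 60L, maxMVP = 20000L) {
    n <- nrow(A)
    e <- rep(1, n); x <- e
    g <- 0.9; etamax <- 0.1; eta <- etamax
    rt <- tol^2
    v <- x * as.numeric(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk); rout <- rho_km1; rold <- rout
    MVP <- 0L; outer <- 0L
    while (rout > rt) {
        outer <- outer + 1L
        if (outer > maxOuter || MVP > maxMVP) return(NULL)
        k <- 0L; y <- e
        innertol <- max(eta^2 * rout, rt)
        rho_km2 <- rho_km1
        Z <- p <- NULL
        while (rho_km1 > innertol) {
            k <- k + 1L
            if (k == 1L) {
                Z <- rk / v
                p <- Z
                rho_km1 <- sum(rk * Z)
            } else {
                beta <- rho_km1 / rho_km2
                p <- Z + beta * p
            }
            w <- x * as.numeric(A %*% (x * p)) + v * p
            denom <- sum(p * w)
            if (!is.finite(denom) || denom <= 0) return(NULL)
            alpha <- rho_km1 / denom
            ap <- alpha * p
            ynew <- y + ap
            if (min(ynew) <= delta) {
                ind <- which(ap < 0)
                gamma <- min((delta - y[ind]) / ap[ind])
                y <- y + gamma * ap
                break
            }
            if (max(ynew) >= Delta) {
                ind <- which(ynew > Delta)
                gamma <- min((Delta - y[ind]) / ap[ind])
                y <- y + gamma * ap
                break
            }
            y <- ynew
            rk <- rk - alpha * w
            rho_km2 <- rho_km1
            Z <- rk / v
            rho_km1 <- sum(rk * Z)
            MVP <- MVP + 1L
            if (MVP > maxMVP) return(NULL)
        }
        x <- x * y
        v <- x * as.numeric(A %*% x)
        rk <- 1 - v
        rho_km1 <- sum(rk * rk)
        rout <- rho_km1
        MVP <- MVP + k + 1L
        rat <- rout / rold; rold <- rout
        eta_o <- eta; eta <- g * rat
        if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
        eta <- max(min(eta, etamax), 0.5 * tol / sqrt(rout))
        if (!is.finite(rout)) return(NULL)
    }
    as.numeric(x)
}

## Symmetric Sinkhorn fallback: x <- x / sqrt(x * (A x)).
.sinkhornSolve <- function(A, tol = 1e-14, maxIter = 50000L) {
    x <- rep(1, nrow(A))
    for (i in seq_len(maxIter)) {
        r <- x * as.numeric(A %*% x)
        if (max(abs(r - 1)) < tol) break
        x <- x / sqrt(r)
    }
    x
}

#' Knight-Ruiz matrix balancing
#'
#' Computes the positive scaling vector `x` such that
#' `diag(x) %*% A %*% diag(x)` has equal row sums (doubly stochastic),
#' the normalization applied to contact matrices before rDNA-anchor
#' extraction. Rows/columns with fewer than `minNonzeroFrac` nonzero
#' entries are masked before balancing. If the Knight-Ruiz iteration
#' stalls, the function falls back to iterative proportional (Sinkhorn)
#' scaling with a warning.
#'
#' @param A Square, symmetric, non-negative matrix.
#' @param tol Convergence tolerance of the residual norm.
#' @param minNonzeroFrac Mask rows with a smaller fraction of nonzero
#'   entries (default 0.1).
#' @param symTol Relative tolerance for the symmetry check.
#' @return List with `x` (scaling vector, NA at masked rows),
#'   `balanced` (matrix with NA at masked rows/columns), and `masked`
#'   (logical vector).
#' @export
#' @examples
#' A <- matrix(c(2, 1, 1, 2), 2)
#' krBalance(A, minNonzeroFrac = 0)$balanced  # equal row sums
krBalance <- function(A, tol = 1e-10, minNonzeroFrac = 0.1,
                      symTol = 1e-8) {
    stopifnot(is.matrix(A), nrow(A) == ncol(A))
    if (any(A < 0)) stop("matrix must be non-negative")
    scale <- max(abs(A), 1)
    if (max(abs(A - t(A))) > symTol * scale)
        stop("matrix is not symmetric within tolerance")
    A <- (A + t(A)) / 2
    n <- nrow(A)
    keep <- rowMeans(A > 0) >= minNonzeroFrac & rowSums(A) > 0
    x <- rep(NA_real_, n)
    B <- matrix(NA_real_, n, n)
    if (!any(keep)) {
        return(list(x = x, balanced = B, masked = !keep))
    }
    sub <- A[keep, keep, drop = FALSE]
    xs <- .krSolve(sub, tol = tol)
    if (is.null(xs)) {
        warning("Knight-Ruiz iteration stalled; ",
                "falling back to iterative proportional scaling")
        xs <- .sinkhornSolve(sub)
    }
    x[keep] <- xs
    B[keep, keep] <- sub * outer(xs, xs)
    list(x = x, balanced = B, masked = !keep)
}

## Parse 7-column pairs text; returns the well-formed records and a
## malformed-line tally.
.readPairs <- function(path) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
    f <- strsplit(ln, "\t", fixed = TRUE)
    nf <- lengths(f)
    ok <- nf == 7L
    if (any(ok)) {
        m <- matrix(unlist(f[ok]), ncol = 7L, byrow = TRUE)
        pos1 <- suppressWarnings(as.numeric(m[, 3L]))
        pos2 <- suppressWarnings(as.numeric(m[, 5L]))
        good <- !is.na(pos1) & !is.na(pos2)
        df <- data.frame(readID = m[good, 1L], chr1 = m[good, 2L],
                         pos1 = pos1[good], chr2 = m[good, 4L],
                         pos2 = pos2[good], strand1 = m[good, 6L],
                         strand2 = m[good, 7L])
        list(pairs = df, malformed = sum(!ok) + sum(!good))
    } else {
        list(pairs = data.frame(readID = character(), chr1 = character(),
                                pos1 = numeric(), chr2 = character(),
                                pos2 = numeric(), strand1 = character(),
                                strand2 = character()),
             malformed = sum(!ok))
    }
}

#' Extract rDNA-anchored contacts from Hi-C pairs
#'
#' Retains a pair if and only if exactly one end lies within the rDNA
#' interval, assigns the other (genomic) end to its fixed-width bin,
#' and accumulates raw counts per bin. Pairs with both ends inside the
#' rDNA interval are excluded and tallied separately, as are pairs with
#' both ends outside and malformed records, so that
#' retained + bothInside + bothOutside + malformed equals the input.
#'
#' @param pairs Path to 7-column pairs text (readID chr1 pos1 chr2 pos2
#'   strand1 strand2, positions 0-based) or an equivalent data.frame
#'   (e.g. from [simulateHicPairs()]).
#' @param index A [GenomeIndex-class] with the rDNA interval.
#' @param binSize Bin width in bp (default 5000).
#' @param balancing Optional `GRanges` with a `weight` column on the
#'   same bin grid; the normalized score of a bin is its raw count
#'   times the matching weight (NA where no weight is available).
#' @param replicate Replicate identifier stored in the table.
#' @return A [ContactTable-class].
#' @export
extractRdnaContacts <- function(pairs, index, binSize = 5000,
                                balancing = NULL, replicate = "rep1") {
    stopifnot(is(index, "GenomeIndex"))
    malformed <- 0
    if (is.character(pairs)) {
        parsed <- .readPairs(pairs)
        pairs <- parsed$pairs
        malformed <- parsed$malformed
    }
    stopifnot(all(c("chr1", "pos1", "chr2", "pos2") %in% names(pairs)))
    sl <- seqlengths(index@seqinfo)
    ok <- pairs$chr1 %in% names(sl) & pairs$chr2 %in% names(sl) &
        !is.na(pairs$pos1) & !is.na(pairs$pos2)
    malformed <- malformed + sum(!ok)
    if (malformed > 0)
        warning(malformed, " malformed pair record(s) skipped")
    pairs <- pairs[ok, , drop = FALSE]
    rchr <- as.character(seqnames(index@rdna))
    r0 <- start(index@rdna) - 1; r1 <- end(index@rdna)
    in1 <- pairs$chr1 == rchr & pairs$pos1 >= r0 & pairs$pos1 < r1
    in2 <- pairs$chr2 == rchr & pairs$pos2 >= r0 & pairs$pos2 < r1
    retained <- xor(in1, in2)
    tallies <- c(retained = sum(retained), bothInside = sum(in1 & in2),
                 bothOutside = sum(!in1 & !in2), malformed = malformed,
                 blacklisted = 0)
    chrO <- ifelse(in1[retained], pairs$chr2[retained],
                   pairs$chr1[retained])
    posO <- ifelse(in1[retained], pairs$pos2[retained],
                   pairs$pos1[retained])
    binStart0 <- floor(posO / binSize) * binSize
    key <- sprintf("%s:%.0f", chrO, binStart0)
    agg <- table(key)
    if (length(agg)) {
        parts <- strsplit(names(agg), ":", fixed = TRUE)
        chrB <- vapply(parts, `[`, character(1), 1L)
        s0 <- as.numeric(vapply(parts, `[`, character(1), 2L))
        gr <- GRanges(chrB,
                      IRanges(s0 + 1, pmin(s0 + binSize, sl[chrB])),
                      seqinfo = index@seqinfo)
        gr$rawCount <- as.numeric(agg)
        o <- order(as.integer(seqnames(gr)), start(gr))
        gr <- gr[o]
    } else {
        gr <- GRanges(seqinfo = index@seqinfo)
        gr$rawCount <- numeric(0)
    }
    if (!is.null(balancing) && length(gr)) {
        hit <- findOverlaps(gr, balancing, select = "first")
        gr$score <- gr$rawCount * balancing$weight[hit]
    } else {
        gr$score <- gr$rawCount
    }
    new("ContactTable", bins = gr, binSize = binSize,
        replicate = replicate, tallies = tallies)
}

#' Remove blacklisted bins from a contact table
#'
#' Drops contact bins overlapping any blacklist interval by at least
#' one bp and records the removed count.
#'
#' @param t A [ContactTable-class].
#' @param blacklist `GRanges` or path to a BED file.
#' @return Filtered [ContactTable-class] (removed count added to the
#'   `blacklisted` tally).
#' @export
filterBlacklist <- function(t, blacklist) {
    stopifnot(is(t, "ContactTable"))
    if (is.character(blacklist))
        blacklist <- rtracklayer::import(blacklist, format = "BED")
    hit <- overlapsAny(t@bins, blacklist, ignore.strand = TRUE)
    tl <- t@tallies
    tl["blacklisted"] <- tl["blacklisted"] + sum(hit)
    new("ContactTable", bins = t@bins[!hit], binSize = t@binSize,
        replicate = t@replicate, tallies = tl)
}

#' Replicate-common contacts
#'
#' Keeps bins with a raw count of at least `minCount` in every
#' replicate; the combined score is the mean of the replicate
#' normalized scores. A per-replicate presence matrix is stored in the
#' metadata of the returned bins.
#'
#' @param tables List of two or more [ContactTable-class] objects with
#'   identical bin size and genome.
#' @param minCount Minimum raw count per replicate (default 1).
#' @return A [ContactTable-class] labelled "common".
#' @export
commonContacts <- function(tables, minCount = 1) {
    stopifnot(is.list(tables), length(tables) >= 2L,
              all(vapply(tables, is, logical(1), "ContactTable")))
    bs <- vapply(tables, binSize, numeric(1))
    if (length(unique(bs)) != 1L) stop("inconsistent binning")
    for (i in seq_along(tables)[-1L])
        .checkSameGenome(tables[[1L]]@bins, tables[[i]]@bins,
                         "contact tables")
    keys <- lapply(tables, function(t)
        paste0(as.character(seqnames(t@bins)), ":", start(t@bins)))
    present <- lapply(seq_along(tables), function(i)
        keys[[i]][tables[[i]]@bins$rawCount >= minCount])
    common <- Reduce(intersect, present)
    allKeys <- sort(unique(unlist(keys)))
    presence <- matrix(FALSE, length(allKeys), length(tables))
    for (i in seq_along(tables))
        presence[, i] <- allKeys %in% present[[i]]
    colnames(presence) <- vapply(tables, function(t) t@replicate,
                                 character(1))
    rownames(presence) <- allKeys
    if (length(common)) {
        i1 <- match(common, keys[[1L]])
        scoreMat <- matrix(NA_real_, length(common), length(tables))
        rawMat <- matrix(NA_real_, length(common), length(tables))
        for (i in seq_along(tables)) {
            mi <- match(common, keys[[i]])
            scoreMat[, i] <- tables[[i]]@bins$score[mi]
            rawMat[, i] <- tables[[i]]@bins$rawCount[mi]
        }
        meanScore <- rowMeans(scoreMat)
        meanRaw <- rowMeans(rawMat)
        out <- tables[[1L]]@bins[i1]
        out$rawCount <- meanRaw
        out$score <- meanScore
        o <- order(as.integer(seqnames(out)), start(out))
        out <- out[o]
    } else {
        out <- GRanges(seqinfo = seqinfo(tables[[1L]]@bins))
        out$rawCount <- numeric(0)
        out$score <- numeric(0)
    }
    metadata(out)$presence <- presence
    new("ContactTable", bins = out, binSize = bs[1L],
        replicate = "common",
        tallies = c(retained = length(out), bothInside = 0,
                    bothOutside = 0, malformed = 0, blacklisted = 0))
}

#' Quintile distribution of contacts
#'
#' Splits every chromosome into five equal-length segments from
#' coordinate 0 (the centromere-proximal end of the acrocentric mouse
#' chromosomes) and reports the proportion of unique contact bins per
#' segment, per chromosome and averaged across chromosomes.
#'
#' @param t A non-empty [ContactTable-class].
#' @param index A [GenomeIndex-class] (supplies chromosome lengths).
#' @return List with `perChromosome` (matrix chromosomes x 5, rows sum
#'   to 1) and `aggregate` (mean proportions across chromosomes).
#' @export
quintileDistribution <- function(t, index) {
    stopifnot(is(t, "ContactTable"))
    if (length(t@bins) == 0L) stop("empty contact table")
    sl <- seqlengths(index@seqinfo)
    short <- names(sl)[sl < 5 * t@binSize]
    if (length(short))
        warning("chromosome(s) shorter than 5 bins excluded: ",
                paste(short, collapse = ", "))
    chroms <- setdiff(names(sl), short)
    rows <- list()
    for (chr in chroms) {
        b <- t@bins[seqnames(t@bins) == chr]
        if (length(b) == 0L) next
        mid0 <- (start(b) - 1 + end(b)) / 2
        seg <- pmin(floor(mid0 / (sl[[chr]] / 5)) + 1L, 5L)
        p <- tabulate(seg, nbins = 5L) / length(b)
        rows[[chr]] <- p
    }
    if (!length(rows)) stop("no chromosome with contacts")
    perChrom <- do.call(rbind, rows)
    colnames(perChrom) <- paste0("q", 1:5)
    list(perChromosome = perChrom, aggregate = colMeans(perChrom))
}

#' Per-chromosome contact summary
#'
#' Unique-contact counts (distinct retained bins) and score
#' distributions per chromosome.
#'
#' @param t A [ContactTable-class].
#' @return data.frame with `chrom`, `uniqueContacts`, `totalRaw`,
#'   `meanScore`, `medianScore`.
#' @export
perChromosomeSummary <- function(t) {
    stopifnot(is(t, "ContactTable"))
    b <- t@bins
    chroms <- seqlevelsInUse(b)
    do.call(rbind, lapply(chroms, function(chr) {
        g <- b[seqnames(b) == chr]
        data.frame(chrom = chr, uniqueContacts = length(g),
                   totalRaw = sum(g$rawCount),
                   meanScore = mean(g$score),
                   medianScore = median(g$score))
    }))
}

#' Cis contact matrix from pairs
#'
#' Bins the intra-chromosomal pairs of one chromosome into a dense
#' symmetric contact matrix, the input to [krBalance()] and
#' [compartmentEigenvector()].
#'
#' @param pairs Pairs data.frame or path (see
#'   [extractRdnaContacts()]).
#' @param chrom Chromosome to extract.
#' @param binSize Bin width in bp.
#' @param seqlen Chromosome length in bp.
#' @return Symmetric numeric matrix (bins x bins).
#' @export
cisContactMatrix <- function(pairs, chrom, binSize, seqlen) {
    if (is.character(pairs)) pairs <- .readPairs(pairs)$pairs
    p <- pairs[pairs$chr1 == chrom & pairs$chr2 == chrom, , drop = FALSE]
    n <- ceiling(seqlen / binSize)
    i <- pmin(floor(p$pos1 / binSize) + 1L, n)
    j <- pmin(floor(p$pos2 / binSize) + 1L, n)
    M <- matrix(0, n, n)
    if (nrow(p)) {
        idx <- (pmin(i, j) - 1L) * n + pmax(i, j)
        tab <- table(idx)
        pos <- as.integer(names(tab))
        M[pos] <- as.numeric(tab)
        M <- M + t(M) - diag(diag(M))
    }
    M
}

#' Read a Juicer-dump-style contact file
#'
#' Parses tab text with columns `start1 start2 count` (bin start
#' coordinates at a fixed resolution) as produced by Juicebox `dump`.
#'
#' @param path File path.
#' @param binSize Bin width the file was dumped at.
#' @param seqlen Optional chromosome length; when given, a dense
#'   symmetric matrix is returned, otherwise the triplet data.frame.
#' @return data.frame (`start1`, `start2`, `count`) or dense matrix.
#' @export
readJuicerDump <- function(path, binSize, seqlen = NULL) {
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("start1", "start2", "count"))
    if (is.null(seqlen)) return(df)
    n <- ceiling(seqlen / binSize)
    M <- matrix(0, n, n)
    i <- floor(df$start1 / binSize) + 1L
    j <- floor(df$start2 / binSize) + 1L
    for (k in seq_along(i)) {
        M[i[k], j[k]] <- M[i[k], j[k]] + df$count[k]
        if (i[k] != j[k]) M[j[k], i[k]] <- M[j[k], i[k]] + df$count[k]
    }
    M
}
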