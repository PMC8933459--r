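#' Two-cell-type example domain architecture
#'
#' Planted domain layouts for a stem-cell-like (ESC) and a neural
#' progenitor-like (NPC) state on the default three 30-Mb chromosome
#' toy genome, designed to encode overlap and relocation fractions
#' realistic for mouse cells:
#' \itemize{
#'   \item 53\% of ESC NAD bp is also LAD and 40\% of LAD bp is also
#'     NAD (NAD 20 Mb, LAD 26.5 Mb, intersection 10.6 Mb);
#'   \item 16\% of ESC NAD bp is ESC-specific (3.2 Mb) and 8\% of NPC
#'     NAD bp is NPC-specific (1.46 Mb);
#'   \item 78\% of the ESC-specific NAD-only bp carries no NAD or LAD
#'     label in the NPC state (it relocates to iNAD/iLAD), the
#'     remaining 22\% becomes LAD-only.
#' }
#' Feeding these layouts to [simConfig()] / [simulateGenome()] yields
#' two cell states over the same genome whose called domains should
#' reproduce the designed fractions.
#'
#' @return Named list with `ESC` and `NPC` `GRanges` layouts (labels
#'   from [layerLevels()]), suitable for the `domainLayout` argument of
#'   [simConfig()].
#' @export
#' @examples
#' lay <- exampleCellTypeLayouts()
#' sum(GenomicRanges::width(lay$ESC[lay$ESC$label != "LAD-only"])) # 20 Mb
exampleCellTypeLayouts <- function() {
    Mb <- 1e6
    blocks <- function(df)
        GRanges(df$chrom, IRanges(df$start * Mb + 1, df$end * Mb),
                label = df$label)
    esc <- blocks(data.frame(
        chrom = c("chr1", "chr2", "chr3",   # NAD/LAD: 10.6 Mb
                  "chr1", "chr2", "chr3",   # NAD-only: 9.4 Mb
                  "chr1", "chr2", "chr3"),  # LAD-only: 15.9 Mb
        start = c(2, 2, 2,    8, 8, 8,      14, 13, 12),
        end   = c(6, 5.6, 5,  12, 11, 10.4, 19, 18, 17.9),
        label = rep(c("NAD/LAD", "NAD-only", "LAD-only"), each = 3)))
    # ESC-specific NAD-only: chr1 8-10.4 + chr2 8-8.8 (3.2 Mb).
    # In the NPC state 22% of it (chr1 8-8.704) becomes LAD-only and
    # 78% is unlabelled; chr3 20-21.46 is NPC-specific NAD-only.
    npc <- blocks(data.frame(
        chrom = c("chr1", "chr2", "chr3",
                  "chr1", "chr2", "chr3", "chr3",
                  "chr1", "chr2", "chr3", "chr1"),
        start = c(2, 2, 2,
                  10.4, 8.8, 8, 20,
                  14, 13, 12, 8),
        end   = c(6, 5.6, 5,
                  12, 11, 10.4, 21.46,
                  19, 18, 17.9, 8.704),
        label = c(rep("NAD/LAD", 3), rep("NAD-only", 4),
                  rep("LAD-only", 4))))
    list(ESC = sort(esc), NPC = sort(npc))
}
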