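# Optional alignment-file adapter, isolated so the core pipeline never
# requires alignment libraries.

#' Bin read counts from a coordinate-sorted alignment file
#'
#' Counts read start positions per bin of a [build_bin_grid()] grid — the
#' binning convention used for shallow-WGS plasma libraries. Unmapped
#' reads, secondary/supplementary alignments and duplicates are skipped.
#' Requires the Rsamtools package (Suggests); everything downstream works
#' from the returned counts and never touches alignments.
#'
#' @param bam_path path to a coordinate-sorted, indexed BAM file.
#' @param grid a `bin_grid`.
#' @param min_mapq minimum mapping quality (default 0; alignments with
#'   missing mapq are kept).
#' @return Integer vector of counts, one per bin (reads on contigs absent
#'   from the grid are ignored).
#' @export
counts_from_bam <- function(bam_path, grid, min_mapq = 0) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("the alignment adapter requires the Rsamtools package")
  stopifnot(inherits(grid, "bin_grid"))
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(what = c("rname", "pos", "mapq"),
                                   flag = flag)
  res <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  keep <- !is.na(res$pos) &
    (is.na(res$mapq) | res$mapq >= min_mapq)
  rname <- as.character(res$rname)[keep]
  pos0 <- res$pos[keep] - 1L          # BAM pos is 1-based; grid is 0-based
  counts <- integer(nrow(grid))
  for (ch in unique(as.character(grid$chrom))) {
    sel <- which(grid$chrom == ch)
    on_ch <- rname == ch
    if (!any(on_ch)) next
    # bins are contiguous within a chromosome; breaks are starts + last end
    breaks <- c(grid$start[sel], grid$end[sel[length(sel)]])
    idx <- findInterval(pos0[on_ch], breaks, left.open = FALSE)
    ok <- idx >= 1 & idx <= length(sel) &
      pos0[on_ch] < grid$end[sel[length(sel)]]
    counts[sel] <- counts[sel] +
      tabulate(idx[ok], nbins = length(sel))
  }
  counts
}
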