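# Circular binary segmentation of per-bin log2 profiles.

#' Segment a log2 profile by circular binary segmentation
#'
#' Recursive maximal-t change-point search per chromosome; a candidate split
#' is accepted when its permutation p-value `(1 + exceedances)/(1 + n_perm)`
#' is below `alpha`. Adjacent segments whose means differ by less than
#' `merge_tol` are re-merged. Masked bins are bridged: a segment may span
#' them in bp but they contribute no bins. Deterministic under a fixed seed.
#'
#' @param profile a normalized `binned_profile` (or any list with `grid`,
#'   `log2`, `masked`, `sample_id`).
#' @param alpha permutation significance level (default 0.01).
#' @param n_perm number of permutations (default 1000).
#' @param min_width minimum segment width in bins (default 3).
#' @param merge_tol post-hoc merge tolerance on segment means (default 0.05).
#' @param seed integer seed for the permutation stream.
#' @return An object of class `segmented_profile`: list with `sample_id`,
#'   `segments` (data.frame `sample chrom start end n_bins mean_log2`),
#'   `grid`, `bin_log2`, `bin_seg` (per-bin segment index, NA for masked)
#'   and `masked`.
#' @export
segment_profile <- function(profile, alpha = 0.01, n_perm = 1000,
                            min_width = 3, merge_tol = 0.05, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  grid <- profile$grid
  l2 <- profile$log2
  masked <- profile$masked | is.na(l2)
  chroms <- unique(as.character(grid$chrom))
  segs <- list()
  bin_seg <- rep(NA_integer_, nrow(grid))
  seg_id <- 0L
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    idx <- which(grid$chrom == ch & !masked)
    if (!length(idx)) {
      warning("chromosome ", ch, " has no unmasked bins; skipped")
      next
    }
    x <- l2[idx]
    ends <- .cbs_chrom(x, alpha, as.integer(n_perm), as.integer(min_width),
                       as.integer(seed + ci * 10007L), merge_tol)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    for (k in seq_along(ends)) {
      sel <- idx[starts[k]:ends[k]]
      seg_id <- seg_id + 1L
      bin_seg[sel] <- seg_id
      segs[[seg_id]] <- data.frame(
        sample = profile$sample_id, chrom = ch,
        start = grid$start[sel[1]], end = grid$end[sel[length(sel)]],
        n_bins = length(sel), mean_log2 = mean(l2[sel]))
    }
  }
  segments <- do.call(rbind, segs)
  rownames(segments) <- NULL
  structure(list(sample_id = profile$sample_id, segments = segments,
                 grid = grid, bin_log2 = l2, bin_seg = bin_seg,
                 masked = masked),
            class = "segmented_profile")
}

#' Per-bin expansion of segment means
#'
#' @param sp a `segmented_profile`.
#' @return Numeric vector, one value per bin (NA on masked bins), carrying
#'   the mean log2 ratio of the covering segment.
#' @export
per_bin_segmented <- function(sp) {
  stopifnot(inherits(sp, "segmented_profile"))
  out <- rep(NA_real_, nrow(sp$grid))
  ok <- !is.na(sp$bin_seg)
  out[ok] <- sp$segments$mean_log2[sp$bin_seg[ok]]
  out
}

#' Build a segmented profile from an external segment table
#'
#' Lets externally segmented data (e.g. array-derived SEG files) enter the
#' downstream callers unchanged: each unmasked bin is assigned the segment
#' covering its midpoint.
#'
#' @param segments data.frame with columns `sample chrom start end n_bins
#'   mean_log2` (n_bins may be NA and is recomputed from the grid).
#' @param grid a `bin_grid`.
#' @param masked optional per-bin mask (default: bins not covered by any
#'   segment are masked).
#' @return A `segmented_profile`.
#' @export
segmented_from_table <- function(segments, grid, masked = NULL) {
  need <- c("sample", "chrom", "start", "end", "mean_log2")
  stopifnot(all(need %in% names(segments)))
  if (is.null(masked)) masked <- rep(FALSE, nrow(grid))
  mid <- (grid$start + grid$end) / 2
  bin_seg <- rep(NA_integer_, nrow(grid))
  for (k in seq_len(nrow(segments))) {
    hit <- which(grid$chrom == segments$chrom[k] & mid >= segments$start[k] &
                 mid < segments$end[k] & !masked)
    bin_seg[hit] <- k
  }
  segments$n_bins <- as.integer(tabulate(bin_seg, nbins = nrow(segments)))
  masked <- masked | is.na(bin_seg)
  bin_log2 <- rep(NA_real_, nrow(grid))
  ok <- !is.na(bin_seg)
  bin_log2[ok] <- segments$mean_log2[bin_seg[ok]]
  structure(list(sample_id = segments$sample[1], segments = segments,
                 grid = grid, bin_log2 = bin_log2, bin_seg = bin_seg,
                 masked = masked),
            class = "segmented_profile")
}

#' Write / read a SEG-like segment table
#'
#' TSV with columns `sample chrom start end n_bins mean_log2`; `state` is
#' included when present (after [call_states()]).
#'
#' @param sp a `segmented_profile` or a segment data.frame.
#' @param path file path.
#' @export
write_seg <- function(sp, path) {
  df <- if (inherits(sp, "segmented_profile")) sp$segments else sp
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
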