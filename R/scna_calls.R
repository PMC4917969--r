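# Gain/loss labelling, altered-genome fractions, 3-SD aberrance classifier.

#' Label segments as gained, lost or balanced
#'
#' Gains are called at a log2-ratio strictly above `gain` (default 0.2) and
#' losses strictly below `loss` (default -0.2); everything else is balanced.
#'
#' @param sp a `segmented_profile`.
#' @param gain gain threshold (> 0).
#' @param loss loss threshold (< 0).
#' @return The profile with a `state` column added to its segments.
#' @export
call_states <- function(sp, gain = 0.2, loss = -0.2) {
  stopifnot(gain > 0, loss < 0)
  segs <- if (inherits(sp, "segmented_profile")) sp$segments else sp
  state <- ifelse(segs$mean_log2 > gain, "gain",
                  ifelse(segs$mean_log2 < loss, "loss", "balanced"))
  segs$state <- state
  if (inherits(sp, "segmented_profile")) {
    sp$segments <- segs
    sp
  } else segs
}

# genomic bp carried by a segment = summed widths of its member bins
segment_bin_bp <- function(sp) {
  w <- sp$grid$end - sp$grid$start
  ok <- !is.na(sp$bin_seg)
  lv <- factor(sp$bin_seg[ok], levels = seq_len(nrow(sp$segments)))
  out <- as.numeric(tapply(w[ok], lv, sum))
  out[is.na(out)] <- 0
  out
}

#' Altered genome fractions of a labelled profile
#'
#' Cumulative unmasked genomic length (and percent of the unmasked genome)
#' carried by gained and lost segments.
#'
#' @param sp a labelled `segmented_profile` (after [call_states()]).
#' @return List with `pct_gain`, `pct_loss`, `mb_gain`, `mb_loss`,
#'   `bp_gain`, `bp_loss`, `bp_total`.
#' @export
altered_fractions <- function(sp) {
  stopifnot(inherits(sp, "segmented_profile"),
            "state" %in% names(sp$segments))
  bp <- segment_bin_bp(sp)
  total <- sum(bp)
  if (total <= 0) stop("zero-length unmasked genome")
  g <- sum(bp[sp$segments$state == "gain"])
  l <- sum(bp[sp$segments$state == "loss"])
  list(pct_gain = 100 * g / total, pct_loss = 100 * l / total,
       mb_gain = g / 1e6, mb_loss = l / 1e6,
       bp_gain = g, bp_loss = l, bp_total = total)
}

#' Control-cohort aberrance statistics
#'
#' Mean and SD of the cumulative gained and lost genomic lengths across
#' control samples processed by the identical pipeline; a sample is later
#' classified as copy-number aberrant when either of its cumulative lengths
#' exceeds the control mean by more than `k` SDs.
#'
#' @param control_fractions list of [altered_fractions()] results from >= 2
#'   controls.
#' @param k SD multiplier (default 3).
#' @return An object of class `aberrance_stats`.
#' @export
aberrance_stats <- function(control_fractions, k = 3) {
  if (length(control_fractions) < 2) stop("need >= 2 controls for SDs")
  g <- vapply(control_fractions, function(x) x$bp_gain, 0)
  l <- vapply(control_fractions, function(x) x$bp_loss, 0)
  structure(list(mean_gain = mean(g), sd_gain = stats::sd(g),
                 mean_loss = mean(l), sd_loss = stats::sd(l),
                 k = k, n_controls = length(control_fractions)),
            class = "aberrance_stats")
}

#' Classify a sample as copy-number aberrant
#'
#' One-sided exceedance rule: aberrant iff the cumulative gained length
#' exceeds `mean_gain + k * sd_gain` or the cumulative lost length exceeds
#' `mean_loss + k * sd_loss` of the control cohort.
#'
#' @param fractions an [altered_fractions()] result for the sample.
#' @param stats an `aberrance_stats` object.
#' @return List with `aberrant` (logical) plus the two exceedance reports.
#' @export
classify_aberrant <- function(fractions, stats) {
  stopifnot(inherits(stats, "aberrance_stats"))
  if (stats$n_controls < 2) stop("aberrance stats from < 2 controls")
  gain_cut <- stats$mean_gain + stats$k * stats$sd_gain
  loss_cut <- stats$mean_loss + stats$k * stats$sd_loss
  gain_exceeds <- fractions$bp_gain > gain_cut
  loss_exceeds <- fractions$bp_loss > loss_cut
  list(aberrant = gain_exceeds || loss_exceeds,
       gain_exceeds = gain_exceeds, loss_exceeds = loss_exceeds,
       gain_cut_bp = gain_cut, loss_cut_bp = loss_cut)
}
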