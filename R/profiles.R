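# Per-bin profiles: GC correction and control-panel normalization.

#' Binned read-count profile
#'
#' The pipeline's common per-bin currency: raw counts on a bin grid, with
#' slots for the GC-corrected normalized ratio and the control-normalized
#' log2 ratio. Masked bins carry NA values and never re-enter downstream
#' computation. chrY bins are masked from the start by default (male plasma
#' samples; Y is simulated but excluded from calling).
#'
#' @param grid a `bin_grid`.
#' @param counts non-negative integer raw counts, one per bin.
#' @param sample_id sample label.
#' @param exclude_y mask chrY bins (default TRUE).
#' @return An object of class `binned_profile`.
#' @export
binned_profile <- function(grid, counts, sample_id = "sample",
                           exclude_y = TRUE) {
  stopifnot(inherits(grid, "bin_grid"), length(counts) == nrow(grid))
  if (any(counts < 0)) stop("counts must be non-negative")
  masked <- rep(FALSE, nrow(grid))
  if (exclude_y) masked <- masked | grid$chrom %in% c("chrY", "Y")
  structure(list(sample_id = sample_id, grid = grid,
                 counts = as.numeric(counts),
                 norm = rep(NA_real_, nrow(grid)),
                 log2 = rep(NA_real_, nrow(grid)),
                 masked = masked),
            class = "binned_profile")
}

#' @export
as_binned_profile <- function(x, ...) UseMethod("as_binned_profile")

#' @export
as_binned_profile.simulated_sample <- function(x, sample_id = "sample", ...) {
  binned_profile(x$grid, x$counts, sample_id = sample_id, ...)
}

#' GC-bias correction by local regression
#'
#' Counts are first normalized by the total read count; each bin's value is
#' then divided by a robust degree-1 local regression (`stats::lowess`) of
#' value against GC fraction, fitted on unmasked autosomal bins. Because a
#' wide-span local-linear smoother underfits a strongly curved bias in one
#' pass, the fit-and-divide step is iterated (at most `max_iter` times)
#' until the incremental correction is below 0.05% RMS, making the
#' operation idempotent. The result is rescaled so its mean over unmasked
#' bins equals the mean of the total-normalized input. Bins whose GC lies
#' outside the fitted support, or where the fit is non-positive, are
#' masked.
#'
#' @param profile a `binned_profile` with raw counts.
#' @param span lowess smoother span of the primary fit (default 0.75);
#'   refinement passes alternate with half this span.
#' @param max_iter maximum fit-and-divide passes (default 8).
#' @return The profile with the `norm` slot filled.
#' @export
gc_correct <- function(profile, span = 0.75, max_iter = 8) {
  stopifnot(inherits(profile, "binned_profile"))
  un <- !profile$masked
  if (sum(profile$counts[un]) <= 0) stop("all counts are zero")
  value <- profile$counts / sum(profile$counts[un])
  gc <- profile$grid$gc
  fit_on0 <- un & is_autosome(profile$grid$chrom)
  if (sum(fit_on0) < 30) stop("too few unmasked autosomal bins for the GC fit")
  masked <- profile$masked
  ratio <- value
  for (it in seq_len(max_iter)) {
    fit_on <- fit_on0 & !masked
    # odd passes use the primary span (robust on the first), even passes a
    # tighter span to pick up curvature the wide window shrinks
    span_it <- if (it %% 2 == 1) span else span / 2
    if (diff(range(gc[fit_on])) < 1e-8) {
      # degenerate support: the local fit is the constant mean
      fitted <- rep(mean(ratio[fit_on]), length(ratio))
      fitted[abs(gc - gc[fit_on][1]) > 1e-8] <- NA_real_
    } else {
      lw <- stats::lowess(gc[fit_on], ratio[fit_on], f = span_it,
                          iter = if (it == 1) 3 else 0)
      fitted <- stats::approx(lw$x, lw$y, xout = gc, rule = 1,
                              ties = mean)$y
    }
    bad <- is.na(fitted) | fitted <= 0
    masked <- masked | bad
    ratio <- ifelse(masked, NA_real_, ratio / fitted)
    rel <- fitted[fit_on & !bad] / mean(fitted[fit_on & !bad])
    # converged when a primary-span pass finds nothing left to remove
    if (span_it == span && sqrt(mean((rel - 1)^2)) < 5e-4) break
  }
  un2 <- !masked
  ratio[un2] <- ratio[un2] * mean(value[un2]) / mean(ratio[un2])
  ratio[masked] <- NA_real_
  profile$norm <- ratio
  profile$masked <- masked
  profile
}

#' Control panel of non-tumour reference samples
#'
#' Per-bin mean of GC-corrected normalized counts over `n >= 2` non-tumour
#' control samples (cell-free DNA controls for plasma mode; constitutional
#' DNA controls for tumour-tissue mode — same operation, different inputs).
#' A bin masked in any control is masked in the panel.
#'
#' @param controls list of `binned_profile` that have been through
#'   [gc_correct()].
#' @return An object of class `control_panel` with per-bin means; the
#'   control-cohort gained/lost-length statistics used by the aberrance
#'   classifier are attached later by [aberrance_stats()].
#' @export
control_panel <- function(controls) {
  if (length(controls) < 2) stop("need at least 2 controls")
  grid <- controls[[1]]$grid
  for (p in controls) {
    stopifnot(inherits(p, "binned_profile"))
    if (!same_grid(p$grid, grid)) stop("controls on different grids")
    if (all(is.na(p$norm))) stop("controls must be GC-corrected first")
  }
  mat <- vapply(controls, function(p) p$norm, numeric(nrow(grid)))
  masked <- Reduce(`|`, lapply(controls, function(p) p$masked))
  means <- rowMeans(mat)
  means[masked] <- NA_real_
  structure(list(grid = grid, means = means, masked = masked,
                 n_controls = length(controls)),
            class = "control_panel")
}

#' Control-normalized log2 ratios
#'
#' Divides each bin's GC-corrected value by the panel's per-bin mean and
#' takes log2. Bins whose panel mean falls below a positivity floor (10% of
#' the genome-wide median panel mean) are masked rather than producing
#' infinite ratios.
#'
#' @param profile a GC-corrected `binned_profile`.
#' @param panel a `control_panel` on the same grid.
#' @param floor_frac positivity floor as a fraction of the median panel mean
#'   (default 0.1).
#' @return The profile with the `log2` slot filled.
#' @export
to_log2 <- function(profile, panel, floor_frac = 0.1) {
  stopifnot(inherits(profile, "binned_profile"),
            inherits(panel, "control_panel"))
  if (!same_grid(profile$grid, panel$grid)) stop("profile/panel grid mismatch")
  if (all(is.na(profile$norm))) stop("profile must be GC-corrected first")
  floor_val <- floor_frac * stats::median(panel$means, na.rm = TRUE)
  masked <- profile$masked | panel$masked | is.na(panel$means) |
    panel$means < floor_val
  l2 <- rep(NA_real_, nrow(profile$grid))
  ok <- !masked
  l2[ok] <- log2(profile$norm[ok] / panel$means[ok])
  profile$log2 <- l2
  profile$masked <- masked
  profile
}

#' One-call normalization: GC correction then control normalization
#'
#' @inheritParams gc_correct
#' @inheritParams to_log2
#' @export
normalize_profile <- function(profile, panel, span = 0.75) {
  to_log2(gc_correct(profile, span = span), panel)
}

#' Write / read a per-bin log2 profile
#'
#' TSV with columns `chrom start end log2 masked`.
#' @param profile a normalized `binned_profile`.
#' @param path file path.
#' @export
write_log2_profile <- function(profile, path) {
  df <- data.frame(chrom = profile$grid$chrom, start = profile$grid$start,
                   end = profile$grid$end, log2 = profile$log2,
                   masked = as.integer(profile$masked))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
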