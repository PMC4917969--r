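# Serial-sample comparison: eligibility, tumour-ratio fit, differential
# regions, clustering, plasma-tissue correlation.

#' Serial-comparison configuration
#'
#' @param min_rho Spearman eligibility threshold (default 0.85).
#' @param ratio_grid_max upper bound of the tumour-ratio grid (default 10).
#' @param ratio_grid_step grid step (default 0.01).
#' @param diff_threshold per-bin differential log2 threshold (default 0.2).
#' @param min_run minimum differential run length in bins (default 5;
#'   1 reproduces the literal single-bin rule).
#' @export
serial_config <- function(min_rho = 0.85, ratio_grid_max = 10,
                          ratio_grid_step = 0.01, diff_threshold = 0.2,
                          min_run = 5) {
  stopifnot(min_rho > 0, min_rho < 1, ratio_grid_step > 0,
            diff_threshold > 0, min_run >= 1)
  structure(list(min_rho = min_rho, ratio_grid_max = ratio_grid_max,
                 ratio_grid_step = ratio_grid_step,
                 diff_threshold = diff_threshold, min_run = min_run),
            class = "serial_config")
}

shared_bins <- function(a, b, autosomes_only = FALSE) {
  stopifnot(same_grid(a$grid, b$grid))
  ok <- !a$masked & !b$masked
  if (autosomes_only) ok <- ok & is_autosome(as.character(a$grid$chrom))
  ok
}

#' Spearman correlation of two segmented profiles
#'
#' Rank correlation of the per-bin expanded segment means over shared
#' unmasked bins; used to gate serial comparisons (only pairs with
#' rho > 0.85, i.e. similar ctDNA content, are compared).
#'
#' @param a,b `segmented_profile`s on the same grid.
#' @return Spearman rho.
#' @export
profile_spearman <- function(a, b) {
  ok <- shared_bins(a, b)
  if (sum(ok) < 10) stop("fewer than 10 shared unmasked bins")
  va <- per_bin_segmented(a)[ok]; vb <- per_bin_segmented(b)[ok]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("constant profile: correlation undefined")
  stats::cor(va, vb, method = "spearman")
}

#' Fit the tumour-content ratio between two serial samples
#'
#' Grid search over r in [0, `ratio_grid_max`] at steps of
#' `ratio_grid_step`, minimizing the sum of squared differences
#' `sum((r * sA - sB)^2)` of the per-bin segmented log2 ratios; ties break
#' toward smaller r. The closed-form least-squares slope through the origin
#' is attached for audit.
#'
#' @param a,b `segmented_profile`s (a = earlier, b = later).
#' @param config a [serial_config()].
#' @return Numeric r on the grid, with attributes `analytic_slope` and
#'   `sse`.
#' @export
fit_tumor_ratio <- function(a, b, config = serial_config()) {
  ok <- shared_bins(a, b)
  sa <- per_bin_segmented(a)[ok]; sb <- per_bin_segmented(b)[ok]
  saa <- sum(sa * sa)
  if (saa == 0) stop("all-zero earlier profile: ratio unidentifiable")
  grid <- seq(0, config$ratio_grid_max, by = config$ratio_grid_step)
  sab <- sum(sa * sb); sbb <- sum(sb * sb)
  sse <- grid^2 * saa - 2 * grid * sab + sbb
  r <- grid[which.min(sse)]
  attr(r, "analytic_slope") <- sab / saa
  attr(r, "sse") <- min(sse)
  r
}

#' Differential regions between two serial samples
#'
#' Per-bin adjusted difference `d = sB - r * sA`; bins with |d| strictly
#' above the threshold are flagged, consecutive same-sign flagged bins merge
#' into regions, and runs shorter than `min_run` bins are dropped. The
#' flagged fraction is reported over the unmasked autosomal genome.
#'
#' @param a,b `segmented_profile`s.
#' @param r tumour-content ratio (from [fit_tumor_ratio()]).
#' @param config a [serial_config()].
#' @return List of class `serial_comparison`: `rho`, `r`, `regions`
#'   (data.frame `chrom start end n_bins direction mean_delta`),
#'   `pct_autosomal_diff`, and the per-bin `delta`.
#' @export
differential_regions <- function(a, b, r = NULL, config = serial_config()) {
  # rho is reported for context; degenerate (constant) profiles yield NA
  rho <- tryCatch(profile_spearman(a, b), error = function(e) NA_real_)
  if (is.null(r)) r <- fit_tumor_ratio(a, b, config)
  ok <- shared_bins(a, b)
  sa <- per_bin_segmented(a); sb <- per_bin_segmented(b)
  d <- sb - as.numeric(r) * sa
  d[!ok] <- NA_real_
  flag <- !is.na(d) & abs(d) > config$diff_threshold
  sign_d <- ifelse(flag, sign(d), 0)
  grid <- a$grid
  regions <- list()
  # runs of consecutive (in bin order, same chromosome) same-sign flags
  n <- length(d)
  run_start <- NA_integer_
  for (i in seq_len(n + 1)) {
    extend <- i <= n && flag[i] && !is.na(run_start) &&
      sign_d[i] == sign_d[run_start] &&
      as.character(grid$chrom[i]) == as.character(grid$chrom[run_start])
    if (!is.na(run_start) && !extend) {
      len <- i - run_start
      if (len >= config$min_run) {
        sel <- run_start:(i - 1)
        regions[[length(regions) + 1]] <- data.frame(
          chrom = as.character(grid$chrom[run_start]),
          start = grid$start[run_start], end = grid$end[i - 1],
          n_bins = len,
          direction = if (sign_d[run_start] > 0) "gain" else "loss",
          mean_delta = mean(d[sel]))
      }
      run_start <- NA_integer_
    }
    if (i <= n && flag[i] && is.na(run_start)) run_start <- i
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_bins = integer(), direction = character(),
               mean_delta = numeric())
  auto <- ok & is_autosome(as.character(grid$chrom))
  in_region <- rep(FALSE, n)
  for (k in seq_len(nrow(regions))) {
    in_region[grid$chrom == regions$chrom[k] &
              grid$start >= regions$start[k] &
              grid$end <= regions$end[k]] <- TRUE
  }
  w <- grid$end - grid$start
  pct <- 100 * sum(w[auto & in_region]) / sum(w[auto])
  structure(list(sample_a = a$sample_id, sample_b = b$sample_id,
                 rho = rho, r = as.numeric(r),
                 analytic_slope = attr(r, "analytic_slope"),
                 regions = regions, pct_autosomal_diff = pct, delta = d),
            class = "serial_comparison")
}

#' Hierarchical clustering of copy-number profiles
#'
#' Pairwise Manhattan (L1) distances over bins unmasked in every profile,
#' merged by average linkage; mirrors clustering of serial plasma samples
#' in which samples from the same patient form clades.
#'
#' @param profiles list of `segmented_profile`s on a shared grid.
#' @param labels sample labels (default: sample ids).
#' @return An `stats::hclust` object.
#' @export
cluster_profiles <- function(profiles, labels = NULL) {
  if (length(profiles) < 2) stop("need >= 2 profiles")
  grid <- profiles[[1]]$grid
  for (p in profiles) stopifnot(same_grid(p$grid, grid))
  ok <- !Reduce(`|`, lapply(profiles, function(p) p$masked))
  mat <- vapply(profiles, function(p) per_bin_segmented(p)[ok],
                numeric(sum(ok)))
  if (is.null(labels))
    labels <- vapply(profiles, function(p) p$sample_id, "")
  colnames(mat) <- labels
  stats::hclust(stats::dist(t(mat), method = "manhattan"),
                method = "average")
}

#' Pearson correlation of plasma and tissue profiles
#'
#' Computed on per-bin segmented log2 ratios of autosomes only: tissue
#' controls come from both sexes, so sex chromosomes would bias the
#' comparison.
#'
#' @param a,b `segmented_profile`s on the same grid.
#' @export
tissue_plasma_pearson <- function(a, b) {
  ok <- shared_bins(a, b, autosomes_only = TRUE)
  va <- per_bin_segmented(a)[ok]; vb <- per_bin_segmented(b)[ok]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("constant profile: correlation undefined")
  stats::cor(va, vb, method = "pearson")
}
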