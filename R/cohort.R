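# Cohort-level summaries and the statistical tests used throughout.

#' Per-bin gain/loss frequency tracks
#'
#' For each bin, the fraction of samples whose covering segment is labelled
#' gained / lost.
#'
#' @param profiles list of labelled `segmented_profile`s (after
#'   [call_states()]) on a shared grid.
#' @return data.frame `chrom start end freq_gain freq_loss` with attribute
#'   `n_samples`.
#' @export
frequency_tracks <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  grid <- profiles[[1]]$grid
  ngain <- nloss <- rep(0, nrow(grid))
  for (p in profiles) {
    if (!same_grid(p$grid, grid)) stop("profiles on different grids")
    stopifnot("state" %in% names(p$segments))
    st <- rep(NA_character_, nrow(grid))
    ok <- !is.na(p$bin_seg)
    st[ok] <- p$segments$state[p$bin_seg[ok]]
    ngain <- ngain + (!is.na(st) & st == "gain")
    nloss <- nloss + (!is.na(st) & st == "loss")
  }
  out <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                    freq_gain = ngain / length(profiles),
                    freq_loss = nloss / length(profiles))
  attr(out, "n_samples") <- length(profiles)
  out
}

#' Two-sided Mann-Whitney U test
#'
#' For combined n <= 12 without ties the p-value is computed by exhaustive
#' enumeration of all group assignments of the pooled values; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y numeric value vectors (both non-empty).
#' @return List of class `group_comparison`: `statistic` (U of x),
#'   `p_value`, `method`, `n`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_x <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (nx + ny <= 12 && !has_ties) {
    combos <- utils::combn(nx + ny, nx)
    u_all <- apply(combos, 2, function(idx)
      sum(rank(pooled)[idx]) - nx * (nx + 1) / 2)
    mid <- nx * ny / 2
    dev <- abs(u_x - mid)
    p <- mean(abs(u_all - mid) >= dev - 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- nx * ny / 2
    nt <- nx + ny
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (nt * (nt - 1))
    sigma <- sqrt(nx * ny / 12 * ((nt + 1) - tie_corr))
    if (sigma == 0) stop("all values identical: test undefined")
    z <- (u_x - mu - sign(u_x - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  structure(list(statistic = u_x, p_value = p, method = method,
                 test = "Mann-Whitney U", n = c(nx = nx, ny = ny)),
            class = "group_comparison")
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' p is the sum of hypergeometric probabilities of all tables (with the
#' observed margins) no more probable than the observed table
#' (minimum-likelihood method).
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return List of class `group_comparison` with `p_value` and `odds_ratio`
#'   (sample odds ratio).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must hold non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has a zero margin")
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x, m, n, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  structure(list(statistic = x, p_value = min(1, p), odds_ratio = or,
                 test = "Fisher exact", method = "minimum likelihood",
                 n = sum(tab)),
            class = "group_comparison")
}

#' Cohort report: focal counts, altered fractions, driver frequencies
#'
#' Per-group focal-count summaries (mean and quartiles), altered-genome
#' fraction summaries, and the fraction of patients carrying at least one
#' driver aberration (a focal amplification containing a driver gene, or a
#' focal deletion: deletion calls are gated on the curated deletion-gene
#' list, which includes the TMPRSS2/ERG fusion interval genes on chr21).
#' "Any sample per patient" counting is used.
#'
#' @param events cohort focal-event data.frame.
#' @param fractions named list (by sample) of [altered_fractions()] results;
#'   may be NULL.
#' @param metadata data.frame with columns `sample`, `patient` and optional
#'   grouping columns.
#' @param group name of the grouping column in `metadata` (optional).
#' @return List with `focal_by_group`, `fraction_by_group`,
#'   `driver_frequency`.
#' @export
cohort_report <- function(events, fractions = NULL, metadata, group = NULL) {
  stopifnot(all(c("sample", "patient") %in% names(metadata)))
  bad <- setdiff(unique(events$sample), metadata$sample)
  if (length(bad)) stop("unmatched sample ids: ", paste(bad, collapse = ", "))
  counts <- count_focal_per_sample(events, metadata$sample)$per_sample
  counts$patient <- metadata$patient[match(counts$sample, metadata$sample)]

  summarise_counts <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75))
    data.frame(n = length(v), mean = mean(v), q25 = q[1], median = q[2],
               q75 = q[3], row.names = NULL)
  }
  if (!is.null(group)) {
    g <- metadata[[group]][match(counts$sample, metadata$sample)]
    focal_by_group <- do.call(rbind, lapply(split(counts$n_total, g),
                                            summarise_counts))
    focal_by_group$group <- rownames(focal_by_group)
  } else {
    focal_by_group <- summarise_counts(counts$n_total)
    focal_by_group$group <- "all"
  }

  fraction_by_group <- NULL
  if (!is.null(fractions)) {
    fr <- data.frame(sample = names(fractions),
                     pct_gain = vapply(fractions, function(x) x$pct_gain, 0),
                     pct_loss = vapply(fractions, function(x) x$pct_loss, 0),
                     row.names = NULL)
    fraction_by_group <- fr
  }

  # driver aberration: any sample of the patient with a driver focal amp
  # or any focal deletion (deletion calls require a curated deletion gene)
  ev_drv <- events[(events$class == "amplification" & events$has_driver) |
                   events$class == "deletion", , drop = FALSE]
  pat <- unique(metadata$patient)
  pat_with <- unique(metadata$patient[match(ev_drv$sample, metadata$sample)])
  driver_frequency <- list(
    n_patients = length(pat),
    n_with_driver = length(pat_with),
    fraction = if (length(pat)) length(pat_with) / length(pat) else NA_real_)

  list(focal_by_group = focal_by_group,
       fraction_by_group = fraction_by_group,
       driver_frequency = driver_frequency,
       per_sample_counts = counts)
}
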