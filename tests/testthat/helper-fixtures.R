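# Shared fixtures, built once per test run.
# A small male-like genome keeps unit tests fast; the acceptance dilution
# experiment uses the full 50,000-bin genome.

.fix <- new.env()

fix_genome <- function() {
  if (is.null(.fix$genome)) .fix$genome <- toy_genome()
  .fix$genome
}

fix_grid <- function(n_bins = 1200) {
  key <- paste0("grid", n_bins)
  if (is.null(.fix[[key]])) .fix[[key]] <- build_bin_grid(fix_genome(), n_bins)
  .fix[[key]]
}

# full-scale male grid (50,000 bins), shared by the tests that need the
# production-scale genome
fix_male_grid <- function() {
  if (is.null(.fix$male_grid))
    .fix$male_grid <- build_bin_grid(male_genome(), 50000)
  .fix$male_grid
}

fix_male_panel <- function(n = 8, seed = 880) {
  key <- paste0("male_panel", n, "_", seed)
  if (is.null(.fix[[key]])) {
    cfg <- sim_config(seed = seed)
    ctrl <- simulate_controls(n, male_genome(), cfg, grid = fix_male_grid())
    .fix[[key]] <- control_panel(lapply(ctrl, function(s)
      gc_correct(as_binned_profile(s))))
  }
  .fix[[key]]
}

# small control panel (f = 0) shared across tests
fix_panel <- function(n = 6, n_bins = 1200, seed = 900) {
  key <- paste0("panel", n, "_", n_bins, "_", seed)
  if (is.null(.fix[[key]])) {
    cfg <- sim_config(n_bins = n_bins, seed = seed)
    ctrl <- simulate_controls(n, fix_genome(), cfg, grid = fix_grid(n_bins))
    .fix[[key]] <- control_panel(lapply(ctrl, function(s)
      gc_correct(as_binned_profile(s))))
  }
  .fix[[key]]
}

# run one simulated sample through normalize + segment
fix_segmented <- function(states_df, f, seed, n_bins = 1200,
                          sample_id = "s", n_perm = 1000) {
  genome <- fix_genome()
  states <- cn_state_map(states_df, genome)
  cfg <- sim_config(n_bins = n_bins, tumour_fraction = f, seed = seed)
  sm <- simulate_sample(genome, states, cfg, grid = fix_grid(n_bins))
  prof <- normalize_profile(as_binned_profile(sm, sample_id = sample_id),
                            fix_panel(n_bins = n_bins))
  segment_profile(prof, seed = seed, n_perm = n_perm)
}

# build a segmented_profile directly from a per-bin vector on a grid
manual_segprofile <- function(values, id = "m", grid = fix_grid(600)) {
  n <- nrow(grid)
  stopifnot(length(values) == n)
  rle_v <- rle(paste(as.character(grid$chrom), values))
  ends <- cumsum(rle_v$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  segments <- data.frame(
    sample = id, chrom = as.character(grid$chrom[starts]),
    start = grid$start[starts], end = grid$end[ends],
    n_bins = rle_v$lengths, mean_log2 = values[starts])
  bin_seg <- rep(seq_along(ends), rle_v$lengths)
  structure(list(sample_id = id, segments = segments, grid = grid,
                 bin_log2 = values, bin_seg = bin_seg,
                 masked = rep(FALSE, n)),
            class = "segmented_profile")
}

# segment table constructor for caller-level tests
seg_table <- function(..., sample = "s1") {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = r[[1]], start = as.numeric(r[[2]]),
               end = as.numeric(r[[3]]), mean_log2 = as.numeric(r[[4]]))))
  df$sample <- sample
  df$n_bins <- pmax(1L, as.integer((df$end - df$start) / 56000))
  df[, c("sample", "chrom", "start", "end", "n_bins", "mean_log2")]
}

# Independent brute-force focal rule checker: no interval libraries, plain
# loops; mirrors the printed criteria lists rule by rule.
brute_focal_check <- function(segments, genes, segdup, dgv, criteria,
                              class = "amplification") {
  out <- logical(nrow(segments))
  for (k in seq_len(nrow(segments))) {
    s <- segments[k, ]
    amp <- class == "amplification"
    if (amp && !(s$mean_log2 > criteria$amp_threshold)) next
    if (!amp && !(s$mean_log2 < criteria$del_threshold)) next
    if (!(s$end - s$start < criteria$max_size)) next
    gidx <- c()
    for (g in seq_len(nrow(genes))) {
      if (genes$chrom[g] == s$chrom && genes$start[g] < s$end &&
          genes$end[g] > s$start) gidx <- c(gidx, g)
    }
    if (length(gidx) < 1 || length(gidx) > criteria$max_genes) next
    if (!amp && !any(genes$is_del_gene[gidx])) next
    # flank weighted mean, brute force over other segments
    wsum <- 0; tot <- 0
    for (j in seq_len(nrow(segments))) {
      if (j == k || segments$chrom[j] != s$chrom) next
      for (win in list(c(max(0, s$start - criteria$flank_window), s$start),
                       c(s$end, s$end + criteria$flank_window))) {
        ov <- min(segments$end[j], win[2]) - max(segments$start[j], win[1])
        if (ov > 0) { wsum <- wsum + ov * segments$mean_log2[j]; tot <- tot + ov }
      }
    }
    flank <- if (tot > 0) wsum / tot else 0
    margin <- if (amp && any(genes$is_driver[gidx])) criteria$driver_delta
              else if (amp) criteria$nondriver_delta
              else criteria$driver_delta
    if (amp && !(s$mean_log2 - flank > margin)) next
    if (!amp && !(flank - s$mean_log2 > margin)) next
    cover_frac <- function(track) {
      if (!nrow(track)) return(0)
      pos <- c()
      for (t in seq_len(nrow(track))) {
        if (track$chrom[t] != s$chrom) next
        a <- max(track$start[t], s$start); b <- min(track$end[t], s$end)
        if (b > a) pos <- c(pos, list(c(a, b)))
      }
      if (!length(pos)) return(0)
      # union length by sweeping
      pos <- pos[order(vapply(pos, `[`, 0, 1))]
      tot <- 0; cur <- pos[[1]]
      for (p in pos[-1]) {
        if (p[1] <= cur[2]) cur[2] <- max(cur[2], p[2])
        else { tot <- tot + cur[2] - cur[1]; cur <- p }
      }
      tot <- tot + cur[2] - cur[1]
      tot / (s$end - s$start)
    }
    if (cover_frac(segdup) > criteria$segdup_max_frac) next
    if (cover_frac(dgv) >= criteria$dgv_max_frac) next
    out[k] <- TRUE
  }
  out
}
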