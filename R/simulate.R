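# Synthetic shallow-WGS plasma profiles with known copy-number truth.

#' Simulation configuration
#'
#' Defaults emulate the plasma-Seq measurement process: ~50,000 bins across a
#' male genome, a mean of ~120 reads per diploid bin (~0.1x genome coverage),
#' Poisson count noise, and a smooth unimodal GC bias peaking near GC 0.45.
#'
#' @param n_bins number of genomic bins (default 50000).
#' @param total_coverage mean reads per diploid bin (default 120).
#' @param tumour_fraction ctDNA content f in [0,1] (default 0).
#' @param gc_bias quadratic bias coefficients `c(a, peak)`: relative
#'   efficiency `max(0.05, 1 + a * (gc - peak)^2)`. The default
#'   `c(-20, 0.45)` makes GC a first-order effect on raw counts
#'   (|Spearman rho| of counts vs GC around 0.4, as seen in uncorrected
#'   shallow WGS); use `c(0, 0.45)` for a flat (no-bias) curve.
#' @param noise_model "poisson" (default) or "nbinom".
#' @param nb_dispersion negative-binomial size parameter (only for "nbinom").
#' @param log2_floor reported expected log2 when the mixture mean is 0.
#' @param seed integer seed; identical (config, seed) reproduce identical
#'   samples bit for bit.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_bins = 50000, total_coverage = 120,
                       tumour_fraction = 0, gc_bias = c(-20, 0.45),
                       noise_model = c("poisson", "nbinom"),
                       nb_dispersion = 50, log2_floor = -8, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (tumour_fraction < 0 || tumour_fraction > 1)
    stop("tumour_fraction must be in [0,1]")
  if (total_coverage <= 0) stop("total_coverage must be > 0")
  structure(list(n_bins = n_bins, total_coverage = total_coverage,
                 tumour_fraction = tumour_fraction, gc_bias = gc_bias,
                 noise_model = noise_model, nb_dispersion = nb_dispersion,
                 log2_floor = log2_floor, seed = as.integer(seed)),
            class = "sim_config")
}

gc_bias_curve <- function(gc, coef) pmax(0.05, 1 + coef[1] * (gc - coef[2])^2)

#' Expected log2 ratio of a diluted copy-number event
#'
#' The tumour contributes a fraction `f` of the cell-free DNA; a region at
#' absolute tumour copy number `c` over baseline `b` is observed at mixture
#' copy number `b(1-f) + cf`, i.e. log2 ratio `log2((b(1-f) + cf) / b)`.
#'
#' @param copies absolute tumour copy number (>= 0).
#' @param f tumour fraction in [0,1].
#' @param baseline baseline copy number (1 or 2).
#' @param floor value returned when the mixture mean is 0 (default -8).
#' @return Expected log2 ratio.
#' @examples
#' expected_log2(13, 0.05, baseline = 1)  # ~0.678, an AR amplicon at 5%
#' @export
expected_log2 <- function(copies, f, baseline = 2, floor = -8) {
  if (any(copies < 0)) stop("copies must be >= 0")
  if (any(f < 0 | f > 1)) stop("f must be in [0,1]")
  stopifnot(all(baseline %in% c(1, 2)))
  mix <- baseline * (1 - f) + copies * f
  ifelse(mix <= 0, floor, log2(mix / baseline))
}

# per-bin absolute tumour copy number: length-weighted over events
bin_tumour_cn <- function(grid, states) {
  cn <- grid_base_cn(grid)
  tum <- as.numeric(cn)
  ev <- states$events
  if (!nrow(ev)) return(tum)
  w <- grid$end - grid$start
  for (k in seq_len(nrow(ev))) {
    hit <- which(grid$chrom == ev$chrom[k] &
                 grid$end > ev$start[k] & grid$start < ev$end[k])
    if (!length(hit)) next
    ov <- pmin(grid$end[hit], ev$end[k]) - pmax(grid$start[hit], ev$start[k])
    tum[hit] <- tum[hit] + (ev$copies[k] - cn[hit]) * ov / w[hit]
  }
  tum
}

#' Simulate one binned plasma sample
#'
#' Per-bin expected count = coverage x GC bias x mappable-length factor x
#' mixture copy number / 2; counts are drawn from the configured noise model.
#' The per-bin truth (tumour copy number and expected log2 ratio) is recorded
#' alongside the counts.
#'
#' @param genome a `genome_model`.
#' @param states a `cn_state_map` of tumour events.
#' @param config a `sim_config`.
#' @param grid optional pre-built `bin_grid` (shared across a series).
#' @return A list of class `simulated_sample` with elements `grid`, `counts`,
#'   `truth` (data.frame `tumour_cn`, `expected_log2`), `states`, `config`.
#' @export
simulate_sample <- function(genome, states, config, grid = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(grid)) grid <- build_bin_grid(genome, config$n_bins)
  base_cn <- grid_base_cn(grid)
  f <- config$tumour_fraction
  tum <- bin_tumour_cn(grid, states)
  mix <- base_cn * (1 - f) + tum * f
  exp_l2 <- ifelse(mix <= 0, config$log2_floor, log2(mix / base_cn))
  bias <- gc_bias_curve(grid$gc, config$gc_bias)
  lenf <- grid$mappable_bp / mean(grid$mappable_bp)
  mu <- config$total_coverage * bias * lenf * mix / 2
  counts <- with_seed(config$seed, {
    if (config$noise_model == "poisson") stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), size = config$nb_dispersion, mu = mu)
  })
  structure(list(grid = grid, counts = counts,
                 truth = data.frame(tumour_cn = tum, expected_log2 = exp_l2),
                 states = states, config = config),
            class = "simulated_sample")
}

#' Simulate a dilution series of one tumour
#'
#' One sample per tumour fraction, sharing the genome, grid and GC bias;
#' the i-th sample uses seed `config$seed + i - 1`, so the series is
#' reproducible yet the levels are independent.
#'
#' @param pure a `cn_state_map` describing the undiluted tumour.
#' @param fractions tumour fractions in (0, 1].
#' @inheritParams simulate_sample
#' @return List of `simulated_sample`, one per fraction.
#' @export
simulate_dilution_series <- function(pure, fractions, genome, config,
                                     grid = NULL) {
  if (!length(fractions)) stop("fractions must be non-empty")
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must be in (0,1]")
  if (is.null(grid)) grid <- build_bin_grid(genome, config$n_bins)
  lapply(seq_along(fractions), function(i) {
    cfg <- config
    cfg$tumour_fraction <- fractions[i]
    cfg$seed <- config$seed + i - 1L
    simulate_sample(genome, pure, cfg, grid = grid)
  })
}

#' Simulate a serial (longitudinal) scenario
#'
#' Time point t carries the base state map with all changes up to and
#' including index t applied; each change adds or removes one event.
#' The per-pair differential truth (which intervals changed, and in which
#' direction) is recorded for testing differential callers.
#'
#' @param base a `cn_state_map`.
#' @param changes data.frame with columns `time` (strictly positive integer),
#'   `action` ("add" or "remove"), `chrom`, `start`, `end`, `copies`
#'   (`copies` ignored for removals, which must match an existing event's
#'   chrom/start/end exactly).
#' @param n_times number of time points to simulate.
#' @param fractions tumour fraction per time point (recycled).
#' @inheritParams simulate_sample
#' @return List with `samples` (one per time point), `states` (per time
#'   point) and `diff_truth` (per consecutive pair: data.frame
#'   `chrom,start,end,direction`).
#' @export
simulate_serial_scenario <- function(base, changes, n_times, genome, config,
                                     fractions = config$tumour_fraction,
                                     grid = NULL) {
  stopifnot(n_times >= 1)
  if (nrow(changes) && is.unsorted(changes$time, strictly = FALSE))
    changes <- changes[order(changes$time), , drop = FALSE]
  fractions <- rep_len(fractions, n_times)
  if (is.null(grid)) grid <- build_bin_grid(genome, config$n_bins)

  states <- vector("list", n_times)
  diffs <- vector("list", max(0, n_times - 1))
  cur <- base$events
  for (t in seq_len(n_times)) {
    ch <- changes[changes$time == t, , drop = FALSE]
    for (k in seq_len(nrow(ch))) {
      if (ch$action[k] == "add") {
        cur <- rbind(cur, data.frame(chrom = ch$chrom[k], start = ch$start[k],
                                     end = ch$end[k], copies = ch$copies[k]))
      } else if (ch$action[k] == "remove") {
        hit <- which(cur$chrom == ch$chrom[k] & cur$start == ch$start[k] &
                     cur$end == ch$end[k])
        if (!length(hit)) stop("cannot remove a non-existent event")
        cur <- cur[-hit[1], , drop = FALSE]
      } else stop("action must be 'add' or 'remove'")
    }
    states[[t]] <- cn_state_map(cur, genome)
    if (t > 1) {
      ch_dir <- if (nrow(ch)) {
        data.frame(chrom = ch$chrom, start = ch$start, end = ch$end,
                   direction = ifelse(ch$action == "add", "gain", "loss"))
      } else {
        data.frame(chrom = character(), start = numeric(), end = numeric(),
                   direction = character())
      }
      diffs[[t - 1]] <- ch_dir
    }
  }
  samples <- lapply(seq_len(n_times), function(t) {
    cfg <- config
    cfg$tumour_fraction <- fractions[t]
    cfg$seed <- config$seed + (t - 1L) * 1000L
    simulate_sample(genome, states[[t]], cfg, grid = grid)
  })
  list(samples = samples, states = states, diff_truth = diffs)
}

#' Simulate non-tumour control samples
#'
#' `n` tumour-free (f = 0) samples on a shared grid with independent seeds,
#' suitable for building a control panel and the control aberrance
#' statistics.
#'
#' @param n number of controls (>= 2, so SDs are defined).
#' @inheritParams simulate_sample
#' @return List of `simulated_sample`.
#' @export
simulate_controls <- function(n, genome, config, grid = NULL) {
  if (n < 2) stop("need at least 2 controls")
  if (is.null(grid)) grid <- build_bin_grid(genome, config$n_bins)
  empty <- cn_state_map(NULL, genome)
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$tumour_fraction <- 0
    cfg$seed <- config$seed + 7919L * i
    simulate_sample(genome, empty, cfg, grid = grid)
  })
}

#' Write the per-bin truth of a simulated sample as BED
#'
#' Columns: `chrom start end copy_number expected_log2`.
#' @param sample a `simulated_sample`.
#' @param path output path.
#' @export
write_truth_bed <- function(sample, path) {
  df <- data.frame(chrom = sample$grid$chrom, start = sample$grid$start,
                   end = sample$grid$end,
                   copy_number = sample$truth$tumour_cn,
                   expected_log2 = sample$truth$expected_log2)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
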