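# Synthetic ctDNA generator: mixture identity, determinism, GC bias, truth.

test_that("expected_log2 implements the tumour-fraction mixture identity", {
  # no alteration: c equals baseline at any fraction
  expect_equal(expected_log2(2, 0.37, baseline = 2), 0)
  expect_equal(expected_log2(1, 0.8, baseline = 1), 0)
  # AR-like amplicon (13 copies on single-copy X) under dilution
  expect_equal(expected_log2(13, 0.05, baseline = 1), log2(1.60),
               tolerance = 1e-12)
  expect_equal(expected_log2(13, 0.01, baseline = 1), log2(1.12),
               tolerance = 1e-12)
  # homozygous deletion at f = 1 hits the floor
  expect_equal(expected_log2(0, 1, baseline = 2, floor = -8), -8)
  expect_error(expected_log2(-1, 0.5), "copies")
  expect_error(expected_log2(2, 1.5), "f must")
})

test_that("simulate_sample is deterministic and records truth", {
  genome <- fix_genome()
  states <- cn_state_map(data.frame(chrom = "chr1", start = 10e6,
                                    end = 40e6, copies = 4), genome)
  cfg <- sim_config(n_bins = 600, tumour_fraction = 0.3, seed = 42)
  s1 <- simulate_sample(genome, states, cfg, grid = fix_grid(600))
  s2 <- simulate_sample(genome, states, cfg, grid = fix_grid(600))
  expect_identical(s1$counts, s2$counts)
  cfg$seed <- 43L
  s3 <- simulate_sample(genome, states, cfg, grid = fix_grid(600))
  expect_false(identical(s1$counts, s3$counts))
  expect_true(all(s1$counts >= 0))
  expect_equal(length(s1$counts), nrow(s1$grid))
  # truth covers every bin; event bins carry the mixture log2
  in_ev <- s1$grid$chrom == "chr1" & s1$grid$start >= 10e6 &
    s1$grid$end <= 40e6
  expect_equal(unique(s1$truth$expected_log2[in_ev]),
               expected_log2(4, 0.3, 2))
  expect_false(anyNA(s1$truth$expected_log2))
})

test_that("a pure 500-bin c=4 event lands near log2 ratio 1", {
  # f = 1, one 500-bin autosomal event on the full 50,000-bin genome:
  # region mean within 0.02 of log2(4/2) = 1
  genome <- male_genome()
  grid <- fix_male_grid()
  # ~500 bins of chr2 (bin span ~61 kb): a 30.5 Mb event
  states <- cn_state_map(data.frame(chrom = "chr2", start = 50e6,
                                    end = 80.5e6, copies = 4), genome)
  cfg <- sim_config(tumour_fraction = 1, seed = 7)
  sm <- simulate_sample(genome, states, cfg, grid = grid)
  prof <- normalize_profile(as_binned_profile(sm), fix_male_panel())
  ev <- prof$grid$chrom == "chr2" & prof$grid$start >= 50e6 &
    prof$grid$end <= 80.5e6 & !prof$masked
  expect_gt(sum(ev), 400)
  # total-count normalization shifts the whole genome down slightly (the
  # event inflates the library total); measure against the copy-neutral
  # baseline, i.e. the genome-wide median
  baseline <- stats::median(prof$log2[!prof$masked & !ev])
  expect_equal(mean(prof$log2[ev]) - baseline, 1, tolerance = 0.02)
})

test_that("dilution series shares the grid and dilutes monotonically", {
  genome <- fix_genome()
  pure <- cn_state_map(data.frame(chrom = "chrX", start = 66e6, end = 68e6,
                                  copies = 13), genome)
  cfg <- sim_config(n_bins = 800, seed = 10)
  ser <- simulate_dilution_series(pure, c(0.20, 0.10, 0.05, 0.01),
                                  genome, cfg, grid = fix_grid(800))
  in_ev <- ser[[1]]$grid$chrom == "chrX" & ser[[1]]$grid$start >= 66e6 &
    ser[[1]]$grid$end <= 68e6
  truth_l2 <- vapply(ser, function(s) mean(s$truth$expected_log2[in_ev]), 0)
  # expected amplitudes from the mixture identity (pure amplitude 3.7)
  expect_equal(truth_l2, log2(1 + 12 * c(0.20, 0.10, 0.05, 0.01)),
               tolerance = 1e-9)
  expect_true(all(diff(truth_l2) < 0))
  # fractions = [1] reproduces simulate_sample at f = 1 exactly
  one <- simulate_dilution_series(pure, 1, genome, cfg, grid = fix_grid(800))
  cfg1 <- cfg; cfg1$tumour_fraction <- 1
  direct <- simulate_sample(genome, pure, cfg1, grid = fix_grid(800))
  expect_identical(one[[1]]$counts, direct$counts)
  expect_error(simulate_dilution_series(pure, numeric(0), genome, cfg),
               "non-empty")
})

test_that("serial scenarios apply cumulative changes and record truth", {
  genome <- fix_genome()
  base <- cn_state_map(data.frame(chrom = "chr1", start = 0, end = 60e6,
                                  copies = 3), genome)
  none <- data.frame(time = integer(), action = character(),
                     chrom = character(), start = numeric(),
                     end = numeric(), copies = numeric())
  cfg <- sim_config(n_bins = 600, tumour_fraction = 0.3, seed = 5)
  quiet <- simulate_serial_scenario(base, none, 2, genome, cfg,
                                    grid = fix_grid(600))
  expect_equal(nrow(quiet$diff_truth[[1]]), 0)

  changes <- data.frame(time = c(2, 3), action = c("add", "remove"),
                        chrom = "chrX", start = 66e6, end = 69e6,
                        copies = 10)
  sc <- simulate_serial_scenario(base, changes, 3, genome, cfg,
                                 grid = fix_grid(600))
  expect_equal(sc$diff_truth[[1]]$direction, "gain")
  expect_equal(sc$diff_truth[[1]]$start, 66e6)
  expect_equal(sc$diff_truth[[2]]$direction, "loss")
  expect_equal(nrow(sc$states[[2]]$events), 2)
  expect_equal(nrow(sc$states[[3]]$events), 1)
  bad <- data.frame(time = 2, action = "remove", chrom = "chr2",
                    start = 1e6, end = 2e6, copies = 0)
  expect_error(simulate_serial_scenario(base, bad, 2, genome, cfg,
                                        grid = fix_grid(600)),
               "non-existent")
})

test_that("controls require n >= 2 and are centred after normalization", {
  genome <- fix_genome()
  cfg <- sim_config(n_bins = 1200, seed = 31)
  expect_error(simulate_controls(1, genome, cfg, grid = fix_grid(1200)),
               "at least 2")
  held_out <- simulate_controls(2, genome,
                                sim_config(n_bins = 1200, seed = 77),
                                grid = fix_grid(1200))
  prof <- normalize_profile(as_binned_profile(held_out[[1]]), fix_panel())
  expect_lt(abs(mean(prof$log2[!prof$masked])), 0.01)
})

test_that("GC bias is injectable and does not touch the truth", {
  genome <- fix_genome()
  empty <- cn_state_map(NULL, genome)
  cfg <- sim_config(n_bins = 1200, seed = 12)  # default non-flat bias
  sm <- simulate_sample(genome, empty, cfg, grid = fix_grid(1200))
  auto <- is_autosome(as.character(sm$grid$chrom))
  rho_raw <- cor(sm$counts[auto], sm$grid$gc[auto], method = "spearman")
  expect_gt(abs(rho_raw), 0.3)
  expect_equal(sd(sm$truth$expected_log2), 0)
})

test_that("empirical event means converge to the mixture identity", {
  # property: 1000-bin events at several (c, f) land within 3 Poisson SEs
  genome <- toy_genome(n_autosomes = 2, autosome_length = 300e6)
  grid <- build_bin_grid(genome, 4000, gc_seed = 5)
  for (case in list(c(4, 0.5), c(8, 0.2), c(1, 0.6))) {
    c_ev <- case[1]; f <- case[2]
    states <- cn_state_map(data.frame(chrom = "chr1", start = 0, end = 250e6,
                                      copies = c_ev), genome)
    cfg <- sim_config(n_bins = 4000, tumour_fraction = f,
                      gc_bias = c(0, 0.45), seed = 100 + c_ev)
    sm <- simulate_sample(genome, states, cfg, grid = grid)
    in_ev <- sm$grid$chrom == "chr1" & sm$grid$end <= 250e6
    n_ev <- sum(in_ev)
    expect_gte(n_ev, 1000)
    mix <- (2 * (1 - f) + c_ev * f) / 2
    # per-bin Poisson SE on the log2 scale, averaged over the event
    se_bin <- 1 / (sqrt(120 * mix) * log(2))
    emp <- mean(log2(sm$counts[in_ev] / 120))
    expect_lt(abs(emp - log2(mix)), 3 * se_bin / sqrt(n_ev) + 0.01)
  }
})
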