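# Serial comparisons: eligibility, ratio fitting, differential regions,
# clustering, plasma-tissue correlation.

test_that("profile Spearman respects rank invariance and sign", {
  set.seed(5)
  grid <- fix_grid(600)
  v <- rep(round(rnorm(20), 2), length.out = nrow(grid))
  a <- manual_segprofile(v, "a")
  expect_equal(profile_spearman(a, a), 1)
  mono <- manual_segprofile(exp(v), "b")      # monotone transform
  expect_equal(profile_spearman(a, mono), 1)
  negd <- manual_segprofile(-v, "c")
  expect_equal(profile_spearman(a, negd), -1)
  flat <- manual_segprofile(rep(0, nrow(grid)), "d")
  expect_error(profile_spearman(a, flat), "constant")
})

test_that("tumour-ratio grid fit matches the analytic slope", {
  set.seed(6)
  grid <- fix_grid(600)
  v <- rep(round(rnorm(30, sd = 0.3), 2), length.out = nrow(grid))
  a <- manual_segprofile(v, "a")
  expect_equal(as.numeric(fit_tumor_ratio(a, a)), 1)
  b <- manual_segprofile(2.5 * v, "b")
  r <- fit_tumor_ratio(a, b)
  expect_equal(as.numeric(r), 2.5)
  expect_equal(attr(r, "analytic_slope"), 2.5, tolerance = 1e-12)
  # grid point nearest the closed-form slope, including under noise
  for (s in 1:10) {
    set.seed(s)
    noise <- rnorm(nrow(grid), sd = 0.05)
    bn <- manual_segprofile(1.7 * v + noise, "bn")
    rn <- fit_tumor_ratio(a, bn)
    slope <- sum(v * (1.7 * v + noise)) / sum(v * v)
    expect_equal(as.numeric(rn), round(slope / 0.01) * 0.01,
                 tolerance = 1e-9)
  }
  zero <- manual_segprofile(rep(0, nrow(grid)), "z")
  expect_error(fit_tumor_ratio(zero, a), "unidentifiable")
  # role swap recovers the reciprocal within one grid step
  r_fwd <- fit_tumor_ratio(a, b)
  r_bwd <- fit_tumor_ratio(b, a)
  expect_equal(as.numeric(r_bwd), 1 / as.numeric(r_fwd), tolerance = 0.011)
})

test_that("injected ratios 0.5-4 are recovered within 0.05 under noise", {
  grid <- fix_grid(600)
  n <- nrow(grid)
  ok_all <- TRUE
  for (s in 1:25) {
    set.seed(1000 + s)
    truth <- round(stats::runif(1, 0.5, 4), 2)
    v <- rep(round(rnorm(40, sd = 0.3), 2), length.out = n)
    a <- manual_segprofile(v, "a")
    b <- manual_segprofile(truth * v + rnorm(n, sd = 0.05), "b")
    r <- as.numeric(fit_tumor_ratio(a, b))
    ok_all <- ok_all && abs(r - truth) <= 0.05
  }
  expect_true(ok_all)
})

test_that("differential regions flag exactly the constructed interval", {
  grid <- fix_grid(600)
  n <- nrow(grid)
  set.seed(7)
  v <- rep(round(rnorm(25, sd = 0.25), 2), length.out = n)
  a <- manual_segprofile(v, "a")
  b_same <- manual_segprofile(2 * v, "b")
  cmp <- differential_regions(a, b_same, config = serial_config())
  expect_equal(nrow(cmp$regions), 0)
  expect_equal(cmp$r, 2)
  expect_equal(cmp$pct_autosomal_diff, 0)

  # inject a new amplicon into b on chr2 bins 30..49 (d = +0.7)
  idx <- which(as.character(grid$chrom) == "chr2")[30:49]
  vb <- 2 * v; vb[idx] <- vb[idx] + 0.7
  b <- manual_segprofile(vb, "b2")
  cmp <- differential_regions(a, b, r = 2, config = serial_config())
  expect_equal(nrow(cmp$regions), 1)
  expect_equal(cmp$regions$direction, "gain")
  expect_equal(cmp$regions$start, grid$start[idx[1]])
  expect_equal(cmp$regions$end, grid$end[idx[length(idx)]])
  expect_gt(cmp$pct_autosomal_diff, 0)

  # boundary: |d| must strictly exceed 0.2, single-bin runs need min_run=1
  v0 <- rep(0, n); a0 <- manual_segprofile(v0, "a0")
  vb0 <- v0; vb0[idx[1]] <- 0.21; vb0[idx[5]] <- 0.19
  b0 <- manual_segprofile(vb0, "b0")
  cmp <- differential_regions(a0, b0, r = 1,
                              config = serial_config(min_run = 1))
  expect_equal(nrow(cmp$regions), 1)
  expect_equal(cmp$regions$start, grid$start[idx[1]])
  expect_equal(cmp$regions$n_bins, 1)
})

test_that("flagged fraction is invariant to common rescaling", {
  grid <- fix_grid(600)
  n <- nrow(grid)
  set.seed(8)
  v <- rep(round(rnorm(25, sd = 0.3), 2), length.out = n)
  w <- v; w[100:140] <- w[100:140] + 0.9
  a <- manual_segprofile(v, "a"); b <- manual_segprofile(w, "b")
  base <- differential_regions(a, b, config = serial_config())
  a2 <- manual_segprofile(1.6 * v, "a2")
  b2 <- manual_segprofile(1.6 * w, "b2")
  scaled <- differential_regions(a2, b2, config = serial_config())
  expect_equal(scaled$pct_autosomal_diff, base$pct_autosomal_diff)
})

test_that("Manhattan average-linkage clustering groups patients", {
  grid <- fix_grid(600)
  n <- nrow(grid)
  # duplicate profiles merge at height 0
  set.seed(9)
  v <- rep(round(rnorm(30, sd = 0.3), 2), length.out = n)
  dup <- cluster_profiles(list(manual_segprofile(v, "x1"),
                               manual_segprofile(v, "x2"),
                               manual_segprofile(v + 1, "y")))
  expect_equal(min(dup$height), 0)
  expect_error(cluster_profiles(list(manual_segprofile(v, "x1"))), ">= 2")

  # two simulated patients x two serial samples each: same-patient samples
  # form clades (noise independent within patient)
  clade_ok <- 0
  for (s in 1:10) {
    p1 <- data.frame(chrom = "chr1", start = 0, end = 60e6, copies = 5)
    p2 <- data.frame(chrom = "chr3", start = 20e6, end = 110e6, copies = 0)
    profs <- list(
      fix_segmented(p1, f = 0.4, seed = 2000 + s, sample_id = "P1_1"),
      fix_segmented(p1, f = 0.4, seed = 2100 + s, sample_id = "P1_2"),
      fix_segmented(p2, f = 0.4, seed = 2200 + s, sample_id = "P2_1"),
      fix_segmented(p2, f = 0.4, seed = 2300 + s, sample_id = "P2_2"))
    tree <- cluster_profiles(profs)
    merged_first <- stats::cutree(tree, k = 2)
    same1 <- merged_first["P1_1"] == merged_first["P1_2"]
    same2 <- merged_first["P2_1"] == merged_first["P2_2"]
    if (same1 && same2) clade_ok <- clade_ok + 1
  }
  expect_gte(clade_ok, 9)
})

test_that("plasma-tissue Pearson ignores sex chromosomes", {
  grid <- fix_grid(600)
  n <- nrow(grid)
  set.seed(10)
  v <- rep(round(rnorm(20, sd = 0.3), 2), length.out = n)
  a <- manual_segprofile(v, "a")
  expect_equal(tissue_plasma_pearson(a, a), 1)
  vx <- v; vx[as.character(grid$chrom) == "chrX"] <- 5
  b <- manual_segprofile(vx, "b")
  expect_equal(tissue_plasma_pearson(a, b), 1)
  # hand-computed correlation on constructed vectors
  auto <- is_autosome(as.character(grid$chrom))
  w <- v; w[auto] <- 0.5 * v[auto] + 0.1
  set.seed(11); w[auto] <- w[auto] + rnorm(sum(auto), sd = 0.1)
  c_prof <- manual_segprofile(w, "c")
  va <- v[auto]; wa <- w[auto]
  hand <- sum((va - mean(va)) * (wa - mean(wa))) /
    sqrt(sum((va - mean(va))^2) * sum((wa - mean(wa))^2))
  expect_equal(tissue_plasma_pearson(a, c_prof), hand, tolerance = 1e-12)
})
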