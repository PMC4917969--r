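# Focal amplification/deletion criteria, annotation, counting.

genes_fix <- gene_annotation(data.frame(
  chrom = c("chr1", "chr1", "chr2", "chr2"),
  start = c(10.2e6, 50e6, 30.1e6, 30.4e6),
  end = c(10.4e6, 50.5e6, 30.3e6, 30.6e6),
  name = c("DRV1", "GENE2", "DELG1", "GENE4"),
  is_driver = c(TRUE, FALSE, FALSE, FALSE),
  is_del_gene = c(FALSE, FALSE, TRUE, FALSE)))

test_that("flank-weighted means are length-weighted and truncated", {
  segs <- seg_table(list("chr1", 0, 10e6, 0.1), list("chr1", 10e6, 20e6, 0.3),
                    list("chr1", 20e6, 22e6, 0.9),
                    list("chr1", 22e6, 32e6, 0.3), list("chr1", 32e6, 42e6, 0.1))
  # 20 Mb windows on each side: 10 Mb at 0.1 + 10 Mb at 0.3 per side -> 0.2
  expect_equal(flank_weighted_mean(segs, 3), 0.2)
  # all-zero flanks give zero
  z <- seg_table(list("chr1", 0, 20e6, 0), list("chr1", 20e6, 22e6, 1),
                 list("chr1", 22e6, 42e6, 0))
  expect_equal(flank_weighted_mean(z, 2), 0)
  # target at chromosome start: right window only, brute-force per-bp check
  edge <- seg_table(list("chr1", 0, 2e6, 1.2), list("chr1", 2e6, 12e6, 0.4),
                    list("chr1", 12e6, 60e6, -0.1))
  got <- flank_weighted_mean(edge, 1)
  brute <- (10e6 * 0.4 + 10e6 * -0.1) / 20e6
  expect_equal(got, brute)
  expect_error(flank_weighted_mean(edge, 9), "not found")
})

test_that("log2 ratios convert to copies at the stated anchor points", {
  expect_equal(round(log2_to_copies(0.58, 2)), 3)
  expect_equal(log2_to_copies(0, 2), 2)
  expect_equal(log2_to_copies(1, 2), 4)
  expect_equal(log2_to_copies(3.7, 1), 13, tolerance = 0.01)
})

test_that("amplification criteria accept and reject as printed", {
  crit <- focal_criteria()
  base <- seg_table(list("chr1", 0, 9e6, 0), list("chr1", 9e6, 11e6, 0.9),
                    list("chr1", 11e6, 60e6, 0))
  # 2 Mb segment at 0.9 over driver gene, flanks 0: called
  res <- call_focal_amplifications(base, genes_fix, empty_track(),
                                   empty_track(), crit)
  expect_equal(nrow(res$events), 1)
  expect_true(res$events$has_driver)
  expect_equal(res$events$genes, "DRV1")
  expect_equal(res$events$delta, 0.9)

  # 25 Mb segment rejected on size
  big <- seg_table(list("chr1", 0, 25e6, 1.5), list("chr1", 25e6, 60e6, 0))
  res <- call_focal_amplifications(big, genes_fix, empty_track(),
                                   empty_track(), crit)
  expect_equal(nrow(res$events), 0)
  expect_equal(res$rejections$first_failed_rule, "size")

  # non-driver gene at 0.5: fails the 0.58 flank rule
  nd <- seg_table(list("chr1", 40e6, 49e6, 0), list("chr1", 49e6, 51e6, 0.5),
                  list("chr1", 51e6, 90e6, 0))
  res <- call_focal_amplifications(nd, genes_fix, empty_track(),
                                   empty_track(), crit)
  expect_equal(nrow(res$events), 0)
  expect_equal(res$rejections$first_failed_rule, "flank_delta")
  # the same segment at 0.6 is called (0.6 > 0.58)
  nd2 <- nd; nd2$mean_log2[2] <- 0.6
  res <- call_focal_amplifications(nd2, genes_fix, empty_track(),
                                   empty_track(), crit)
  expect_equal(nrow(res$events), 1)
  expect_false(res$events$has_driver)

  # 60% segmental-duplication coverage: rejected
  segdup <- data.frame(chrom = "chr1", start = 9e6, end = 10.2e6)
  res <- call_focal_amplifications(base, genes_fix, segdup,
                                   empty_track(), crit)
  expect_equal(res$rejections$first_failed_rule, "segdup")
  # 40% coverage passes
  segdup2 <- data.frame(chrom = "chr1", start = 9e6, end = 9.8e6)
  res <- call_focal_amplifications(base, genes_fix, segdup2,
                                   empty_track(), crit)
  expect_equal(nrow(res$events), 1)
  # a gene-free segment is rejected for lack of genes
  lone <- seg_table(list("chr2", 0, 2e6, 0.9), list("chr2", 2e6, 90e6, 0))
  res <- call_focal_amplifications(lone, genes_fix, empty_track(),
                                   empty_track(), crit)
  expect_equal(res$rejections$first_failed_rule, "no_gene")
  expect_error(call_focal_amplifications(base, genes_fix, NULL,
                                         empty_track(), crit),
               "annotation tracks")
})

test_that("deletion criteria require a known deletion gene", {
  crit <- focal_criteria()
  del <- seg_table(list("chr2", 0, 30e6, 0), list("chr2", 30e6, 31e6, -0.9),
                   list("chr2", 31e6, 90e6, 0))
  res <- call_focal_deletions(del, genes_fix, empty_track(), empty_track(),
                              crit)
  expect_equal(nrow(res$events), 1)
  expect_equal(res$events$class, "deletion")
  expect_match(res$events$genes, "DELG1")
  # without the flagged gene: rejected
  no_flag <- genes_fix; no_flag$is_del_gene <- FALSE
  res <- call_focal_deletions(del, no_flag, empty_track(), empty_track(),
                              crit)
  expect_equal(nrow(res$events), 0)
  expect_equal(res$rejections$first_failed_rule, "no_deletion_gene")
  # -0.15 never reaches candidacy
  weak <- del; weak$mean_log2[2] <- -0.15
  res <- call_focal_deletions(weak, genes_fix, empty_track(), empty_track(),
                              crit)
  expect_equal(nrow(res$events) + nrow(res$rejections), 0)
})

test_that("caller decisions match the brute-force rule checker", {
  # randomized segment tables, gene sets and tracks; acceptance re-runs
  # this at 1,000 configurations — a fast slice here guards refactors
  crit <- focal_criteria()
  set.seed(99)
  for (it in 1:60) {
    n_seg <- sample(3:8, 1)
    bounds <- sort(sample(seq(0, 120e6, 1e6), n_seg + 1))
    while (any(diff(bounds) == 0))
      bounds <- sort(sample(seq(0, 120e6, 1e6), n_seg + 1))
    segs <- do.call(rbind, lapply(seq_len(n_seg), function(i)
      data.frame(sample = "r", chrom = "chr1", start = bounds[i],
                 end = bounds[i + 1], n_bins = 10,
                 mean_log2 = round(stats::runif(1, -1.5, 1.5), 2))))
    n_gene <- sample(0:6, 1)
    gs <- if (n_gene) {
      gstart <- sample(seq(0, 119e6, 1e6), n_gene)
      gene_annotation(data.frame(
        chrom = "chr1", start = gstart, end = gstart + 5e5,
        name = paste0("G", seq_len(n_gene)),
        is_driver = sample(c(TRUE, FALSE), n_gene, TRUE),
        is_del_gene = sample(c(TRUE, FALSE), n_gene, TRUE)))
    } else gene_annotation(data.frame(chrom = character(), start = numeric(),
                                      end = numeric(), name = character()))
    mk_track <- function() {
      n <- sample(0:3, 1)
      if (!n) return(empty_track())
      st <- sample(seq(0, 110e6, 1e6), n)
      data.frame(chrom = "chr1", start = st,
                 end = st + sample(c(5e5, 2e6, 8e6), n, TRUE))
    }
    sd_tr <- mk_track(); dgv_tr <- mk_track()
    for (cls in c("amplification", "deletion")) {
      got <- if (cls == "amplification")
        call_focal_amplifications(segs, gs, sd_tr, dgv_tr, crit)
      else call_focal_deletions(segs, gs, sd_tr, dgv_tr, crit)
      want <- brute_focal_check(segs, gs, sd_tr, dgv_tr, crit, cls)
      called <- rep(FALSE, nrow(segs))
      if (nrow(got$events)) {
        for (r in seq_len(nrow(got$events)))
          called[segs$start == got$events$start[r] &
                 segs$end == got$events$end[r]] <- TRUE
      }
      expect_equal(called, want,
                   info = paste("iteration", it, cls))
    }
  }
})

test_that("adding a driver gene never revokes a call (nested thresholds)", {
  crit <- focal_criteria()
  set.seed(17)
  for (it in 1:20) {
    amp <- round(stats::runif(1, 0.3, 1.5), 2)
    segs <- seg_table(list("chr1", 0, 9e6, 0), list("chr1", 9e6, 11e6, amp),
                      list("chr1", 11e6, 60e6, 0))
    g0 <- gene_annotation(data.frame(chrom = "chr1", start = 9.5e6,
                                     end = 9.7e6, name = "G1",
                                     is_driver = FALSE, is_del_gene = FALSE))
    g1 <- g0; g1$is_driver <- TRUE
    before <- nrow(call_focal_amplifications(segs, g0, empty_track(),
                                             empty_track(), crit)$events)
    after <- nrow(call_focal_amplifications(segs, g1, empty_track(),
                                            empty_track(), crit)$events)
    expect_gte(after, before)
  }
})

test_that("every rejected candidate carries exactly one first failure", {
  crit <- focal_criteria()
  segs <- seg_table(list("chr1", 0, 25e6, 0.9), list("chr1", 25e6, 26e6, 0.5),
                    list("chr1", 26e6, 60e6, 0.1))
  res <- call_focal_amplifications(segs, genes_fix, empty_track(),
                                   empty_track(), crit)
  above <- sum(segs$mean_log2 > crit$amp_threshold)
  expect_equal(nrow(res$events) + nrow(res$rejections), above)
  expect_true(all(nchar(res$rejections$first_failed_rule) > 0))
})

test_that("external segment tables produce identical focal calls", {
  sp <- fix_segmented(data.frame(chrom = "chr1", start = 30e6, end = 32e6,
                                 copies = 20),
                      f = 0.4, seed = 88)
  genes <- gene_annotation(data.frame(chrom = "chr1", start = 30.5e6,
                                      end = 31e6, name = "DRV",
                                      is_driver = TRUE,
                                      is_del_gene = FALSE))
  direct <- call_focal_amplifications(sp, genes, empty_track(),
                                      empty_track())
  roundtrip <- segmented_from_table(sp$segments, sp$grid)
  external <- call_focal_amplifications(roundtrip, genes, empty_track(),
                                        empty_track())
  expect_equal(direct$events, external$events)
})

test_that("per-sample focal counts reproduce the cohort means", {
  # 594 events over 95 samples -> 6.25; 343 over 43 patients -> 7.98
  ev <- data.frame(sample = rep(paste0("s", 1:95), length.out = 594),
                   class = "amplification")
  res <- count_focal_per_sample(ev, paste0("s", 1:95))
  expect_equal(round(res$mean_per_sample, 2), 6.25)
  ev2 <- data.frame(sample = rep(paste0("p", 1:43), length.out = 343),
                    class = "amplification")
  pm <- data.frame(sample = paste0("p", 1:43), patient = paste0("P", 1:43))
  res2 <- count_focal_per_sample(ev2, paste0("p", 1:43), pm,
                                 one_per_patient = TRUE)
  expect_equal(round(res2$mean_per_sample, 2), 7.98)
  none <- count_focal_per_sample(ev[0, ], paste0("s", 1:5))
  expect_equal(none$mean_per_sample, 0)
  expect_error(count_focal_per_sample(ev2, "unknown", pm,
                                      one_per_patient = TRUE), "missing")
})
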