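#!/usr/bin/env Rscript
# Simulate a small synthetic plasma cohort with known copy-number truth:
# 10 non-tumour controls plus 8 tumour samples (mixed arm-level and focal
# events at tumour fractions 0.1-0.6), written as bin-count TSVs.
#
# Output: results/cohort/counts/*.tsv, truth/*.bed, cohort manifest.

suppressPackageStartupMessages(library(plasmacnv))

out_dir <- "results/cohort"
dir.create(file.path(out_dir, "counts"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out_dir, "truth"), recursive = TRUE, showWarnings = FALSE)

seed <- 20160624L
n_bins <- 50000
genome <- male_genome()
cfg <- sim_config(n_bins = n_bins, seed = seed)
grid <- build_bin_grid(genome, n_bins)

message("simulating 10 non-tumour controls...")
controls <- simulate_controls(10, genome, cfg, grid = grid)
for (i in seq_along(controls))
  write_bin_counts(controls[[i]],
                   file.path(out_dir, "counts", sprintf("control_%02d.tsv", i)))

# tumour scenarios: arm-level gains/losses plus focal driver amplicons
scenarios <- list(
  P1 = list(f = 0.35, ev = data.frame(
    chrom = c("chr8", "chr8", "chrX"), start = c(0, 127e6, 66e6),
    end = c(40e6, 129.5e6, 68e6), copies = c(1, 9, 13))),
  P2 = list(f = 0.2, ev = data.frame(
    chrom = c("chr10", "chr13"), start = c(88e6, 0),
    end = c(90.5e6, 115e6), copies = c(0, 1))),
  P3 = list(f = 0.5, ev = data.frame(
    chrom = c("chr7", "chr11", "chrX"), start = c(0, 69e6, 66e6),
    end = c(159e6, 70.5e6, 68.2e6), copies = c(3, 10, 8))),
  P4 = list(f = 0.1, ev = data.frame(
    chrom = c("chrX", "chr21"), start = c(66e6, 39.8e6),
    end = c(68e6, 42.9e6), copies = c(13, 1))),
  P5 = list(f = 0.6, ev = data.frame(
    chrom = c("chr5", "chr8"), start = c(0, 127.5e6),
    end = c(46e6, 129e6), copies = c(3, 12))),
  P6 = list(f = 0.3, ev = data.frame(
    chrom = c("chr17", "chr10"), start = c(0, 89.5e6),
    end = c(22e6, 90.7e6), copies = c(1, 0))),
  P7 = list(f = 0.25, ev = data.frame(
    chrom = c("chrX", "chr12"), start = c(66.2e6, 57.5e6),
    end = c(68.1e6, 59e6), copies = c(11, 9))),
  P8 = list(f = 0.0, ev = data.frame(  # tumour-free "responder" sample
    chrom = character(), start = numeric(), end = numeric(),
    copies = numeric()))
)

message("simulating ", length(scenarios), " tumour samples...")
for (nm in names(scenarios)) {
  sc <- scenarios[[nm]]
  cfg_s <- cfg
  cfg_s$tumour_fraction <- sc$f
  cfg_s$seed <- seed + match(nm, names(scenarios)) * 101L
  sm <- simulate_sample(genome, cn_state_map(sc$ev, genome), cfg_s,
                        grid = grid)
  write_bin_counts(sm, file.path(out_dir, "counts", paste0(nm, ".tsv")))
  write_truth_bed(sm, file.path(out_dir, "truth", paste0(nm, ".bed")))
}

manifest <- data.frame(sample = names(scenarios),
                       tumour_fraction = vapply(scenarios, `[[`, 0, "f"),
                       n_events = vapply(scenarios,
                                         function(s) nrow(s$ev), 0L))
write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("cohort written under ", out_dir,
        " (", length(scenarios), " tumour + 10 control samples, ",
        nrow(grid), " bins each)")
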