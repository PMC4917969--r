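#!/usr/bin/env Rscript
# Cohort statistics: per-bin gain/loss frequency tracks over the simulated
# cohort, group comparisons of focal counts (Mann-Whitney), and the
# printed AR contingency table (Fisher exact).
#
# Input:  results/cohort  (from 01-03)
# Output: results/cohort/stats/{frequency_track.tsv,tests.txt}

suppressPackageStartupMessages(library(plasmacnv))

in_dir <- "results/cohort"
if (!file.exists(file.path(in_dir, "calls", "summary.tsv")))
  stop("run analysis/03_call_events.R first")
dir.create(file.path(in_dir, "stats"), showWarnings = FALSE)

genome <- male_genome()
grid <- build_bin_grid(genome, 50000)

seg_files <- list.files(file.path(in_dir, "seg"), "[.]seg$",
                        full.names = TRUE)
profs <- lapply(seg_files, function(fp)
  call_states(segmented_from_table(read_seg(fp), grid)))
tr <- frequency_tracks(profs)
write.table(data.frame(chrom = tr$chrom, start = tr$start, end = tr$end,
                       freq_gain = round(tr$freq_gain, 3),
                       freq_loss = round(tr$freq_loss, 3)),
            file.path(in_dir, "stats", "frequency_track.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

summ <- read.delim(file.path(in_dir, "calls", "summary.tsv"))
manifest <- read.delim(file.path(in_dir, "manifest.tsv"))
summ$f <- manifest$tumour_fraction[match(summ$sample, manifest$sample)]

sink(file.path(in_dir, "stats", "tests.txt"))
cat("== Simulated cohort ==\n")
n_focal <- summ$n_focal_amp + summ$n_focal_del
cat(sprintf("mean focal events per sample: %.2f\n", mean(n_focal)))

# focal counts, low vs high tumour fraction (analogue of stage grouping)
hi <- n_focal[summ$f >= 0.3]; lo <- n_focal[summ$f < 0.3]
mw <- mann_whitney_u(lo, hi)
cat(sprintf("focal counts low-f (n=%d, mean %.2f) vs high-f (n=%d, mean %.2f): U=%.1f, p=%.3g (%s)\n",
            length(lo), mean(lo), length(hi), mean(hi), mw$statistic,
            mw$p_value, mw$method))

cat("\n== Printed AR contingency table (TCGA 0/493 vs plasma 27/43) ==\n")
fe <- fisher_exact_2x2(matrix(c(0, 27, 493, 16), 2))
cat(sprintf("Fisher exact two-sided p = %.3g (reported as p <= 2.2e-16)\n",
            fe$p_value))
cat(sprintf("plasma AR focal-amp frequency: %.1f%%\n", 100 * 27 / 43))
sink()

message(readLines(file.path(in_dir, "stats", "tests.txt")))
message("cohort statistics written under ", file.path(in_dir, "stats"))
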