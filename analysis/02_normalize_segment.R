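#!/usr/bin/env Rscript
# Normalize the simulated cohort (GC local regression + control panel) and
# segment every tumour sample by circular binary segmentation.
#
# Input:  results/cohort/counts/*.tsv (from 01_simulate_cohort.R)
# Output: results/cohort/log2/*.tsv, results/cohort/seg/*.seg

suppressPackageStartupMessages(library(plasmacnv))

in_dir <- "results/cohort"
if (!dir.exists(file.path(in_dir, "counts")))
  stop("run analysis/01_simulate_cohort.R first")
dir.create(file.path(in_dir, "log2"), showWarnings = FALSE)
dir.create(file.path(in_dir, "seg"), showWarnings = FALSE)

genome <- male_genome()
ctrl_files <- list.files(file.path(in_dir, "counts"), "^control_",
                         full.names = TRUE)
message("building control panel from ", length(ctrl_files), " controls...")
controls <- lapply(ctrl_files, function(fp) {
  cc <- read_bin_counts(fp, genome)
  gc_correct(binned_profile(cc$grid, cc$counts,
                            sample_id = sub("[.]tsv$", "", basename(fp))))
})
panel <- control_panel(controls)

samples <- setdiff(list.files(file.path(in_dir, "counts"), "[.]tsv$"),
                   basename(ctrl_files))
seed <- 20160624L
for (fn in samples) {
  id <- sub("[.]tsv$", "", fn)
  cc <- read_bin_counts(file.path(in_dir, "counts", fn), genome)
  prof <- normalize_profile(binned_profile(cc$grid, cc$counts,
                                           sample_id = id), panel)
  write_log2_profile(prof, file.path(in_dir, "log2", paste0(id, ".tsv")))
  sp <- suppressWarnings(segment_profile(prof, seed = seed))
  write_seg(sp, file.path(in_dir, "seg", paste0(id, ".seg")))
  message(sprintf("%s: %d segments, median |log2| %.3f", id,
                  nrow(sp$segments),
                  median(abs(prof$log2), na.rm = TRUE)))
}
message("log2 profiles and SEG tables written under ", in_dir)
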