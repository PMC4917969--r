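#!/usr/bin/env Rscript
# Gain/loss labelling, altered-genome fractions, the 3-SD aberrance
# classifier, and focal amplification/deletion calling on the segmented
# cohort, with an AR-centred driver annotation.
#
# Input:  results/cohort/{counts,seg}  (from 01 and 02)
# Output: results/cohort/calls/{summary.tsv,focal_events.tsv,rejections.tsv}

suppressPackageStartupMessages(library(plasmacnv))

in_dir <- "results/cohort"
if (!dir.exists(file.path(in_dir, "seg")))
  stop("run analysis/02_normalize_segment.R first")
dir.create(file.path(in_dir, "calls"), showWarnings = FALSE)

genome <- male_genome()
grid <- build_bin_grid(genome, 50000)
seed <- 20160624L

# control aberrance statistics from the identical pipeline
ctrl_files <- list.files(file.path(in_dir, "counts"), "^control_",
                         full.names = TRUE)
controls <- lapply(ctrl_files, function(fp) {
  cc <- read_bin_counts(fp, genome)
  gc_correct(binned_profile(cc$grid, cc$counts))
})
panel <- control_panel(controls)
ctrl_fr <- lapply(seq_along(controls), function(i) {
  prof <- to_log2(controls[[i]], panel)
  sp <- suppressWarnings(segment_profile(prof, seed = seed + i))
  altered_fractions(call_states(sp))
})
ab_stats <- aberrance_stats(ctrl_fr)

# annotation: AR (driver) plus the key-gene subset shipped with the package
bed <- read.table(system.file("extdata", "genes_hg19_synthetic.bed",
                              package = "plasmacnv"),
                  col.names = c("chrom", "start", "end", "name"))
lists <- default_gene_lists()
genes <- gene_annotation(transform(
  bed, is_driver = name %in% lists$amplification,
  is_del_gene = name %in% lists$deletion))
anno <- annotation_bundle(genes)

seg_files <- list.files(file.path(in_dir, "seg"), "[.]seg$",
                        full.names = TRUE)
summaries <- list(); events <- list(); rejections <- list()
for (fp in seg_files) {
  id <- sub("[.]seg$", "", basename(fp))
  sp <- segmented_from_table(read_seg(fp), grid)
  sp <- call_states(sp)
  fr <- altered_fractions(sp)
  ab <- classify_aberrant(fr, ab_stats)
  amps <- call_focal_amplifications(sp, anno$genes, anno$segdup, anno$dgv)
  dels <- call_focal_deletions(sp, anno$genes, anno$segdup, anno$dgv)
  summaries[[id]] <- data.frame(
    sample = id, pct_gain = round(fr$pct_gain, 2),
    pct_loss = round(fr$pct_loss, 2), mb_gain = round(fr$mb_gain, 1),
    mb_loss = round(fr$mb_loss, 1), aberrant = ab$aberrant,
    n_focal_amp = nrow(amps$events), n_focal_del = nrow(dels$events))
  events[[id]] <- rbind(amps$events, dels$events)
  rejections[[id]] <- rbind(amps$rejections, dels$rejections)
  message(sprintf(
    "%s: %.1f%% gained, %.1f%% lost, aberrant=%s, %d focal amp, %d focal del",
    id, fr$pct_gain, fr$pct_loss, ab$aberrant, nrow(amps$events),
    nrow(dels$events)))
}

write.table(do.call(rbind, summaries),
            file.path(in_dir, "calls", "summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
ev <- do.call(rbind, events)
write.table(ev, file.path(in_dir, "calls", "focal_events.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
rej <- do.call(rbind, rejections)
if (!is.null(rej) && nrow(rej))
  write.table(rej, file.path(in_dir, "calls", "rejections.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
message("calls written under ", file.path(in_dir, "calls"))
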