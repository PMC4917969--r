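# End-to-end orchestration over the module functions.

#' Annotation bundle for a simulated run
#'
#' Convenience constructor: gene table plus (optionally empty) segmental
#' duplication and germline-CNV tracks.
#'
#' @param genes a [gene_annotation()] table.
#' @param segdup,dgv interval tracks (default [empty_track()]).
#' @export
annotation_bundle <- function(genes, segdup = empty_track(),
                              dgv = empty_track()) {
  list(genes = gene_annotation(genes), segdup = segdup, dgv = dgv)
}

#' AR-centred annotation for simulated male genomes
#'
#' A minimal annotation with the AR gene (hg19 gene body,
#' chrX:66,764,465-66,950,461) flagged as an amplification driver; suitable
#' for dilution and serial simulations on the default male genome.
#'
#' @param extra_genes optional additional gene rows.
#' @export
ar_annotation <- function(extra_genes = NULL) {
  genes <- data.frame(chrom = "chrX", start = 66764465, end = 66950461,
                      name = "AR", is_driver = TRUE, is_del_gene = FALSE)
  if (!is.null(extra_genes)) {
    extra_genes$is_driver <- extra_genes$is_driver %||% FALSE
    genes <- rbind(genes, extra_genes[, names(genes)])
  }
  annotation_bundle(genes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the single-sample pipeline
#'
#' simulate/ingest -> GC correction -> control normalization -> CBS
#' segmentation -> gain/loss labelling -> altered fractions (+ aberrance if
#' control stats given) -> focal calling.
#'
#' @param sample a `simulated_sample` or `binned_profile`.
#' @param panel a `control_panel`.
#' @param annotation an [annotation_bundle()].
#' @param aberrance optional `aberrance_stats` from controls.
#' @param sample_id label for the sample.
#' @param alpha,n_perm,min_width,merge_tol,seed segmentation parameters.
#' @param criteria [focal_criteria()].
#' @param out_dir optional directory; when given, log2/SEG/event TSVs and a
#'   JSON manifest are written.
#' @return List with `profile`, `segmented`, `fractions`, `aberrant`,
#'   `amplifications`, `deletions`.
#' @export
run_sample_pipeline <- function(sample, panel, annotation,
                                aberrance = NULL, sample_id = "sample",
                                alpha = 0.01, n_perm = 1000, min_width = 3,
                                merge_tol = 0.05, seed = 1L,
                                criteria = focal_criteria(),
                                out_dir = NULL) {
  prof <- if (inherits(sample, "binned_profile")) sample
          else as_binned_profile(sample, sample_id = sample_id)
  prof$sample_id <- sample_id
  prof <- normalize_profile(prof, panel)
  sp <- segment_profile(prof, alpha = alpha, n_perm = n_perm,
                        min_width = min_width, merge_tol = merge_tol,
                        seed = seed)
  sp <- call_states(sp)
  fr <- altered_fractions(sp)
  ab <- if (!is.null(aberrance)) classify_aberrant(fr, aberrance) else NULL
  amps <- call_focal_amplifications(sp, annotation$genes, annotation$segdup,
                                    annotation$dgv, criteria)
  dels <- call_focal_deletions(sp, annotation$genes, annotation$segdup,
                               annotation$dgv, criteria)
  res <- list(profile = prof, segmented = sp, fractions = fr, aberrant = ab,
              amplifications = amps$events, deletions = dels$events,
              rejections = rbind(amps$rejections, dels$rejections))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_log2_profile(prof, file.path(out_dir, paste0(sample_id, "_log2.tsv")))
    write_seg(sp, file.path(out_dir, paste0(sample_id, ".seg")))
    utils::write.table(rbind(res$amplifications, res$deletions),
                       file.path(out_dir, paste0(sample_id, "_focal.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(sample_id = sample_id, alpha = alpha, n_perm = n_perm,
                     min_width = min_width, merge_tol = merge_tol,
                     seed = seed, criteria = unclass(criteria),
                     n_controls = panel$n_controls,
                     pct_gain = fr$pct_gain, pct_loss = fr$pct_loss)
    jsonlite::write_json(manifest,
                         file.path(out_dir, paste0(sample_id, "_manifest.json")),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' Run the serial-comparison pipeline over consecutive sample pairs
#'
#' Pairs failing the Spearman eligibility gate are recorded as skipped
#' ("low correlation") rather than compared.
#'
#' @param segmented list of `segmented_profile`s in time order.
#' @param config a [serial_config()].
#' @return List with `comparisons` (one per consecutive pair: either a
#'   `serial_comparison` or a skip record) and `tree` (hclust over the
#'   profiles, NULL if < 2).
#' @export
run_serial_pipeline <- function(segmented, config = serial_config()) {
  if (length(segmented) < 2) stop("need >= 2 samples")
  comparisons <- list()
  for (i in seq_len(length(segmented) - 1)) {
    a <- segmented[[i]]; b <- segmented[[i + 1]]
    rho <- profile_spearman(a, b)
    if (rho > config$min_rho) {
      comparisons[[i]] <- differential_regions(a, b, config = config)
    } else {
      comparisons[[i]] <- list(sample_a = a$sample_id, sample_b = b$sample_id,
                               rho = rho, skipped = "low correlation")
    }
  }
  tree <- cluster_profiles(segmented)
  list(comparisons = comparisons, tree = tree)
}

#' Simulated dilution-limit experiment for a focal AR amplification
#'
#' Emulates the VCaP dilution control experiment: a male genome with an
#' AR-region amplicon whose pure-tumour log2 ratio is 3.7 (13 copies on the
#' single-copy X baseline, ~2 Mb), simulated on ~50,000 bins at ~0.1x
#' Poisson coverage, diluted to the given tumour fractions with `n_reps`
#' replicates per level; every replicate runs normalization, segmentation
#' and the focal-amplification caller (AR flagged as a driver). A level is
#' detectable when the amplicon is called in at least `detect_frac` of its
#' replicates.
#'
#' @param seed base seed.
#' @param fractions dilution levels (default 20/10/5/1%).
#' @param n_reps replicates per level (default 25).
#' @param n_bins bins (default 50000).
#' @param coverage mean reads per diploid bin (default 120).
#' @param n_controls control-panel size (default 10).
#' @param ar_copies amplicon copy number (default 13: log2(13/1) = 3.70).
#' @param detect_frac detection majority threshold (default 0.5).
#' @param n_perm segmentation permutations (default 1000).
#' @return List with `detection` (level x replicate logical matrix),
#'   `detect_rate` per level, and `lowest_detectable` (% tumour DNA, NA if
#'   none).
#' @export
run_dilution_experiment <- function(seed = 1L,
                                    fractions = c(0.20, 0.10, 0.05, 0.01),
                                    n_reps = 25, n_bins = 50000,
                                    coverage = 120, n_controls = 10,
                                    ar_copies = 13, detect_frac = 0.5,
                                    n_perm = 1000) {
  genome <- male_genome()
  cfg <- sim_config(n_bins = n_bins, total_coverage = coverage,
                    seed = as.integer(seed))
  grid <- build_bin_grid(genome, n_bins)
  # AR-region amplicon, ~2 Mb around the gene body
  ar <- c(66e6, 68e6)
  states <- cn_state_map(data.frame(chrom = "chrX", start = ar[1],
                                    end = ar[2], copies = ar_copies), genome)
  anno <- ar_annotation()

  ctrl <- simulate_controls(n_controls, genome, cfg, grid = grid)
  panel <- control_panel(lapply(ctrl, function(s)
    gc_correct(as_binned_profile(s))))

  detection <- matrix(FALSE, nrow = length(fractions), ncol = n_reps,
                      dimnames = list(paste0(100 * fractions, "%"), NULL))
  for (li in seq_along(fractions)) {
    for (rep_i in seq_len(n_reps)) {
      cfg_r <- cfg
      cfg_r$tumour_fraction <- fractions[li]
      cfg_r$seed <- as.integer(seed + 100003L * li + 211L * rep_i)
      sm <- simulate_sample(genome, states, cfg_r, grid = grid)
      res <- run_sample_pipeline(sm, panel, anno,
                                 sample_id = sprintf("dil_%d_%d", li, rep_i),
                                 n_perm = n_perm,
                                 seed = cfg_r$seed)
      ev <- res$amplifications
      detection[li, rep_i] <- nrow(ev) > 0 &&
        any(ev$chrom == "chrX" & ev$start < ar[2] & ev$end > ar[1] &
            ev$has_driver)
    }
  }
  rate <- rowMeans(detection)
  detectable <- fractions[rate >= detect_frac]
  list(detection = detection, detect_rate = rate,
       lowest_detectable = if (length(detectable))
         100 * min(detectable) else NA_real_)
}
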