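# Rule-based focal amplification / deletion calling with gene annotation.

#' Focal-event calling criteria
#'
#' The seven amplification rules: segment < 20 Mb; mean log2 > 0.2; contains
#' at least one gene but not more than 100; mean exceeds the length-weighted
#' mean of the neighbouring 20 Mb on both sides by more than 0.2 if the
#' segment contains a known amplification driver gene, else by more than
#' 0.58 (a log2 ratio of 0.58 corresponds to about three copies at diploid
#' baseline); segmental duplications must not cover more than 50% of the
#' segment; germline copy-number variants (DGV entries) must not cover it
#' beyond the configured fraction. Deletions mirror the list with mean
#' < -0.2, a mandatory known deletion gene, and a fixed 0.2 flank margin.
#'
#' @param max_size maximum segment span in bp (default 20e6, strict `<`).
#' @param amp_threshold base amplification log2 threshold (default 0.2).
#' @param del_threshold base deletion log2 threshold (default -0.2).
#' @param flank_window flank window on each side in bp (default 20e6).
#' @param driver_delta flank margin when a driver gene is contained (0.2).
#' @param nondriver_delta flank margin otherwise (0.58).
#' @param max_genes maximum genes per segment (default 100).
#' @param segdup_max_frac maximum segmental-duplication coverage (0.5).
#' @param dgv_max_frac maximum germline-CNV coverage before disqualification
#'   (0.5; the literal no-overlap rule would annihilate all calls given
#'   genome-wide DGV coverage, so a coverage cap mirroring the segmental
#'   duplication rule is used).
#' @return List of class `focal_criteria`.
#' @export
focal_criteria <- function(max_size = 20e6, amp_threshold = 0.2,
                           del_threshold = -0.2, flank_window = 20e6,
                           driver_delta = 0.2, nondriver_delta = 0.58,
                           max_genes = 100, segdup_max_frac = 0.5,
                           dgv_max_frac = 0.5) {
  stopifnot(max_size > 0, amp_threshold > 0, del_threshold < 0,
            flank_window > 0, nondriver_delta > driver_delta,
            driver_delta > 0, max_genes >= 1)
  structure(list(max_size = max_size, amp_threshold = amp_threshold,
                 del_threshold = del_threshold, flank_window = flank_window,
                 driver_delta = driver_delta,
                 nondriver_delta = nondriver_delta, max_genes = max_genes,
                 segdup_max_frac = segdup_max_frac,
                 dgv_max_frac = dgv_max_frac),
            class = "focal_criteria")
}

#' Length-weighted flank mean of a segment
#'
#' Mean log2 ratio of the segments overlapping the `window` bp immediately
#' left and right of the target segment on its chromosome, weighted by each
#' neighbour's overlap length with the window. Windows are truncated at
#' chromosome ends; if one side is empty the other side alone is used; if
#' both are empty, 0 is returned.
#'
#' @param segments segment data.frame (`chrom start end mean_log2`).
#' @param target_idx row index of the target segment.
#' @param window flank window size in bp (default 20e6).
#' @return Length-weighted mean log2 of the flanks.
#' @export
flank_weighted_mean <- function(segments, target_idx, window = 20e6) {
  if (target_idx < 1 || target_idx > nrow(segments)) stop("target not found")
  t <- segments[target_idx, ]
  same <- which(segments$chrom == t$chrom)
  same <- setdiff(same, target_idx)
  wl <- c(max(0, t$start - window), t$start)   # left window
  wr <- c(t$end, t$end + window)               # right window
  tot_w <- 0; tot_sum <- 0
  for (k in same) {
    for (win in list(wl, wr)) {
      ov <- min(segments$end[k], win[2]) - max(segments$start[k], win[1])
      if (ov > 0) {
        tot_w <- tot_w + ov
        tot_sum <- tot_sum + ov * segments$mean_log2[k]
      }
    }
  }
  if (tot_w == 0) 0 else tot_sum / tot_w
}

#' Convert a log2 ratio to absolute copies
#'
#' `baseline * 2^log2`; at diploid baseline a log2 ratio of 0.58 translates
#' to about three copies.
#'
#' @param log2_ratio log2 ratio.
#' @param baseline baseline copy number (1 or 2).
#' @export
log2_to_copies <- function(log2_ratio, baseline = 2) {
  stopifnot(all(baseline %in% c(1, 2)))
  baseline * 2^log2_ratio
}

#' Gene annotation table
#'
#' @param genes data.frame with columns `chrom`, `start`, `end`, `name` and
#'   logical flags `is_driver` (amplification driver list) and `is_del_gene`
#'   (known deletion genes). Missing flags default to FALSE.
#' @return data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(genes) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(genes)))
  if (is.null(genes$is_driver)) genes$is_driver <- rep(FALSE, nrow(genes))
  if (is.null(genes$is_del_gene)) genes$is_del_gene <- rep(FALSE, nrow(genes))
  class(genes) <- c("gene_annotation", "data.frame")
  genes
}

#' Empty interval track
#'
#' Explicit empty segdup/germline-CNV track (annotation tracks must be
#' passed deliberately; `NULL` is an error in the focal callers).
#' @export
empty_track <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric())
}

to_gr <- function(df, levels = NULL) {
  if (is.null(levels)) levels <- unique(as.character(df$chrom))
  GenomicRanges::GRanges(factor(as.character(df$chrom), levels = levels),
                         IRanges::IRanges(df$start + 1, df$end))
}

# fraction of each query interval covered by (the union of) a track
track_coverage_frac <- function(query_df, track_df) {
  if (nrow(track_df) == 0) return(rep(0, nrow(query_df)))
  lv <- unique(c(as.character(query_df$chrom), as.character(track_df$chrom)))
  q <- to_gr(query_df, lv)
  tr <- GenomicRanges::reduce(to_gr(track_df, lv))
  hits <- GenomicRanges::findOverlaps(q, tr)
  ov <- GenomicRanges::pintersect(q[S4Vectors::queryHits(hits)],
                                  tr[S4Vectors::subjectHits(hits)])
  cov <- rep(0, nrow(query_df))
  if (length(hits)) {
    agg <- tapply(BiocGenerics::width(ov), S4Vectors::queryHits(hits), sum)
    cov[as.integer(names(agg))] <- as.numeric(agg)
  }
  cov / (query_df$end - query_df$start)
}

# gene indices overlapping each query interval (>= 1 bp)
genes_in_segments <- function(query_df, genes) {
  if (nrow(genes) == 0)
    return(rep(list(integer(0)), nrow(query_df)))
  lv <- unique(c(as.character(query_df$chrom), as.character(genes$chrom)))
  hits <- GenomicRanges::findOverlaps(to_gr(query_df, lv), to_gr(genes, lv))
  out <- rep(list(integer(0)), nrow(query_df))
  if (length(hits)) {
    sp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    out[as.integer(names(sp))] <- sp
  }
  out
}

focal_call_engine <- function(segments, genes, segdup, dgv, criteria,
                              class = c("amplification", "deletion")) {
  class <- match.arg(class)
  stopifnot(inherits(criteria, "focal_criteria"))
  if (is.null(genes) || is.null(segdup) || is.null(dgv))
    stop("annotation tracks are required (pass empty_track() explicitly)")
  genes <- gene_annotation(as.data.frame(genes))
  amp <- class == "amplification"
  base_thr <- if (amp) criteria$amp_threshold else criteria$del_threshold
  cand <- which(if (amp) segments$mean_log2 > base_thr
                else segments$mean_log2 < base_thr)
  events <- list(); rejections <- list()
  if (length(cand)) {
    glist <- genes_in_segments(segments[cand, , drop = FALSE], genes)
    segdup_frac <- track_coverage_frac(segments[cand, , drop = FALSE], segdup)
    dgv_frac <- track_coverage_frac(segments[cand, , drop = FALSE], dgv)
  }
  for (q in seq_along(cand)) {
    k <- cand[q]
    s <- segments[k, ]
    gidx <- glist[[q]]
    n_genes <- length(gidx)
    has_driver <- any(genes$is_driver[gidx])
    has_del_gene <- any(genes$is_del_gene[gidx])
    flank <- flank_weighted_mean(segments, k, criteria$flank_window)
    delta <- s$mean_log2 - flank
    # ordered rules; first failure recorded for the audit trail
    fail <- NULL
    if (s$end - s$start >= criteria$max_size) {
      fail <- "size"
    } else if (!amp && !has_del_gene) {
      fail <- "no_deletion_gene"
    } else if (n_genes < 1) {
      fail <- "no_gene"
    } else if (n_genes > criteria$max_genes) {
      fail <- "too_many_genes"
    } else if (amp && !(delta > (if (has_driver) criteria$driver_delta
                                 else criteria$nondriver_delta))) {
      fail <- if (has_driver) "flank_delta_driver" else "flank_delta"
    } else if (!amp && !(-delta > criteria$driver_delta)) {
      fail <- "flank_delta"
    } else if (segdup_frac[q] > criteria$segdup_max_frac) {
      fail <- "segdup"
    } else if (dgv_frac[q] >= criteria$dgv_max_frac) {
      fail <- "germline_cnv"
    }
    if (is.null(fail)) {
      events[[length(events) + 1]] <- data.frame(
        sample = s$sample, chrom = s$chrom, start = s$start, end = s$end,
        class = class, mean_log2 = s$mean_log2, flank_mean = flank,
        delta = delta,
        genes = paste(genes$name[gidx], collapse = ","),
        n_genes = n_genes, has_driver = has_driver,
        stringsAsFactors = FALSE)
    } else {
      rejections[[length(rejections) + 1]] <- data.frame(
        sample = s$sample, chrom = s$chrom, start = s$start, end = s$end,
        class = class, mean_log2 = s$mean_log2, first_failed_rule = fail,
        stringsAsFactors = FALSE)
    }
  }
  empty_ev <- data.frame(sample = character(), chrom = character(),
                         start = numeric(), end = numeric(),
                         class = character(), mean_log2 = numeric(),
                         flank_mean = numeric(), delta = numeric(),
                         genes = character(), n_genes = integer(),
                         has_driver = logical())
  list(events = if (length(events)) do.call(rbind, events) else empty_ev,
       rejections = if (length(rejections)) do.call(rbind, rejections)
                    else data.frame())
}

#' Call focal amplifications
#'
#' Applies the amplification criteria (see [focal_criteria()]) to a
#' segmented profile; every candidate above the base threshold that is
#' rejected carries the first failed rule for audit.
#'
#' @param sp a `segmented_profile` or a segment data.frame.
#' @param genes a [gene_annotation()] table.
#' @param segdup segmental-duplication track (`chrom start end`); pass
#'   [empty_track()] for none.
#' @param dgv germline-CNV track; pass [empty_track()] for none.
#' @param criteria a [focal_criteria()] object.
#' @return List with `events` and `rejections` data.frames.
#' @export
call_focal_amplifications <- function(sp, genes, segdup, dgv,
                                      criteria = focal_criteria()) {
  segments <- if (inherits(sp, "segmented_profile")) sp$segments else sp
  focal_call_engine(segments, genes, segdup, dgv, criteria, "amplification")
}

#' Call focal deletions
#'
#' Deletion criteria: span < 20 Mb, mean log2 < -0.2, contains a known
#' deletion gene, not more than 100 genes, mean more than 0.2 below the
#' flank-weighted mean, segmental-duplication and germline-CNV coverage
#' rules as for amplifications.
#'
#' @inheritParams call_focal_amplifications
#' @export
call_focal_deletions <- function(sp, genes, segdup, dgv,
                                 criteria = focal_criteria()) {
  segments <- if (inherits(sp, "segmented_profile")) sp$segments else sp
  focal_call_engine(segments, genes, segdup, dgv, criteria, "deletion")
}

#' Per-sample focal-event counts
#'
#' @param events focal-event data.frame (with a `sample` column), the
#'   concatenation over the cohort.
#' @param sample_ids all sample ids in the cohort (samples with zero events
#'   included in the mean).
#' @param patient_map optional data.frame `sample, patient`; required when
#'   `one_per_patient` is TRUE.
#' @param one_per_patient count a single designated sample per patient (the
#'   first in `sample_ids` order) to avoid double-counting serial samples.
#' @return List with `per_sample` (data.frame `sample n_amplification
#'   n_deletion n_total`) and `mean_per_sample`.
#' @export
count_focal_per_sample <- function(events, sample_ids, patient_map = NULL,
                                   one_per_patient = FALSE) {
  if (one_per_patient) {
    if (is.null(patient_map)) stop("patient_map required")
    miss <- setdiff(sample_ids, patient_map$sample)
    if (length(miss)) stop("patient map missing samples: ",
                           paste(miss, collapse = ", "))
    pm <- patient_map[match(sample_ids, patient_map$sample), ]
    keep <- sample_ids[!duplicated(pm$patient)]
    sample_ids <- keep
    events <- events[events$sample %in% keep, , drop = FALSE]
  }
  n_amp <- vapply(sample_ids, function(s)
    sum(events$sample == s & events$class == "amplification"), 0L)
  n_del <- vapply(sample_ids, function(s)
    sum(events$sample == s & events$class == "deletion"), 0L)
  per_sample <- data.frame(sample = sample_ids, n_amplification = n_amp,
                           n_deletion = n_del, n_total = n_amp + n_del,
                           row.names = NULL)
  list(per_sample = per_sample,
       mean_per_sample = if (length(sample_ids)) mean(per_sample$n_total)
                         else 0)
}

#' Packaged default gene lists
#'
#' Gene-name lists shipped with the package: 30 genes used to map focal
#' amplifications (including AR), and the 42 genes known to be affected by
#' focal deletions. Coordinates in the companion BED
#' (`genes_hg19_synthetic.bed`) cover a key-gene subset with approximate
#' hg19 gene-body positions and are labelled synthetic; for simulated
#' genomes, build annotation in code instead.
#'
#' @return List with character vectors `amplification` and `deletion`.
#' @export
default_gene_lists <- function() {
  amp <- readLines(system.file("extdata", "amplification_genes.txt",
                               package = "plasmacnv"))
  del <- readLines(system.file("extdata", "deletion_genes.txt",
                               package = "plasmacnv"))
  list(amplification = amp[nzchar(amp) & !startsWith(amp, "#")],
       deletion = del[nzchar(del) & !startsWith(del, "#")])
}
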