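#' Genome model for copy-number simulation and binning
#'
#' A genome model lists chromosomes with their lengths and baseline copy
#' number (2 for autosomes; 1 for X and Y in a male sample) together with
#' masked intervals that are excluded from the mappable genome (e.g. the
#' Y pseudo-autosomal regions).
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp) and
#'   `base_cn` (baseline copy number, 1 or 2).
#' @param masked_intervals optional data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open) of regions excluded from mappable length.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, masked_intervals = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length", "base_cn") %in% names(chromosomes)))
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be > 0")
  if (!all(chromosomes$base_cn %in% c(1L, 2L)))
    stop("baseline copy number must be 1 or 2")
  if (anyDuplicated(chromosomes$name)) stop("duplicate chromosome names")
  if (is.null(masked_intervals)) {
    masked_intervals <- data.frame(chrom = character(), start = numeric(),
                                   end = numeric())
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(masked_intervals)))
  if (nrow(masked_intervals)) {
    m <- match(masked_intervals$chrom, chromosomes$name)
    if (anyNA(m)) stop("masked interval on unknown chromosome")
    bad <- masked_intervals$start < 0 |
      masked_intervals$end > chromosomes$length[m] |
      masked_intervals$start >= masked_intervals$end
    if (any(bad)) stop("masked intervals must lie within their chromosome")
  }
  structure(list(chromosomes = chromosomes, masked = masked_intervals),
            class = "genome_model")
}

#' Default male genome (hg19 chromosome lengths)
#'
#' 22 autosomes plus X and Y with hg19 lengths; X and Y carry baseline copy
#' number 1 (all simulated subjects are male). The Y pseudo-autosomal
#' regions are masked, mirroring the reference-masking convention used for
#' male plasma samples.
#'
#' @param include_y keep chrY in the model (it is excluded from calling
#'   downstream regardless); default TRUE.
#' @return A `genome_model`.
#' @export
male_genome <- function(include_y = TRUE) {
  len <- c(249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
           159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
           115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
           59128983, 63025520, 48129895, 51304566, 155270560, 59373566)
  nm <- c(paste0("chr", 1:22), "chrX", "chrY")
  cn <- c(rep(2L, 22), 1L, 1L)
  masked <- data.frame(chrom = c("chrY", "chrY"),
                       start = c(0, 59034049),
                       end = c(2649520, 59363566))
  if (!include_y) {
    keep <- nm != "chrY"
    nm <- nm[keep]; len <- len[keep]; cn <- cn[keep]
    masked <- masked[masked$chrom != "chrY", , drop = FALSE]
  }
  genome_model(data.frame(name = nm, length = len, base_cn = cn), masked)
}

#' Small genome for fast tests and property checks
#'
#' A scaled-down male-like genome (a few autosomes plus X) preserving the
#' autosome/X baseline structure, so pipeline properties can be exercised at
#' a fraction of the 50,000-bin cost.
#'
#' @param n_autosomes number of autosomes (default 4).
#' @param autosome_length length of each autosome in bp.
#' @param x_length length of chrX in bp.
#' @return A `genome_model`.
#' @export
toy_genome <- function(n_autosomes = 4, autosome_length = 120e6,
                       x_length = 155e6) {
  nm <- c(paste0("chr", seq_len(n_autosomes)), "chrX")
  genome_model(data.frame(name = nm,
                          length = c(rep(autosome_length, n_autosomes), x_length),
                          base_cn = c(rep(2L, n_autosomes), 1L)))
}

#' Copy-number state map
#'
#' Absolute tumour copy-number events over a genome; outside the listed
#' events the tumour carries the chromosome's baseline copy number.
#' Coordinates are 0-based half-open; events must not overlap.
#'
#' @param events data.frame with columns `chrom`, `start`, `end`, `copies`
#'   (absolute tumour copy number, >= 0). May have zero rows.
#' @param genome a `genome_model` used to validate bounds.
#' @return An object of class `cn_state_map`.
#' @export
cn_state_map <- function(events = NULL, genome) {
  stopifnot(inherits(genome, "genome_model"))
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), copies = numeric())
  }
  stopifnot(all(c("chrom", "start", "end", "copies") %in% names(events)))
  if (any(events$copies < 0)) stop("tumour copy number must be >= 0")
  m <- match(events$chrom, genome$chromosomes$name)
  if (anyNA(m)) stop("event on unknown chromosome")
  if (any(events$start < 0 | events$end > genome$chromosomes$length[m] |
          events$start >= events$end))
    stop("event outside chromosome bounds")
  ev <- events[order(m, events$start), , drop = FALSE]
  if (nrow(ev) > 1) {
    same <- ev$chrom[-1] == ev$chrom[-nrow(ev)]
    if (any(same & ev$start[-1] < ev$end[-nrow(ev)]))
      stop("events must not overlap")
  }
  rownames(ev) <- NULL
  structure(list(events = ev, genome = genome), class = "cn_state_map")
}
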