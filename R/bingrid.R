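# Bin grids: equal-mappability partition of the genome.

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# mappable sub-intervals (0-based half-open) of one chromosome
mappable_intervals <- function(genome, chrom) {
  len <- genome$chromosomes$length[genome$chromosomes$name == chrom]
  m <- genome$masked[genome$masked$chrom == chrom, , drop = FALSE]
  if (!nrow(m)) return(data.frame(start = 0, end = len))
  m <- m[order(m$start), , drop = FALSE]
  starts <- c(0, m$end)
  ends <- c(m$start, len)
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}

#' Build an equal-mappability bin grid
#'
#' Partitions the mappable genome into approximately `n_bins` bins such that
#' every bin contains the same number of mappable positions (masked intervals
#' contribute no mappable length, so bins spanning a mask are wider in bp).
#' Bin boundaries never cross chromosomes; the last bin of each chromosome
#' absorbs (or, if large enough, forms) the remainder, so only those bins may
#' deviate from the common mappable length.
#'
#' A per-bin GC fraction is attached: either supplied, or generated once as a
#' smooth, spatially correlated field (mean ~0.41, sd ~0.05, clipped to
#' [0.30, 0.62]) from `gc_seed`, so that the same genome always yields the
#' same grid.
#'
#' @param genome a `genome_model`.
#' @param n_bins target number of bins (default 50000).
#' @param gc optional numeric vector of per-bin GC fractions (recycled
#'   checked against the realised bin count).
#' @param gc_seed seed for the generated GC field (default 715).
#' @return A data.frame of class `bin_grid` with columns `chrom`, `start`,
#'   `end`, `gc`, `mappable_bp`.
#' @export
build_bin_grid <- function(genome, n_bins = 50000, gc = NULL, gc_seed = 715L) {
  stopifnot(inherits(genome, "genome_model"))
  n_chrom <- nrow(genome$chromosomes)
  if (n_bins < n_chrom) stop("n_bins must be >= number of chromosomes")
  maps <- lapply(genome$chromosomes$name, function(ch)
    mappable_intervals(genome, ch))
  total_mappable <- sum(vapply(maps, function(m) sum(m$end - m$start), 0))
  target <- total_mappable / n_bins
  if (target < 1) stop("n_bins exceeds mappable positions")

  out <- vector("list", n_chrom)
  for (ci in seq_len(n_chrom)) {
    m <- maps[[ci]]
    L <- sum(m$end - m$start)
    n_full <- floor(L / target)
    rem <- L - n_full * target
    # remainder >= half a bin becomes its own bin, else extends the last
    n_c <- if (n_full == 0) 1 else if (rem >= 0.5 * target) n_full + 1 else n_full
    cuts <- pmin(seq_len(n_c) * target, L)
    cuts[n_c] <- L
    # map mappable-space offsets to genomic coordinates
    cum <- cumsum(m$end - m$start)
    idx <- findInterval(cuts, cum, left.open = TRUE) + 1
    idx <- pmin(idx, nrow(m))
    prev <- c(0, cum)[idx]
    gpos <- m$start[idx] + (cuts - prev)
    gstart <- c(m$start[1], gpos[-n_c])
    out[[ci]] <- data.frame(chrom = genome$chromosomes$name[ci],
                            start = round(gstart), end = round(gpos),
                            mappable_bp = round(diff(c(0, cuts))))
  }
  grid <- do.call(rbind, out)
  n <- nrow(grid)
  if (is.null(gc)) {
    win <- min(31, if (n %% 2 == 0) n - 1 else n)
    gc <- with_seed(gc_seed, {
      z <- stats::rnorm(n)
      w <- if (win >= 3) stats::filter(z, rep(1, win) / win, circular = TRUE)
           else z
      as.numeric(0.41 + 0.05 * (w / stats::sd(w)))
    })
    gc <- pmin(pmax(gc, 0.30), 0.62)
  } else {
    if (length(gc) != n) stop("gc length does not match realised bin count")
    if (any(gc < 0 | gc > 1)) stop("gc fractions must be in [0,1]")
  }
  grid$gc <- gc
  grid <- grid[, c("chrom", "start", "end", "gc", "mappable_bp")]
  rownames(grid) <- NULL
  class(grid) <- c("bin_grid", "data.frame")
  attr(grid, "genome") <- genome
  grid
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$chrom, b$chrom)) &&
    isTRUE(all.equal(a$start, b$start)) &&
    isTRUE(all.equal(a$end, b$end))
}

# baseline copy number per bin (from the genome model)
grid_base_cn <- function(grid) {
  genome <- attr(grid, "genome")
  genome$chromosomes$base_cn[match(grid$chrom, genome$chromosomes$name)]
}

#' Is a chromosome an autosome?
#'
#' @param chrom character vector of chromosome names.
#' @return Logical vector; FALSE for X and Y (with or without "chr" prefix).
#' @export
is_autosome <- function(chrom) !(chrom %in% c("chrX", "chrY", "X", "Y"))

#' Write / read a bin-count table
#'
#' TSV with columns `chrom start end gc mappable_bp count` (0-based,
#' half-open), the on-disk exchange format for binned read counts.
#'
#' @param sample a `simulated_sample` or `binned_profile` carrying a grid and
#'   raw counts.
#' @param path output path.
#' @export
write_bin_counts <- function(sample, path) {
  df <- cbind(as.data.frame(sample$grid)[, c("chrom", "start", "end", "gc",
                                             "mappable_bp")],
              count = sample$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bin_counts
#' @param genome the `genome_model` the grid belongs to.
#' @return `read_bin_counts` returns a list with elements `grid` (a
#'   `bin_grid`) and `counts`.
#' @export
read_bin_counts <- function(path, genome) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  grid <- df[, c("chrom", "start", "end", "gc", "mappable_bp")]
  class(grid) <- c("bin_grid", "data.frame")
  attr(grid, "genome") <- genome
  list(grid = grid, counts = df$count)
}
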