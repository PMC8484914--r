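#' Partition a genome into fixed-width read-depth bins
#'
#' Tiles each chromosome with non-overlapping windows of `bin_size` bp
#' (default 10 kb, the standard window for low-pass CNV-seq). Coordinates
#' are 0-based half-open; the last bin of a chromosome may be shorter than
#' `bin_size`. Each bin carries a GC fraction, either taken from a supplied
#' per-bin table or drawn as a seeded smooth random field in [0.3, 0.6].
#'
#' @param chrom_table data.frame with columns `chrom` (unique names) and
#'   `length` (bp, positive).
#' @param bin_size window width in bp, > 0.
#' @param gc optional numeric vector of per-bin GC fractions (length must
#'   equal the total number of bins, values in \[0, 1\]). When `NULL`, a
#'   smooth random GC field is generated with `seed`.
#' @param seed integer seed for the generated GC field.
#' @return A `bin_grid`: data.frame with columns `chrom`, `start`, `end`,
#'   `gc`, plus attributes `bin_size` and `chrom_table`.
#' @examples
#' grid <- make_bin_grid(data.frame(chrom = "chr1", length = 105000), 10000)
#' nrow(grid)  # 11 bins, last one short
#' @export
make_bin_grid <- function(chrom_table, bin_size = 10000, gc = NULL, seed = 1L) {
  stopifnot(is.data.frame(chrom_table), all(c("chrom", "length") %in% names(chrom_table)))
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0)
    stop("bin_size must be a positive number")
  if (anyDuplicated(chrom_table$chrom))
    stop("duplicate chromosome names in chrom_table")
  if (any(chrom_table$length <= 0))
    stop("chromosome lengths must be positive")

  pieces <- lapply(seq_len(nrow(chrom_table)), function(i) {
    len <- chrom_table$length[i]
    n <- ceiling(len / bin_size)
    start <- (seq_len(n) - 1L) * bin_size
    data.frame(chrom = chrom_table$chrom[i], start = start,
               end = pmin(start + bin_size, len))
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL

  if (is.null(gc)) {
    gc <- smooth_gc_field(nrow(grid), seed = seed)
  } else {
    if (length(gc) != nrow(grid)) stop("gc vector length must equal number of bins")
    if (any(gc < 0 | gc > 1)) stop("gc fractions must lie in [0, 1]")
  }
  grid$gc <- gc

  structure(grid,
            bin_size = bin_size,
            chrom_table = chrom_table,
            class = c("bin_grid", "data.frame"))
}

# Smooth GC track in [0.3, 0.6]: moving-average of white noise, rescaled.
smooth_gc_field <- function(n, seed = 1L, window = 21L) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  x <- stats::rnorm(n + window)
  x <- stats::filter(x, rep(1 / window, window), sides = 1)
  x <- as.numeric(x[(window + 1):(n + window)])
  r <- range(x)
  if (diff(r) == 0) return(rep(0.45, n))
  0.3 + 0.3 * (x - r[1]) / diff(r)
}

#' Toy five-chromosome genome for desk-scale analyses
#'
#' Three autosomes plus X and Y, ~10 Mb in total, which at the default
#' 10 kb window gives 1,000 bins — large enough for segmentation and
#' aneuploidy statistics, small enough for fast simulation.
#'
#' @return data.frame with columns `chrom` and `length`.
#' @export
toy_genome <- function() {
  data.frame(chrom = c("chr1", "chr2", "chr3", "chrX", "chrY"),
             length = c(3e6, 2.5e6, 2e6, 1.5e6, 1e6))
}

#' hg19 chromosome sizes
#'
#' Lengths of the 24 hg19 reference chromosomes (chr1-chr22, chrX, chrY),
#' for building genome-scale bin grids.
#'
#' @return data.frame with columns `chrom` and `length`.
#' @export
hg19_chromosomes <- function() {
  data.frame(
    chrom = c(paste0("chr", 1:22), "chrX", "chrY"),
    length = c(249250621L, 243199373L, 198022430L, 191154276L, 180915260L,
               171115067L, 159138663L, 146364022L, 141213431L, 135534747L,
               135006516L, 133851895L, 115169878L, 107349540L, 102531392L,
               90354753L, 81195210L, 78077248L, 59128983L, 63025520L,
               48129895L, 51304566L, 155270560L, 59373566L))
}

is_autosome <- function(chrom) !(chrom %in% c("chrX", "chrY", "X", "Y"))

# Seed handling: save/restore .Random.seed so helpers are reproducible
# without clobbering the caller's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
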