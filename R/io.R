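#' Write binned read counts to TSV
#'
#' Columns `chrom start end gc count`, 0-based half-open coordinates.
#'
#' @param counts a `bin_counts`.
#' @param path output file.
#' @export
write_bin_counts <- function(counts, path) {
  stopifnot(inherits(counts, "bin_counts"))
  utils::write.table(counts[, c("chrom", "start", "end", "gc", "count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load binned read counts from TSV
#'
#' Validates the table: required columns, sorted non-overlapping bins
#' within each chromosome, nonnegative finite counts. Errors name the
#' offending row.
#'
#' @param path TSV with header `chrom start end gc count`.
#' @param sample_id label stored on the result (default: file name).
#' @return a `bin_counts`.
#' @export
load_bin_counts <- function(path, sample_id = basename(path)) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gc", "count")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  bad <- which(!is.finite(x$count) | x$count < 0)
  if (length(bad))
    stop("negative or non-finite count at row ", bad[1])
  bad <- which(x$end <= x$start)
  if (length(bad))
    stop("empty or inverted bin at row ", bad[1])
  for (ch in unique(x$chrom)) {
    i <- which(x$chrom == ch)
    if (is.unsorted(x$start[i], strictly = TRUE))
      stop("bins not sorted within ", ch, " (row ", i[1], ")")
    if (length(i) > 1L && any(x$start[i][-1] < x$end[i][-length(i)]))
      stop("overlapping bins within ", ch)
  }
  chrom_table <- data.frame(chrom = unique(x$chrom),
                            length = tapply(x$end, x$chrom, max)[unique(x$chrom)])
  rownames(chrom_table) <- NULL
  bin_size <- max(x$end - x$start)
  grid <- x[, c("chrom", "start", "end", "gc")]
  out <- grid
  out$count <- x$count
  structure(out, bin_size = bin_size, chrom_table = chrom_table,
            sample_id = sample_id,
            class = c("bin_counts", "bin_grid", "data.frame"))
}

#' Export a depth profile to TSV
#'
#' Columns `chrom start end R Z usable`.
#'
#' @param profile a `depth_profile`.
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "depth_profile"))
  out <- profile[, c("chrom", "start", "end", "R", "Z", "usable")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export called segments to BED-like TSV
#'
#' Columns `chrom start end mean_R n_bins Z_seg`.
#'
#' @param segments segment data.frame from [cbs_segment()].
#' @param path output file.
#' @export
write_segments <- function(segments, path) {
  out <- segments[, c("chrom", "start_bp", "end_bp", "mean_R", "n_bins", "Z_seg")]
  names(out)[2:3] <- c("start", "end")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a karyotype report to JSON
#'
#' @param report a `karyotype_report` (see [cnv_call()]).
#' @param path output file.
#' @export
write_report <- function(report, path) {
  payload <- list(sample_id = report$sample_id,
                  sex_call = report$sex_call,
                  iscn = report$iscn,
                  result_class = report$result_class,
                  events = report$events)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
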