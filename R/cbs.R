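#' Best circular-arc split of a numeric track
#'
#' The CBS inner maximization: over all circular arcs, find the one whose
#' mean differs most from the complement mean by the pooled-variance
#' two-sample t-like statistic. The arc is reported 0-based half-open, so
#' `(i, j)` covers `values[(i+1):j]` in R's 1-based indexing; ties are
#' broken by smallest `i`, then smallest `j`. A zero-variance split with
#' differing means scores an effectively infinite statistic.
#'
#' @param values numeric vector, length at least 4.
#' @param min_seg minimum number of points in the arc and in its
#'   complement.
#' @return list with `i`, `j` (0-based half-open arc bounds) and
#'   `statistic`.
#' @examples
#' max_arc_statistic(c(0, 0, 0, 1, 1, 1, 0, 0, 0))  # arc (3, 6)
#' @export
max_arc_statistic <- function(values, min_seg = 1L) {
  if (length(values) < 4L) stop("need at least 4 values")
  if (anyNA(values)) stop("values must be finite")
  .cbs_max_arc(as.numeric(values), as.integer(min_seg))
}

#' Circular binary segmentation with permutation significance
#'
#' Recursively splits each chromosome's usable-bin R track: the best arc
#' split (see [max_arc_statistic()]) is accepted when its permutation
#' p-value — the statistic recomputed on `n_perm` seeded shuffles of bin
#' order — falls below `alpha`; both sides are then segmented further.
#' Adjacent segments whose means differ by less than `merge_tol` are
#' merged. Chromosomes with fewer than `2 * min_width` usable bins return
#' a single segment. Segments partition the usable bins of each
#' chromosome and are sorted by position.
#'
#' Defaults (`alpha` 0.01, `n_perm` 1000, `min_width` 5 bins = 50 kb at
#' the 10 kb window, `merge_tol` 0.1 R units) follow common CBS practice;
#' the 0.1 Mb reporting resolution is enforced downstream by the event
#' caller, not here.
#'
#' @param profile a `depth_profile` (R and usable filled).
#' @param alpha permutation significance level in (0, 1).
#' @param n_perm permutations per split test (>= 100); early-stopped once
#'   the p-value provably exceeds `alpha`.
#' @param min_width minimum segment width in bins (>= 2).
#' @param merge_tol merge adjacent segments closer than this in mean R.
#' @param seed integer seed for the permutation streams.
#' @return data.frame of class `cnv_segments` with columns `chrom`,
#'   `start_bin`, `end_bin` (0-based half-open bin indices within the
#'   chromosome), `start_bp`, `end_bp`, `mean_R`, `n_bins` (usable bins),
#'   `Z_seg`.
#' @export
cbs_segment <- function(profile, alpha = 0.01, n_perm = 1000L,
                        min_width = 5L, merge_tol = 0.1, seed = 1L) {
  stopifnot(inherits(profile, "depth_profile"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (min_width < 2L) stop("min_width must be at least 2 bins")

  counter <- new.env(parent = emptyenv())
  counter$k <- 0L
  next_seed <- function() {
    counter$k <- counter$k + 1L
    as.integer((as.numeric(seed) * 7919 + counter$k * 104729) %% 2147483647)
  }

  split_rec <- function(x) {
    # returns boundaries (0-based, within x) of accepted changepoints
    n <- length(x)
    if (n < 2L * min_width) return(integer())
    res <- .cbs_perm_p(x, as.integer(min_width), as.integer(n_perm),
                       alpha, next_seed())
    if (res$p >= alpha) return(integer())
    cuts <- setdiff(c(res$i, res$j), c(0L, n))
    if (!length(cuts)) return(integer())
    bounds <- sort(unique(c(0L, cuts, n)))
    out <- cuts
    for (b in seq_len(length(bounds) - 1L)) {
      lo <- bounds[b]; hi <- bounds[b + 1L]
      out <- c(out, lo + split_rec(x[(lo + 1L):hi]))
    }
    sort(unique(out))
  }

  chroms <- unique(profile$chrom)
  pieces <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    chrom_idx <- which(profile$chrom == ch)
    use <- chrom_idx[profile$usable[chrom_idx]]
    if (!length(use)) next
    x <- profile$R[use]
    cuts <- split_rec(x)
    bounds <- c(0L, cuts, length(x))
    segs <- lapply(seq_len(length(bounds) - 1L), function(b) {
      members <- use[(bounds[b] + 1L):bounds[b + 1L]]
      seg_row(profile, ch, chrom_idx, members)
    })
    segs <- merge_segments(segs, merge_tol, profile, ch, chrom_idx)
    pieces[[ci]] <- do.call(rbind, segs)
  }
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(chrom = character(), start_bin = integer(),
                      end_bin = integer(), start_bp = numeric(),
                      end_bp = numeric(), mean_R = numeric(),
                      n_bins = integer(), Z_seg = numeric())
  rownames(out) <- NULL
  class(out) <- c("cnv_segments", "data.frame")
  out
}

seg_row <- function(profile, ch, chrom_idx, members) {
  rz <- region_Z(profile, members)
  data.frame(chrom = ch,
             start_bin = match(members[1], chrom_idx) - 1L,
             end_bin = match(members[length(members)], chrom_idx),
             start_bp = profile$start[members[1]],
             end_bp = profile$end[members[length(members)]],
             mean_R = mean(profile$R[members]),
             n_bins = length(members),
             Z_seg = rz$Z)
}

# Iteratively merge the closest adjacent pair with |mean diff| < tol.
merge_segments <- function(segs, tol, profile, ch, chrom_idx) {
  repeat {
    if (length(segs) < 2L) return(segs)
    means <- vapply(segs, function(s) s$mean_R, numeric(1))
    diffs <- abs(diff(means))
    k <- which.min(diffs)
    if (diffs[k] >= tol) return(segs)
    a <- segs[[k]]; b <- segs[[k + 1L]]
    lo_bin <- a$start_bin; hi_bin <- b$end_bin
    members <- chrom_idx[(lo_bin + 1L):hi_bin]
    members <- members[profile$usable[members]]
    segs[[k]] <- seg_row(profile, ch, chrom_idx, members)
    segs[[k + 1L]] <- NULL
  }
}

#' @export
print.cnv_segments <- function(x, ...) {
  cat(sprintf("%d segments over %d chromosomes\n",
              nrow(x), length(unique(x$chrom))))
  print.data.frame(x, ...)
  invisible(x)
}
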