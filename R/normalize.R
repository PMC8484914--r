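#' GC-stratified depth correction
#'
#' Multiplicative median correction of smooth GC bias. Depths are first
#' normalized by their chromosome median (so whole-chromosome copy-number
#' changes sit at unit scale and cannot distort the fit), then a GC shape
#' curve is built from median knots per GC decile, linearly interpolated
#' at each bin's GC and linearly extrapolated (clamped) beyond the
#' outermost knots. Knots are fitted twice: once against the global
#' level and once against the first-pass curve, which undoes the
#' asymmetric truncation a strong GC slope causes; bins farther than 30%
#' from the reference level (residual copy-number outliers, e.g. large
#' segmental events) are excluded from the fit. Each count is divided by
#' the shape at its GC; the sample's global median depth is preserved.
#'
#' @param counts a `bin_counts`.
#' @param min_bins minimum stratum occupancy for a knot (default 20).
#' @return `bin_counts` whose `count` column holds real-valued corrected
#'   depths; attribute `gc_corrected` is set.
#' @export
gc_correct <- function(counts, min_bins = 20L) {
  stopifnot(inherits(counts, "bin_counts"))
  x <- counts$count
  if (all(x == 0)) stop("all-zero sample: cannot GC-correct")
  gc <- counts$gc

  # chromosome-median normalization: CN events are chromosome-scale or
  # large, so this removes most dosage signal before the GC fit
  ch_med <- tapply(x, counts$chrom, stats::median)
  z <- x / as.numeric(ch_med[counts$chrom])
  z[!is.finite(z)] <- NA

  breaks <- unique(stats::quantile(gc, probs = 0:10 / 10, names = FALSE))
  stratum <- findInterval(gc, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  sf <- factor(stratum, levels = sort(unique(stratum)))
  gc_mid <- tapply(gc, sf, mean)

  fit_shape <- function(inlier) {
    med <- tapply(ifelse(inlier, z, NA), sf, stats::median, na.rm = TRUE)
    n_in <- tapply(inlier, sf, sum)
    ok <- !is.na(med) & n_in >= min_bins & med > 0
    if (!any(ok)) stop("no GC stratum has enough bins with coverage")
    if (sum(ok) == 1L) return(rep(med[ok], length(gc)))
    gk <- gc_mid[ok]; mk <- med[ok]; nk <- length(gk)
    y <- stats::approx(gk, mk, xout = gc, rule = 2)$y
    lo <- gc < gk[1]
    y[lo] <- mk[1] + (mk[2] - mk[1]) / (gk[2] - gk[1]) * (gc[lo] - gk[1])
    hi <- gc > gk[nk]
    y[hi] <- mk[nk] + (mk[nk] - mk[nk - 1]) / (gk[nk] - gk[nk - 1]) *
      (gc[hi] - gk[nk])
    # clamp tail extrapolation against knot noise
    y <- pmin(pmax(y, 0.5 * min(mk)), 2 * max(mk))
    y
  }

  ok_bin <- is.finite(z)
  inlier <- ok_bin & z > 0.7 & z < 1.3
  shape <- fit_shape(inlier)
  resid <- z / shape
  inlier <- ok_bin & resid > 0.7 & resid < 1.3
  shape <- fit_shape(inlier)

  corrected <- x / shape
  corrected <- corrected * stats::median(x[x > 0]) /
    stats::median(corrected[corrected > 0])
  out <- counts
  out$count <- corrected
  attr(out, "gc_corrected") <- TRUE
  out
}

# Usable-bin mask from the GC-corrected panel: a bin is unusable when the
# panel median is 0, GC is outside [0.2, 0.8], or the panel coefficient of
# variation exceeds 0.5 (surrogate for the platform's opaque bin filter).
panel_mask <- function(panel_mat, gc, gc_range = c(0.2, 0.8), max_cv = 0.5) {
  m <- apply(panel_mat, 1L, stats::median)
  s <- apply(panel_mat, 1L, stats::sd)
  cv <- ifelse(m > 0, s / m, Inf)
  m > 0 & gc >= gc_range[1] & gc <= gc_range[2] & cv <= max_cv
}

#' Compute the per-bin copy-ratio deviation R against a reference panel
#'
#' The sample and every panel member (all GC-corrected internally unless
#' already corrected) are rescaled to a common total over usable bins;
#' `R_i = s_i / m_i - 1` where `m_i` is the panel median of bin i, so R is
#' 0 for euploid bins, +0.5 for a full trisomy and -0.5 for a full
#' monosomy. Panel members' own R profiles are computed leave-one-out
#' against the remaining panel and stored for Z standardization.
#'
#' Unusable bins (panel median 0, GC outside \[0.2, 0.8\], panel CV > 0.5)
#' are masked; masked bins carry `NA` R and are excluded from all
#' downstream statistics.
#'
#' @param sample a `bin_counts` for the test sample.
#' @param panel list of `bin_counts` on the same grid.
#' @return a `depth_profile`: data.frame `chrom start end gc R Z usable`
#'   (Z filled by [compute_Z()]), with the leave-one-out panel R matrix and
#'   corrected sample depths as attributes.
#' @export
compute_R <- function(sample, panel) {
  stopifnot(inherits(sample, "bin_counts"), is.list(panel), length(panel) >= 2)
  n <- nrow(sample)
  for (p in panel)
    if (nrow(p) != n || any(p$chrom != sample$chrom) || any(p$start != sample$start))
      stop("sample and panel must share one bin grid")

  corr1 <- function(x) if (isTRUE(attr(x, "gc_corrected"))) x else gc_correct(x)
  s_corr <- corr1(sample)
  p_corr <- lapply(panel, corr1)
  pm <- vapply(p_corr, function(p) p$count, numeric(n))

  usable <- panel_mask(pm, sample$gc)
  target <- 1e6
  scale_to <- function(x) x * (target / sum(x[usable]))
  s <- scale_to(s_corr$count)
  pm <- apply(pm, 2L, scale_to)

  m <- apply(pm, 1L, stats::median)
  usable <- usable & m > 0
  # Rescale so the median per-chromosome median ratio is 1: robust both to
  # large events (which inflate the sample total) and to a whole aneuploid
  # chromosome (which would drag a plain bin-median baseline).
  rescale <- function(ratio) {
    ch_med <- tapply(ratio[usable], sample$chrom[usable], stats::median)
    ratio / stats::median(ch_med, na.rm = TRUE)
  }
  R <- rescale(ifelse(usable, s / m, NA_real_)) - 1

  np <- ncol(pm)
  panel_R <- matrix(NA_real_, n, np)
  for (j in seq_len(np)) {
    mj <- apply(pm[, -j, drop = FALSE], 1L, stats::median)
    ok <- usable & mj > 0
    panel_R[, j] <- rescale(ifelse(ok, pm[, j] / mj, NA_real_)) - 1
  }

  out <- sample[, c("chrom", "start", "end", "gc")]
  out$R <- R
  out$Z <- NA_real_
  out$usable <- usable
  structure(out,
            bin_size = attr(sample, "bin_size"),
            chrom_table = attr(sample, "chrom_table"),
            sample_id = attr(sample, "sample_id"),
            corrected = s_corr$count,
            panel_R = panel_R,
            class = c("depth_profile", "data.frame"))
}

#' Fill panel-standardized Z values on a depth profile
#'
#' For any bin set S, `Z(S) = (R_sample(S) - mean_panel R(S)) / sd_panel
#' R(S)` with the n-1 sd denominator, where panel R profiles were computed
#' leave-one-out. This fills the per-bin Z column; region- or
#' chromosome-level Z is computed on demand by [region_Z()]. Bins whose
#' panel sd is 0 are masked.
#'
#' @param profile a `depth_profile` from [compute_R()].
#' @return the profile with `Z` filled.
#' @export
compute_Z <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  pr <- attr(profile, "panel_R")
  mu <- rowMeans(pr)
  sdv <- apply(pr, 1L, stats::sd)
  usable <- profile$usable & is.finite(sdv) & sdv > 0
  profile$Z <- ifelse(usable, (profile$R - mu) / sdv, NA_real_)
  profile$usable <- usable
  profile
}

#' Region-level Z for an arbitrary bin set
#'
#' @param profile a `depth_profile` with panel R attached.
#' @param idx logical or integer index of bins defining the region.
#' @return list with `R` (mean sample R over usable region bins), `Z`, and
#'   `n_bins` used; `Z` is `NA` when fewer than 2 usable bins or zero
#'   panel spread.
#' @export
region_Z <- function(profile, idx) {
  pr <- attr(profile, "panel_R")
  if (is.logical(idx)) idx <- which(idx)
  idx <- idx[profile$usable[idx]]
  if (length(idx) == 0L)
    return(list(R = NA_real_, Z = NA_real_, n_bins = 0L))
  r_s <- mean(profile$R[idx])
  r_p <- colMeans(pr[idx, , drop = FALSE])
  sdv <- stats::sd(r_p)
  z <- if (is.finite(sdv) && sdv > 0) (r_s - mean(r_p)) / sdv else NA_real_
  list(R = r_s, Z = z, n_bins = length(idx))
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("Depth profile: %d bins (%d usable), %d chromosomes\n",
              nrow(x), sum(x$usable), length(unique(x$chrom))))
  invisible(x)
}
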