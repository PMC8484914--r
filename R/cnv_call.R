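#' Call copy-number events in one low-pass sample against a panel
#'
#' The full read-depth calling pipeline in one fit: GC correction,
#' reference-panel R/Z statistics, sex inference (XY samples have chrX
#' rescaled to its half-dosage baseline before calling), circular binary
#' segmentation, five-state HMM decoding, segmental-event calling under
#' the `|R| > 0.2` and `|Z| > 3` rule with a 100 kb floor,
#' Z-gated whole-chromosome aneuploidy and mosaic-fraction estimation,
#' and ISCN-style karyotype reporting.
#'
#' Segmental events spanning most (>= 80%) of a chromosome that also
#' received a whole-chromosome call are absorbed into that call rather
#' than double-reported.
#'
#' @param sample `bin_counts` for the test sample.
#' @param panel list of `bin_counts` (euploid reference panel, same grid).
#' @param alpha,n_perm,min_width,merge_tol CBS parameters, see
#'   [cbs_segment()].
#' @param R0,Z0,min_size segmental calling thresholds, see
#'   [call_segmental_cnvs()].
#' @param Z0_chrom,f_min aneuploidy thresholds, see [detect_aneuploidy()].
#' @param p_stay HMM self-transition probability, see [hmm_model()].
#' @param mask_sex report "XN" in the karyotype (fetal convention).
#' @param seed seed for the CBS permutation streams.
#' @return object of class `cnv_call`: a karyotype report (`sample_id`,
#'   `sex_call`, `iscn`, `events`, `result_class`) plus the underlying
#'   `profile`, `segments`, `hmm_path`, `sigma` and call parameters.
#' @examples
#' grid <- make_bin_grid(toy_genome())
#' panel <- simulate_reference_panel(8, grid, seed = 7)
#' spec <- simulation_spec(data.frame(chrom = "chr2", start = NA, end = NA,
#'                                    cn = 3L, f = 1), seed = 11)
#' fit <- cnv_call(simulate_sample(spec, grid), panel, n_perm = 200)
#' fit$iscn
#' @export
cnv_call <- function(sample, panel,
                     alpha = 0.01, n_perm = 1000L, min_width = 5L,
                     merge_tol = 0.1,
                     R0 = 0.2, Z0 = 3, min_size = 1e5,
                     Z0_chrom = 3, f_min = 0.1,
                     p_stay = 0.999, mask_sex = TRUE, seed = 1L) {
  profile <- compute_Z(compute_R(sample, panel))
  sex_call <- infer_sex(profile)
  if (sex_call == "XY") {
    on_x <- profile$chrom %in% c("chrX", "X") & profile$usable
    profile$R[on_x] <- 2 * profile$R[on_x] + 1
    profile <- compute_Z(profile)
  }

  sigma <- fit_sigma(profile)
  model <- hmm_model(sigma = sigma, p_stay = p_stay)
  hmm_path <- viterbi_decode(profile, model)
  segments <- cbs_segment(profile, alpha = alpha, n_perm = n_perm,
                          min_width = min_width, merge_tol = merge_tol,
                          seed = seed)

  seg_events <- call_segmental_cnvs(segments, hmm_path, profile,
                                    R0 = R0, Z0 = Z0, min_size = min_size)
  aneu <- detect_aneuploidy(profile, Z0_chrom = Z0_chrom, f_min = f_min,
                            segments = segments)

  if (nrow(seg_events) && nrow(aneu)) {
    chrom_len <- tapply(profile$end, profile$chrom, max)
    frac <- seg_events$size_bp / as.numeric(chrom_len[seg_events$chrom])
    absorbed <- seg_events$chrom %in% aneu$chrom & frac >= 0.8
    seg_events <- seg_events[!absorbed, , drop = FALSE]
  }
  events <- rbind(aneu, seg_events)
  rownames(events) <- NULL

  structure(list(
    sample_id = attr(sample, "sample_id"),
    sex_call = sex_call,
    iscn = format_karyotype(events, sex_call, mask_sex = mask_sex),
    events = events,
    result_class = classify_result(events),
    profile = profile,
    segments = segments,
    hmm_path = hmm_path,
    sigma = sigma,
    params = list(alpha = alpha, n_perm = n_perm, min_width = min_width,
                  merge_tol = merge_tol, R0 = R0, Z0 = Z0,
                  min_size = min_size, Z0_chrom = Z0_chrom, f_min = f_min,
                  p_stay = p_stay, mask_sex = mask_sex, seed = seed)),
    class = "cnv_call")
}

#' @export
print.cnv_call <- function(x, ...) {
  cat("CNV-seq call\n")
  cat("  sample:   ", x$sample_id, "\n", sep = "")
  cat("  sex call: ", x$sex_call, "\n", sep = "")
  cat("  karyotype:", x$iscn, "\n")
  cat("  result:   ", x$result_class, "\n", sep = "")
  cat(sprintf("  %d event(s), emission sd %.4f\n", nrow(x$events), x$sigma))
  invisible(x)
}

#' @method summary cnv_call
#' @export
summary.cnv_call <- function(object, ...) {
  chroms <- unique(object$profile$chrom)
  tab <- do.call(rbind, lapply(chroms, function(ch) {
    rz <- region_Z(object$profile, object$profile$chrom == ch)
    data.frame(chrom = ch, n_usable = rz$n_bins, R = rz$R, Z = rz$Z)
  }))
  out <- list(call = object, chrom_table = tab)
  class(out) <- "summary.cnv_call"
  out
}

#' @export
print.summary.cnv_call <- function(x, ...) {
  print(x$call)
  cat("\nChromosome-level statistics:\n")
  print(x$chrom_table, row.names = FALSE, digits = 3)
  if (nrow(x$call$events)) {
    cat("\nEvents:\n")
    print(x$call$events, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
fitted.cnv_call <- function(object, ...) {
  fit <- rep(NA_real_, nrow(object$profile))
  for (k in seq_len(nrow(object$segments))) {
    s <- object$segments[k, ]
    bins <- which(object$profile$chrom == s$chrom)[(s$start_bin + 1L):s$end_bin]
    fit[bins] <- s$mean_R
  }
  fit[!object$profile$usable] <- NA_real_
  fit
}

#' @method residuals cnv_call
#' @export
residuals.cnv_call <- function(object, ...) {
  object$profile$R - fitted(object)
}

#' @method coef cnv_call
#' @export
coef.cnv_call <- function(object, ...) {
  chroms <- unique(object$profile$chrom)
  stats::setNames(vapply(chroms, function(ch)
    region_Z(object$profile, object$profile$chrom == ch)$R, numeric(1)),
    chroms)
}

#' Plot the R track with fitted segments
#'
#' Per-bin copy-ratio deviation R in genome order, chromosome boundaries
#' dashed, segment means overlaid, the +/-0.2 reference band shaded.
#'
#' @param x a `cnv_call`.
#' @param ... passed to [graphics::plot()].
#' @method plot cnv_call
#' @export
plot.cnv_call <- function(x, ...) {
  pr <- x$profile
  gx <- seq_len(nrow(pr))
  graphics::plot(gx, pr$R, pch = 16, cex = 0.3,
                 col = ifelse(pr$usable, "grey40", "grey85"),
                 xlab = "bin (genome order)", ylab = "R",
                 main = paste(x$sample_id, x$iscn), ...)
  graphics::rect(0, -0.2, nrow(pr) + 1, 0.2,
                 col = grDevices::adjustcolor("steelblue", 0.15), border = NA)
  bounds <- cumsum(table(factor(pr$chrom, levels = unique(pr$chrom))))
  graphics::abline(v = bounds + 0.5, lty = 2, col = "grey70")
  for (k in seq_len(nrow(x$segments))) {
    s <- x$segments[k, ]
    bins <- which(pr$chrom == s$chrom)[(s$start_bin + 1L):s$end_bin]
    graphics::segments(min(bins), s$mean_R, max(bins), s$mean_R,
                       col = "red", lwd = 2)
  }
  invisible(x)
}
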