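#' Specify a ground-truth karyotype for read-depth simulation
#'
#' Describes one sample for the forward model of binned low-pass WGS:
#' expected depth per bin is `mean_reads_per_bin` x a GC-bias factor x the
#' copy-number dosage, and counts are drawn negative-binomially (Poisson
#' when `dispersion = 0`). Dosage inside an event is `1 + f * (cn - 2) / 2`
#' relative to the diploid baseline, so a full trisomy gives 1.5 and a 15%
#' mosaic monosomy gives 0.925. Sex chromosomes follow the stated `sex`:
#' chrY has dosage 0 for XX and 1/2 for XY, chrX has 1/2 for XY.
#'
#' @param events data.frame of ground-truth events with columns `chrom`,
#'   `start`, `end` (0-based half-open bp; `NA` start/end means the whole
#'   chromosome), `cn` (integer copy state in 0..4, not 2) and `f` (mosaic
#'   cell fraction in (0, 1]; 1 = non-mosaic). `NULL` or zero rows = euploid.
#' @param sex "XX" or "XY".
#' @param mean_reads_per_bin expected reads per diploid bin before GC bias;
#'   the default 100 corresponds to ~1x coverage of 100 bp reads in 10 kb
#'   windows.
#' @param dispersion negative-binomial overdispersion `d` so that
#'   `var = mu + d * mu^2`; 0 gives Poisson counts.
#' @param gc_bias_coeffs quadratic coefficients `c(c0, c1, c2)` of the raw
#'   GC factor `c0 + c1*gc + c2*gc^2`, normalized to mean 1 over the grid.
#' @param seed integer RNG seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(events = NULL, sex = c("XX", "XY"),
                            mean_reads_per_bin = 100, dispersion = 0.01,
                            gc_bias_coeffs = c(0.19, 3.6, -4), seed = 1L) {
  sex <- match.arg(sex)
  if (is.null(events))
    events <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), cn = integer(), f = numeric())
  stopifnot(is.data.frame(events),
            all(c("chrom", "cn", "f") %in% names(events)))
  if (is.null(events$start)) events$start <- rep(NA_real_, nrow(events))
  if (is.null(events$end)) events$end <- rep(NA_real_, nrow(events))
  if (nrow(events)) {
    if (any(!(events$cn %in% c(0L, 1L, 3L, 4L))))
      stop("event cn must be an integer in {0,1,3,4} (cn = 2 is no event)")
    if (any(events$f <= 0 | events$f > 1))
      stop("mosaic fraction f must lie in (0, 1]")
    seg <- !is.na(events$start)
    if (any(seg & (is.na(events$end) | events$end <= events$start)))
      stop("segmental events need end > start")
    for (ch in unique(events$chrom)) {
      ev <- events[events$chrom == ch, , drop = FALSE]
      if (any(is.na(ev$start)) && nrow(ev) > 1L)
        stop("whole-chromosome event overlaps another event on ", ch)
      ev <- ev[order(ev$start), , drop = FALSE]
      if (nrow(ev) > 1L && any(ev$start[-1] < ev$end[-nrow(ev)]))
        stop("events overlap on ", ch)
    }
  }
  if (mean_reads_per_bin <= 0) stop("mean_reads_per_bin must be positive")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(events = events, sex = sex,
                 mean_reads_per_bin = mean_reads_per_bin,
                 dispersion = dispersion,
                 gc_bias_coeffs = gc_bias_coeffs,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# Multiplicative GC factor, quadratic in gc, mean-1 over the grid,
# floored at 0.01 so expected counts stay positive.
gc_bias_factor <- function(gc, coeffs) {
  raw <- coeffs[1] + coeffs[2] * gc + coeffs[3] * gc^2
  raw <- pmax(raw, 0.01)
  raw / mean(raw)
}

# Per-bin copy-number dosage implied by the ground-truth events and sex.
truth_dosage <- function(spec, grid) {
  dosage <- rep(1, nrow(grid))
  if (spec$sex == "XX") {
    dosage[grid$chrom %in% c("chrY", "Y")] <- 0
  } else {
    dosage[grid$chrom %in% c("chrX", "X")] <- 0.5
    dosage[grid$chrom %in% c("chrY", "Y")] <- 0.5
  }
  ev <- spec$events
  for (k in seq_len(nrow(ev))) {
    on_chrom <- grid$chrom == ev$chrom[k]
    if (!any(on_chrom)) stop("event chromosome not in grid: ", ev$chrom[k])
    idx <- if (is.na(ev$start[k])) on_chrom else {
      if (ev$end[k] > max(grid$end[on_chrom]))
        stop("event coordinates outside grid on ", ev$chrom[k])
      on_chrom & grid$start < ev$end[k] & grid$end > ev$start[k]
    }
    dosage[idx] <- dosage[idx] * (1 + ev$f[k] * (ev$cn[k] - 2) / 2)
  }
  dosage
}

#' Simulate binned read counts for one sample
#'
#' @param spec a [simulation_spec()].
#' @param grid a `bin_grid` from [make_bin_grid()].
#' @return A `bin_counts`: the grid with an integer `count` column and a
#'   `sample_id` attribute. Deterministic for a fixed spec (the seed lives
#'   in the spec).
#' @param sample_id label stored on the result.
#' @export
simulate_sample <- function(spec, grid, sample_id = "sample") {
  stopifnot(inherits(spec, "simulation_spec"), inherits(grid, "bin_grid"))
  lambda <- spec$mean_reads_per_bin *
    gc_bias_factor(grid$gc, spec$gc_bias_coeffs) *
    truth_dosage(spec, grid)
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))
  counts <- if (spec$dispersion == 0) {
    stats::rpois(length(lambda), lambda)
  } else {
    stats::rnbinom(length(lambda), mu = lambda, size = 1 / spec$dispersion)
  }
  out <- grid
  out$count <- as.integer(counts)
  structure(out, sample_id = sample_id,
            class = c("bin_counts", class(grid)))
}

#' Simulate a euploid reference panel
#'
#' All panel members are euploid 46,XN of the given sex; per-member seeds
#' are derived deterministically from the master seed, so the same master
#' seed always yields the same panel.
#'
#' @param n_samples panel size, at least 2 (a single sample leaves the Z
#'   denominator undefined).
#' @param grid a `bin_grid`.
#' @param depth mean reads per bin.
#' @param dispersion negative-binomial overdispersion.
#' @param seed master seed.
#' @param sex panel sex, default "XX".
#' @inheritParams simulation_spec
#' @return list of `bin_counts`.
#' @export
simulate_reference_panel <- function(n_samples, grid, depth = 100,
                                     dispersion = 0.01, seed = 1L,
                                     sex = "XX",
                                     gc_bias_coeffs = c(0.19, 3.6, -4)) {
  if (n_samples < 2) stop("reference panel needs n_samples >= 2")
  old <- local_seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_samples)
  restore_seed(old)
  lapply(seq_len(n_samples), function(i) {
    sp <- simulation_spec(sex = sex, mean_reads_per_bin = depth,
                          dispersion = dispersion,
                          gc_bias_coeffs = gc_bias_coeffs,
                          seed = sub_seeds[i])
    simulate_sample(sp, grid, sample_id = sprintf("panel_%02d", i))
  })
}

#' Specify a cohort composition for simulation
#'
#' Category counts per stratum; rows are expanded into exactly those
#' numbers of samples (counts are assigned, not sampled), with maternal
#' ages and gestational weeks drawn uniformly within the group bounds.
#'
#' @param counts data.frame with columns `result_class` and `n`, plus
#'   optional `age_group` (one of `<25`, `25-29`, `30-34`, `35-39`, `>=40`,
#'   `<30`, `<35`, `>=35`) and `gest_group` (`early` = 4-12 weeks,
#'   `middle` = 13-27 weeks).
#' @param seed integer RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(counts, seed = 1L) {
  stopifnot(is.data.frame(counts), all(c("result_class", "n") %in% names(counts)))
  if (nrow(counts) && any(counts$n < 0 | counts$n != round(counts$n)))
    stop("counts must be nonnegative integers")
  structure(list(counts = counts, seed = as.integer(seed)),
            class = "cohort_spec")
}

age_group_bounds <- function(label) {
  switch(label,
         "<25" = c(18, 24), "25-29" = c(25, 29), "30-34" = c(30, 34),
         "35-39" = c(35, 39), ">=40" = c(40, 46),
         "<30" = c(18, 29), "<35" = c(18, 34), ">=35" = c(35, 46),
         stop("unknown age group label: ", label))
}

gest_group_bounds <- function(label) {
  switch(label,
         "early" = c(4, 12), "<=12" = c(4, 12),
         "middle" = c(13, 27), "13-27" = c(13, 27),
         stop("unknown gestational group label: ", label))
}

#' Expand a cohort specification into a per-sample table
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `sample_id`, `maternal_age_years`,
#'   `gestational_weeks`, `result_class`; category frequencies match the
#'   spec counts exactly.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cnt <- spec$counts
  if (!nrow(cnt) || sum(cnt$n) == 0)
    return(data.frame(sample_id = character(),
                      maternal_age_years = numeric(),
                      gestational_weeks = numeric(),
                      result_class = character()))
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))
  rows <- lapply(seq_len(nrow(cnt)), function(i) {
    n <- cnt$n[i]
    if (n == 0) return(NULL)
    ab <- if (!is.null(cnt$age_group)) age_group_bounds(cnt$age_group[i]) else c(18, 46)
    gb <- if (!is.null(cnt$gest_group)) gest_group_bounds(cnt$gest_group[i]) else c(4, 27)
    data.frame(maternal_age_years = pmin(floor(stats::runif(n, ab[1], ab[2] + 1)), ab[2]),
               gestational_weeks = pmin(floor(stats::runif(n, gb[1], gb[2] + 1)), gb[2]),
               result_class = cnt$result_class[i])
  })
  out <- do.call(rbind, rows)
  out <- data.frame(sample_id = sprintf("S%04d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}
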