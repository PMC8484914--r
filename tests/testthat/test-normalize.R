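test_that("GC-independent counts pass through gc_correct nearly unchanged", {
  s <- sim_counts(seed = 9, id = "flat")
  # regenerate with flat GC response
  spec <- simulation_spec(gc_bias_coeffs = c(1, 0, 0), seed = 9)
  s <- simulate_sample(spec, toy_grid, "flat")
  corr <- gc_correct(s)
  expect_lt(max(abs(corr$count / pmax(s$count, 1) - 1)[s$count > 20]), 0.25)
  expect_equal(median(corr$count / pmax(s$count, 0.5)), 1, tolerance = 0.05)
})

test_that("gc_correct flattens a monotone GC bias at least 5-fold", {
  spec <- simulation_spec(gc_bias_coeffs = c(0, 1, 0), seed = 10)
  s <- simulate_sample(spec, toy_grid, "biased")
  auto <- s$chrom %in% c("chr1", "chr2", "chr3")  # chrY is zero-coverage in XX
  slope_before <- abs(coef(lm(s$count[auto] ~ s$gc[auto]))[2])
  corr <- gc_correct(s)
  slope_after <- abs(coef(lm(corr$count[auto] ~ corr$gc[auto]))[2])
  expect_lt(slope_after, slope_before / 5)
})

test_that("correction factors rebuild from brute-force stratum medians", {
  s <- sim_counts(seed = 11)
  corr <- gc_correct(s)
  # independent reconstruction: chromosome-median-normalized depths,
  # group-by stratum median knots (two-pass inliers), linear
  # interpolation/extrapolation with tail clamping
  ch_med <- tapply(s$count, s$chrom, median)
  z <- s$count / as.numeric(ch_med[s$chrom])
  z[!is.finite(z)] <- NA
  breaks <- unique(quantile(s$gc, 0:10 / 10, names = FALSE))
  stratum <- findInterval(s$gc, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  shape_from <- function(inl) {
    kn <- sapply(sort(unique(stratum)), function(st) {
      idx <- stratum == st
      c(gc = mean(s$gc[idx]), med = median(z[idx & inl]), n = sum(idx & inl))
    })
    keep <- kn["n", ] >= 20 & !is.na(kn["med", ]) & kn["med", ] > 0
    gk <- kn["gc", keep]; mk <- kn["med", keep]; nk <- length(gk)
    y <- approx(gk, mk, xout = s$gc, rule = 2)$y
    lo <- s$gc < gk[1]
    y[lo] <- mk[1] + (mk[2] - mk[1]) / (gk[2] - gk[1]) * (s$gc[lo] - gk[1])
    hi <- s$gc > gk[nk]
    y[hi] <- mk[nk] + (mk[nk] - mk[nk - 1]) / (gk[nk] - gk[nk - 1]) * (s$gc[hi] - gk[nk])
    pmin(pmax(y, 0.5 * min(mk)), 2 * max(mk))
  }
  okb <- is.finite(z)
  shape <- shape_from(okb & z > 0.7 & z < 1.3)
  shape <- shape_from(okb & z / shape > 0.7 & z / shape < 1.3)
  want <- s$count / shape
  want <- want * median(s$count[s$count > 0]) / median(want[want > 0])
  expect_equal(corr$count, want, tolerance = 1e-12)
  expect_error(gc_correct({ z <- s; z$count <- 0L * z$count; z }), "all-zero")
})

test_that("R is 0 when the sample equals every panel member", {
  base <- toy_panel[[1]]
  panel <- lapply(1:5, function(i) base)
  pr <- compute_R(base, panel)
  expect_true(all(abs(pr$R[pr$usable]) < 1e-10))
})

test_that("R recovers dosage algebra: trisomy +0.5, mosaic f=0.4 ~ +0.2", {
  s <- sim_counts(whole_event("chr2", 3), seed = 21, dispersion = 0)
  pr <- compute_R(s, toy_panel)
  on2 <- pr$usable & pr$chrom == "chr2"
  off <- pr$usable & pr$chrom %in% c("chr1", "chr3")
  expect_lt(abs(mean(pr$R[on2]) - 0.5), 0.03)
  expect_lt(abs(mean(pr$R[off])), 0.02)

  s <- sim_counts(whole_event("chr2", 3, f = 0.4), seed = 22, dispersion = 0)
  pr <- compute_R(s, toy_panel)
  expect_lt(abs(mean(pr$R[pr$usable & pr$chrom == "chr2"]) - 0.2), 0.02)
})

test_that("R is invariant to rescaling all sample counts", {
  s <- sim_counts(whole_event("chr1", 3), seed = 23)
  pr1 <- compute_R(s, toy_panel)
  s2 <- s
  s2$count <- s$count * 7L
  pr2 <- compute_R(s2, toy_panel)
  expect_equal(pr1$R, pr2$R, tolerance = 1e-10)
})

test_that("Z is 0 at the panel mean and exactly 10 for a +10 sd shift", {
  pr <- compute_Z(compute_R(sim_counts(seed = 31), toy_panel))
  idx <- which(pr$chrom == "chr2")
  panel_R <- attr(pr, "panel_R")
  use <- idx[pr$usable[idx]]
  r_p <- colMeans(panel_R[use, ])
  # force the sample's region R to the panel mean, then shift by 10 sd
  pr$R[use] <- mean(r_p)
  expect_equal(region_Z(pr, idx)$Z, 0, tolerance = 1e-9)
  pr$R[use] <- mean(r_p) + 10 * sd(r_p)
  expect_equal(region_Z(pr, idx)$Z, 10, tolerance = 1e-9)
})

test_that("euploid chromosome medians sit inside the +/-0.2 reference band", {
  for (seed in 1:8) {
    pr <- compute_Z(compute_R(sim_counts(seed = 300 + seed), toy_panel))
    med <- tapply(pr$R[pr$usable], pr$chrom[pr$usable], median)
    expect_true(all(abs(med) < 0.2))
  }
})

test_that("panel leave-one-out chromosome Z is standardized (mean ~0, sd ~1)", {
  pr <- compute_Z(compute_R(sim_counts(seed = 41), toy_panel))
  panel_R <- attr(pr, "panel_R")
  z <- vapply(c("chr1", "chr2", "chr3"), function(ch) {
    use <- which(pr$chrom == ch & pr$usable)
    r_p <- colMeans(panel_R[use, ])
    (r_p - mean(r_p)) / sd(r_p)
  }, numeric(ncol(panel_R)))
  expect_lt(abs(mean(z)), 0.2)
  expect_equal(sd(as.numeric(z)), 1, tolerance = 0.15)
})

test_that("grid mismatch and tiny panels are rejected", {
  s <- sim_counts(seed = 51)
  other <- simulate_sample(simulation_spec(seed = 1),
                           make_bin_grid(data.frame(chrom = "chr1", length = 1e6)))
  expect_error(compute_R(s, list(other, other)), "grid")
  expect_error(compute_R(s, toy_panel[1]), "length")
})
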