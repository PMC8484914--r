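test_that("segmental calling applies the R/Z/size rule literally", {
  # 100 bins, plateau of +0.5 over bins 21..60 (400 kb)
  x <- c(rep(0, 20), rep(0.5, 40), rep(0, 40))
  pr <- make_profile(list(chr1 = x), panel_sd = 0.01)
  seg <- cbs_segment(pr, n_perm = 200, seed = 2)
  path <- viterbi_decode(pr, hmm_model(sigma = 0.05))
  ev <- call_segmental_cnvs(seg, path, pr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "duplication")
  expect_equal(ev$cn, 3L)
  expect_equal(ev$evidence, "both")
  expect_equal(c(ev$start_bp, ev$end_bp), c(20, 60) * 1e4)
})

test_that("R inside the reference band blocks a call even at high Z", {
  seg <- data.frame(chrom = "chr1", start_bin = 0L, end_bin = 50L,
                    start_bp = 0, end_bp = 5e5, mean_R = 0.15,
                    n_bins = 50L, Z_seg = 8)
  pr <- make_profile(list(chr1 = rep(0.15, 50)), panel_sd = 0.01)
  ev <- call_segmental_cnvs(seg, rep(3L, 50), pr)
  expect_equal(nrow(ev), 0L)

  # |R| above band but Z below threshold also blocks
  seg$mean_R <- 0.5; seg$Z_seg <- 2
  expect_equal(nrow(call_segmental_cnvs(seg, rep(3L, 50), pr)), 0L)

  # size below 100 kb blocks
  seg$Z_seg <- 9; seg$end_bp <- 9e4; seg$end_bin <- 9L
  expect_equal(nrow(call_segmental_cnvs(seg, rep(3L, 50), pr)), 0L)

  expect_error(call_segmental_cnvs(seg, rep(3L, 50), pr, R0 = -1), "positive")
})

test_that("a simulated 500 kb deletion is recovered with >= 90% reciprocal overlap", {
  truth <- seg_event("chr1", 1.2e6, 1.7e6, 1)
  s <- sim_counts(truth, seed = 61, id = "del500k")
  fit <- cnv_call(s, toy_panel, n_perm = 300, seed = 6)
  del <- fit$events[fit$events$kind == "deletion" & !fit$events$whole_chromosome, ]
  expect_equal(nrow(del), 1L)
  ro <- min((min(del$end_bp, 1.7e6) - max(del$start_bp, 1.2e6)) / 5e5,
            (min(del$end_bp, 1.7e6) - max(del$start_bp, 1.2e6)) / del$size_bp)
  expect_gte(ro, 0.9)
})

test_that("aneuploidy detection inverts the dosage formula", {
  # noiseless full trisomy: R = +0.5 -> f = 1, cn 3
  pr <- make_profile(list(chr1 = rep(0.5, 100), chr2 = rep(0, 100)))
  ev <- detect_aneuploidy(pr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$cn, 3L)
  expect_equal(ev$f, 1)
  expect_true(ev$whole_chromosome)

  # noiseless mosaic monosomy f = 0.15: R = -0.075 -> f = 0.15, cn 1
  pr <- make_profile(list(chr1 = rep(-0.075, 100), chr2 = rep(0, 100)))
  ev <- detect_aneuploidy(pr)
  expect_equal(ev$cn, 1L)
  expect_equal(ev$f, 0.15, tolerance = 1e-9)

  # tetrasomy region: R = +1 -> cn 4
  pr <- make_profile(list(chr1 = rep(1, 100), chr2 = rep(0, 100)))
  expect_equal(detect_aneuploidy(pr)$cn, 4L)

  # sub-threshold implied fraction is not called
  pr <- make_profile(list(chr1 = rep(0.02, 100), chr2 = rep(0, 100)))
  expect_equal(nrow(detect_aneuploidy(pr)), 0L)
})

test_that("segmented chromosomes are not whole-chromosome calls", {
  x <- c(rep(0, 50), rep(-0.5, 100), rep(0, 50))  # interior deletion
  pr <- make_profile(list(chr1 = x), panel_sd = 0.01)
  seg <- cbs_segment(pr, n_perm = 200, seed = 9)
  expect_equal(nrow(detect_aneuploidy(pr, segments = seg)), 0L)
  # without segmentation evidence the chromosome mean would trigger a call
  expect_gt(nrow(detect_aneuploidy(pr)), 0L)
})

test_that("sex inference from simulated XX, XY and 45,X", {
  prXX <- compute_Z(compute_R(sim_counts(seed = 71), toy_panel))
  expect_equal(infer_sex(prXX), "XX")
  prXY <- compute_Z(compute_R(sim_counts(seed = 72, sex = "XY"), toy_panel))
  expect_equal(infer_sex(prXY), "XY")
  pr45X <- compute_Z(compute_R(sim_counts(whole_event("chrX", 1), seed = 73),
                               toy_panel))
  expect_equal(infer_sex(pr45X), "undetermined")
  fit <- cnv_call(sim_counts(whole_event("chrX", 1), seed = 73, id = "m45x"),
                  toy_panel, n_perm = 200, seed = 7)
  expect_equal(fit$iscn, "45,X")
})

test_that("karyotype strings match clinical reporting conventions", {
  tri16 <- ev_row("chr16", 0, 9e7, whole = TRUE, cn = 3)
  expect_equal(format_karyotype(tri16, "XX"), "47,XN,+16")
  expect_equal(format_karyotype(tri16, "XX", mask_sex = FALSE), "47,XX,+16")

  monoX <- ev_row("chrX", 0, 1.5e8, whole = TRUE, cn = 1)
  expect_equal(format_karyotype(monoX, "undetermined"), "45,X")

  tetra7 <- ev_row("chr7", 0, 1.6e8, whole = TRUE, cn = 4)
  expect_equal(format_karyotype(tetra7, "XX"), "48,XN,+7,+7")

  mosX <- ev_row("chrX", 0, 1.5e8, whole = TRUE, cn = 1, f = 0.15)
  expect_equal(format_karyotype(mosX, "XX"), "45,X[15%]/46,XN[85%]")

  expect_equal(format_karyotype(NULL, "XX"), "46,XN")

  multi <- rbind(ev_row("chr13", 0, 1e8, whole = TRUE, cn = 3, f = 0.4),
                 ev_row("chr21", 0, 5e7, whole = TRUE, cn = 3, f = 0.4),
                 ev_row("chr22", 0, 5e7, whole = TRUE, cn = 3, f = 0.2))
  expect_equal(format_karyotype(multi, "XX"),
               "47,XN,+13[40%]/47,XN,+21[40%]/47,XN,+22[20%]")

  del <- ev_row("chr3", 5e5, 1.5e6, cn = 1)
  expect_equal(format_karyotype(del, "XX"), "46,XN,del(3:500000-1500000)")

  expect_error(format_karyotype(rbind(ev_row("chr1", 0, 1e6, whole = TRUE, cn = 3),
                                      ev_row("chr1", 0, 1e6, whole = TRUE, cn = 1)),
                                "XX"), "inconsistent")
})

test_that("formatter output round-trips through the parser", {
  cases <- list(
    ev_row("chr16", 0, 9e7, whole = TRUE, cn = 3),
    ev_row("chrX", 0, 1.5e8, whole = TRUE, cn = 1),
    ev_row("chr7", 0, 1.6e8, whole = TRUE, cn = 4),
    ev_row("chrX", 0, 1.5e8, whole = TRUE, cn = 1, f = 0.15),
    rbind(ev_row("chr13", 0, 1e8, whole = TRUE, cn = 3, f = 0.4),
          ev_row("chr21", 0, 5e7, whole = TRUE, cn = 3, f = 0.4)),
    rbind(ev_row("chr2", 0, 2.4e8, whole = TRUE, cn = 3),
          ev_row("chr5", 1e6, 3e6, cn = 1),
          ev_row("chr9", 2e6, 2.8e6, cn = 3)),
    NULL)
  for (ev in cases) {
    s <- format_karyotype(ev, "XX")
    parsed <- parse_karyotype(s)
    s2 <- format_karyotype(parsed$events, "XX")
    expect_equal(s2, s)
  }
})

test_that("result classes follow the numerical > chimera > structural precedence", {
  expect_equal(classify_result(ev_row("chr16", 0, 9e7, whole = TRUE, cn = 3)),
               "numerical abnormality")
  expect_equal(classify_result(ev_row("chrX", 0, 1e8, whole = TRUE, cn = 1, f = 0.2)),
               "chimera")
  expect_equal(classify_result(ev_row("chr1", 0, 8e5, cn = 3)),
               "structural abnormality")
  expect_equal(classify_result(NULL), "normal")
  mixed <- classify_result(rbind(ev_row("chr16", 0, 9e7, whole = TRUE, cn = 3),
                                 ev_row("chr1", 0, 8e5, cn = 3)))
  expect_equal(as.character(mixed), "numerical abnormality")
  expect_true(isTRUE(attr(mixed, "mixed")))
})
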