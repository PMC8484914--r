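test_that("gene annotation returns overlapped symbols in positional order", {
  res <- toy_resources()
  ev <- ev_row("chr1", 120e3, 720e3, cn = 3)   # spans G1..G4 partially
  expect_equal(annotate_genes(ev, res), c("G1", "G2", "G3", "G4"))
  expect_equal(annotate_genes(ev_row("chr1", 2e6, 2.1e6, cn = 3), res),
               character(0))
  expect_equal(annotate_genes(ev_row("chr2", 0, 1e6, cn = 3), res),
               character(0))
})

test_that("interval-tree annotation equals a brute-force all-pairs scan", {
  set.seed(91)
  genes <- data.frame(
    chrom = sample(c("chr1", "chr2", "chr3"), 200, TRUE),
    start = sample.int(5e6, 200))
  genes$end <- genes$start + sample.int(2e5, 200)
  genes$symbol <- sprintf("G%03d", 1:200)
  res <- annotation_resources(genes,
                              data.frame(chrom = character(), start = numeric(),
                                         end = numeric(), label = character(),
                                         min_overlap = numeric(), sign = character()),
                              data.frame(chrom = character(), start = numeric(),
                                         end = numeric(), label = character(),
                                         min_overlap = numeric(), sign = character()))
  for (k in 1:1000) {
    st <- sample.int(5e6, 1)
    ev <- ev_row(sample(c("chr1", "chr2", "chr3"), 1), st, st + sample.int(5e5, 1),
                 cn = 3)
    expect_equal(annotate_genes(ev, res), oracle_annotate(ev, genes))
  }
})

test_that("the tier cascade matches its rules on constructed cases", {
  res <- toy_resources()
  # rule 1: event equal to the pathogenic region (matching sign: del)
  expect_equal(classify_tier(ev_row("chr1", 1.2e6, 1.7e6, cn = 1), res),
               "pathogenic")
  # sign mismatch falls through
  expect_equal(classify_tier(ev_row("chr1", 1.2e6, 1.7e6, cn = 3), res), "VOUS")
  # rule 2a: 0.25 <= reciprocal overlap < min_overlap
  expect_equal(classify_tier(ev_row("chr1", 1.5e6, 2.0e6, cn = 1), res),
               "likely pathogenic")
  # rule 2b: contains a dosage-sensitive gene
  expect_equal(classify_tier(ev_row("chr1", 480e3, 580e3, cn = 1), res),
               "likely pathogenic")
  # rule 3: fully inside a benign region
  expect_equal(classify_tier(ev_row("chr1", 2.1e6, 2.4e6, cn = 3), res),
               "benign")
  # rule 4: half-overlap with benign region, no genes
  expect_equal(classify_tier(ev_row("chr1", 2.3e6, 2.9e6, cn = 3), res),
               "likely benign")
  # rule 5: gene-containing event overlapping nothing
  expect_equal(classify_tier(ev_row("chr1", 280e3, 380e3, cn = 3), res), "VOUS")
})

test_that("every event gets exactly one tier and growth never lowers it", {
  res <- toy_resources()
  tiers <- c("pathogenic", "likely pathogenic", "VOUS", "likely benign", "benign")
  set.seed(92)
  for (k in 1:50) {
    st <- sample.int(3e6, 1)
    ev <- ev_row("chr1", st, st + sample.int(1e6, 1), cn = sample(c(1, 3), 1))
    expect_true(classify_tier(ev, res) %in% tiers)
  }
  # monotonicity: growing a deletion toward the pathogenic region
  rank <- function(t) match(t, rev(tiers))  # higher = worse
  t_small <- classify_tier(ev_row("chr1", 1.60e6, 1.75e6, cn = 1), res)
  t_mid <- classify_tier(ev_row("chr1", 1.45e6, 1.75e6, cn = 1), res)
  t_big <- classify_tier(ev_row("chr1", 1.22e6, 1.72e6, cn = 1), res)
  expect_true(rank(t_small) <= rank(t_mid))
  expect_true(rank(t_mid) <= rank(t_big))
  # determinism
  expect_identical(classify_tier(ev_row("chr1", 1.2e6, 1.7e6, cn = 1), res),
                   classify_tier(ev_row("chr1", 1.2e6, 1.7e6, cn = 1), res))
})

test_that("size classes use the closed 1-10 Mb middle bin", {
  expect_equal(size_class(8e5), "<1 Mb")
  expect_equal(size_class(1e6), "1-10 Mb")
  expect_equal(size_class(1e7), "1-10 Mb")
  expect_equal(size_class(1.00001e7), ">10 Mb")
  expect_error(size_class(0), "positive")
})

test_that("tier_events annotates a frame of events end to end", {
  res <- toy_resources()
  evs <- rbind(ev_row("chr1", 1.2e6, 1.7e6, cn = 1),
               ev_row("chr1", 100e3, 1.2e6, cn = 3))
  out <- tier_events(evs, res)
  # the second event contains the dosage-sensitive G3, hence likely pathogenic
  expect_equal(out$tier, c("pathogenic", "likely pathogenic"))
  expect_equal(out$size_class, c("<1 Mb", "1-10 Mb"))
  expect_equal(out$genes[2], "G1,G2,G3,G4,G5")
})
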