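# Shared fixtures, built once per test run.

toy_grid <- make_bin_grid(toy_genome(), seed = 101)
toy_panel <- simulate_reference_panel(20, toy_grid, depth = 100,
                                      dispersion = 0.01, seed = 424242)

sim_counts <- function(events = NULL, seed = 1L, sex = "XX",
                       depth = 100, dispersion = 0.01, id = "s") {
  simulate_sample(simulation_spec(events, sex = sex,
                                  mean_reads_per_bin = depth,
                                  dispersion = dispersion, seed = seed),
                  toy_grid, sample_id = id)
}

whole_event <- function(chrom, cn, f = 1) {
  data.frame(chrom = chrom, start = NA_real_, end = NA_real_,
             cn = as.integer(cn), f = f)
}

seg_event <- function(chrom, start, end, cn, f = 1) {
  data.frame(chrom = chrom, start = start, end = end,
             cn = as.integer(cn), f = f)
}

# Hand-built depth profile with exact R values and a synthetic panel-R
# matrix (n_panel members of iid noise at sd panel_sd, seeded), for unit
# tests that need noiseless control over the calling statistics.
make_profile <- function(R_by_chrom, bin_size = 1e4, panel_sd = 0.001,
                         n_panel = 10, gc = 0.45, seed = 99,
                         corrected = NULL) {
  chrom <- rep(names(R_by_chrom), lengths(R_by_chrom))
  R <- unlist(R_by_chrom, use.names = FALSE)
  n <- length(R)
  starts <- unlist(lapply(lengths(R_by_chrom), function(k) (0:(k - 1)) * bin_size))
  df <- data.frame(chrom = chrom, start = starts, end = starts + bin_size,
                   gc = gc, R = R, Z = NA_real_, usable = TRUE)
  set.seed(seed)
  panel_R <- matrix(stats::rnorm(n * n_panel, 0, panel_sd), n, n_panel)
  pr <- structure(df,
                  bin_size = bin_size,
                  chrom_table = data.frame(chrom = names(R_by_chrom),
                                           length = lengths(R_by_chrom) * bin_size),
                  sample_id = "synthetic",
                  corrected = if (is.null(corrected)) rep(100, n) * (1 + R) else corrected,
                  panel_R = panel_R,
                  class = c("depth_profile", "data.frame"))
  compute_Z(pr)
}

# Small annotation fixture: five genes on chr1, one pathogenic and one
# benign region.
toy_resources <- function() {
  genes <- data.frame(
    chrom = "chr1",
    start = c(100e3, 300e3, 500e3, 700e3, 900e3),
    end = c(150e3, 350e3, 550e3, 750e3, 950e3),
    symbol = c("G1", "G2", "G3", "G4", "G5"))
  pathogenic <- data.frame(chrom = "chr1", start = 1.2e6, end = 1.7e6,
                           label = "SYNDROME1", min_overlap = 0.5,
                           sign = "del")
  benign <- data.frame(chrom = "chr1", start = 2.0e6, end = 2.6e6,
                       label = "COMMON1", min_overlap = 0.5, sign = "any")
  annotation_resources(genes, pathogenic, benign, dosage_genes = "G3")
}

# One event row in the package's internal layout.
ev_row <- function(chrom, start_bp, end_bp, whole = FALSE, cn = 3L, f = 1,
                   kind = if (cn > 2) "duplication" else "deletion",
                   R = (cn - 2) / 2 * f, Z = 10, evidence = "both") {
  data.frame(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
             whole_chromosome = whole, kind = kind, cn = as.integer(cn),
             f = f, size_bp = end_bp - start_bp, R_event = R, Z_event = Z,
             evidence = evidence)
}
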