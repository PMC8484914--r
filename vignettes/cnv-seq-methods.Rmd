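---
title: "Read-depth CNV calling for products-of-conception samples: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-depth CNV calling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvseqr)
```

# Scope

cnvseqr implements binned read-depth copy-number analysis of low-pass
(~1×) whole-genome sequencing, as used for chromosomal screening of
miscarriage tissue: per-bin R and Z copy-number statistics against a
euploid reference panel, circular binary segmentation (CBS), a 5-state
copy-number HMM, whole-chromosome and mosaic aneuploidy calling with
ISCN-style reporting, a five-tier clinical classification cascade,
cohort contingency statistics, and hypergeometric gene-set
over-representation. Everything runs on synthetic data with known
ground truth; no alignment, external database, or network access is
involved.

# The forward model

The generator emulates the measurement process downstream of
sequencing and alignment. A genome is tiled into 10 kb bins
(`make_bin_grid()`); each bin carries a GC fraction, either supplied or
drawn as a smooth random field in [0.3, 0.6]. For a sample with
ground-truth events, the expected depth of bin $i$ is

$$\lambda_i = \mu \cdot g(\mathrm{gc}_i) \cdot d_i,$$

where $\mu$ is the mean reads per diploid bin, $g$ a quadratic
multiplicative GC factor normalized to mean 1, and $d_i$ the dosage:
$1 + f\,(CN-2)/2$ inside an event with copy number $CN$ and cell
fraction $f$, 1 elsewhere; chrY has dosage 0 for XX and 1/2 for XY,
chrX 1/2 for XY. Counts are negative-binomial with
$\mathrm{var} = \lambda + d\,\lambda^2$ (Poisson at $d = 0$).

Defaults are chosen to match the assay: $\mu = 100$ (roughly 1×
coverage of 100 bp reads in 10 kb windows), dispersion $d = 0.01$
(about twice-Poisson variance, typical of low-pass WGS), and a mild
unimodal GC factor (±10%, peaking near GC 0.45). Mosaic events are
modeled as a bulk mixture — a uniform fraction $f$ of cells across the
tissue — matching the bracketed-percentage karyotype notation; spatial
clonal structure is not modeled.

The bundled `toy_genome()` (three autosomes + X + Y, 10 Mb, 1,000
bins) is the default test fixture; `hg19_chromosomes()` provides
genome-scale lengths when realistic bin counts are wanted.

What the generator does **not** emulate: mappability and blacklist
structure, replication-timing waves, maternal-cell contamination,
library-specific insert effects, and reference-genome artifacts. Tests
passing on this generator therefore demonstrate correctness of the
statistics and calling logic under the stated noise model, not
end-to-end performance on clinical libraries.

# GC correction

Real samples differ in their GC response, so depths are corrected per
sample before panel comparison (`gc_correct()`). The correction is a
median-knot curve: depths are first normalized by their chromosome
median — whole-chromosome copy-number changes then sit at unit scale
and cannot distort the fit — and each GC decile contributes a median
knot at its mean GC. The curve is linearly interpolated at each bin's
GC and linearly extrapolated (clamped to [0.5×, 2×] of the knot range)
beyond the outermost knots. Knots are fitted twice: first against the
global level, then against the first-pass curve, which undoes the
asymmetric truncation a strong GC slope causes at the tails; bins
farther than 30% from the reference level (residual copy-number
outliers such as large segmental events) are excluded from the fit.
This assumes GC modulates depth by well under ±30% — comfortably true
for the defaults, and for most low-pass libraries after deduplication.

Plain constant-per-decile factors were rejected: they leave residual
slope inside the wide edge strata, and event-dominated strata drag
their factors. A bare median over all bins was also rejected as the
scale anchor (a whole aneuploid chromosome shifts it); the chromosome-
median construction handles both.

# R and Z

`compute_R()` scales the corrected sample and panel members to a
common total over usable bins, takes the panel median $m_i$ per bin,
and rescales the sample so the median per-chromosome median ratio is 1
— robust both to large events inflating the sample total and to a
whole aneuploid chromosome dragging a bin-level median. Then
$R_i = s_i/m_i - 1$.

R is a *linear* ratio deviation, not log2: the symmetric published
reference band (−0.2, 0.2) and the trisomy/monosomy magnitudes (+0.5 /
−0.5) fit the linear scale naturally. This is a documented convention;
platforms reporting log ratios need a transform before comparison.

Usable-bin mask: panel median 0, GC outside [0.2, 0.8], or panel
coefficient of variation > 0.5 — a desk surrogate for the opaque bin
filtering that commercial pipelines apply. chrY drops out automatically
against an XX panel (median 0).

`compute_Z()` standardizes against the panel's leave-one-out R
profiles: for any bin set $S$,
$Z(S) = (R(S) - \overline{R_{panel}(S)}) / \mathrm{sd}(R_{panel}(S))$
with the $n-1$ denominator. Region and chromosome Z are computed on
demand (`region_Z()`); bins with zero panel spread are masked. With a
panel of $n$ members the null chromosome Z behaves like a
$t_{n-1}$-ish variable, so the |Z| > 3 rule is slightly
anti-conservative at small panels; panels of 20 are used throughout.

Sex is inferred from corrected chrX/chrY dosage relative to the
autosomal median (`infer_sex()`); monosomy X presents as neither XX nor
XY and is deliberately returned as `undetermined`, with the monosomy
itself called by the aneuploidy detector. For XY samples the chrX R is
rescaled to the half-dosage baseline before calling, since the default
reference panel is XX.

# Segmentation

`cbs_segment()` implements permutation CBS: per chromosome, the best
circular-arc split maximizes a pooled-variance two-sample t statistic
(all O(n²) arc pairs, compiled); the split is accepted when its
permutation p — the maximal statistic recomputed on seeded shuffles of
bin order — falls below `alpha`, and both sides recurse. Only the
permutation form is implemented (no hybrid tail approximation or
stopping-rule pruning). Permutations stop early once the p-value
provably exceeds `alpha`, which makes null chromosomes cheap.

Defaults: `alpha = 0.01`, `n_perm = 1000`, `min_width = 5` bins
(50 kb — below the 0.1 Mb reporting resolution, which is enforced at
the event-calling stage, not here), `merge_tol = 0.1` R units for
merging adjacent near-equal segments. Zero-variance splits with
differing means are treated as "always split". Ties in the arc search
break toward the smallest start, then smallest end. The per-split
permutation streams are derived deterministically from the seed, so
segmentations are reproducible.

# The copy-number HMM

`hmm_model()` defines 5 states (CN 0–4) with Gaussian emissions on the
R scale centered at $(CN-2)/2$ and a shared sd, `p_stay = 0.999`
self-transitions (expected segment length 10 Mb at 10 kb bins — a
long-segment prior matching the aneuploidy-dominated signal), uniform
off-diagonal mass, and initial mass $1-\varepsilon$ on CN 2. The
emission sd is estimated per sample by `fit_sigma()`:
$1.4826 \times \mathrm{MAD}$ of R on bins inside the reference band
(|R| < 0.2), floored at $10^{-3}$.

`viterbi_decode()` runs in log space with ties broken toward CN 2,
then lower CN; `forward_backward()` provides log-sum-exp-stabilized
posteriors. Mosaic events are **not** represented by fractional HMM
states — the HMM emits the nearest integer-CN explanation and mosaicism
is estimated downstream — keeping the state space small and matching
the integer karyotype vocabulary.

# Event calling and reconciliation

The three computational steps are reconciled as follows
(`cnv_call()`):

* **Segmental events** (`call_segmental_cnvs()`): a CBS segment is
  reported iff |mean R| > 0.2 AND |Z| > 3 (same sign) AND span
  ≥ 100 kb. The published rule reads as a conjunction of the R and Z
  exceedances and is implemented literally. The copy state is the HMM
  majority state over the segment when its sign agrees with the depth
  deviation (evidence `both`), else the nearest integer to
  $2(1+\bar R)$ (evidence `cbs`). Same-state events separated by < 2
  bins merge.
* **Whole-chromosome events** (`detect_aneuploidy()`): Z-gated only —
  a 10% mosaic monosomy has expected R −0.05, inside the reference
  band, yet such mosaics are clinically reported, so the R gate cannot
  apply at chromosome level. A chromosome is called when
  |Z<sub>chrom</sub>| > 3, its dominant CBS segment covers ≥ 90% of its
  usable bins (chromosomes carved into smaller pieces carry segmental,
  not whole-chromosome, signal — this resolves the CBS/HMM/Z
  reconciliation left open by the published description), and the
  implied fraction $\hat f = 2R_{chrom}/(CN-2)$ is ≥ 0.1. CN is 3 for
  gains (4 when R > 0.75) and 1 for losses. Events carry both the raw
  $\hat f$ and the reported fraction, which rounds $\hat f \ge 0.9$ to
  non-mosaic.
* Segmental events spanning ≥ 80% of a chromosome that also received a
  whole-chromosome call are absorbed into it.

`format_karyotype()` renders the ISCN-style string: modal count
$46 + \sum (CN-2)$, "XN" sex masking by default (the fetal reporting
convention), gain/loss tokens repeated per copy, monosomy X as "45,X",
mosaic clones with integer-percent brackets ordered by descending
fraction with the residual normal clone last, and segmental events
appended as `dup(chrom:start-end)` / `del(chrom:start-end)` — an
artifact convention, since full ISCN microarray nomenclature carries
no extra information here. A parser (`parse_karyotype()`) inverts the
formatter for round-trip testing. `classify_result()` maps events to
the reporting classes (numerical abnormality > chimera > structural
abnormality > normal, mixed cases flagged).

# Five-tier classification

The clinical five-grade scheme (pathogenic, likely pathogenic, VOUS,
likely benign, benign) is reduced to a deterministic overlap cascade
against local annotation tables (`classify_tier()`): reciprocal
overlap with a pathogenic region at the region's own threshold
(default 0.5) → pathogenic; reciprocal overlap ≥ 0.25 or containment
of a dosage-sensitive gene → likely pathogenic; containment in a
benign region of matching sign → benign; reciprocal overlap ≥ 0.5 with
a benign region and no gene content → likely benign; else VOUS. The
full evidence-point guideline process, which in practice rests on
curated online databases and judgment, is not desk-reproducible; all
thresholds are arguments. Size classes use the closed middle bin:
< 1 Mb, [1 Mb, 10 Mb], > 10 Mb.

# Cohort and enrichment statistics

`pearson_chi2()` computes the uncorrected Pearson statistic with
expected counts from the margins and the upper-tail χ² p-value. No
Yates continuity correction is applied: published 2×2 cohort
comparisons of this assay back-calculate exactly under the uncorrected
statistic. Published p-values occasionally disagree with their own χ²
(a χ² of 3.837 at 1 df corresponds to p ≈ 0.050, not 0.082, and 1.497
to p ≈ 0.221, not 0.574, suggesting a different procedure such as an
exact test was used for some cells); the analytic p is reported and
the χ² value itself is the comparable quantity.

`hypergeom_enrich()` scores a query gene list against GMT term sets by
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$, with
Benjamini–Hochberg adjustment across tested terms. Both raw-p and
adjusted-p significance filters exist behind `use_adjusted` (default
adjusted); the universe defaults to the supplied background, not the
genome, and must contain the query. Term sets are intersected with the
universe before testing.

# Numerical choices and degenerate inputs

* Seeds: every stochastic component (generator, panel derivation, CBS
  permutations) is an explicit argument; derived seeds stay below
  $2^{31}$.
* Zero-variance arcs in CBS score as "split if means differ"; constant
  tracks yield a single segment with exact mean.
* `fit_sigma()` floors at $10^{-3}$; chromosomes with fewer than
  `2 * min_width` usable bins return a single segment; panels of one
  are rejected (Z undefined).
* HMM ties (exact, within $10^{-12}$) prefer CN 2, then lower CN.
* GMT terms deduplicate genes; malformed lines (< 3 fields) error with
  the line number.
* The bin-count loader rejects negative counts, unsorted or
  overlapping bins, naming the offending row.

# Problem sizes in the test suite

The suite runs on the 1,000-bin toy genome with panels of 20 at depth
100: oracle equivalences use exhaustive enumeration (arc search n ≤ 30,
HMM chains ≤ 8 bins, hypergeometric universes ≤ 25); recovery and
calibration properties use 20–150 seeded replicates per condition, with
CBS at 200–300 permutations per split. These sizes were chosen so the
whole suite exercises every calling path in a few minutes while keeping
Monte Carlo standard errors well inside the asserted margins;
`scripts/acceptance.R` re-runs the same computations from scratch at
comparable sizes.

# Known limitations

* Triploidy and balanced rearrangements are undetectable from binned
  depth alone, and uniparental disomy needs genotypes; none are
  attempted.
* Mosaic fractions below ~10% fall under the eligibility gate by
  design; segmental mosaics inside the R band (e.g. f = 0.2, expected
  |R| = 0.1) are uncallable under the published thresholds.
* The tier cascade is only as good as its local annotation tables; it
  is a reproducible skeleton, not a clinical classifier.
* Performance figures from the synthetic generator transfer to real
  libraries only to the extent the noise model holds (see the forward
  model section).
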