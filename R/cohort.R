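#' Cross-tabulate a cohort by two categorical variables
#'
#' Recognized variables: `result_class` (as stored), `age_group`
#' (maternal age binned <35 vs >=35), `age_decade` (<25, 25-29, 30-34,
#' 35-39, >=40), `gest_group` (gestational weeks <=12 = early vs 13-27 =
#' middle), or any column already present in the cohort table.
#'
#' @param cohort per-sample data.frame (see [simulate_cohort()]).
#' @param row_var,col_var variable names.
#' @return contingency matrix of counts.
#' @export
tabulate_cohort <- function(cohort, row_var, col_var) {
  get_var <- function(v) {
    if (v %in% names(cohort)) return(cohort[[v]])
    switch(v,
           age_group = ifelse(cohort$maternal_age_years < 35, "<35", ">=35"),
           age_decade = cut(cohort$maternal_age_years,
                            c(-Inf, 24, 29, 34, 39, Inf),
                            labels = c("<25", "25-29", "30-34", "35-39", ">=40")),
           gest_group = ifelse(cohort$gestational_weeks <= 12, "early", "middle"),
           stop("unknown variable: ", v))
  }
  table(get_var(row_var), get_var(col_var), dnn = c(row_var, col_var))
}

#' Pearson chi-square test of independence
#'
#' The uncorrected Pearson statistic `sum((O - E)^2 / E)` with expected
#' counts from the margins, `df = (r - 1) (c - 1)`, and the upper-tail
#' chi-square p-value. No continuity correction is applied (the
#' convention under which published 2x2 cohort comparisons back-calculate
#' exactly).
#'
#' @param observed r x c matrix of counts (r, c >= 2).
#' @return object of class `contingency_result`: list with `observed`,
#'   `expected`, `chi2`, `df`, `p`.
#' @examples
#' pearson_chi2(matrix(c(197, 198, 34, 68), 2))$chi2  # 8.915
#' @export
pearson_chi2 <- function(observed) {
  observed <- as.matrix(observed)
  if (nrow(observed) < 2 || ncol(observed) < 2)
    stop("need at least a 2x2 table")
  if (any(observed < 0)) stop("counts must be nonnegative")
  rs <- rowSums(observed); cs <- colSums(observed)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin")
  n <- sum(observed)
  expected <- outer(rs, cs) / n
  chi2 <- sum((observed - expected)^2 / expected)
  df <- (nrow(observed) - 1L) * (ncol(observed) - 1L)
  structure(list(observed = observed, expected = expected,
                 chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.3f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Category rates with exact fractions
#'
#' Proportion of each result class in the cohort, reported as percent to
#' 1 decimal place alongside the exact fraction.
#'
#' @param cohort per-sample data.frame with `result_class`, or a named
#'   vector/table of category counts.
#' @param total optional denominator (default: sum of counts / rows).
#' @return data.frame `category`, `count`, `total`, `percent`.
#' @export
rates <- function(cohort, total = NULL) {
  counts <- if (is.data.frame(cohort)) {
    if (!nrow(cohort)) stop("empty cohort")
    table(cohort$result_class)
  } else {
    cohort  # named vector or table of counts
  }
  if (is.null(names(counts))) stop("counts must be named")
  if (is.null(total)) total <- sum(counts)
  data.frame(category = names(counts),
             count = as.integer(counts),
             total = total,
             percent = round(100 * as.integer(counts) / total, 1),
             row.names = NULL)
}

#' Venn region cardinalities for 2-3 gene sets
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return named integer vector of disjoint region sizes; for two sets
#'   `A_only`, `both`, `B_only`; for three sets the seven regions.
#' @export
gene_set_partition <- function(sets) {
  sets <- lapply(sets, unique)
  if (length(sets) == 2L) {
    a <- sets[[1]]; b <- sets[[2]]
    out <- c(length(setdiff(a, b)), length(intersect(a, b)), length(setdiff(b, a)))
    names(out) <- c(paste0(names(sets)[1], "_only"), "both",
                    paste0(names(sets)[2], "_only"))
    return(out)
  }
  if (length(sets) == 3L) {
    a <- sets[[1]]; b <- sets[[2]]; cc <- sets[[3]]
    abc <- intersect(intersect(a, b), cc)
    ab <- setdiff(intersect(a, b), abc)
    ac <- setdiff(intersect(a, cc), abc)
    bc <- setdiff(intersect(b, cc), abc)
    out <- c(length(setdiff(a, union(b, cc))),
             length(setdiff(b, union(a, cc))),
             length(setdiff(cc, union(a, b))),
             length(ab), length(ac), length(bc), length(abc))
    nm <- names(sets)
    names(out) <- c(paste0(nm, "_only"),
                    paste(nm[1], nm[2], sep = "&"),
                    paste(nm[1], nm[3], sep = "&"),
                    paste(nm[2], nm[3], sep = "&"),
                    paste(nm, collapse = "&"))
    return(out)
  }
  stop("gene_set_partition supports 2 or 3 sets")
}
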