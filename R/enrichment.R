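#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated `term_id`,
#' `description`, then gene symbols. Duplicate genes within a term are
#' dropped. The description field may carry a category tag (`BP`, `MF`,
#' `CC`, `pathway`).
#'
#' @param path GMT file.
#' @return a `term_collection`: list of terms, each with `term_id`,
#'   `description`, `genes`.
#' @export
load_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  terms <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    list(term_id = f[1], description = f[2], genes = unique(f[-(1:2)]))
  })
  ids <- vapply(terms, `[[`, character(1), "term_id")
  if (anyDuplicated(ids)) stop("duplicate term ids in GMT")
  names(terms) <- ids
  structure(terms, class = "term_collection")
}

#' Write a term collection to GMT
#'
#' @param terms a `term_collection` (or compatible list).
#' @param path output file.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(terms, function(t)
    paste(c(t$term_id, t$description, t$genes), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted p-values, order-preserving.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation of gene sets
#'
#' For each term with `K` genes in the universe, a query of `n` genes
#' hitting `k` of them is scored by the upper-tail hypergeometric
#' probability `P(X >= k)` with `X ~ Hypergeometric(N, K, n)`, `N` the
#' universe size. P-values are Benjamini-Hochberg adjusted across tested
#' terms; results are sorted by p ascending, ties by term id. Terms are
#' intersected with the universe first; terms with no universe genes are
#' dropped.
#'
#' @param query character vector of gene symbols, a subset of `universe`.
#' @param universe character vector of background symbols.
#' @param terms a `term_collection`.
#' @param alpha significance cutoff.
#' @param use_adjusted select significant terms by adjusted p (default,
#'   as in figure-level reporting) or by raw p.
#' @return data.frame `term_id description k K n N p p_adj significant`.
#' @export
hypergeom_enrich <- function(query, universe, terms, alpha = 0.05,
                             use_adjusted = TRUE) {
  universe <- unique(universe)
  query <- unique(query)
  if (!length(universe)) stop("empty universe")
  if (length(setdiff(query, universe)))
    stop("query genes missing from universe: ",
         paste(utils::head(setdiff(query, universe), 3), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(terms, function(t) {
    g <- intersect(t$genes, universe)
    K <- length(g)
    if (!K) return(NULL)
    k <- length(intersect(g, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = t$term_id, description = t$description,
               k = k, K = K, n = n, N = N, p = p)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term_id = character(), description = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), p_adj = numeric(),
                      significant = logical()))
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  out$significant <- if (use_adjusted) out$p_adj < alpha else out$p < alpha
  rownames(out) <- NULL
  out
}
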