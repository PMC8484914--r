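# Independent brute-force oracles. These deliberately avoid the package's
# own computational paths.

# O(n^2) arc search computing the pooled-variance t directly per pair.
oracle_max_arc <- function(x, min_seg = 1L) {
  n <- length(x)
  best <- -1; bi <- 0L; bj <- 0L
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      k <- j - i
      if (k < min_seg || (n - k) < min_seg) next
      a <- x[(i + 1):j]
      b <- x[-((i + 1):j)]
      ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
      d <- mean(a) - mean(b)
      s <- if (ss <= 0 || n <= 2) {
        if (d == 0) 0 else 1e12 * abs(d)
      } else {
        abs(d) / sqrt(ss / (n - 2) * (1 / k + 1 / (n - k)))
      }
      if (s > best + 1e-12) { best <- s; bi <- i; bj <- j }
    }
  }
  list(i = bi, j = bj, statistic = best)
}

# Exhaustive Viterbi / posteriors over all 5^n state paths.
oracle_paths <- function(x, model) {
  n <- length(x)
  grid <- as.matrix(expand.grid(rep(list(1:5), n)))[, n:1, drop = FALSE]
  logp <- apply(grid, 1L, function(path) {
    lp <- log(model$init[path[1]]) +
      stats::dnorm(x[1], model$means[path[1]], model$sigma, log = TRUE)
    if (n > 1) for (t in 2:n)
      lp <- lp + log(model$trans[path[t - 1], path[t]]) +
        stats::dnorm(x[t], model$means[path[t]], model$sigma, log = TRUE)
    lp
  })
  list(grid = grid, logp = logp)
}

oracle_viterbi <- function(x, model) {
  pp <- oracle_paths(x, model)
  model$states[pp$grid[which.max(pp$logp), ]]
}

oracle_posterior <- function(x, model) {
  pp <- oracle_paths(x, model)
  w <- exp(pp$logp - max(pp$logp))
  w <- w / sum(w)
  n <- length(x)
  post <- matrix(0, n, 5)
  for (r in seq_along(w))
    for (t in 1:n)
      post[t, pp$grid[r, t]] <- post[t, pp$grid[r, t]] + w[r]
  post
}

# Upper-tail hypergeometric by direct combinatorial summation.
oracle_hyper_p <- function(N, K, n, k) {
  xs <- k:min(K, n)
  xs <- xs[n - xs <= N - K]
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# All-pairs interval overlap scan (1 bp), sorted by gene start.
oracle_annotate <- function(event, genes) {
  hit <- genes$chrom == event$chrom &
    genes$start < event$end_bp & genes$end > event$start_bp
  g <- genes[hit, , drop = FALSE]
  g$symbol[order(g$start)]
}
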