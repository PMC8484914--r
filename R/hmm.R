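#' Five-state copy-number HMM
#'
#' States are integer copy numbers 0..4 with Gaussian emissions on the R
#' scale centered at `(CN - 2) / 2` (so -1, -0.5, 0, +0.5, +1) and a
#' shared emission sd. Transitions keep the current state with
#' probability `p_stay` and move to each other state with equal share of
#' the remainder; the chain starts in CN = 2 with mass `1 - eps`. The
#' default `p_stay = 0.999` encodes an expected segment length of ~10 Mb
#' at 10 kb bins, matching the aneuploidy-dominated signal of
#' products-of-conception samples.
#'
#' @param sigma emission standard deviation (> 0), typically from
#'   [fit_sigma()].
#' @param p_stay self-transition probability in (0, 1).
#' @param eps initial-distribution mass spread over the non-diploid
#'   states.
#' @return an `hmm_model` list with `states`, `means`, `sigma`,
#'   `trans` (5x5), `init`.
#' @export
hmm_model <- function(sigma = 0.1, p_stay = 0.999, eps = 1e-3) {
  if (sigma <= 0) stop("sigma must be positive")
  if (p_stay <= 0 || p_stay >= 1) stop("p_stay must be in (0, 1)")
  states <- 0:4
  trans <- matrix((1 - p_stay) / 4, 5, 5)
  diag(trans) <- p_stay
  init <- rep(eps / 4, 5)
  init[3] <- 1 - eps
  structure(list(states = states, means = (states - 2) / 2,
                 sigma = sigma, trans = trans, init = init),
            class = "hmm_model")
}

# Preference order for tie-breaking: CN = 2 first, then lower CN.
.cn_pref <- c(3L, 1L, 2L, 4L, 5L)  # state indices for CN 2, 0, 1, 3, 4

#' Viterbi decoding of per-bin copy-number states
#'
#' Maximum-probability state path in log space, per chromosome
#' independently, over usable bins only (unusable bins get `NA`). Ties
#' are broken toward CN = 2, then toward the lower copy number.
#'
#' @param profile a `depth_profile`.
#' @param model an [hmm_model()].
#' @return integer vector of decoded CN per bin (NA on masked bins).
#' @export
viterbi_decode <- function(profile, model) {
  stopifnot(inherits(profile, "depth_profile"), inherits(model, "hmm_model"))
  out <- rep(NA_integer_, nrow(profile))
  for (ch in unique(profile$chrom)) {
    idx <- which(profile$chrom == ch & profile$usable)
    if (!length(idx)) next
    out[idx] <- viterbi_path(profile$R[idx], model)
  }
  out
}

viterbi_path <- function(x, model) {
  n <- length(x)
  if (n == 0L) stop("empty chromosome")
  lt <- log(model$trans)
  emis <- function(t) stats::dnorm(x[t], model$means, model$sigma, log = TRUE)
  delta <- log(model$init) + emis(1)
  back <- matrix(0L, nrow = n, ncol = 5)
  if (n > 1L) for (t in 2:n) {
    nxt <- numeric(5)
    for (s in 1:5) {
      cand <- delta + lt[, s]
      best <- pick_pref(cand)
      back[t, s] <- best
      nxt[s] <- cand[best]
    }
    delta <- nxt + emis(t)
  }
  path <- integer(n)
  path[n] <- pick_pref(delta)
  if (n > 1L) for (t in (n - 1):1) path[t] <- back[t + 1L, path[t + 1L]]
  model$states[path]
}

# argmax with CN-2-then-lower-CN preference on exact ties
pick_pref <- function(v) {
  m <- max(v)
  .cn_pref[which(v[.cn_pref] >= m - 1e-12)][1]
}

#' Posterior state probabilities by the forward-backward algorithm
#'
#' Log-sum-exp stabilized; per chromosome over usable bins. Rows
#' (usable bins) sum to 1.
#'
#' @inheritParams viterbi_decode
#' @return matrix `n_bins x 5` of posteriors (NA rows on masked bins),
#'   columns named by CN 0..4.
#' @export
forward_backward <- function(profile, model) {
  stopifnot(inherits(profile, "depth_profile"), inherits(model, "hmm_model"))
  out <- matrix(NA_real_, nrow(profile), 5,
                dimnames = list(NULL, paste0("CN", 0:4)))
  for (ch in unique(profile$chrom)) {
    idx <- which(profile$chrom == ch & profile$usable)
    if (!length(idx)) next
    out[idx, ] <- fb_posterior(profile$R[idx], model)
  }
  out
}

fb_posterior <- function(x, model) {
  n <- length(x)
  if (n == 0L) stop("empty chromosome")
  lt <- log(model$trans)
  le <- vapply(seq_len(n),
               function(t) stats::dnorm(x[t], model$means, model$sigma, log = TRUE),
               numeric(5))  # 5 x n
  fwd <- matrix(-Inf, n, 5)
  fwd[1, ] <- log(model$init) + le[, 1]
  if (n > 1L) for (t in 2:n)
    for (s in 1:5)
      fwd[t, s] <- logsumexp(fwd[t - 1L, ] + lt[, s]) + le[s, t]
  bwd <- matrix(0, n, 5)
  if (n > 1L) for (t in (n - 1):1)
    for (s in 1:5)
      bwd[t, s] <- logsumexp(lt[s, ] + le[, t + 1L] + bwd[t + 1L, ])
  lp <- fwd + bwd
  post <- exp(lp - apply(lp, 1L, logsumexp))
  post / rowSums(post)
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' Robust emission-sd estimate from putatively euploid bins
#'
#' `sigma = 1.4826 * MAD` of R restricted to bins with `|R| < 0.2` (the
#' diploid reference band), floored at `1e-3`; robust to a moderate
#' fraction of event bins.
#'
#' @param profile a `depth_profile`.
#' @param min_bins minimum usable bins required (default 100).
#' @param floor lower bound on the estimate.
#' @return numeric sigma.
#' @export
fit_sigma <- function(profile, min_bins = 100L, floor = 1e-3) {
  r <- profile$R[profile$usable]
  if (length(r) < min_bins) stop("too few usable bins to estimate sigma")
  r <- r[abs(r) < 0.2]
  if (!length(r)) stop("no bins inside the reference band")
  max(stats::mad(r, center = stats::median(r)), floor)
}
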