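# MCMC convergence diagnostics: rank-normalized split-Rhat and bulk/tail
# effective sample size, following the rank-normalization scheme of the
# modern Rhat literature. Inputs are draws x chains matrices.

.split_chains <- function(x) {
  x <- as.matrix(x)
  half <- nrow(x) %/% 2L
  x <- x[seq_len(2L * half), , drop = FALSE]
  cbind(x[seq_len(half), , drop = FALSE],
        x[half + seq_len(half), , drop = FALSE])
}

.rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  matrix(z, nrow(x), ncol(x))
}

# classic potential-scale-reduction on an already transformed draws matrix
.rhat_basic <- function(z) {
  n <- nrow(z); M <- ncol(z)
  W <- mean(apply(z, 2, stats::var))
  B <- n * stats::var(colMeans(z))
  if (!is.finite(W) || W < 1e-300) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# biased autocovariance (lag 0..n-1) via FFT
.acov <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  L <- 2^ceiling(log2(2L * n))
  f <- stats::fft(c(x, rep(0, L - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / L
  ac / n
}

# combined-chain ESS with Geyer's initial monotone sequence
.ess_basic <- function(z) {
  n <- nrow(z); M <- ncol(z); S <- n * M
  if (n < 4L) return(NA_real_)
  acov <- vapply(seq_len(M), function(m) .acov(z[, m]), numeric(n))
  chain_var <- acov[1, ] * n / (n - 1)
  W <- mean(chain_var)
  B <- if (M > 1L) n * stats::var(colMeans(z)) else 0
  var_plus <- W * (n - 1) / n + B / n
  if (!is.finite(var_plus) || var_plus < 1e-300) return(NA_real_)
  rho <- 1 - (W - rowMeans(acov)) / var_plus   # rho[t+1] = lag-t correlation
  max_pairs <- (n - 1) %/% 2L
  P <- numeric(0)
  for (k in seq_len(max_pairs)) {
    pk <- rho[2 * k - 1] + rho[2 * k]          # lags 2(k-1) and 2k-1
    if (pk <= 0) break
    if (k > 1L && pk > P[k - 1]) pk <- P[k - 1]  # enforce monotone decrease
    P[k] <- pk
  }
  tau <- if (length(P)) -1 + 2 * sum(P) else 1
  tau <- max(tau, 1 / log10(S))
  S / tau
}

#' Rank-normalized split-Rhat
#'
#' Potential-scale-reduction statistic computed on rank-normalized split
#' chains: each chain is halved, all draws are converted to normal scores of
#' their pooled ranks, and the classic between/within comparison is applied.
#' Being rank-based, the statistic is invariant under strictly monotone
#' transformations of the draws.
#'
#' @param x numeric matrix of posterior draws, one column per chain (at
#'   least 2 chains, 4 draws each).
#' @return Scalar Rhat; `NA` with a warning when the draws are constant.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("split_rhat needs at least 2 chains")
  if (nrow(x) < 4L) stop("split_rhat needs at least 4 draws per chain")
  if (stats::sd(x) < 1e-300 || !is.finite(stats::sd(x))) {
    warning("zero-variance draws: split-Rhat undefined, returning NA")
    return(NA_real_)
  }
  .rhat_basic(.rank_normalize(.split_chains(x)))
}

#' Bulk effective sample size
#'
#' Effective number of independent draws for location summaries, computed on
#' rank-normalized split chains with a paired autocorrelation sum truncated
#' by the initial monotone sequence rule. Independent draws give an estimate
#' close to the nominal draw count; antithetic chains may exceed it.
#'
#' @inheritParams split_rhat
#' @return Scalar ESS estimate; `NA` with a warning for constant draws.
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  if (stats::sd(x) < 1e-300 || !is.finite(stats::sd(x))) {
    warning("zero-variance draws: ESS undefined, returning NA")
    return(NA_real_)
  }
  .ess_basic(.rank_normalize(.split_chains(x)))
}

#' Tail effective sample size
#'
#' Minimum of the effective sample sizes of the 5% and 95% quantile
#' indicators, measuring sampling efficiency in the distribution tails.
#'
#' @inheritParams split_rhat
#' @return Scalar ESS estimate; `NA` with a warning for constant draws.
#' @export
ess_tail <- function(x) {
  x <- as.matrix(x)
  if (stats::sd(x) < 1e-300 || !is.finite(stats::sd(x))) {
    warning("zero-variance draws: ESS undefined, returning NA")
    return(NA_real_)
  }
  ess_q <- function(p) {
    ind <- (x <= stats::quantile(x, p, names = FALSE)) * 1.0
    if (stats::sd(ind) < 1e-300) return(NA_real_)
    .ess_basic(.split_chains(matrix(ind, nrow(x), ncol(x))))
  }
  min(ess_q(0.05), ess_q(0.95), na.rm = TRUE)
}

#' Convergence report for a GPCM fit
#'
#' Per-parameter rank-normalized split-Rhat and bulk/tail ESS over all item
#' parameters, person parameters, and free correlations, plus an overall
#' pass flag (`max Rhat < rhat_max` and `min ESS > ess_min`).
#'
#' @param fit an `ers_fit` object from [fit_gpcm()].
#' @param rhat_max,ess_min thresholds for the pass flag; defaults come from
#'   the fit's own config.
#' @return Object of class `ers_convergence`: data frame `parameters` plus
#'   scalars `max_rhat`, `min_ess_bulk`, `min_ess_tail`, `pass`.
#' @export
convergence_report <- function(fit, rhat_max = NULL, ess_min = NULL) {
  cfg <- fit$config
  rhat_max <- rhat_max %||% cfg$rhat_max
  ess_min <- ess_min %||% cfg$ess_min
  mats <- .fit_param_matrices(fit)
  res <- lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    if (stats::sd(m) < 1e-12)
      return(data.frame(parameter = nm, rhat = NA_real_,
                        ess_bulk = NA_real_, ess_tail = NA_real_))
    data.frame(parameter = nm, rhat = split_rhat(m),
               ess_bulk = ess_bulk(m), ess_tail = ess_tail(m))
  })
  tab <- do.call(rbind, res)
  max_rhat <- suppressWarnings(max(tab$rhat, na.rm = TRUE))
  min_eb <- suppressWarnings(min(tab$ess_bulk, na.rm = TRUE))
  min_et <- suppressWarnings(min(tab$ess_tail, na.rm = TRUE))
  structure(list(parameters = tab, max_rhat = max_rhat,
                 min_ess_bulk = min_eb, min_ess_tail = min_et,
                 pass = is.finite(max_rhat) && max_rhat < rhat_max &&
                   min(min_eb, min_et) > ess_min),
            class = "ers_convergence")
}

#' @export
print.ers_convergence <- function(x, ...) {
  cat(sprintf("<ers_convergence> max Rhat %.4f, min bulk ESS %.0f, min tail ESS %.0f, pass: %s\n",
              x$max_rhat, x$min_ess_bulk, x$min_ess_tail, x$pass))
  invisible(x)
}

# draws x chains matrix per scalar parameter
.fit_param_matrices <- function(fit) {
  ch <- fit$chain
  chains <- sort(unique(ch))
  per_chain <- function(v) vapply(chains, function(cc) v[ch == cc],
                                  numeric(sum(ch == chains[1])))
  out <- list()
  K <- dim(fit$draws$alpha)[2]
  for (i in seq_len(K)) out[[paste0("alpha[", i, "]")]] <-
      per_chain(fit$draws$alpha[, i])
  cf <- dim(fit$draws$intercepts)[3]
  for (i in seq_len(K)) for (j in seq_len(cf))
    out[[paste0("d[", i, ",", j + 1, "]")]] <-
      per_chain(fit$draws$intercepts[, i, j])
  N <- dim(fit$draws$theta)[2]; V <- dim(fit$draws$theta)[3]
  for (n in seq_len(N)) for (v in seq_len(V))
    out[[paste0("theta[", n, ",", v, "]")]] <-
      per_chain(fit$draws$theta[, n, v])
  if (V > 1L)
    for (a in seq_len(V - 1)) for (b in (a + 1):V)
      out[[paste0("corr[", a, ",", b, "]")]] <-
        per_chain(fit$draws$corr[, a, b])
  out
}
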