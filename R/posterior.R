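#' MCMC configuration for the Bayesian GPCM
#'
#' Priors follow the package's estimation model: traits are standard normal
#' (multivariate with an estimated correlation matrix under a uniform
#' LKJ(1)-type prior when V > 1), slopes are `Normal(1, sd = sqrt(5))`
#' (diffuse, deliberately not truncated to positive values), and the free
#' cumulative intercepts are independent `Normal(0, sd = sqrt(5))`.
#'
#' @param n_chains number of chains (at least 2; default 2).
#' @param n_burnin burn-in iterations per chain (default 1000). Proposal
#'   scales adapt only during burn-in.
#' @param n_sampling retained iterations per chain (default 2000).
#' @param seed integer seed; every fit is deterministic given the seed.
#' @param slope_prior_mean,slope_prior_sd slope prior (default 1, sqrt(5)).
#' @param intercept_prior_sd prior sd of free intercepts (default sqrt(5)).
#' @param rhat_max,ess_min convergence thresholds (defaults 1.01 and 400).
#' @param max_retries on a failed convergence check the sampling length is
#'   doubled and the seed advanced, at most this many times (default 2).
#' @return Object of class `mcmc_config` (a named list).
#' @export
mcmc_config <- function(n_chains = 2L, n_burnin = 1000L, n_sampling = 2000L,
                        seed = 1L, slope_prior_mean = 1,
                        slope_prior_sd = sqrt(5),
                        intercept_prior_sd = sqrt(5),
                        rhat_max = 1.01, ess_min = 400, max_retries = 2L) {
  if (n_chains < 2L) stop("need at least 2 chains for split-chain diagnostics")
  if (n_burnin < 1L || n_sampling < 1L) stop("iteration counts must be >= 1")
  structure(list(n_chains = as.integer(n_chains),
                 n_burnin = as.integer(n_burnin),
                 n_sampling = as.integer(n_sampling),
                 seed = as.integer(seed),
                 slope_prior_mean = slope_prior_mean,
                 slope_prior_sd = slope_prior_sd,
                 intercept_prior_sd = intercept_prior_sd,
                 rhat_max = rhat_max, ess_min = ess_min,
                 max_retries = as.integer(max_retries)),
            class = "mcmc_config")
}

#' Fit the Bayesian GPCM by MCMC
#'
#' Adaptive random-walk Metropolis-within-blocks sampler for the
#' (multidimensional) GPCM: person traits given item parameters, item
#' parameters given traits, and (for V > 1) the trait correlation matrix
#' given the traits, with a uniform prior over positive-definite correlation
#' matrices. The scale is identified by the standard-normal trait prior;
#' slopes are not sign-constrained. Slopes are initialized at +1, and any
#' residual reflection of a dimension (majority-negative slopes within a
#' chain) is flipped post hoc and logged.
#'
#' Convergence is assessed with rank-normalized split-Rhat and bulk/tail ESS
#' on every scalar parameter; on failure the fit is retried with doubled
#' sampling length (see [mcmc_config()]). A fit that still fails is returned
#' with `convergence$pass == FALSE` and a warning, never discarded.
#'
#' @param data an `ers_responses` object.
#' @param dim_of_item integer vector mapping items to dimensions (default:
#'   unidimensional).
#' @param config an [mcmc_config()].
#' @param fix_items optional list with elements `slopes` (length K) and
#'   `intercepts` (K x (n_cat-1) free intercepts, or K x n_cat with the zero
#'   column): item parameters are then held fixed and only persons (and the
#'   correlation) are sampled.
#' @return Object of class `ers_fit`: draws (`theta` T x N x V array,
#'   `alpha` T x K, `intercepts` T x K x (n_cat-1), `corr` T x V x V), chain
#'   labels, the convergence report, the config as used, reflection log, and
#'   the data.
#' @export
fit_gpcm <- function(data, dim_of_item = NULL, config = mcmc_config(),
                     fix_items = NULL) {
  stopifnot(inherits(data, "ers_responses"))
  K <- ncol(data$responses)
  dim_of_item <- as.integer(dim_of_item %||% rep(1L, K))
  if (length(dim_of_item) != K) stop("dim_of_item must have one entry per item")
  V <- max(dim_of_item)
  if (!setequal(unique(dim_of_item), seq_len(V)))
    stop("dim_of_item must use dimensions 1..V")

  cfg <- config
  attempt <- 0L
  repeat {
    fit <- .fit_gpcm_once(data, dim_of_item, V, cfg, fix_items)
    fit$convergence <- convergence_report(fit)
    if (fit$convergence$pass || attempt >= cfg$max_retries) break
    attempt <- attempt + 1L
    cfg$n_sampling <- 2L * cfg$n_sampling
    cfg$seed <- cfg$seed + 1L
  }
  fit$retries <- attempt
  if (!fit$convergence$pass)
    warning(sprintf("GPCM fit did not pass convergence checks after %d retries (max Rhat %.3f)",
                    attempt, fit$convergence$max_rhat))
  fit
}

.fit_gpcm_once <- function(data, dim_of_item, V, cfg, fix_items) {
  resp <- data$responses
  N <- nrow(resp); K <- ncol(resp); cc <- data$n_cat
  resp0 <- resp - 1L          # internal scores 0..c-1, NA preserved
  est_items <- is.null(fix_items)
  if (est_items) {
    alpha_fix <- rep(1, K)
    d_fix <- matrix(0, K, cc - 1L)
  } else {
    alpha_fix <- as.numeric(fix_items$slopes)
    d_fix <- as.matrix(fix_items$intercepts)
    if (ncol(d_fix) == cc) d_fix <- d_fix[, -1, drop = FALSE]
    stopifnot(length(alpha_fix) == K, nrow(d_fix) == K)
  }
  set.seed(cfg$seed)
  raw <- cpp_fit_gpcm(resp0, dim_of_item - 1L, V, cc,
                      cfg$n_chains, cfg$n_burnin, cfg$n_sampling,
                      cfg$slope_prior_mean, cfg$slope_prior_sd,
                      cfg$intercept_prior_sd,
                      est_items, alpha_fix, d_fix, V > 1L)
  T_tot <- cfg$n_chains * cfg$n_sampling
  theta <- array(raw$theta, dim = c(T_tot, N, V))  # stored person-major
  alpha <- raw$alpha
  # intercepts are stored item-major (item i, category j at column i*cf+j),
  # so reshape category-first and permute to draws x items x categories
  darr <- aperm(array(raw$d, dim = c(T_tot, cc - 1L, K)), c(1, 3, 2))
  corr <- aperm(array(raw$corr, dim = c(T_tot, V, V)), c(1, 3, 2))
  chain <- raw$chain

  # post-hoc reflection fix: per chain and dimension, flip when the median
  # slope of that dimension's items is negative
  reflections <- character(0)
  if (est_items) {
    for (ch in unique(chain)) {
      rows <- chain == ch
      for (v in seq_len(V)) {
        items_v <- which(dim_of_item == v)
        if (stats::median(alpha[rows, items_v]) < 0) {
          alpha[rows, items_v] <- -alpha[rows, items_v]
          theta[rows, , v] <- -theta[rows, , v]
          # cumulative intercepts are invariant under (alpha, theta) ->
          # (-alpha, -theta) since they multiply x * alpha * theta jointly
          reflections <- c(reflections,
                           sprintf("chain %d dimension %d flipped", ch, v))
        }
      }
    }
  }

  structure(list(draws = list(theta = theta, alpha = alpha,
                              intercepts = darr, corr = corr),
                 chain = chain, config = cfg, data = data,
                 dim_of_item = dim_of_item, V = V, n_cat = cc,
                 accept = raw$accept, reflections = reflections),
            class = "ers_fit")
}

#' @export
print.ers_fit <- function(x, ...) {
  cat(sprintf("<ers_fit> %d draws (%d chains), N=%d, K=%d, V=%d\n",
              length(x$chain), x$config$n_chains, dim(x$draws$theta)[2],
              dim(x$draws$alpha)[2], x$V))
  if (!is.null(x$convergence)) print(x$convergence)
  invisible(x)
}

#' Posterior-predictive replicated datasets
#'
#' For each requested posterior draw, samples a full replicated response
#' matrix from the GPCM category probabilities at that draw. Missing cells of
#' the template stay missing in every replicate (the missingness pattern is
#' replicated exactly). Deterministic given `seed`.
#'
#' Materializing all draws can be memory-heavy; [run_ppc()] consumes
#' replicates draw-by-draw instead and only needs this function for small
#' problems and cross-checks.
#'
#' @param fit an `ers_fit`.
#' @param template an `ers_responses` giving the missingness pattern
#'   (default: the fitted data).
#' @param draw_indices which draws to replicate (default all).
#' @param seed RNG seed.
#' @return List of `ers_responses` replicates, one per draw.
#' @export
replicate_datasets <- function(fit, template = fit$data, draw_indices = NULL,
                               seed = 1L) {
  draw_indices <- draw_indices %||% seq_along(fit$chain)
  resp0 <- template$responses - 1L
  cc <- template$n_cat
  K <- ncol(resp0)
  set.seed(seed)
  lapply(draw_indices, function(t) {
    r <- cpp_replicate_one(as.numeric(fit$draws$theta[t, , ]),
                           fit$draws$alpha[t, ],
                           matrix(fit$draws$intercepts[t, , ], K, cc - 1L),
                           fit$dim_of_item - 1L, resp0, cc, fit$V)
    response_matrix(r$rep, n_cat = cc, person_ids = template$person_ids,
                    item_ids = template$item_ids)
  })
}
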