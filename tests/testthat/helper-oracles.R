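# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: probabilities are built by explicit
# enumeration of the unnormalized terms, PPC quantities by materializing
# every replicate in plain R.

# brute-force GPCM category probabilities: form the c unnormalized terms
# exp(cumulative sums of slope*(theta - tau_j)) explicitly and normalize
oracle_gpcm_probs <- function(theta, slope, tau) {
  cc <- length(tau) + 1L
  terms <- numeric(cc)
  terms[1] <- exp(0)
  for (x in seq_len(cc - 1L)) {
    terms[x + 1L] <- exp(sum(slope * (theta - tau[seq_len(x)])))
  }
  terms / sum(terms)
}

# cell-by-cell log-likelihood oracle
oracle_loglik <- function(resp, slopes, taus, theta) {
  ll <- 0
  for (n in seq_len(nrow(resp))) for (i in seq_len(ncol(resp))) {
    if (is.na(resp[n, i])) next
    p <- oracle_gpcm_probs(theta[n], slopes[i], taus[[i]])
    ll <- ll + log(p[resp[n, i]])
  }
  ll
}

# explicit-tree enumeration of the four branch products
oracle_tree_probs <- function(theta, ers, item) {
  pn <- function(m) {
    eta <- item$sub_slopes[m] * theta[item$dimension] +
      item$ers_slopes[m] * ers + item$d[m]
    1 / (1 + exp(-eta))
  }
  p1 <- pn(1); p2 <- pn(2); p3 <- pn(3)
  c((1 - p1) * (1 - p2), (1 - p1) * p2, p1 * (1 - p3), p1 * p3)
}

# naive PPC oracle: materializes the given replicates and recomputes every
# PPP family in plain R, with its own expected-count computation
oracle_ppc <- function(resp, reps, theta_draws, alpha_draws, d_draws,
                       dim_of_item, n_cat) {
  N <- nrow(resp); Tn <- length(reps)
  n_obs <- rowSums(!is.na(resp))
  ne_obs <- rowSums(resp == 1 | resp == n_cat, na.rm = TRUE)
  er_obs <- ne_obs / n_obs
  E <- matrix(0, Tn, N)
  ne_rep <- matrix(0, Tn, N)
  for (t in seq_len(Tn)) {
    for (n in seq_len(N)) {
      for (i in seq_len(ncol(resp))) {
        if (is.na(resp[n, i])) next
        th <- theta_draws[t, n, dim_of_item[i]]
        d_free <- d_draws[t, i, ]
        terms <- c(0, seq_len(n_cat - 1L) * alpha_draws[t, i] * th + d_free)
        p <- exp(terms - max(terms)); p <- p / sum(p)
        E[t, n] <- E[t, n] + p[1] + p[n_cat]
      }
      ne_rep[t, n] <- sum(reps[[t]][n, ] == 1 | reps[[t]][n, ] == n_cat,
                          na.rm = TRUE)
    }
  }
  ppp_er <- sapply(seq_len(N), function(n)
    mean((ne_rep[, n] > ne_obs[n]) + 0.5 * (ne_rep[, n] == ne_obs[n])))
  d_obs <- sweep(-E, 2, ne_obs, "+")^2
  d_rep <- (ne_rep - E)^2
  ppp_d <- colMeans(d_rep >= d_obs)
  er_rep <- sweep(ne_rep, 2, n_obs, "/")
  list(ppp_er = ppp_er, ppp_d = ppp_d,
       group_ppp_d = mean(rowSums(d_rep) >= rowSums(d_obs)),
       group_ppp_er = mean(apply(er_rep, 1, var) >= var(er_obs)),
       mean_E = colMeans(E))
}

# small fixed GPCM item set used by several tests
toy_items <- function(K = 6, slope = 1.2) {
  list(slopes = rep(slope, K),
       taus = lapply(seq_len(K), function(i)
         c(-1, 0, 1) + seq(-0.5, 0.5, length.out = K)[i]))
}

# data drawn from a known GPCM (independent of the package's samplers)
draw_gpcm_data <- function(N, items, seed) {
  set.seed(seed)
  theta <- rnorm(N)
  K <- length(items$slopes)
  resp <- matrix(NA_integer_, N, K)
  for (i in seq_len(K)) {
    for (n in seq_len(N)) {
      p <- oracle_gpcm_probs(theta[n], items$slopes[i], items$taus[[i]])
      resp[n, i] <- sample.int(4, 1, prob = p)
    }
  }
  list(resp = resp, theta = theta)
}

# fake ers_fit object around externally supplied draws
fake_fit <- function(data, theta_draws, alpha_draws, d_draws,
                     dim_of_item = NULL, n_chains = 2L) {
  Tn <- dim(theta_draws)[1]
  K <- dim(alpha_draws)[2]
  V <- dim(theta_draws)[3]
  structure(list(
    draws = list(theta = theta_draws, alpha = alpha_draws,
                 intercepts = d_draws, corr = array(diag(V), c(Tn, V, V))),
    chain = rep(seq_len(n_chains), each = Tn / n_chains),
    config = mcmc_config(), data = data,
    dim_of_item = dim_of_item %||% rep(1L, K), V = V,
    n_cat = data$n_cat), class = "ers_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
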