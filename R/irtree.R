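# IRTree data-generating model for four-category items. A response is the
# outcome of three binary pseudo-decisions (nodes), each a logistic model in
# the substantive trait(s) and a person ERS value:
#   node 1: agree (categories 3/4) vs disagree (1/2)   — ERS slope 0
#   node 2: within disagree, mild (2) vs strong (1)    — ERS slope negative
#   node 3: within agree, strong (4) vs mild (3)       — ERS slope positive
# Positive ERS therefore inflates both extreme categories and never moves
# the agree/disagree split.

#' IRTree item parameters
#'
#' Node intercepts follow the convention `d_m = -sub_slope_m * b_m` where
#' `b_m` is the node difficulty on the item's substantive dimension (the ERS
#' trait carries no difficulty). An item-specific staggering constant
#' `e_value` and a global `shift` are added to all three node difficulties.
#'
#' @param sub_slopes substantive slopes of nodes 1-3 (defaults
#'   `c(1.9, 1.1, 1.1)`: equal in nodes 2 and 3).
#' @param ers_slopes ERS slopes of nodes 1-3 (defaults `c(0, -1.4, 1.4)`:
#'   zero in node 1, equal magnitude and opposite sign in nodes 2 and 3).
#' @param base_difficulties mean node difficulties (defaults `c(0, -1, 1)`,
#'   giving balanced items).
#' @param e_value per-item difficulty stagger added to all nodes (default
#'   0).
#' @param shift global difficulty shift added to all nodes (default 0).
#' @param dimension substantive dimension the item loads on (default 1).
#' @return Object of class `tree_item`: slopes, intercepts `d`, difficulty
#'   vector, dimension.
#' @export
tree_item_params <- function(sub_slopes = c(1.9, 1.1, 1.1),
                             ers_slopes = c(0, -1.4, 1.4),
                             base_difficulties = c(0, -1, 1),
                             e_value = 0, shift = 0, dimension = 1L) {
  stopifnot(length(sub_slopes) == 3L, length(ers_slopes) == 3L,
            length(base_difficulties) == 3L)
  if (ers_slopes[1] != 0)
    stop("ERS must not influence the agree/disagree node (slope 0 in node 1)")
  if (abs(ers_slopes[2] + ers_slopes[3]) > 1e-12)
    stop("ERS slopes in nodes 2 and 3 must have equal magnitude, opposite sign")
  if (abs(sub_slopes[2] - sub_slopes[3]) > 1e-12)
    stop("substantive slopes in nodes 2 and 3 must be equal")
  b <- base_difficulties + e_value + shift
  structure(list(sub_slopes = sub_slopes, ers_slopes = ers_slopes,
                 difficulties = b, d = -sub_slopes * b,
                 dimension = as.integer(dimension)),
            class = "tree_item")
}

#' Single-node response probability
#'
#' Logistic probability of the node's "1" outcome:
#' `plogis(sub_slope * theta_v + ers_slope * ers + d)`, where `theta_v` is
#' the trait on the item's dimension.
#'
#' @param theta substantive trait value(s); a scalar, or a vector over
#'   dimensions from which `dimension` selects.
#' @param ers person ERS value.
#' @param sub_slope,ers_slope,d node parameters.
#' @param dimension which entry of `theta` the item loads on.
#' @return Probability in (0, 1).
#' @export
node_probability <- function(theta, ers, sub_slope, ers_slope, d,
                             dimension = 1L) {
  if (!all(is.finite(c(theta, ers, sub_slope, ers_slope, d))))
    stop("node_probability needs finite inputs")
  stats::plogis(sub_slope * theta[dimension] + ers_slope * ers + d)
}

#' IRTree category probabilities
#'
#' Products of node probabilities along the four branches of the response
#' tree; always sums to 1.
#'
#' @param theta substantive trait vector (length >= item's dimension).
#' @param ers person ERS value.
#' @param item a `tree_item`.
#' @return Probability vector of length 4 `(cat1, cat2, cat3, cat4)`.
#' @export
tree_category_probabilities <- function(theta, ers, item) {
  p1 <- node_probability(theta, ers, item$sub_slopes[1], item$ers_slopes[1],
                         item$d[1], item$dimension)
  p2 <- node_probability(theta, ers, item$sub_slopes[2], item$ers_slopes[2],
                         item$d[2], item$dimension)
  p3 <- node_probability(theta, ers, item$sub_slopes[3], item$ers_slopes[3],
                         item$d[3], item$dimension)
  c((1 - p1) * (1 - p2),   # strong disagree
    (1 - p1) * p2,         # mild disagree
    p1 * (1 - p3),         # mild agree
    p1 * p3)               # strong agree
}

#' Trait-marginal category probabilities of a tree item
#'
#' Integrates the category probabilities over a standard-normal substantive
#' trait (the item's single relevant dimension) at a fixed ERS value, by
#' quadrature on a fine equally spaced grid with normalized normal weights.
#' With the defaults the quadrature error is far below 1e-6. The default
#' balanced item gives approximately `(0.2, 0.3, 0.3, 0.2)` and an exact
#' agree-side mass of 0.5.
#'
#' @param item a `tree_item`.
#' @param ers fixed ERS value (default 0).
#' @param n_quad number of grid points (default 4001).
#' @param range half-width of the integration grid (default 10 prior sds).
#' @return Probability vector of length 4.
#' @export
marginal_category_probabilities <- function(item, ers = 0, n_quad = 4001L,
                                            range = 10) {
  g <- seq(-range, range, length.out = n_quad)
  w <- stats::dnorm(g)
  w <- w / sum(w)
  p <- vapply(g, function(th) tree_category_probabilities(th, ers, item),
              numeric(4))
  as.numeric(p %*% w)
}

#' Sample discrete ERS values
#'
#' Independent draws from the ERS grid with probabilities proportional to
#' the standard-normal density at each grid value.
#'
#' @param n number of persons.
#' @param grid ERS grid (default `seq(-3, 3, by = 0.5)`).
#' @param seed optional RNG seed.
#' @return Numeric vector of grid values.
#' @export
sample_ers_values <- function(n, grid = seq(-3, 3, by = 0.5), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pr <- stats::dnorm(grid)
  sample(grid, n, replace = TRUE, prob = pr / sum(pr))
}

#' Simulation condition
#'
#' One cell of the simulation design: test length `K` (12, 24, 48 in the
#' study grid), dimension count `V` (1 or 4; the combination V = 4, K = 12
#' is excluded), difficulty shift (0 or -1), sample size (250), and the
#' generator constants (node slopes, base difficulties, e-value range, ERS
#' grid).
#'
#' @param K number of items; must be divisible by `V`.
#' @param V number of substantive dimensions.
#' @param shift difficulty shift added to all node difficulties of all
#'   items.
#' @param N sample size (default 250).
#' @param replications replications of the cell at full scale (default
#'   200).
#' @param sub_slopes,ers_slopes,base_difficulties generator constants, see
#'   [tree_item_params()].
#' @param e_range range of the per-item difficulty stagger (default
#'   `c(-0.5, 0.5)`, endpoints included).
#' @param ers_grid discrete ERS grid for experimental data.
#' @return Object of class `condition_spec`.
#' @export
condition_spec <- function(K, V = 1L, shift = 0, N = 250L,
                           replications = 200L,
                           sub_slopes = c(1.9, 1.1, 1.1),
                           ers_slopes = c(0, -1.4, 1.4),
                           base_difficulties = c(0, -1, 1),
                           e_range = c(-0.5, 0.5),
                           ers_grid = seq(-3, 3, by = 0.5)) {
  K <- as.integer(K); V <- as.integer(V); N <- as.integer(N)
  if (V == 4L && K == 12L)
    stop("the combination V = 4, K = 12 is not part of the design")
  if (K %% V != 0L) stop("K must be divisible by V")
  structure(list(K = K, V = V, shift = shift, N = N,
                 replications = as.integer(replications),
                 sub_slopes = sub_slopes, ers_slopes = ers_slopes,
                 base_difficulties = base_difficulties, e_range = e_range,
                 ers_grid = ers_grid),
            class = "condition_spec")
}

#' Build the item set of a condition
#'
#' K items with e-values equally spaced over `e_range` (endpoints included)
#' assigned in ascending item order, the condition's shift applied to every
#' item, and dimensions assigned in contiguous blocks of K/V items.
#'
#' @param spec a [condition_spec()].
#' @return List of `tree_item` objects, length K.
#' @export
build_condition_items <- function(spec) {
  e <- if (spec$K == 1L) mean(spec$e_range) else
    seq(spec$e_range[1], spec$e_range[2], length.out = spec$K)
  dims <- rep(seq_len(spec$V), each = spec$K %/% spec$V)
  lapply(seq_len(spec$K), function(i)
    tree_item_params(sub_slopes = spec$sub_slopes,
                     ers_slopes = spec$ers_slopes,
                     base_difficulties = spec$base_difficulties,
                     e_value = e[i], shift = spec$shift,
                     dimension = dims[i]))
}

#' Generate a synthetic dataset from the IRTree model
#'
#' Traits are multivariate standard normal with identity correlation; the
#' ERS value is zero for every person under `type = "null"` and drawn from
#' the discrete grid (normal-density weights) under `type =
#' "experimental"`. Responses are sampled item-by-item from the tree
#' category probabilities. Fully reproducible given `seed`.
#'
#' @param spec a [condition_spec()].
#' @param type `"null"` or `"experimental"`.
#' @param seed RNG seed.
#' @return Object of class `sim_dataset`: `data` (`ers_responses`), `theta`
#'   (N x V), `ers` (length N), `items`, `dim_of_item`, `spec`, `type`,
#'   `seed`.
#' @export
generate_dataset <- function(spec, type = c("null", "experimental"),
                             seed = 1L) {
  type <- match.arg(type)
  set.seed(seed)
  items <- build_condition_items(spec)
  N <- spec$N; K <- spec$K; V <- spec$V
  theta <- matrix(stats::rnorm(N * V), N, V)
  ers <- if (type == "null") rep(0, N) else
    sample_ers_values(N, grid = spec$ers_grid)
  resp <- matrix(NA_integer_, N, K)
  for (i in seq_len(K)) {
    it <- items[[i]]
    p1 <- stats::plogis(it$sub_slopes[1] * theta[, it$dimension] +
                          it$ers_slopes[1] * ers + it$d[1])
    p2 <- stats::plogis(it$sub_slopes[2] * theta[, it$dimension] +
                          it$ers_slopes[2] * ers + it$d[2])
    p3 <- stats::plogis(it$sub_slopes[3] * theta[, it$dimension] +
                          it$ers_slopes[3] * ers + it$d[3])
    agree <- stats::runif(N) < p1
    extreme_dis <- stats::runif(N) >= p2   # node 2 outcome 0 -> category 1
    extreme_agr <- stats::runif(N) < p3    # node 3 outcome 1 -> category 4
    resp[, i] <- ifelse(agree, ifelse(extreme_agr, 4L, 3L),
                        ifelse(extreme_dis, 1L, 2L))
  }
  structure(list(data = response_matrix(resp, n_cat = 4L),
                 theta = theta, ers = ers, items = items,
                 dim_of_item = vapply(items, `[[`, 1L, "dimension"),
                 spec = spec, type = type, seed = seed),
            class = "sim_dataset")
}

#' Write a simulated dataset to disk
#'
#' Responses as wide CSV, per-person truth (trait values and ERS) as CSV,
#' and the condition as a YAML echo.
#'
#' @param sim a `sim_dataset`.
#' @param prefix output path prefix.
#' @export
write_sim_dataset <- function(sim, prefix) {
  write_responses(sim$data, paste0(prefix, "_responses.csv"))
  truth <- data.frame(person = sim$data$person_ids, sim$theta,
                      ers = sim$ers)
  names(truth)[1 + seq_len(ncol(sim$theta))] <-
    paste0("theta", seq_len(ncol(sim$theta)))
  utils::write.csv(truth, paste0(prefix, "_truth.csv"), row.names = FALSE)
  spec <- sim$spec
  yaml::write_yaml(c(unclass(spec), list(type = sim$type, seed = sim$seed)),
                   paste0(prefix, "_condition.yaml"))
  invisible(prefix)
}

#' Maximum category-curve gap between a tree item and its best GPCM proxy
#'
#' With the ERS trait fixed at zero the tree item is practically equivalent
#' to a GPCM item. This finds the GPCM item (slope and three thresholds)
#' minimizing the mean squared category-probability difference over a trait
#' grid, and returns the maximum absolute per-category gap at the optimum.
#'
#' @param item a `tree_item`, or a 4 x `length(theta_grid)` matrix of
#'   target category curves (e.g. from a GPCM item, for degenerate
#'   cross-checks).
#' @param theta_grid trait grid (default `seq(-4, 4, by = 0.05)`).
#' @param tol acceptance tolerance stored alongside the result (default
#'   0.05).
#' @return List: `max_gap`, `within_tol`, `alpha`, `tau`, `mse`.
#' @export
ccc_max_difference <- function(item, theta_grid = seq(-4, 4, by = 0.05),
                               tol = 0.05) {
  target <- if (is.matrix(item)) item else
    vapply(theta_grid,
           function(th) tree_category_probabilities(th, 0, item),
           numeric(4))
  stopifnot(ncol(target) == length(theta_grid), nrow(target) == 4L)
  obj <- function(par) {
    pr <- vapply(theta_grid,
                 function(th) category_probabilities(th, par[1], par[2:4]),
                 numeric(4))
    mean((pr - target)^2)
  }
  fit <- stats::optim(c(1.5, -1, 0, 1), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  pr <- vapply(theta_grid,
               function(th) category_probabilities(th, fit$par[1],
                                                   fit$par[2:4]),
               numeric(4))
  gap <- max(abs(pr - target))
  list(max_gap = gap, within_tol = gap <= tol, alpha = fit$par[1],
       tau = fit$par[2:4], mse = fit$value)
}
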