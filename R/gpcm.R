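#' Ordinal response matrix
#'
#' Container for an N persons x K items matrix of ordinal responses coded
#' `1..n_cat` externally, with `NA` marking missing cells. All model code in
#' the package scores categories `0..n_cat-1` internally; this constructor is
#' the single place where the external 1-based coding is validated.
#'
#' @param responses integer matrix (persons x items); values in `1..n_cat` or
#'   `NA`.
#' @param n_cat number of response categories (at least 3; default 4).
#' @param person_ids,item_ids optional labels; defaults are taken from
#'   dimnames or generated (`P1..`, `I1..`).
#' @return An object of class `ers_responses`: a list with elements
#'   `responses` (integer matrix with `NA`s), `n_cat`, `person_ids`,
#'   `item_ids`.
#' @examples
#' x <- response_matrix(rbind(c(1, 4, 2, 3), c(2, NA, 3, 3)))
#' x$n_cat
#' @export
response_matrix <- function(responses, n_cat = 4L, person_ids = NULL,
                            item_ids = NULL) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  n_cat <- as.integer(n_cat)
  if (nrow(responses) < 1L || ncol(responses) < 1L)
    stop("need at least one person and one item")
  if (n_cat < 3L) stop("n_cat must be at least 3")
  obs <- responses[!is.na(responses)]
  bad <- obs < 1L | obs > n_cat
  if (any(bad)) {
    idx <- which(!is.na(responses) & (responses < 1L | responses > n_cat),
                 arr.ind = TRUE)[1, ]
    stop(sprintf("response out of range 1..%d at person %d, item %d",
                 n_cat, idx[1], idx[2]))
  }
  if (is.null(person_ids))
    person_ids <- rownames(responses) %||% paste0("P", seq_len(nrow(responses)))
  if (is.null(item_ids))
    item_ids <- colnames(responses) %||% paste0("I", seq_len(ncol(responses)))
  dimnames(responses) <- list(person_ids, item_ids)
  structure(list(responses = responses, n_cat = n_cat,
                 person_ids = person_ids, item_ids = item_ids),
            class = "ers_responses")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ers_responses <- function(x, ...) {
  cat(sprintf("<ers_responses> %d persons x %d items, %d categories, %.1f%% missing\n",
              nrow(x$responses), ncol(x$responses), x$n_cat,
              100 * mean(is.na(x$responses))))
  invisible(x)
}

#' Missingness mask of a response matrix
#'
#' @param x an `ers_responses` object.
#' @return Logical matrix, `TRUE` where the response is absent.
#' @export
missing_mask <- function(x) is.na(x$responses)

#' GPCM item parameters
#'
#' Bundles slopes and cumulative category intercepts for K items, the
#' item-to-dimension map for multidimensional fits, and the trait correlation
#' matrix. The intercept for the first (lowest) category is fixed at zero for
#' every item; `intercepts` therefore has `n_cat` columns whose first column
#' is all zeros. Equivalently the item can be described by `n_cat - 1`
#' thresholds (see [thresholds_to_intercepts()]).
#'
#' @param slopes numeric vector of item slopes (one per item).
#' @param intercepts K x n_cat matrix of cumulative intercepts, first column
#'   zero; or K x (n_cat-1) matrix of the free intercepts.
#' @param dim_of_item integer vector mapping items to dimensions (default all
#'   1).
#' @param trait_correlation V x V correlation matrix (default identity).
#' @return Object of class `gpcm_params`.
#' @export
gpcm_params <- function(slopes, intercepts, dim_of_item = NULL,
                        trait_correlation = NULL) {
  slopes <- as.numeric(slopes)
  K <- length(slopes)
  intercepts <- as.matrix(intercepts)
  if (nrow(intercepts) != K) stop("intercepts must have one row per item")
  if (all(abs(intercepts[, 1]) < 1e-12) && ncol(intercepts) > 2) {
    # full form with the fixed zero column present
    free <- intercepts[, -1, drop = FALSE]
  } else {
    free <- intercepts
  }
  dim_of_item <- as.integer(dim_of_item %||% rep(1L, K))
  if (length(dim_of_item) != K) stop("dim_of_item must have one entry per item")
  V <- max(dim_of_item)
  if (!setequal(unique(dim_of_item), seq_len(V)))
    stop("dim_of_item must use dimensions 1..V")
  trait_correlation <- trait_correlation %||% diag(V)
  trait_correlation <- as.matrix(trait_correlation)
  if (!isTRUE(all.equal(trait_correlation, t(trait_correlation))) ||
      any(abs(diag(trait_correlation) - 1) > 1e-8))
    stop("trait_correlation must be symmetric with unit diagonal")
  if (min(eigen(trait_correlation, symmetric = TRUE,
                only.values = TRUE)$values) <= 0)
    stop("trait_correlation must be positive definite")
  structure(list(slopes = slopes,
                 intercepts = cbind(0, free),
                 dim_of_item = dim_of_item, V = V,
                 trait_correlation = trait_correlation,
                 n_cat = ncol(free) + 1L),
            class = "gpcm_params")
}

#' GPCM category probabilities (threshold form)
#'
#' Probability of each of the `c = length(thresholds) + 1` ordered categories
#' under the generalized partial credit model, for a scalar trait value. The
#' probability of internal score `x` is proportional to
#' `exp(sum_{j<=x} slope * (theta - tau_j))`, with the empty sum for the
#' lowest category. Evaluated on the log scale with the running maximum
#' subtracted, so linear predictors of magnitude up to about 40 are handled
#' without overflow.
#'
#' @param theta scalar trait value.
#' @param slope item slope.
#' @param thresholds numeric vector of `c - 1` thresholds.
#' @return Numeric probability vector of length `c`, summing to 1.
#' @examples
#' category_probabilities(0, 1, c(-1, 0, 1))
#' @export
category_probabilities <- function(theta, slope, thresholds) {
  if (!all(is.finite(c(theta, slope, thresholds))))
    stop("theta, slope and thresholds must be finite")
  d <- thresholds_to_intercepts(thresholds, slope)
  category_probabilities_d(theta, slope, d[-1])
}

# intercept-form kernel: d_free = intercepts for scores 1..c-1 (score 0 is 0)
category_probabilities_d <- function(theta, slope, d_free) {
  cc <- length(d_free) + 1L
  eta <- c(0, (seq_len(cc - 1L)) * slope * theta + d_free)
  eta <- eta - max(eta)
  p <- exp(eta)
  p / sum(p)
}

#' Convert GPCM thresholds to cumulative intercepts
#'
#' The threshold form `exp(sum_j slope*(theta - tau_j))` and the intercept
#' form `exp(x*slope*theta + d_x)` describe the same model with
#' `d_x = -slope * sum_{j<=x} tau_j` and `d_0 = 0`. The intercept form is
#' used internally for numerical convenience.
#'
#' @param thresholds numeric vector of `c - 1` thresholds.
#' @param slope item slope.
#' @return Cumulative intercept vector of length `c`, first entry 0.
#' @seealso [intercepts_to_thresholds()]
#' @export
thresholds_to_intercepts <- function(thresholds, slope) {
  c(0, -slope * cumsum(thresholds))
}

#' Convert cumulative intercepts back to thresholds
#'
#' @param intercepts cumulative intercept vector of length `c` (first entry
#'   0).
#' @param slope item slope; must be nonzero unless all intercepts are zero.
#' @return Threshold vector of length `c - 1`.
#' @export
intercepts_to_thresholds <- function(intercepts, slope) {
  if (abs(intercepts[1]) > 1e-12)
    stop("first cumulative intercept must be 0")
  if (slope == 0) {
    if (any(abs(intercepts) > 1e-12))
      stop("thresholds are undefined for slope 0 with nonzero intercepts")
    return(rep(0, length(intercepts) - 1L))
  }
  -diff(intercepts) / slope
}

#' GPCM log-likelihood
#'
#' Sum of log category probabilities over all non-missing cells; missing
#' cells contribute nothing (ignorable missingness).
#'
#' @param data an `ers_responses` object.
#' @param params a `gpcm_params` object.
#' @param theta N x V matrix (or length-N vector when V = 1) of trait values.
#' @return Scalar log-likelihood (non-positive).
#' @export
gpcm_loglik <- function(data, params, theta) {
  theta <- as.matrix(theta)
  resp <- data$responses
  N <- nrow(resp); K <- ncol(resp)
  if (nrow(theta) != N || ncol(theta) != params$V)
    stop("theta must be N x V")
  if (length(params$slopes) != K) stop("params cover a different item count")
  cc <- data$n_cat
  if (params$n_cat != cc) stop("category counts of data and params disagree")
  ll <- 0
  for (i in seq_len(K)) {
    v <- params$dim_of_item[i]
    d_free <- params$intercepts[i, -1]
    obs <- which(!is.na(resp[, i]))
    for (n in obs) {
      p <- category_probabilities_d(theta[n, v], params$slopes[i], d_free)
      ll <- ll + log(p[resp[n, i]])
    }
  }
  ll
}
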