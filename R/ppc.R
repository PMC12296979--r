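#' PPC flagging cutoffs
#'
#' Defaults: the two-sided proportion check flags a person when its PPP value
#' leaves `[er_low, er_high]` = `[.05, .95]`; the one-sided discrepancy check
#' flags below `d_cut = .1`; group-level checks flag below `group_cut = .1`.
#'
#' @param er_low,er_high two-sided person cutoffs for the extreme-proportion
#'   PPP value.
#' @param d_cut one-sided person cutoff for the discrepancy PPP value.
#' @param group_cut one-sided cutoff for both group-level PPP values.
#' @return Named list of cutoffs.
#' @export
ppc_cutoffs <- function(er_low = 0.05, er_high = 0.95, d_cut = 0.1,
                        group_cut = 0.1) {
  list(er_low = er_low, er_high = er_high, d_cut = d_cut,
       group_cut = group_cut)
}

#' Observed proportion of extreme responses
#'
#' Share of a person's non-missing responses that sit in the lowest or
#' highest category.
#'
#' @param responses integer vector of one person's responses (1-based
#'   coding, `NA` missing).
#' @param n_cat number of categories.
#' @return Proportion in `[0, 1]`; `NA` with a warning when every response
#'   is missing.
#' @examples
#' extreme_proportion(c(1, 4, 2, 3), 4)  # 0.5
#' @export
extreme_proportion <- function(responses, n_cat = 4L) {
  obs <- responses[!is.na(responses)]
  if (length(obs) == 0L) {
    warning("all responses missing: extreme proportion undefined")
    return(NA_real_)
  }
  mean(obs == 1L | obs == n_cat)
}

#' Person-level PPP value for the extreme-response proportion
#'
#' Mean over draws of `I(rep > obs) + 0.5 * I(rep == obs)`: replicated
#' proportions strictly above the observed count as 1, ties as one half
#' (a deliberate conservative correction for the discreteness of the
#' statistic). Because a person's observed-item count is identical across
#' replicates, passing integer extreme *counts* for `obs` and `rep` makes
#' the tie test exact with no floating-point tolerance; [run_ppc()] does so.
#'
#' @param obs observed statistic (count or proportion) of one person.
#' @param rep numeric vector of the replicated statistic over draws, on the
#'   same scale as `obs`.
#' @return PPP value in `[0, 1]`.
#' @examples
#' person_ppp_er(2, c(1, 2, 2, 3))  # (1 + .5 + .5 + 0)/4 = 0.5
#' @export
person_ppp_er <- function(obs, rep) {
  stopifnot(length(rep) >= 1L)
  mean((rep > obs) + 0.5 * (rep == obs))
}

#' Expected number of extreme responses at one posterior draw
#'
#' Sum over a person's observed items of the GPCM probability of the bottom
#' or top category at the given draw. Missing items are excluded so that the
#' expectation is commensurable with the person's observed extreme count.
#'
#' @param theta person trait values at the draw (length V).
#' @param slopes item slopes at the draw (length K).
#' @param intercepts K x (n_cat-1) free cumulative intercepts at the draw.
#' @param dim_of_item item-to-dimension map.
#' @param observed logical vector, `TRUE` for the person's non-missing
#'   items.
#' @param n_cat number of categories.
#' @return Expected extreme count in `[0, sum(observed)]`.
#' @export
expected_extreme_count <- function(theta, slopes, intercepts, dim_of_item,
                                   observed, n_cat = 4L) {
  theta <- as.numeric(theta)
  s <- 0
  for (i in which(observed)) {
    p <- category_probabilities_d(theta[dim_of_item[i]], slopes[i],
                                  intercepts[i, ])
    s <- s + p[1] + p[n_cat]
  }
  s
}

#' Person-level PPP value for the squared extreme-count discrepancy
#'
#' The discrepancy at draw t is the squared difference between an extreme
#' count and its model-expected value at that draw. The PPP value is the
#' proportion of draws where the replicated discrepancy is at least the
#' observed one; the check is one-sided, so exact ties count fully.
#'
#' @param ne_obs observed extreme count of the person.
#' @param ne_rep replicated extreme counts over draws (length T).
#' @param expected expected extreme counts over draws (length T).
#' @return PPP value in `[0, 1]`.
#' @examples
#' person_ppp_d(4, c(3, 4, 5, 6), c(2, 2, 2, 2))  # D_obs = 4 each draw
#' @export
person_ppp_d <- function(ne_obs, ne_rep, expected) {
  stopifnot(length(ne_rep) == length(expected), length(ne_rep) >= 1L)
  mean((ne_rep - expected)^2 >= (ne_obs - expected)^2)
}

#' Group-level PPP value for the summed discrepancy
#'
#' Proportion of draws where the sum over persons of the replicated squared
#' discrepancies is at least the sum of the observed ones.
#'
#' @param d_obs,d_rep T x N matrices of per-draw, per-person squared
#'   discrepancies (or length-T vectors of their person sums).
#' @return PPP value in `[0, 1]`.
#' @export
group_ppp_d <- function(d_obs, d_rep) {
  if (is.matrix(d_obs)) d_obs <- rowSums(d_obs)
  if (is.matrix(d_rep)) d_rep <- rowSums(d_rep)
  stopifnot(length(d_obs) == length(d_rep))
  mean(d_rep >= d_obs)
}

#' Group-level PPP value for the variance of extreme proportions
#'
#' Individual differences in ERS inflate the spread of per-person extreme
#' proportions without necessarily moving their mean, so the group check
#' compares the variance (sample variance, denominator N-1) of the observed
#' proportions to that of each replicate. One-sided: the PPP value tends to
#' zero under ERS.
#'
#' @param er_obs length-N vector of observed extreme proportions.
#' @param er_rep T x N matrix of replicated proportions (or length-T vector
#'   of precomputed replicate variances).
#' @return PPP value in `[0, 1]`.
#' @export
group_ppp_er <- function(er_obs, er_rep) {
  v_obs <- stats::var(er_obs)
  v_rep <- if (is.matrix(er_rep)) apply(er_rep, 1, stats::var) else er_rep
  mean(v_rep >= v_obs)
}

#' Classify person-level ERS flags with direction
#'
#' The two-sided proportion check flags H-ERS (more observed extremes than
#' replicated) below `er_low` and L-ERS above `er_high`. The one-sided
#' discrepancy check flags below `d_cut`; its direction is read from the
#' mean (over draws) expected extreme count versus the observed count:
#' below the observed count means H-ERS, above means L-ERS, exact equality
#' is reported as indeterminate.
#'
#' @param ppp_er,ppp_d person PPP values.
#' @param ne_obs observed extreme count.
#' @param mean_expected mean over draws of the expected extreme count.
#' @param cutoffs a [ppc_cutoffs()] list.
#' @return List with `flag_er` and `flag_d`, each one of `"H-ERS"`,
#'   `"L-ERS"`, `"none"` (and `"indeterminate"` for `flag_d`).
#' @export
classify_flags <- function(ppp_er, ppp_d, ne_obs, mean_expected,
                           cutoffs = ppc_cutoffs()) {
  flag_er <- if (ppp_er < cutoffs$er_low) "H-ERS"
    else if (ppp_er > cutoffs$er_high) "L-ERS" else "none"
  flag_d <- "none"
  if (ppp_d < cutoffs$d_cut) {
    flag_d <- if (mean_expected < ne_obs) "H-ERS"
      else if (mean_expected > ne_obs) "L-ERS" else "indeterminate"
  }
  list(flag_er = flag_er, flag_d = flag_d)
}

#' Run all posterior predictive checks
#'
#' Single pass over the posterior draws: for each draw one replicated
#' dataset is sampled (missingness preserved), and the four PPP families
#' are accumulated — person-level extreme-proportion and discrepancy checks,
#' and their group-level aggregates. Replicates are consumed draw-by-draw
#' and never materialized unless `materialize = TRUE`, which computes the
#' identical quantities from fully stored replicates (used as an internal
#' cross-check).
#'
#' Ties in the proportion check are decided on integer extreme counts, which
#' share each person's observed-item denominator, so tie detection is exact.
#' Persons with no observed responses are excluded with a warning.
#'
#' @param data the observed `ers_responses`.
#' @param fit the `ers_fit` for `data`.
#' @param seed RNG seed for replicate sampling.
#' @param cutoffs a [ppc_cutoffs()] list.
#' @param materialize store every replicate and compute from the stored
#'   matrices instead of streaming (identical results; memory-heavy).
#' @return Object of class `ers_ppc`: `person` data frame (id, er_obs,
#'   ne_obs, n_obs, ppp_er, ppp_d, mean_expected_ne, flag_er, flag_d),
#'   `group` list (ppp_er, ppp_d, flag_er, flag_d), `n_draws`, `cutoffs`,
#'   `seed`.
#' @export
run_ppc <- function(data, fit, seed = 1L, cutoffs = ppc_cutoffs(),
                    materialize = FALSE) {
  resp <- data$responses
  cc <- data$n_cat
  N <- nrow(resp); K <- ncol(resp)
  n_obs <- rowSums(!is.na(resp))
  keep <- n_obs > 0L
  if (!all(keep))
    warning(sprintf("%d person(s) with no observed responses excluded from PPCs",
                    sum(!keep)))
  ne_obs <- rowSums(resp == 1L | resp == cc, na.rm = TRUE)
  er_obs <- ifelse(keep, ne_obs / n_obs, NA_real_)
  var_obs <- stats::var(er_obs[keep])
  T_tot <- length(fit$chain)
  resp0 <- resp - 1L
  dim0 <- fit$dim_of_item - 1L

  gt <- eq <- dge <- sumE <- numeric(N)
  grp_d <- grp_er <- 0
  reps <- if (materialize) vector("list", T_tot) else NULL
  Emat <- if (materialize) matrix(0, T_tot, N) else NULL

  set.seed(seed)
  for (t in seq_len(T_tot)) {
    r <- cpp_replicate_one(as.numeric(fit$draws$theta[t, , ]),
                           fit$draws$alpha[t, ],
                           matrix(fit$draws$intercepts[t, , ], K, cc - 1L),
                           dim0, resp0, cc, fit$V)
    if (materialize) { reps[[t]] <- r$rep; Emat[t, ] <- r$E; next }
    ne_rep <- r$ne_rep; E <- r$E
    gt <- gt + (ne_rep > ne_obs)
    eq <- eq + (ne_rep == ne_obs)
    d_obs_t <- (ne_obs - E)^2
    d_rep_t <- (ne_rep - E)^2
    dge <- dge + (d_rep_t >= d_obs_t)
    sumE <- sumE + E
    grp_d <- grp_d + (sum(d_rep_t[keep]) >= sum(d_obs_t[keep]))
    grp_er <- grp_er +
      (stats::var((ne_rep / n_obs)[keep]) >= var_obs)
  }

  if (materialize) {
    for (t in seq_len(T_tot)) {
      rm_t <- reps[[t]]
      ne_rep <- rowSums(rm_t == 1L | rm_t == cc, na.rm = TRUE)
      E <- Emat[t, ]
      gt <- gt + (ne_rep > ne_obs)
      eq <- eq + (ne_rep == ne_obs)
      d_obs_t <- (ne_obs - E)^2
      d_rep_t <- (ne_rep - E)^2
      dge <- dge + (d_rep_t >= d_obs_t)
      sumE <- sumE + E
      grp_d <- grp_d + (sum(d_rep_t[keep]) >= sum(d_obs_t[keep]))
      grp_er <- grp_er +
        (stats::var((ne_rep / n_obs)[keep]) >= var_obs)
    }
  }

  ppp_er <- (gt + 0.5 * eq) / T_tot
  ppp_d <- dge / T_tot
  mean_E <- sumE / T_tot
  flags <- lapply(which(keep), function(n)
    classify_flags(ppp_er[n], ppp_d[n], ne_obs[n], mean_E[n], cutoffs))
  person <- data.frame(person = data$person_ids[keep],
                       er_obs = er_obs[keep], ne_obs = ne_obs[keep],
                       n_obs = n_obs[keep], ppp_er = ppp_er[keep],
                       ppp_d = ppp_d[keep],
                       mean_expected_ne = mean_E[keep],
                       flag_er = vapply(flags, `[[`, "", "flag_er"),
                       flag_d = vapply(flags, `[[`, "", "flag_d"),
                       stringsAsFactors = FALSE)
  group <- list(ppp_er = grp_er / T_tot, ppp_d = grp_d / T_tot,
                flag_er = grp_er / T_tot < cutoffs$group_cut,
                flag_d = grp_d / T_tot < cutoffs$group_cut)
  structure(list(person = person, group = group, n_draws = T_tot,
                 cutoffs = cutoffs, seed = seed),
            class = "ers_ppc")
}

#' @export
print.ers_ppc <- function(x, ...) {
  cat(sprintf("<ers_ppc> %d draws, %d persons; group PPP_ER = %.3f, PPP_D = %.3f\n",
              x$n_draws, nrow(x$person), x$group$ppp_er, x$group$ppp_d))
  cat(sprintf("  person flags: ER %d, D %d\n",
              sum(x$person$flag_er != "none"),
              sum(x$person$flag_d != "none")))
  invisible(x)
}

#' Write PPC results to tidy CSV with a JSON sidecar
#'
#' Writes the per-person table and a one-row group table, plus a JSON
#' sidecar echoing seed, cutoffs and draw count.
#'
#' @param ppc an `ers_ppc` object.
#' @param prefix output path prefix; files `<prefix>_person.csv`,
#'   `<prefix>_group.csv`, `<prefix>_meta.json` are written.
#' @export
write_ppc <- function(ppc, prefix) {
  utils::write.csv(ppc$person, paste0(prefix, "_person.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(ppp_er = ppc$group$ppp_er,
                              ppp_d = ppc$group$ppp_d,
                              flag_er = ppc$group$flag_er,
                              flag_d = ppc$group$flag_d),
                   paste0(prefix, "_group.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = ppc$seed, cutoffs = ppc$cutoffs,
                            n_draws = ppc$n_draws),
                       paste0(prefix, "_meta.json"), auto_unbox = TRUE)
  invisible(prefix)
}
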