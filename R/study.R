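#' Run one simulation condition
#'
#' For each replication: generate a dataset from the IRTree model, fit the
#' GPCM by MCMC, run all posterior predictive checks, and record group-level
#' flags and per-person flags together with the true ERS values. Replication
#' seeds are derived from the master seed by a counter scheme
#' (`seed + 1000003 * replication`), so any subset of replications can be
#' rerun independently and results are reproducible from the master seed
#' alone. Replications whose fit fails the convergence check are kept and
#' marked, never dropped; aggregates are reported both including and
#' excluding them.
#'
#' Desk-scale defaults use shortened chains with relaxed diagnostics; `full
#' _scale = TRUE` switches to the study-length chains (2 x 1000 burn-in +
#' 2000 sampling, Rhat < 1.01, ESS > 400) and the condition's full
#' replication count.
#'
#' @param spec a [condition_spec()].
#' @param type `"null"` or `"experimental"`.
#' @param replications number of replications; default 10 at desk scale,
#'   `spec$replications` (200) when `full_scale = TRUE`.
#' @param seed master seed.
#' @param mcmc an [mcmc_config()] template; default depends on
#'   `full_scale`.
#' @param cutoffs a [ppc_cutoffs()] list.
#' @param full_scale run the condition at full study scale (hours of CPU).
#' @return Object of class `ers_study`: `group` data frame (one row per
#'   replication: PPP values, flags, convergence), `person` data frame (one
#'   row per person-replication: true ERS, PPP values, flags), `rates` (see
#'   [study_rates()]), the spec, type and seed.
#' @export
run_condition <- function(spec, type = c("null", "experimental"),
                          replications = NULL, seed = 1L, mcmc = NULL,
                          cutoffs = ppc_cutoffs(), full_scale = FALSE) {
  type <- match.arg(type)
  replications <- replications %||%
    (if (full_scale) spec$replications else 10L)
  mcmc <- mcmc %||% (if (full_scale)
    mcmc_config(n_burnin = 1000L, n_sampling = 2000L,
                rhat_max = 1.01, ess_min = 400)
  else
    mcmc_config(n_burnin = 400L, n_sampling = 600L,
                rhat_max = 1.1, ess_min = 50, max_retries = 1L))

  group_rows <- vector("list", replications)
  person_rows <- vector("list", replications)
  for (r in seq_len(replications)) {
    rep_seed <- (seed + 1000003 * r) %% 2147483647L
    sim <- generate_dataset(spec, type, seed = rep_seed)
    mcmc_r <- mcmc
    mcmc_r$seed <- rep_seed
    fit <- suppressWarnings(
      fit_gpcm(sim$data, dim_of_item = sim$dim_of_item, config = mcmc_r))
    ppc <- run_ppc(sim$data, fit, seed = rep_seed + 1L, cutoffs = cutoffs)
    group_rows[[r]] <- data.frame(
      replication = r, seed = rep_seed,
      ppp_er = ppc$group$ppp_er, ppp_d = ppc$group$ppp_d,
      flag_er = ppc$group$flag_er, flag_d = ppc$group$flag_d,
      converged = fit$convergence$pass,
      max_rhat = fit$convergence$max_rhat)
    person_rows[[r]] <- cbind(replication = r, ers_true = sim$ers,
                              converged = fit$convergence$pass,
                              ppc$person)
  }
  group <- do.call(rbind, group_rows)
  person <- do.call(rbind, person_rows)
  out <- structure(list(group = group, person = person, spec = spec,
                        type = type, seed = seed,
                        replications = replications,
                        cutoffs = cutoffs),
                   class = "ers_study")
  out$rates <- study_rates(out)
  out
}

#' Aggregate flag rates of a study condition
#'
#' Group level: proportion of replications flagged per PPP (FPR under the
#' null, TPR under the experimental condition). Person level: proportion of
#' persons with true ERS zero that are flagged (FPR), pooled over
#' replications, and per nonzero ERS grid value the proportion flagged
#' (TPR). Reported both over all replications and restricted to converged
#' fits.
#'
#' @param study an `ers_study`.
#' @param converged_only drop non-converged replications (default FALSE).
#' @return List: `group` (flag rates per PPP), `person_fpr`, `tpr_by_ers`
#'   data frame, `n_replications`, `n_converged`.
#' @export
study_rates <- function(study, converged_only = FALSE) {
  g <- study$group
  p <- study$person
  if (converged_only) {
    g <- g[g$converged, , drop = FALSE]
    p <- p[p$converged, , drop = FALSE]
  }
  null_p <- p[p$ers_true == 0, , drop = FALSE]
  person_fpr <- c(er = mean(null_p$flag_er != "none"),
                  d = mean(null_p$flag_d != "none"))
  tpr <- NULL
  nz <- sort(unique(p$ers_true[p$ers_true != 0]))
  if (length(nz)) {
    tpr <- do.call(rbind, lapply(nz, function(g0) {
      sub <- p[p$ers_true == g0, , drop = FALSE]
      data.frame(ers = g0, n = nrow(sub),
                 tpr_er = mean(sub$flag_er != "none"),
                 tpr_d = mean(sub$flag_d != "none"))
    }))
  }
  list(group = c(er = mean(g$flag_er), d = mean(g$flag_d)),
       person_fpr = person_fpr, tpr_by_ers = tpr,
       n_replications = nrow(g), n_converged = sum(g$converged))
}

#' Person-level TPR per ERS grid value
#'
#' @param study an `ers_study` from an experimental condition.
#' @param converged_only restrict to converged replications.
#' @return Data frame with columns `ers`, `n`, `tpr_er`, `tpr_d`, plus an
#'   asymmetry table `attr(, "asymmetry")` comparing TPR at -g and +g.
#' @export
tpr_by_ers <- function(study, converged_only = FALSE) {
  tab <- study_rates(study, converged_only)$tpr_by_ers
  if (is.null(tab)) return(NULL)
  pos <- tab[tab$ers > 0, , drop = FALSE]
  asym <- do.call(rbind, lapply(pos$ers, function(g0) {
    neg <- tab[tab$ers == -g0, , drop = FALSE]
    if (!nrow(neg)) return(NULL)
    data.frame(magnitude = g0,
               tpr_er_neg = neg$tpr_er, tpr_er_pos = pos$tpr_er[pos$ers == g0],
               tpr_d_neg = neg$tpr_d, tpr_d_pos = pos$tpr_d[pos$ers == g0])
  }))
  attr(tab, "asymmetry") <- asym
  tab
}

#' The full study condition grid
#'
#' The 10 cells of the simulation design: K in (12, 24, 48) crossed with
#' shift in (0, -1) for V = 1, and K in (24, 48) crossed with shift for
#' V = 4 (V = 4 with 12 items is excluded).
#'
#' @param N sample size per replication (default 250).
#' @param replications full-scale replication count (default 200).
#' @return List of [condition_spec()] objects.
#' @export
paper_conditions <- function(N = 250L, replications = 200L) {
  grid <- rbind(expand.grid(K = c(12L, 24L, 48L), V = 1L, shift = c(0, -1)),
                expand.grid(K = c(24L, 48L), V = 4L, shift = c(0, -1)))
  lapply(seq_len(nrow(grid)), function(i)
    condition_spec(K = grid$K[i], V = grid$V[i], shift = grid$shift[i],
                   N = N, replications = replications))
}

#' Association between ERS flags and a covariate
#'
#' Pearson chi-squared test (no continuity correction) on the 3 x L
#' contingency table of flag status (L-ERS / none / H-ERS) against a
#' covariate with L levels, with the testing alpha Bonferroni-adjusted for
#' the number of PPP families tested.
#'
#' @param flags character vector of person flags (`"L-ERS"`, `"none"`,
#'   `"H-ERS"`; `"indeterminate"` is counted as flagged but direction-less
#'   and dropped with a message).
#' @param covariate factor-like vector, same length, 2+ levels.
#' @param n_tests number of PPP families tested (default 2); the adjusted
#'   alpha `0.05 / n_tests` is echoed in the result.
#' @param alpha base alpha (default 0.05).
#' @return List: `table`, `statistic`, `df`, `p_value`, `alpha_adjusted`,
#'   `low_expected` (cells with expected count < 5).
#' @export
covariate_association <- function(flags, covariate, n_tests = 2L,
                                  alpha = 0.05) {
  keep <- flags != "indeterminate"
  if (!all(keep)) {
    message(sum(!keep), " indeterminate flag(s) dropped from the table")
    flags <- flags[keep]; covariate <- covariate[keep]
  }
  f <- factor(flags, levels = c("L-ERS", "none", "H-ERS"))
  g <- factor(covariate)
  if (nlevels(g) < 2L) stop("covariate needs at least 2 levels")
  tab <- table(f, g)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    stat <- unname(suppressWarnings(
      stats::chisq.test(tab, correct = FALSE))$statistic)
  } else {
    # empty flag rows contribute nothing; df stays fixed by the 3-row design
    stat <- sum(ifelse(expected > 0, (tab - expected)^2 / expected, 0))
  }
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(table = tab, statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       alpha_adjusted = alpha / n_tests,
       low_expected = sum(expected < 5 & expected > 0))
}
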