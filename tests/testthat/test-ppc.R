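test_that("extreme proportion counts endpoint categories over observed items", {
  expect_equal(extreme_proportion(c(1, 4, 2, 3), 4), 0.5)
  expect_equal(extreme_proportion(c(2, 3, 3, 2), 4), 0)
  # missing responses leave the denominator
  expect_equal(extreme_proportion(c(1, 4, NA, 4), 4), 1)
  expect_warning(p <- extreme_proportion(c(NA, NA), 4), "all responses missing")
  expect_true(is.na(p))
})

test_that("proportion PPP value scores ties as one half", {
  expect_equal(person_ppp_er(0.2, c(0.3, 0.4, 0.5)), 1)
  expect_equal(person_ppp_er(0.5, rep(0.5, 7)), 0.5)
  # four-draw worked example
  expect_equal(person_ppp_er(0.5, c(0.25, 0.5, 0.5, 0.75)), 0.5)
})

test_that("swapping observed and replicated roles mirrors the PPP value", {
  set.seed(4)
  for (r in 1:30) {
    K <- sample(4:12, 1)
    obs <- sample(0:K, 1)
    rep <- sample(0:K, 50, replace = TRUE)
    ppp <- person_ppp_er(obs, rep)
    swapped <- mean(vapply(rep, function(x) person_ppp_er(x, obs), 1))
    expect_equal(swapped, 1 - ppp, tolerance = 1e-12)
    expect_gte(ppp, 0); expect_lte(ppp, 1)
  }
})

test_that("expected extreme count follows the category probabilities", {
  # zero slopes: every item contributes 2/4
  K <- 12
  e <- expected_extreme_count(0, rep(0, K), matrix(0, K, 3), rep(1L, K),
                              rep(TRUE, K))
  expect_equal(e, 6)
  # bounded by the observed item count
  expect_lte(expected_extreme_count(2, rep(1.5, 5), matrix(0, 5, 3),
                                    rep(1L, 5), c(TRUE, TRUE, FALSE, TRUE, FALSE)),
             3)
  # two items against the enumeration oracle
  taus <- list(c(-1, 0, 1), c(-0.5, 0.2, 0.9))
  alph <- c(1.2, 0.8)
  dmat <- t(sapply(1:2, function(i)
    thresholds_to_intercepts(taus[[i]], alph[i])[-1]))
  want <- sum(sapply(1:2, function(i) {
    p <- oracle_gpcm_probs(0.6, alph[i], taus[[i]]); p[1] + p[4]
  }))
  expect_equal(expected_extreme_count(0.6, alph, dmat, c(1L, 1L),
                                      c(TRUE, TRUE)),
               want, tolerance = 1e-10)
})

test_that("discrepancy PPP value counts ties fully", {
  # replicated counts equal to observed every draw: tie on both sides
  expect_equal(person_ppp_d(3, rep(3, 5), c(1.2, 2, 2.5, 3.8, 3)), 1)
  # four-draw worked example: D_obs = 4, D_rep = (1, 4, 9, 16)
  expect_equal(person_ppp_d(4, c(3, 4, 5, 6), rep(2, 4)), 0.75)
  set.seed(6)
  for (r in 1:20) {
    v <- person_ppp_d(sample(0:8, 1), sample(0:8, 30, TRUE), runif(30, 0, 8))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("group discrepancy PPP reduces to the person value for N = 1", {
  ne_rep <- c(2, 5, 3, 7); E <- c(3.2, 4.1, 3.9, 5)
  ne_obs <- 4
  expect_equal(group_ppp_d(matrix((ne_obs - E)^2, 4, 1),
                           matrix((ne_rep - E)^2, 4, 1)),
               person_ppp_d(ne_obs, ne_rep, E))
  # replicated equal to observed in every draw
  d <- matrix(runif(12), 4, 3)
  expect_equal(group_ppp_d(d, d), 1)
  # 3 persons x 2 draws full enumeration
  d_obs <- rbind(c(1, 4, 2), c(2, 2, 2))
  d_rep <- rbind(c(3, 3, 2), c(1, 2, 1))
  # sums: obs (7, 6), rep (8, 4) -> indicators (1, 0)
  expect_equal(group_ppp_d(d_obs, d_rep), 0.5)
})

test_that("variance-based group PPP responds to spread, not arrangement", {
  er_obs <- c(0.1, 0.5, 0.3, 0.7, 0.2)
  # every replicate a permutation of the observed proportions
  set.seed(7)
  er_rep <- t(replicate(20, sample(er_obs)))
  expect_equal(group_ppp_er(er_obs, er_rep), 1)
  # three-draw worked example: var_obs = var(c(0.4, 0.6)) = 0.02 against
  # replicate variances (0.01, 0.02, 0.03)
  expect_equal(group_ppp_er(c(0.4, 0.6), c(0.01, 0.02, 0.03)), 2 / 3)
  # inflating observed deviations weakly decreases the PPP value
  infl <- mean(er_obs) + 2 * (er_obs - mean(er_obs))
  expect_lte(group_ppp_er(infl, er_rep), group_ppp_er(er_obs, er_rep))
})

test_that("flags carry the documented directions", {
  expect_equal(classify_flags(0.97, 0.5, 3, 3.2)$flag_er, "L-ERS")
  expect_equal(classify_flags(0.03, 0.5, 7, 2.1)$flag_er, "H-ERS")
  f <- classify_flags(0.5, 0.9, 3, 3.2)
  expect_equal(f$flag_er, "none"); expect_equal(f$flag_d, "none")
  expect_equal(classify_flags(0.5, 0.05, 7, 2.1)$flag_d, "H-ERS")
  expect_equal(classify_flags(0.5, 0.05, 2, 5.5)$flag_d, "L-ERS")
  expect_equal(classify_flags(0.5, 0.05, 4, 4)$flag_d, "indeterminate")
})

test_that("run_ppc matches a naive materializing re-implementation", {
  set.seed(123)
  N <- 5; K <- 6; Tn <- 20
  resp <- matrix(sample(c(1:4, NA), N * K, TRUE,
                        prob = c(rep(0.22, 4), 0.12)), N, K)
  resp[1, ] <- c(1, 4, 1, 4, 2, 3)  # ensure a fully observed person
  dat <- response_matrix(resp)
  theta_draws <- array(rnorm(Tn * N), c(Tn, N, 1))
  alpha_draws <- matrix(runif(Tn * K, 0.5, 2), Tn, K)
  d_draws <- array(rnorm(Tn * K * 3, sd = 0.8), c(Tn, K, 3))
  fit <- fake_fit(dat, theta_draws, alpha_draws, d_draws)

  ppc <- run_ppc(dat, fit, seed = 55)
  reps_mats <- lapply(replicate_datasets(fit, seed = 55), `[[`, "responses")
  ora <- oracle_ppc(resp, reps_mats, theta_draws, alpha_draws, d_draws,
                    rep(1L, K), 4L)
  expect_equal(ppc$person$ppp_er, ora$ppp_er, tolerance = 1e-12)
  expect_equal(ppc$person$ppp_d, ora$ppp_d, tolerance = 1e-12)
  expect_equal(ppc$person$mean_expected_ne, ora$mean_E, tolerance = 1e-8)
  expect_equal(ppc$group$ppp_d, ora$group_ppp_d, tolerance = 1e-12)
  expect_equal(ppc$group$ppp_er, ora$group_ppp_er, tolerance = 1e-12)
})

test_that("streaming and materialized PPC computations agree exactly", {
  set.seed(321)
  N <- 8; K <- 5; Tn <- 30
  resp <- matrix(sample(c(1:4, NA), N * K, TRUE,
                        prob = c(rep(0.23, 4), 0.08)), N, K)
  resp[2, ] <- 2L
  dat <- response_matrix(resp)
  fit <- fake_fit(dat, array(rnorm(Tn * N), c(Tn, N, 1)),
                  matrix(runif(Tn * K, 0.5, 2), Tn, K),
                  array(rnorm(Tn * K * 3), c(Tn, K, 3)))
  a <- run_ppc(dat, fit, seed = 9)
  b <- run_ppc(dat, fit, seed = 9, materialize = TRUE)
  expect_identical(a$person, b$person)
  expect_identical(a$group, b$group)
})

test_that("single-person datasets give group results consistent with the person", {
  set.seed(77)
  Tn <- 40; K <- 6
  resp <- matrix(c(1L, 4L, 4L, 1L, 2L, 4L), 1, K)
  dat <- response_matrix(resp)
  fit <- fake_fit(dat, array(rnorm(Tn), c(Tn, 1, 1)),
                  matrix(1.2, Tn, K), array(rnorm(Tn * K * 3), c(Tn, K, 3)))
  ppc <- run_ppc(dat, fit, seed = 2)
  # with one person the group discrepancy sum is the person discrepancy
  expect_equal(ppc$group$ppp_d, ppc$person$ppp_d[1])
})

test_that("all-missing persons are excluded with a warning", {
  resp <- rbind(c(1L, 4L, 2L), c(NA, NA, NA))
  dat <- response_matrix(resp)
  Tn <- 10
  fit <- fake_fit(dat, array(rnorm(Tn * 2), c(Tn, 2, 1)),
                  matrix(1, Tn, 3), array(0, c(Tn, 3, 3)))
  expect_warning(ppc <- run_ppc(dat, fit, seed = 3), "excluded")
  expect_equal(nrow(ppc$person), 1)
})

test_that("replication preserves the missingness pattern bitwise", {
  set.seed(31)
  N <- 6; K <- 4; Tn <- 8
  resp <- matrix(sample(c(1:4, NA), N * K, TRUE), N, K)
  resp[, 3] <- NA  # an all-missing column
  resp[1, 1] <- 1L
  dat <- response_matrix(resp)
  fit <- fake_fit(dat, array(rnorm(Tn * N), c(Tn, N, 1)),
                  matrix(1, Tn, K), array(0, c(Tn, K, 3)))
  reps <- replicate_datasets(fit, seed = 5)
  for (r in reps) {
    expect_identical(is.na(r$responses), is.na(dat$responses))
    expect_true(all(is.na(r$responses[, 3])))
  }
})

test_that("zero-slope draws replicate near-uniform category frequencies", {
  # all slopes zero: every cell uniform over 4 categories; chi-squared
  # goodness of fit over a large pooled table should not reject
  set.seed(12)
  N <- 100; K <- 20; Tn <- 50
  dat <- response_matrix(matrix(1L, N, K))
  fit <- fake_fit(dat, array(rnorm(Tn * N), c(Tn, N, 1)),
                  matrix(0, Tn, K), array(0, c(Tn, K, 3)))
  reps <- replicate_datasets(fit, seed = 6)
  counts <- table(factor(unlist(lapply(reps, `[[`, "responses")),
                         levels = 1:4))
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("replicated item frequencies are calibrated to the draw's probabilities", {
  # one fixed parameter draw replicated many times over many persons: the
  # standardized per-category frequency errors (exact heterogeneous-
  # Bernoulli standard errors) should behave like standard normal noise
  set.seed(90)
  N <- 2000; K <- 2; R <- 24
  theta <- rnorm(N)
  dat <- response_matrix(matrix(1L, N, K))
  alph <- c(1.3, 0.9)
  taus <- list(c(-1, 0, 1), c(-0.6, 0.1, 0.8))
  dmat <- t(sapply(1:2, function(i)
    thresholds_to_intercepts(taus[[i]], alph[i])[-1]))
  fit <- fake_fit(dat, array(theta, c(1, N, 1)),
                  matrix(alph, 1, K, byrow = TRUE),
                  array(dmat, c(1, K, 3)), n_chains = 1L)
  z <- NULL
  for (s in seq_len(R)) {
    rep1 <- replicate_datasets(fit, seed = s)[[1]]$responses
    for (i in 1:K) {
      pn <- vapply(theta, function(th)
        oracle_gpcm_probs(th, alph[i], taus[[i]]), numeric(4))
      pbar <- rowMeans(pn)
      for (x in 1:4) {
        se <- sqrt(sum(pn[x, ] * (1 - pn[x, ]))) / N
        z <- c(z, (mean(rep1[, i] == x) - pbar[x]) / se)
      }
    }
  }
  # 192 standardized errors: centered, unit-scale, no gross outliers
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_gt(sd(z), 0.75); expect_lt(sd(z), 1.3)
  expect_lt(max(abs(z)), 4.5)
})
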