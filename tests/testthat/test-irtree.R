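test_that("node probability is the logistic of the node linear predictor", {
  # hand arithmetic: 1.1*1 - 1.4*0.5 + 1.1 = 1.5
  expect_equal(node_probability(1, 0.5, 1.1, -1.4, 1.1), plogis(1.5))
  expect_equal(node_probability(0.3, 2, 0, 0, 0), 0.5)
  # strictly increasing in theta for positive substantive slope
  g <- seq(-3, 3, by = 0.5)
  p <- vapply(g, function(th) node_probability(th, 0, 1.1, 1.4, -0.2), 1)
  expect_true(all(diff(p) > 0))
  expect_error(node_probability(NaN, 0, 1, 1, 0), "finite")
})

test_that("tree category probabilities are branch products summing to one", {
  it <- tree_item_params()
  # balanced item at theta = 0, ers = 0: agree mass exactly one half
  p0 <- tree_category_probabilities(0, 0, it)
  expect_equal(p0[3] + p0[4], 0.5)
  expect_equal(sum(p0), 1)
  set.seed(15)
  for (r in 1:20) {
    th <- rnorm(1); ers <- rnorm(1)
    it2 <- tree_item_params(e_value = runif(1, -0.5, 0.5),
                            shift = sample(c(0, -1), 1))
    p <- tree_category_probabilities(th, ers, it2)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, oracle_tree_probs(th, ers, it2), tolerance = 1e-12)
  }
})

test_that("positive ERS inflates and negative ERS deflates the extreme mass", {
  it <- tree_item_params()
  for (th in c(-2, -0.5, 0, 1, 2.3)) {
    ext <- vapply(c(-2, -1, 0, 1, 2), function(e) {
      p <- tree_category_probabilities(th, e, it); p[1] + p[4]
    }, 1)
    expect_true(all(diff(ext) > 0))
  }
})

test_that("null tree items are reflection-symmetric", {
  it <- tree_item_params()  # default difficulties, no stagger or shift
  for (th in c(0.3, 1.2, 2.5)) {
    expect_equal(tree_category_probabilities(th, 0, it),
                 rev(tree_category_probabilities(-th, 0, it)),
                 tolerance = 1e-12)
  }
})

test_that("trait-marginal probabilities reproduce the balanced-item profile", {
  it <- tree_item_params()
  m <- marginal_category_probabilities(it)
  expect_equal(round(m, 1), c(0.2, 0.3, 0.3, 0.2))
  # node-1 difficulty zero makes the agree mass exactly one half
  expect_equal(m[3] + m[4], 0.5, tolerance = 1e-12)
  # quadrature error against a 10-fold finer grid
  m_fine <- marginal_category_probabilities(it, n_quad = 40001L)
  expect_lt(max(abs(m - m_fine)), 1e-6)
  # Monte-Carlo cross-check within 3 MC standard errors
  set.seed(19)
  th <- rnorm(2e5)
  pm <- rowMeans(vapply(th, function(t)
    tree_category_probabilities(t, 0, it), numeric(4)))
  se <- sqrt(pm * (1 - pm) / 2e5)
  expect_true(all(abs(m - pm) < 3 * se + 1e-8))
})

test_that("discrete ERS values follow normalized normal-density weights", {
  grid <- seq(-3, 3, by = 0.5)
  pr <- dnorm(grid) / sum(dnorm(grid))
  expect_equal(sum(pr), 1)
  expect_equal(pr, rev(pr))  # symmetry
  # normalization oracle: direct 13-term summation
  expect_equal(pr[grid == 0], dnorm(0) / sum(dnorm(grid)))
  expect_equal(round(pr[grid == 0], 4), 0.1997)
  set.seed(10)
  v <- sample_ers_values(5000, grid)
  expect_true(all(v %in% grid))
  expect_lt(abs(mean(v == 0) - pr[grid == 0]), 3 * sqrt(0.2 * 0.8 / 5000))
  expect_identical(sample_ers_values(50, grid, seed = 3),
                   sample_ers_values(50, grid, seed = 3))
})

test_that("condition items stagger difficulties and split dimensions in blocks", {
  s3 <- condition_spec(K = 3, V = 1, shift = 0)
  e3 <- vapply(build_condition_items(s3), function(it)
    it$difficulties[1] - 0, 1)  # node-1 base difficulty is 0, so e shows up
  expect_equal(e3, c(-0.5, 0, 0.5))
  # default item at e = 0, no shift
  it0 <- build_condition_items(s3)[[2]]
  expect_equal(it0$difficulties, c(0, -1, 1))
  # shift of -1 moves every node difficulty
  s3s <- condition_spec(K = 3, V = 1, shift = -1)
  expect_equal(build_condition_items(s3s)[[2]]$difficulties, c(-1, -2, 0))
  # contiguous dimension blocks
  s24 <- condition_spec(K = 24, V = 4)
  expect_equal(vapply(build_condition_items(s24), `[[`, 1L, "dimension"),
               rep(1:4, each = 6))
  # the excluded design cell
  expect_error(condition_spec(K = 12, V = 4), "not part of the design")
  expect_error(condition_spec(K = 10, V = 4), "divisible")
})

test_that("generated datasets are reproducible and match analytic marginals", {
  spec <- condition_spec(K = 12, V = 1, shift = 0, N = 250)
  a <- generate_dataset(spec, "null", seed = 99)
  b <- generate_dataset(spec, "null", seed = 99)
  expect_identical(a$data$responses, b$data$responses)
  expect_identical(a$theta, b$theta)
  expect_true(all(a$ers == 0))

  # pooled extreme rate against the quadrature marginal prediction
  items <- build_condition_items(spec)
  pext <- mean(vapply(items, function(it) {
    m <- marginal_category_probabilities(it); m[1] + m[4]
  }, 1))
  obs <- mean(a$data$responses == 1 | a$data$responses == 4)
  n_cells <- length(a$data$responses)
  expect_lt(abs(obs - pext), 3 * sqrt(pext * (1 - pext) / n_cells))
})

test_that("strong positive ERS yields more extremes than strong negative ERS", {
  # two-point ERS grid gives large groups at +3 and -3 in a single dataset
  spec <- condition_spec(K = 12, V = 1, shift = 0, N = 500,
                         ers_grid = c(-3, 3))
  sim <- generate_dataset(spec, "experimental", seed = 17)
  er <- rowMeans(sim$data$responses == 1 | sim$data$responses == 4)
  expect_gt(sum(sim$ers == 3), 200)
  expect_gt(mean(er[sim$ers == 3]), mean(er[sim$ers == -3]))
  expect_true(all(sim$ers %in% c(-3, 3)))
})

test_that("tree items are practically equivalent to their best GPCM proxy", {
  r <- ccc_max_difference(tree_item_params())
  expect_lt(r$max_gap, 0.05)
  expect_true(r$within_tol)
  # degenerate call: a GPCM-generated curve recovers itself
  grid <- seq(-4, 4, by = 0.05)
  target <- vapply(grid, function(th)
    category_probabilities(th, 1.3, c(-1.1, 0, 0.9)), numeric(4))
  r0 <- ccc_max_difference(target, theta_grid = grid)
  expect_lt(r0$max_gap, 1e-6)
  # optimizer beats a coarse brute-force grid search
  it <- tree_item_params(e_value = 0.25)
  coarse <- expand.grid(a = seq(0.8, 1.6, by = 0.2),
                        t1 = seq(-1.5, -0.5, by = 0.25),
                        t2 = seq(-0.5, 0.5, by = 0.25),
                        t3 = seq(0.5, 1.5, by = 0.25))
  tcur <- vapply(grid, function(th)
    tree_category_probabilities(th, 0, it), numeric(4))
  best <- min(apply(coarse, 1, function(pr) {
    pm <- vapply(grid, function(th)
      category_probabilities(th, pr[1], pr[2:4]), numeric(4))
    mean((pm - tcur)^2)
  }))
  expect_lte(ccc_max_difference(it, theta_grid = grid)$mse, best)
})

test_that("tree item parameter constraints are enforced", {
  expect_error(tree_item_params(ers_slopes = c(0.5, -1.4, 1.4)), "node 1")
  expect_error(tree_item_params(ers_slopes = c(0, -1.4, 1.2)), "opposite")
  expect_error(tree_item_params(sub_slopes = c(1.9, 1.1, 1.2)), "equal")
})
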