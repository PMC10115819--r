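test_that("energy evaluates the negated field-plus-pair sum", {
  p0 <- maxent_params(c(0, 0), matrix(0, 2, 2))
  expect_equal(energy(c(1, 1), c(1, 0.5), p0), 0)
  expect_equal(energy(c(0, 1), c(0, 0), p0), 0)

  p1 <- maxent_params(0.5, matrix(0, 1, 1))
  expect_equal(energy(1, c(0, 0), p1), -0.5)

  p2 <- maxent_params(c(-0.1, -0.1), matrix(c(0, 1, 1, 0), 2))
  expect_equal(energy(c(1, 1), c(0, 0), p2), -0.8) # pair counted once
  expect_error(energy(c(1, 1, 1), c(0, 0), p2), "components")

  # environment couplings enter through ea and es
  p3 <- maxent_params(0, matrix(0, 1, 1), g_a = 2, g_s = -1)
  expect_equal(energy(1, c(1, 0.5), p3), -(2 - 0.5))
})

test_that("energy is invariant under simultaneous component relabeling", {
  set.seed(1)
  p <- random_maxent_params(6)
  sigma <- as.numeric(runif(6) < 0.5)
  perm <- sample(6)
  pp <- maxent_params(p$h[perm], p$J[perm, perm], p$g_a[perm], p$g_s[perm])
  expect_equal(energy(sigma, c(1, 0.3), p),
               energy(sigma[perm], c(1, 0.3), pp))
})

test_that("exact distribution normalizes and matches closed-form ratios", {
  p0 <- maxent_params(c(0, 0), matrix(0, 2, 2))
  d0 <- exact_distribution(p0, c(0, 0))
  expect_equal(d0$prob, rep(0.25, 4))

  for (n in c(3, 8, 12)) {
    set.seed(n)
    d <- exact_distribution(random_maxent_params(n), c(1, 0.53))
    expect_equal(sum(d$prob), 1, tolerance = 1e-10)
  }

  p2 <- maxent_params(c(0, 0), matrix(c(0, 2, 2, 0), 2))
  d2 <- exact_distribution(p2, c(0, 0))
  i11 <- state_index(matrix(c(1, 1), 1))
  i00 <- state_index(matrix(c(0, 0), 1))
  expect_equal(d2$prob[i11] / d2$prob[i00], exp(2))

  expect_error(exact_distribution(p2, c(0, 0), kinds = c("binary", "continuous")),
               "binary components only")
})

test_that("Gibbs sampling agrees with enumeration and honors clamps", {
  set.seed(5)
  p <- random_maxent_params(5)
  d <- exact_distribution(p, c(0, 1))
  s <- gibbs_sample(p, c(0, 1), 2e4, seed = 9)
  emp <- tabulate(state_index(s), 2^5) / 2e4
  expect_lt(0.5 * sum(abs(emp - d$prob)), 0.03)

  # an uncoupled, unbiased component has marginal 1/2
  pj <- maxent_params(c(0, 1), matrix(0, 2, 2))
  sj <- gibbs_sample(pj, c(0, 0), 2e4, seed = 2)
  expect_equal(mean(sj[, 1]), 0.5, tolerance = 0.02)

  # clamped components never move
  sc <- gibbs_sample(p, c(0, 1), 500, seed = 3,
                     clamped = c(TRUE, rep(FALSE, 4)),
                     init = c(1, 0, 0, 0, 0))
  expect_true(all(sc[, 1] == 1))
})

test_that("fit recovers a matching-moments solution on simple data", {
  # one binary component present in half the samples, constant environment:
  # the matching h is 0
  vals <- matrix(rep(c(0, 1), 25), ncol = 1, dimnames = list(NULL, "x"))
  cm <- component_matrix(vals)
  em <- environment_matrix(rep(0, 50), rep(0, 50))
  fit <- fit_maxent(cm, em, maxent_control(n_iter = 1000, n_chains = 50),
                    seed = 1)
  expect_lt(abs(fit$params$h), 0.15)
  # constant environment: g blocks were not estimated and remain zero
  expect_false(any(fit$estimated))
  expect_true(all(fit$params$g_a == 0) && all(fit$params$g_s == 0))
})

test_that("moments match at convergence and the trace settles", {
  set.seed(2)
  truth <- random_maxent_params(5, limit = 0.8)
  m <- ground_truth_model(truth, environments = study_environments())
  com <- generate_community(m, 400, seed = 3)
  fit <- fit_maxent(com$components, com$env, maxent_control(), seed = 4)
  # final simulated sufficient statistics track the observed ones
  expect_lt(max(abs(fit$moments$observed$h - fit$moments$simulated$h)), 0.08)
  # smoothed trace decreases from early to late phase
  sm <- stats::filter(fit$trace, rep(1 / 200, 200), sides = 1)
  sm <- sm[!is.na(sm)]
  early <- median(sm[seq_len(500)])
  late <- median(sm[(length(sm) - 500):length(sm)])
  expect_lt(late, early)
})

test_that("degenerate components hit the h cap with a warning", {
  vals <- cbind(always = rep(1, 30), var = rep(c(0, 1), 15))
  cm <- component_matrix(vals)
  em <- environment_matrix(rep(0, 30), rep(0, 30))
  expect_warning(
    fit <- fit_maxent(cm, em, maxent_control(n_iter = 300, n_chains = 20),
                      seed = 1),
    "always absent or always present")
  expect_lte(abs(fit$params$h["always"]), 10)
})

test_that("p-values respect the resolution floor and the unit interval", {
  # a strong coupling on a small system: every bootstrap estimate has the
  # same sign, so p lands exactly on the 1/(n_reps + 1) floor
  p <- maxent_params(c(0, 0), matrix(c(0, 2.5, 2.5, 0), 2))
  m <- ground_truth_model(p, environments = list(c(0, 0)))
  com <- generate_community(m, 400, seed = 1)
  ctl <- maxent_control(n_iter = 300, n_chains = 20)
  sg <- maxent_significance(com$components, com$env, ctl,
                            n_reps = 120, seed = 2)
  expect_equal(min(sg$p_values$J[1, 2]), 1 / 121)
  flat <- unlist(sg$p_values)
  expect_true(all(flat >= 1 / 121 & flat <= 1))
  expect_warning(
    maxent_significance(com$components, com$env, ctl, n_reps = 50, seed = 3),
    "unstable")
})

test_that("parameter serialization round-trips", {
  set.seed(7)
  p <- random_maxent_params(4, names = c("a", "b", "c", "d"))
  d <- file.path(tempdir(), "params_io")
  write_maxent_params(p, d)
  q <- read_maxent_params(d)
  expect_equal(q$h, p$h)
  expect_equal(q$J, p$J)
  expect_equal(q$g_a, p$g_a)
  expect_equal(q$g_s, p$g_s)
})
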