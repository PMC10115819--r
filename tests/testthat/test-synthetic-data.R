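test_that("exact community sampler matches the analytic distribution", {
  # single free component, all params zero: presence frequency 1/2
  m1 <- ground_truth_model(maxent_params(0, matrix(0, 1, 1)))
  s1 <- generate_community(m1, 1e5, seed = 1)
  expect_equal(mean(s1$components$values), 0.5, tolerance = 0.01)

  # two components with a strong positive coupling: co-occurrence frequency
  # agrees with direct enumeration of the four states within 3 MC errors
  p2 <- maxent_params(c(0, 0), matrix(c(0, 2, 2, 0), 2))
  m2 <- ground_truth_model(p2)
  s2 <- generate_community(m2, 2e4, seed = 2)
  d <- exact_distribution(p2, c(0, 0))
  p11 <- d$prob[state_index(matrix(c(1, 1), 1))]
  emp <- mean(rowSums(s2$components$values) == 2)
  mc_se <- sqrt(p11 * (1 - p11) / 2e4)
  expect_lt(abs(emp - p11), 3 * mc_se)
})

test_that("samplers are pure functions of (arguments, seed)", {
  m <- ground_truth_model(random_maxent_params(4),
                          environments = list(c(0, 0), c(1, 1)))
  a <- generate_community(m, 50, seed = 7)
  b <- generate_community(m, 50, seed = 7)
  expect_identical(a, b)
  c <- generate_community(m, 50, seed = 8)
  expect_false(identical(a$components$values, c$components$values))
})

test_that("exact sampling stays within TV 0.02 of the analytic law (N <= 5)", {
  for (seed in 1:3) {
    set.seed(seed)
    p <- random_maxent_params(4)
    m <- ground_truth_model(p, environments = list(c(1, 0.53)))
    s <- generate_community(m, 1e5, seed = seed + 10)
    d <- exact_distribution(p, c(1, 0.53))
    emp <- tabulate(state_index(s$components$values), 2^4) / 1e5
    expect_lt(0.5 * sum(abs(emp - d$prob)), 0.02)
  }
})

test_that("exact sampling refuses continuous components", {
  m <- ground_truth_model(random_maxent_params(3),
                          component_kinds = c("binary", "binary", "continuous"))
  expect_error(generate_community(m, 10, seed = 1, method = "exact"),
               "unsupported")
  # but the Gibbs path handles them, keeping values inside [0, 1]
  s <- generate_community(m, 200, seed = 1)
  expect_true(all(s$components$values >= 0 & s$components$values <= 1))
  expect_true(all(s$components$values[, 1:2] %in% c(0, 1)))
})

test_that("mock study has the trial's design", {
  st <- generate_study(12, seed = 1)
  expect_equal(nrow(st$metadata), 36)
  expect_equal(as.integer(table(st$metadata$group)[c("CON", "EXP")]),
               c(18L, 18L))
  expect_equal(length(unique(st$metadata$animal_id[st$metadata$group == "CON"])), 6)
  # exactly one sample per animal per day
  expect_true(all(table(st$metadata$animal_id, st$metadata$day) == 1))
  expect_true(all(abs(rowSums(st$abundance) - 1) < 1e-12))
  expect_true(all(st$chemicals > 0))
  expect_error(generate_study(2, seed = 1), "at least 4")
  expect_error(generate_study(7, seed = 1), "even")
})

test_that("trial profile plants the designed treatment responses", {
  st <- generate_study(12, seed = 3)
  g <- st$metadata$group
  but <- st$chemicals[, "butyrate"]
  expect_gt(mean(but[g == "EXP"]), mean(but[g == "CON"]))
  meth <- st$abundance[, grep("Methanobrevibacter", colnames(st$abundance))]
  expect_gt(mean(meth[g == "CON"]), mean(meth[g == "EXP"]))
})

test_that("null profile removes all group effects", {
  st <- generate_study(12, seed = 4, effect_profile = "null")
  g <- st$metadata$group
  but <- log(st$chemicals[, "butyrate"])
  # group difference is pure noise; a t-test at alpha = 0.01 should not fire
  expect_gt(t.test(but[g == "EXP"], but[g == "CON"])$p.value, 0.01)
})

test_that("study export is deterministic and round-trips", {
  st <- generate_study(12, seed = 5)
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  write_study(st, d1)
  write_study(generate_study(12, seed = 5), d2)
  for (f in c("abundance.tsv", "chemicals.tsv", "metadata.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  back <- read_study(d1)
  expect_equal(unname(back$abundance), unname(st$abundance),
               tolerance = 1e-12)
  expect_equal(back$metadata$group, st$metadata$group)
})

test_that("SEM generator obeys its closed-form moments", {
  B <- matrix(0, 2, 2)
  B[2, 1] <- 1.5
  X <- generate_sem(B, "uniform", 1e4, seed = 1)
  x1 <- X[, "x1"]
  x2 <- X[, "x2"]
  # var(x2) = 1.5^2 var(x1) + var(e2), both noise variances are 1
  expect_equal(var(x2), 1.5^2 * var(x1) + 1, tolerance = 0.1)
  expect_equal(cov(x1, x2), 1.5 * var(x1), tolerance = 0.1)
})

test_that("empty SEM gives mutually independent columns", {
  X <- generate_sem(matrix(0, 3, 3), "uniform", 1e4, seed = 2)
  cm <- cor(X)
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)
})

test_that("SEM generator records the shuffling permutation", {
  B <- matrix(0, 3, 3)
  B[2, 1] <- 1
  B[3, 2] <- -1
  X <- generate_sem(B, "laplace", 100, seed = 3)
  perm <- attr(X, "permutation")
  expect_setequal(perm, 1:3)
  expect_identical(colnames(X), paste0("x", perm))
  expect_identical(attr(X, "b_true"), B)
  expect_warning(generate_sem(B, "gaussian", 10, seed = 1), "unidentifiable")
  expect_no_warning(generate_sem(B, "gaussian", 10, seed = 1,
                                 allow_gaussian = TRUE))
  expect_error(generate_sem(matrix(1, 2, 2), "uniform", 10, seed = 1),
               "lower triangular")
})
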