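test_that("delta transform subtracts each animal's baseline", {
  d <- data.frame(animal_id = rep("A1", 3), day = c(3, 30, 60),
                  y = c(5, 8, 2))
  out <- delta_transform(d)
  expect_equal(out$y, c(0, 3, -3))
  # constant trajectories give all zeros; translation drops out
  d$y <- 7
  expect_equal(delta_transform(d)$y, c(0, 0, 0))
  d2 <- data.frame(animal_id = rep(c("A1", "A2"), each = 3),
                   day = rep(c(3, 30, 60), 2), y = rnorm(6))
  shifted <- d2
  shifted$y <- shifted$y + 100
  expect_equal(delta_transform(d2)$y, delta_transform(shifted)$y)
  # missing baseline names the animal
  expect_error(delta_transform(d2[d2$day != 3 | d2$animal_id != "A2", ]),
               "A2")
  # baseline rows can be dropped
  expect_equal(nrow(delta_transform(d2, keep_baseline = FALSE)), 4)
})

test_that("a planted two-variable effect is recovered with its strength", {
  B <- matrix(0, 2, 2)
  B[2, 1] <- 1.5
  X <- generate_sem(B, "uniform", 1e4, seed = 1)
  m <- direct_lingam(X)
  expect_equal(m$causal_order, c("x1", "x2"))
  expect_gt(m$B["x2", "x1"], 1.45)
  expect_lt(m$B["x2", "x1"], 1.55)
})

test_that("independent columns give a near-zero strengths matrix", {
  X <- generate_sem(matrix(0, 3, 3), "uniform", 1e4, seed = 2)
  m <- direct_lingam(X)
  expect_lt(max(abs(m$B)), 0.05)
})

test_that("column shuffling permutes the recovered order consistently", {
  B <- matrix(0, 3, 3)
  B[2, 1] <- 0.8
  B[3, 2] <- -0.7
  X <- generate_sem(B, "uniform", 5000, seed = 3)
  m <- direct_lingam(X)
  expect_equal(m$causal_order, c("x1", "x2", "x3"))
  # reshuffle the same data differently: same order in variable labels
  set.seed(11)
  X2 <- X[, sample(3), drop = FALSE]
  m2 <- direct_lingam(X2)
  expect_equal(m2$causal_order, c("x1", "x2", "x3"))
  expect_equal(m2$B[colnames(X), colnames(X)], m$B[colnames(X), colnames(X)],
               tolerance = 1e-8)
})

test_that("estimation is scale-equivariant", {
  B <- matrix(0, 3, 3)
  B[2, 1] <- 0.8
  B[3, 2] <- -0.7
  X <- generate_sem(B, "laplace", 4000, seed = 4)
  m <- direct_lingam(X)
  Xs <- X
  Xs[, "x2"] <- 10 * Xs[, "x2"]
  ms <- direct_lingam(Xs)
  expect_equal(ms$causal_order, m$causal_order)
  expect_equal(ms$B["x2", "x1"], 10 * m$B["x2", "x1"], tolerance = 1e-6)
  expect_equal(ms$B["x3", "x2"], m$B["x3", "x2"] / 10, tolerance = 1e-6)
})

test_that("Gaussian noise degrades order recovery toward chance", {
  B <- matrix(0, 2, 2)
  B[2, 1] <- 1
  hit_u <- hit_g <- 0
  for (s in 1:30) {
    Xu <- generate_sem(B, "uniform", 500, seed = s)
    Xg <- suppressWarnings(generate_sem(B, "gaussian", 500, seed = s))
    hit_u <- hit_u + identical(direct_lingam(Xu)$causal_order, c("x1", "x2"))
    hit_g <- hit_g +
      identical(suppressWarnings(direct_lingam(Xg))$causal_order,
                c("x1", "x2"))
  }
  expect_gte(hit_u, 27)  # identifiable case: nearly always right
  expect_lte(hit_g, 24)  # unidentifiable case: drifts toward coin-flipping
})

test_that("more variables than rows is refused", {
  expect_error(direct_lingam(matrix(rnorm(6), 2, 3)), "more observations")
})

test_that("nested family/genus pairs act as internal standards", {
  set.seed(6)
  n <- 300
  genus <- runif(n, 0, 1)
  other <- runif(n, 0, 0.1)
  family <- genus + other # the family is its dominant genus + 5% residual
  m <- suppressWarnings(direct_lingam(cbind(genus = genus, family = family)))
  rep <- internal_standard_check(m, list(c("genus", "family")))
  expect_true(rep$pass)
  expect_gt(rep$coefficient, 0.9)
  expect_lt(rep$coefficient, 1.1)

  # an absent edge fails with coefficient 0
  m0 <- direct_lingam(generate_sem(matrix(0, 2, 2), "uniform", 500, seed = 7))
  m0$B[] <- 0
  rep0 <- internal_standard_check(m0, list(c("x1", "x2")))
  expect_false(rep0$pass)
  expect_equal(rep0$coefficient, 0)
  expect_error(internal_standard_check(m0, list(c("x1", "zz"))), "zz")
})

test_that("DAG export round-trips and thresholds monotonically", {
  B <- matrix(0, 3, 3)
  B[2, 1] <- 0.8
  B[3, 2] <- -0.7
  X <- generate_sem(B, "uniform", 2000, seed = 8)
  m <- direct_lingam(X)
  for (fmt in c("graphml", "tsv")) {
    f <- tempfile(fileext = paste0(".", fmt))
    edges <- export_dag(m, f, format = fmt)
    back <- read_dag(f, format = fmt)
    expect_equal(back$from, edges$from)
    expect_equal(back$to, edges$to)
    expect_equal(as.numeric(back$weight), edges$weight, tolerance = 1e-12)
  }
  # raising the threshold never adds edges
  n_prev <- Inf
  for (thr in c(0, 0.1, 0.5, 1)) {
    f <- tempfile(fileext = ".tsv")
    n_now <- nrow(export_dag(m, f, threshold = thr, format = "tsv"))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
  # an empty strengths matrix exports a node-only graph
  m$B[] <- 0
  f <- tempfile(fileext = ".graphml")
  export_dag(m, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::ecount(g), 0)
  expect_equal(igraph::vcount(g), 3)
  # DOT export is at least syntactically complete
  fd <- tempfile(fileext = ".dot")
  export_dag(direct_lingam(X), fd, format = "dot")
  txt <- readLines(fd)
  expect_equal(txt[1], "digraph causal_model {")
  expect_equal(sum(grepl("->", txt)), nrow(export_dag(direct_lingam(X),
                                                      tempfile(), format = "tsv")))
})
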