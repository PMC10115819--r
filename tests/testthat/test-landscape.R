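two_state_params <- function() {
  maxent_params(c(-0.1, -0.1), matrix(c(0, 1, 1, 0), 2))
}

test_that("the two-component example has exactly two stable states", {
  ls <- find_minima(two_state_params(), c(0, 0))
  expect_false(ls$flat)
  expect_equal(nrow(ls$minima), 2)
  expect_equal(sort(ls$minima$state), c("00", "11"))
  expect_equal(ls$minima$energy[ls$minima$state == "00"], 0)
  expect_equal(ls$minima$energy[ls$minima$state == "11"], -0.8)
})

test_that("degenerate landscapes are flagged, not faked", {
  flat <- find_minima(maxent_params(c(0, 0), matrix(0, 2, 2)), c(0, 0))
  expect_true(flat$flat)
  expect_equal(nrow(flat$minima), 0)

  neg <- find_minima(maxent_params(c(-3, -3, -3), matrix(0, 3, 3)), c(0, 0))
  expect_equal(neg$minima$state, "000")
  expect_equal(neg$minima$basin_size, 8L)
})

test_that("descent walks downhill to the right minimum", {
  p <- two_state_params()
  # a minimum is its own fixed point
  d0 <- descend(c(1, 1), p, c(0, 0))
  expect_equal(d0$state, c(1, 1))
  expect_equal(d0$steps, 0L)
  # E(1,0) = 0.1; neighbors (0,0) at 0 and (1,1) at -0.8 -> go to (1,1)
  d1 <- descend(c(1, 0), p, c(0, 0))
  expect_equal(d1$state, c(1, 1))
  expect_equal(d1$energy, -0.8)
  # flat start is returned as-is with the flag raised
  df <- descend(c(1, 0), maxent_params(c(0, 0), matrix(0, 2, 2)), c(0, 0))
  expect_equal(df$state, c(1, 0))
  expect_true(df$flat)
})

test_that("basins partition the enumerated state space", {
  for (seed in 1:4) {
    set.seed(seed)
    p <- random_maxent_params(6)
    ls <- find_minima(p, c(1, 0.53))
    if (ls$flat) next
    expect_equal(sum(ls$minima$basin_size), 2^6)
    expect_equal(length(ls$basin_of), 2^6)
    expect_false(anyNA(ls$basin_of))
    # every enumerated state's descent endpoint agrees with its basin label
    states <- calfscape:::enumerate_states(6)
    for (k in sample(2^6, 8)) {
      d <- descend(states[k, ], p, c(1, 0.53))
      lab <- paste(d$state, collapse = "")
      expect_equal(ls$minima$state[ls$basin_of[k]], lab)
    }
  }
})

test_that("find_minima commutes with component permutation", {
  set.seed(9)
  p <- random_maxent_params(5)
  perm <- sample(5)
  pp <- maxent_params(p$h[perm], p$J[perm, perm], p$g_a[perm], p$g_s[perm])
  a <- find_minima(p, c(0, 1))
  b <- find_minima(pp, c(0, 1))
  # permute each state string of `a` into the relabeled coordinates
  relabel <- vapply(strsplit(a$minima$state, ""), function(bits)
    paste(bits[perm], collapse = ""), character(1))
  expect_setequal(relabel, b$minima$state)
  expect_equal(sort(a$minima$energy), sort(b$minima$energy))
})

test_that("clamped chemicals shift fields and offset energies", {
  # one binary taxon coupled to one clamped chemical
  p <- maxent_params(c(-1, 0.2), matrix(c(0, 2, 2, 0), 2))
  kinds <- c("binary", "continuous")
  # chemical clamped at 1: effective field -1 + 2 = +1 -> taxon present
  ls1 <- find_minima(p, c(0, 0), kinds = kinds, clamp = 1)
  expect_equal(ls1$minima$state, "1")
  # full-model energy of (sigma=1, chem=1): -(2 + (-1) + 0.2) = -1.2
  expect_equal(ls1$minima$energy, -1.2)
  # chemical clamped at 0: field -1 -> taxon absent
  ls0 <- find_minima(p, c(0, 0), kinds = kinds, clamp = 0)
  expect_equal(ls0$minima$state, "0")
})

test_that("the gradient scan tracks minima across environments", {
  set.seed(3)
  # no stage couplings: minima identical at every stage gridpoint
  p_nostage <- maxent_params(runif(4, -1, 1), {
    J <- matrix(0, 4, 4)
    J[upper.tri(J)] <- runif(6, -1, 1)
    J + t(J)
  })
  g <- landscape_over_gradient(p_nostage, ea_values = 0,
                               es_grid = c(0, 0.5, 1))
  per_point <- split(g$state, g$es)
  expect_true(all(vapply(per_point, identical, logical(1),
                         y = per_point[[1]])))

  # single component flipped by the treatment: g_a = +2 overcomes h = -1
  p_sw <- maxent_params(-1, matrix(0, 1, 1), g_a = 2)
  sw <- landscape_over_gradient(p_sw, ea_values = c(0, 1), es_grid = 0.5)
  expect_equal(sw$state[sw$ea == 0], "0")
  expect_equal(sw$state[sw$ea == 1], "1")

  # a single gridpoint reduces to find_minima
  one <- landscape_over_gradient(two_state_params(), ea_values = 0,
                                 es_grid = 0)
  ref <- find_minima(two_state_params(), c(0, 0))
  expect_equal(one$state, ref$minima$state)
  expect_equal(one$energy, ref$minima$energy)
})
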