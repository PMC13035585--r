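test_that("blood model right-hand side matches the two-compartment equations", {
  m <- make_blood_model(5, 1, 6)
  expect_equal(unname(m$params), c(5, 1, 6))
  # hand evaluation at (x1, x2) = (2, 1): dx1 = -10 + 1 - 12/3, dx2 = 10 - 1
  expect_equal(m$rhs(c(2, 1), m$params), c(-13, 9))
  # origin is a fixed point
  expect_equal(m$rhs(c(0, 0), m$params), c(0, 0))
  # mass balance: d(x1+x2)/dt = -Ve*x1/(1+x1) at any state
  st <- c(0.7, 0.3)
  expect_equal(sum(m$rhs(st, m$params)), -6 * 0.7 / 1.7)
  expect_error(make_blood_model(-1, 1, 6), "positive")
  expect_error(make_blood_model(5, 1, 0), "positive")
})

test_that("SIR right-hand side conserves the population and has the disease-free equilibrium", {
  m <- make_sir_model(5.5 / 1e4, 5, 1e4, 1)
  expect_equal(unname(m$initial_state), c(9999, 1, 0))
  # closed population: components sum to zero at any state
  expect_equal(sum(m$rhs(c(8000, 1500, 500), m$params)), 0)
  # I = 0 is an equilibrium
  expect_equal(m$rhs(c(9000, 0, 1000), m$params), c(0, 0, 0))
  expect_error(make_sir_model(5.5e-4, 5, 100, 100), "I0")
  expect_error(make_sir_model(-1, 5, 100, 1), "positive")
})

test_that("simulated SIR trajectories conserve S+I+R to solver tolerance", {
  m <- make_sir_model()
  traj <- simulate_model(m, seq(0, 30, length.out = 31))
  expect_equal(nrow(traj$states), 31)
  expect_true(all(abs(rowSums(traj$states) - 1e4) < 1e-6))
  expect_equal(traj$observed, traj$states[, "I"])
})

test_that("blood trajectory decays and agrees with an independent RK4 integrator", {
  m <- make_blood_model()
  tt <- seq(0, 2, length.out = 41)
  traj <- simulate_model(m, tt)
  expect_lt(traj$observed[41], traj$observed[1])
  expect_lt(traj$observed[41], 0.05)
  oracle <- rk4(function(y) m$rhs(y, m$params), m$initial_state, tt)
  expect_lt(max(abs(traj$states - oracle)), 1e-8)
})

test_that("zero-rate dynamics are constant (simulate contract)", {
  # rates must be positive for the constructor; near-zero rates give a
  # near-constant trajectory, approaching the exact invariance
  m <- make_blood_model(1e-12, 1e-12, 1e-12, ic = c(1, 0.5))
  traj <- simulate_model(m, seq(0, 2, length.out = 11))
  expect_lt(max(abs(sweep(traj$states, 2, c(1, 0.5)))), 1e-10)
  expect_error(simulate_model(m, c(1, 2, 3)), "start at 0")
  expect_error(simulate_model(m, c(0, 0.5, 0.5)), "increasing")
})

test_that("blood coefficient map takes (5,1,6) to (6,6,12) and is injective", {
  expect_equal(coefficient_map_blood(5, 1, 6),
               c(w1 = 6, w2 = 6, w3 = 12))
  # w3 - w2 = Ve identically
  set.seed(1)
  for (i in 1:25) {
    p <- runif(3, 0.1, 10)
    w <- coefficient_map_blood(p[1], p[2], p[3])
    expect_equal(unname(w[3] - w[2]), p[3])
  }
  # injectivity on random positive triples: distinct p -> distinct w
  set.seed(2)
  P <- matrix(runif(3 * 40, 0.1, 10), ncol = 3)
  W <- t(apply(P, 1, function(p) coefficient_map_blood(p[1], p[2], p[3])))
  expect_equal(nrow(unique(round(W, 10))), nrow(P))
  expect_error(coefficient_map_blood(0, 1, 1), "positive")
})

test_that("coefficient map inversion recovers rates and flags impossible cells", {
  inv <- invert_coefficient_map_blood(c(6, 6, 12))
  expect_true(inv$valid)
  expect_equal(c(inv$k12, inv$k21, inv$Ve), c(5, 1, 6))
  expect_false(invert_coefficient_map_blood(c(6, 12, 10))$valid)  # w3 <= w2
  expect_false(invert_coefficient_map_blood(c(30, 1, 10))$valid)  # k12 <= 0
  # round trip on random valid rates
  set.seed(3)
  for (i in 1:20) {
    p <- runif(3, 0.2, 8)
    inv <- invert_coefficient_map_blood(coefficient_map_blood(p[1], p[2], p[3]))
    expect_true(inv$valid)
    expect_equal(c(inv$k12, inv$k21, inv$Ve), p, tolerance = 1e-10)
  }
})

test_that("strong-form input-output residual vanishes at the true coefficients", {
  m <- make_blood_model()
  w <- coefficient_map_blood(5, 1, 6)
  res <- vapply(c(200, 400, 800), function(M) {
    traj <- simulate_model(m, seq(0, 2, length.out = M + 1))
    max(abs(strong_io_residual("blood_tissue", traj, w)))
  }, numeric(1))
  # central differences: converges at >= 1st order under refinement
  # (the fast initial transient dominates the finite-difference error)
  expect_lt(res[1], 0.15)
  expect_true(all(diff(res) < 0))
  expect_gt(res[1] / res[3], 4 * 0.9)  # close to 2nd order over a 4x refinement
  # perturbed coefficients leave a strictly larger residual
  traj <- simulate_model(m, seq(0, 2, length.out = 801))
  r_true <- sqrt(sum(strong_io_residual("blood_tissue", traj, w)^2))
  r_pert <- sqrt(sum(strong_io_residual("blood_tissue", traj, 1.1 * w)^2))
  expect_gt(r_pert, r_true)
  # identically-zero observed signal solves the blood equation exactly
  traj0 <- traj
  traj0$observed <- rep(0, length(traj$times))
  expect_equal(strong_io_residual("blood_tissue", traj0, w),
               rep(0, length(traj$times) - 2))
})

test_that("strong-form SIR residual works at the printed parameters and guards I <= 0", {
  m <- make_sir_model()
  traj <- simulate_model(m, seq(0, 30, length.out = 1201))
  r <- strong_io_residual("sir", traj, c(5.5e-4, 5))
  scale <- max(abs(traj$observed))^2 * 5.5e-4 * 5
  expect_lt(max(abs(r)) / scale, 1e-3)
  bad <- traj
  bad$observed[5] <- -1
  expect_error(strong_io_residual("sir", bad, c(5.5e-4, 5)), "I\\(t\\) > 0")
})

test_that("model registry resolves names", {
  expect_equal(get_model("blood_tissue")$name, "blood_tissue")
  expect_equal(get_model("sir")$name, "sir")
  expect_error(get_model("lotka"))
})
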