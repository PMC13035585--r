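test_that("weak blood system has the three printed coefficient columns", {
  sys <- build_weak_blood_system()
  expect_equal(sys$n_params, 3L)
  expect_equal(sys$param_names, c("w1", "w2", "w3"))
  # x1 == 0 kills the w1 and w2 columns; the w3 column integrates phi' * 1
  obs0 <- list(times = blood40$times, y = rep(0, length(blood40$times)))
  ls <- assemble(sys, obs0, blood40$tfg)
  expect_equal(max(abs(ls$G[, "w1"])), 0)
  expect_equal(max(abs(ls$G[, "w2"])), 0)
  expect_lt(max(abs(ls$G[, "w3"])), 1e-8)
  expect_equal(max(abs(ls$b)), 0)
})

test_that("weak SIR system is a single-parameter regression, degenerate at I == 0", {
  sys <- build_weak_sir_system(alpha_known = 5, S0 = 9999)
  expect_equal(sys$n_params, 1L)
  expect_equal(sys$param_names, "beta")
  obs0 <- list(times = sir31$times, y = rep(0, length(sir31$times)))
  ls <- assemble(sys, obs0, sir31$tfg)
  expect_equal(max(abs(ls$b)), 0)
  expect_equal(max(abs(ls$G)), 0)
  expect_error(wendy_solve(ls, sys, obs0, sir31$tfg), "rank")
})

test_that("assembly has the contracted shape and the linear b-side scales linearly", {
  obs <- noiseless_obs(blood40)
  ls <- assemble(blood40$system, obs, blood40$tfg)
  expect_equal(dim(ls$G), c(blood40$tfg$K, 3L))
  expect_length(ls$b, blood40$tfg$K)
  # SIR b is linear in the data
  obs_s <- noiseless_obs(sir31)
  b1 <- assemble(sir31$system, obs_s, sir31$tfg)$b
  obs2 <- obs_s; obs2$y <- 2 * obs_s$y
  b2 <- assemble(sir31$system, obs2, sir31$tfg)$b
  expect_equal(b2, 2 * b1, tolerance = 1e-12)
  # mismatched grids are refused
  expect_error(assemble(blood40$system, obs_s, blood40$tfg), "grid")
  # non-finite data maps are reported with the offending term
  obs_bad <- obs; obs_bad$y[3] <- -1  # 1/(1+y) blows up
  expect_error(assemble(blood40$system, obs_bad, blood40$tfg), "non-finite")
})

test_that("noiseless weak-form estimation recovers (6,6,12) with refinement convergence", {
  errs <- vapply(c(40, 80, 160), function(M) {
    cfg <- blood_config(M = M)
    fit <- wendy_solve(NULL, cfg$system, noiseless_obs(cfg), cfg$tfg)
    max(abs(fit$w_hat - c(6, 6, 12)) / c(6, 6, 12))
  }, numeric(1))
  expect_lt(errs[1], 1e-3)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-5)
})

test_that("noiseless weak-form SIR estimation recovers beta = 5.5e-4", {
  fit <- wendy_solve(NULL, sir31$system, noiseless_obs(sir31), sir31$tfg)
  expect_equal(unname(fit$w_hat), 5.5e-4, tolerance = 1e-3)
})

test_that("the weak residual at the true coefficients shrinks as the grid refines", {
  res <- vapply(c(40, 120), function(M) {
    cfg <- blood_config(M = M)
    ls <- assemble(cfg$system, noiseless_obs(cfg), cfg$tfg)
    sqrt(sum((ls$b - ls$G %*% cfg$w_true)^2)) / sqrt(sum(ls$b^2))
  }, numeric(1))
  expect_lt(res[1], 1e-4)
  expect_lt(res[2], res[1])
})

test_that("noiseless data short-circuit to ordinary least squares with degenerate intervals", {
  obs <- noiseless_obs(blood40)
  fit <- wendy_solve(NULL, blood40$system, obs, blood40$tfg)
  expect_true(fit$converged)
  expect_equal(fit$iterations, 0L)
  expect_equal(max(abs(fit$covariance)), 0)
  expect_equal(fit$ci_low, fit$w_hat)
  expect_equal(fit$ci_high, fit$w_hat)
  ls <- assemble(blood40$system, obs, blood40$tfg)
  expect_equal(fit$w_hat, qr.solve(ls$G, ls$b), tolerance = 1e-12)
})

test_that("rank deficiency raises a diagnosable non-identifiability error", {
  cfg <- blood_config(M = 40, K = 2)  # 2 rows cannot determine 3 unknowns
  err <- tryCatch(wendy_solve(NULL, cfg$system, noiseless_obs(cfg), cfg$tfg),
                  wendio_rank_error = function(e) e)
  expect_s3_class(err, "wendio_rank_error")
  expect_lte(err$rank_G, 2L)
  # a K x 1 system with duplicated rows is still rank 1 and solvable
  tfg1 <- sir31$tfg
  for (i in 2:tfg1$K) for (o in 1:3) tfg1$PhiQ[[o]][i, ] <- tfg1$PhiQ[[o]][1, ]
  fit <- wendy_solve(NULL, sir31$system, noiseless_obs(sir31), tfg1)
  expect_equal(unname(fit$w_hat), 5.5e-4, tolerance = 1e-2)
})

test_that("Wald intervals have the prescribed geometry", {
  f <- fake_fit(c(1, 2), half = c(0.5, 1))
  f2 <- confidence_intervals(f, 0.95)
  expect_true(all(f2$ci_low <= f2$w_hat & f2$w_hat <= f2$ci_high))
  # widths scale as the square root of the covariance diagonal
  w <- f2$ci_high - f2$ci_low
  expect_equal(w[2] / w[1], sqrt(diag(f$covariance)[2] / diag(f$covariance)[1]))
  f3 <- f; f3$covariance <- matrix(0, 2, 2)
  f3 <- confidence_intervals(f3, 0.95)
  expect_equal(f3$ci_low, f3$w_hat)
  expect_error(confidence_intervals(f, 1.5), "level")
})

test_that("interval coverage is close to nominal in a moderate-noise SIR study", {
  res <- run_replicates(sir31, 0.5, "additive_gaussian", D = 250, seed = 20L)
  cov <- res$summary$coverage
  expect_gt(cov, 0.90)
  expect_lt(cov, 0.99)
})

test_that("rank diagnostics report the conjectured full-rank conditions", {
  obs <- noiseless_obs(blood40)
  ls <- assemble(blood40$system, obs, blood40$tfg)
  d <- check_rank(ls, blood40$tfg)
  expect_equal(d$rank_G, 3L)
  expect_true(d$identifiable)
  expect_equal(unname(d$rank_Phi), rep(blood40$tfg$K, 3))
  cfg1 <- blood_config(M = 40, K = 1)
  ls1 <- assemble(cfg1$system, noiseless_obs(cfg1), cfg1$tfg)
  d1 <- check_rank(ls1, cfg1$tfg)
  expect_lte(d1$rank_G, 1L)
  expect_false(d1$identifiable)
})

test_that("estimates are reproducible and error grows with the noise level", {
  set.seed(1)
  e_grid <- c(0.01, 0.05, 0.15)
  med <- vapply(e_grid, function(e) {
    r <- run_replicates(blood40, e, "additive_gaussian", D = 60, seed = 9L)
    stats::median(r$summary$rel_err)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
  r1 <- run_replicates(blood40, 0.05, "additive_gaussian", D = 20, seed = 5L)
  r2 <- run_replicates(blood40, 0.05, "additive_gaussian", D = 20, seed = 5L)
  expect_identical(r1$summary$mse, r2$summary$mse)
})
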