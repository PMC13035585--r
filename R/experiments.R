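#' Benchmark experiment configurations
#'
#' Bundle a benchmark model, its weak-form input-output system, the
#' observation grid, the test-function grid and the true coefficient vector
#' into one object, so that ensemble studies, (e,q) maps and the baseline
#' comparison all run from the same description.
#'
#' Defaults follow the simulation studies of the two benchmarks:
#' \itemize{
#'   \item blood-tissue: rates `(k12, k21, Ve) = (5, 1, 6)`, initial state
#'     `(1, 0)`, horizon `[0, 2]` model time units (the dynamics at these
#'     rates decay within about one time unit), `M = 40` observation points,
#'     12th-order polynomial test functions with radius `a = 0.52`.
#'   \item SIR: `N = 10000`, `I0 = 1`, `beta = 5.5/N`, recovery rate 5,
#'     31 daily observations on `[0, 30]`, polynomial test functions with
#'     radius one quarter of the observation window.
#' }
#'
#' @param M number of observation points (40 for identifiability studies of
#'   the blood model, 400 for dense single-fit studies).
#' @param horizon end of the observation window (start is 0).
#' @param k12,k21,Ve,ic blood-tissue model parameters, see
#'   [make_blood_model()].
#' @param beta,alpha,N,I0 SIR parameters, see [make_sir_model()].
#' @param family,a,eta,K test-function options, see
#'   [test_function_family()] and [place_test_functions()].
#' @return An object of class `wendy_experiment`: list with `model`,
#'   `system`, `times`, `tfg`, `w_true` and `name`.
#' @export
blood_config <- function(M = 40, horizon = 2, k12 = 5, k21 = 1, Ve = 6,
                         ic = c(1, 0), family = "poly12", a = 0.52,
                         eta = 9, K = NULL) {
  model <- make_blood_model(k12, k21, Ve, ic)
  times <- seq(0, horizon, length.out = M)
  tf <- test_function_family(family, a, eta)
  tfg <- place_test_functions(times, tf, K = K, n_params = 3L)
  structure(list(name = "blood_tissue", model = model,
                 system = build_weak_blood_system(),
                 times = times, tfg = tfg,
                 w_true = coefficient_map_blood(k12, k21, Ve)),
            class = "wendy_experiment")
}

#' @rdname blood_config
#' @export
sir_config <- function(M = 31, horizon = 30, beta = 5.5 / 10000, alpha = 5,
                       N = 10000, I0 = 1, family = "poly12", a = NULL,
                       eta = 9, K = NULL) {
  model <- make_sir_model(beta, alpha, N, I0)
  times <- seq(0, horizon, length.out = M)
  if (is.null(a)) a <- 0.25 * horizon
  tf <- test_function_family(family, a, eta)
  tfg <- place_test_functions(times, tf, K = K, n_params = 1L)
  structure(list(name = "sir", model = model,
                 system = build_weak_sir_system(alpha_known = alpha,
                                                S0 = N - I0),
                 times = times, tfg = tfg,
                 w_true = c(beta = beta)),
            class = "wendy_experiment")
}

#' @export
print.wendy_experiment <- function(x, ...) {
  cat("<wendy_experiment> ", x$name, ": ", length(x$times),
      " observations on [", x$times[1L], ", ", x$times[length(x$times)],
      "], K = ", x$tfg$K, " test functions (", x$tfg$family$family, ")\n",
      sep = "")
  cat("  true coefficients: ",
      paste(sprintf("%s = %g", names(x$w_true), x$w_true), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Run a Monte-Carlo ensemble of WENDy fits
#'
#' Generates `D` noisy replicates of the experiment's truth trajectory at
#' observation error ratio `e` and fits each with [wendy_solve()].  Failed
#' fits (rank deficiency or non-finite assembly) are recorded, not raised.
#'
#' @param config a [blood_config()] / [sir_config()] experiment.
#' @param e observation error ratio (0.05 = 5\%).
#' @param kind noise kind, see [noise_spec()].
#' @param D replicate count.
#' @param seed base seed.
#' @param level confidence level.
#' @return List with `fits` (list of `wendy_fit` or `NULL` for failures) and
#'   `summary` (a [summarize_fits()] result).
#' @export
run_replicates <- function(config, e, kind = "additive_gaussian", D = 1000,
                           seed = 1L, level = 0.95) {
  stopifnot(inherits(config, "wendy_experiment"))
  spec <- noise_spec(kind, e, seed)
  ens <- generate_ensemble(config$model, config$times, spec, D)
  fits <- lapply(ens, function(obs) {
    tryCatch(wendy_solve(NULL, config$system, obs, config$tfg, level = level),
             error = function(err) NULL)
  })
  list(fits = fits,
       summary = summarize_fits(fits, config$w_true, e))
}
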