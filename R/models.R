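#' Benchmark ODE models for weak-form input-output estimation
#'
#' @description
#' `make_blood_model()` builds the two-compartment blood-tissue drug diffusion
#' model
#' \deqn{\dot x_1 = -k_{12} x_1 + k_{21} x_2 - V_e x_1/(1+x_1), \qquad
#'       \dot x_2 = k_{12} x_1 - k_{21} x_2,}
#' where \eqn{x_1} is the drug concentration in blood (the observed state),
#' \eqn{x_2} the concentration in tissue, \eqn{k_{12}} and \eqn{k_{21}} the
#' diffusion rates between the compartments and \eqn{V_e} the decay rate of
#' the drug in blood.
#'
#' `make_sir_model()` builds the closed-population SIR epidemic model
#' \deqn{\dot S = -\beta S I, \quad \dot I = \beta S I - \alpha I, \quad
#'       \dot R = \alpha I,}
#' with transmission rate \eqn{\beta}, recovery rate \eqn{\alpha}, total
#' population \eqn{N = S + I + R} and the infected compartment \eqn{I} as the
#' observed state.
#'
#' @param k12,k21,Ve positive rates of the blood-tissue model (per model time
#'   unit).
#' @param ic nonnegative initial concentrations `c(x1, x2)`.
#' @param beta per-contact transmission rate (per individual per day).
#' @param alpha recovery rate (per day).
#' @param N total population size.
#' @param I0 initial number of infected individuals, `0 < I0 < N`;
#'   `S0 = N - I0`, `R0 = 0`.
#' @return An object of class `ode_model` with fields `name`, `state_names`,
#'   `param_names`, `params`, `initial_state`, `observed_index` and `rhs`.
#' @examples
#' m <- make_blood_model(5, 1, 6)
#' m$rhs(c(1, 0), m$params)
#' @export
make_blood_model <- function(k12 = 5, k21 = 1, Ve = 6, ic = c(1, 0)) {
  if (!all(is.finite(c(k12, k21, Ve))) || any(c(k12, k21, Ve) <= 0))
    stop("blood model rates k12, k21, Ve must be positive", call. = FALSE)
  if (length(ic) != 2L || any(ic < 0))
    stop("initial state must be a nonnegative 2-vector", call. = FALSE)
  params <- c(k12 = k12, k21 = k21, Ve = Ve)
  rhs <- function(state, p) {
    x1 <- state[1L]; x2 <- state[2L]
    c(-p[["k12"]] * x1 + p[["k21"]] * x2 - p[["Ve"]] * x1 / (1 + x1),
      p[["k12"]] * x1 - p[["k21"]] * x2)
  }
  structure(list(
    name = "blood_tissue",
    state_names = c("x1", "x2"),
    param_names = names(params),
    params = params,
    initial_state = stats::setNames(as.numeric(ic), c("x1", "x2")),
    observed_index = 1L,
    rhs = rhs
  ), class = "ode_model")
}

#' @rdname make_blood_model
#' @export
make_sir_model <- function(beta = 5.5 / 10000, alpha = 5, N = 10000, I0 = 1) {
  if (!all(is.finite(c(beta, alpha))) || beta <= 0 || alpha <= 0)
    stop("beta and alpha must be positive", call. = FALSE)
  if (I0 <= 0 || I0 >= N)
    stop("I0 must satisfy 0 < I0 < N", call. = FALSE)
  params <- c(beta = beta, alpha = alpha)
  rhs <- function(state, p) {
    S <- state[1L]; I <- state[2L]
    c(-p[["beta"]] * S * I,
      p[["beta"]] * S * I - p[["alpha"]] * I,
      p[["alpha"]] * I)
  }
  structure(list(
    name = "sir",
    state_names = c("S", "I", "R"),
    param_names = names(params),
    params = params,
    N = N,
    initial_state = c(S = N - I0, I = I0, R = 0),
    observed_index = 2L,
    rhs = rhs
  ), class = "ode_model")
}

#' @export
print.ode_model <- function(x, ...) {
  cat("<ode_model> ", x$name, "\n", sep = "")
  cat("  states:   ", paste(x$state_names, collapse = ", "),
      " (observed: ", x$state_names[x$observed_index], ")\n", sep = "")
  cat("  params:   ",
      paste(sprintf("%s = %g", x$param_names, x$params), collapse = ", "),
      "\n", sep = "")
  cat("  initial:  ",
      paste(sprintf("%s = %g", x$state_names, x$initial_state),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Model registry
#'
#' Look up a benchmark model constructor by its registry key.
#'
#' @param name one of `"blood_tissue"` or `"sir"`.
#' @param ... passed to the model constructor.
#' @return An `ode_model`.
#' @export
get_model <- function(name, ...) {
  switch(match.arg(name, c("blood_tissue", "sir")),
         blood_tissue = make_blood_model(...),
         sir = make_sir_model(...))
}

#' Simulate a model on an observation grid
#'
#' Integrates an `ode_model` with a high-accuracy variable-step solver
#' (`deSolve::ode`, `lsoda`, relative tolerance 1e-10, absolute tolerance
#' 1e-12 by default), so that solver error is negligible against any
#' measurement noise subsequently applied.
#'
#' @param model an `ode_model`.
#' @param times strictly increasing observation times starting at 0.
#' @param rtol,atol solver tolerances.
#' @return An object of class `trajectory`: list with `times`, `states`
#'   (matrix, one row per time) and `observed` (the observed-state column).
#' @export
simulate_model <- function(model, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(model, "ode_model"))
  if (length(times) < 2L || any(diff(times) <= 0) || times[1L] != 0)
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  deriv <- function(t, y, p) list(model$rhs(y, p))
  sol <- deSolve::ode(y = model$initial_state, times = times, func = deriv,
                      parms = model$params, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0 || nrow(sol) != length(times))
    stop("ODE solver failed for model '", model$name, "': ",
         paste(utils::capture.output(deSolve::diagnostics(sol)), collapse = "\n"),
         call. = FALSE)
  states <- unname(sol[, -1L, drop = FALSE])
  colnames(states) <- model$state_names
  structure(list(times = as.numeric(times), states = states,
                 observed = states[, model$observed_index],
                 model = model$name),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$model, ": ", length(x$times), " points on [",
      x$times[1L], ", ", x$times[length(x$times)], "]\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(t = x$times, x$states, observed = x$observed,
             check.names = FALSE)
}

#' Identifiable parameter combinations of the blood-tissue model
#'
#' The input-output equation of the blood-tissue model in the observed state
#' \eqn{x_1} has coefficients
#' \eqn{w_1 = k_{21} V_e}, \eqn{w_2 = k_{12} + k_{21}},
#' \eqn{w_3 = k_{12} + k_{21} + V_e}; these are the globally structurally
#' identifiable combinations estimated by the weak-form regression.
#' `invert_coefficient_map_blood()` recovers `(k12, k21, Ve)` from a `w`
#' vector when possible: `Ve = w3 - w2`, `k21 = w1 / Ve`, `k12 = w2 - k21`,
#' all of which must be positive.
#'
#' @param k12,k21,Ve positive model rates.
#' @return `coefficient_map_blood`: named 3-vector `(w1, w2, w3)`.
#' @examples
#' coefficient_map_blood(5, 1, 6)  # (6, 6, 12)
#' @export
coefficient_map_blood <- function(k12, k21, Ve) {
  if (any(c(k12, k21, Ve) <= 0))
    stop("rates must be positive", call. = FALSE)
  c(w1 = k21 * Ve, w2 = k12 + k21, w3 = k12 + k21 + Ve)
}

#' @rdname coefficient_map_blood
#' @param w numeric 3-vector `(w1, w2, w3)`.
#' @return `invert_coefficient_map_blood`: list with `k12`, `k21`, `Ve` and a
#'   logical `valid` flag (FALSE when the cell does not correspond to positive
#'   rates, i.e. `w3 <= w2`, `w1 <= 0` or `k12 <= 0`).
#' @export
invert_coefficient_map_blood <- function(w) {
  w <- as.numeric(w)
  stopifnot(length(w) == 3L)
  Ve <- w[3L] - w[2L]
  if (!(Ve > 0) || !(w[1L] > 0))
    return(list(k12 = NA_real_, k21 = NA_real_, Ve = NA_real_, valid = FALSE))
  k21 <- w[1L] / Ve
  k12 <- w[2L] - k21
  if (!(k12 > 0))
    return(list(k12 = NA_real_, k21 = k21, Ve = Ve, valid = FALSE))
  list(k12 = k12, k21 = k21, Ve = Ve, valid = TRUE)
}

#' Strong-form input-output equation residual
#'
#' Evaluates the strong-form input-output equation of a benchmark model on a
#' (noiseless, densely sampled) trajectory, estimating time derivatives of
#' the observed state by central finite differences.  This is a validation
#' oracle: at the true coefficient vector the residual vanishes up to finite
#' difference and solver error.
#'
#' For the blood-tissue model (observed \eqn{x = x_1}):
#' \deqn{\ddot x (x^2 + 2x + 1) + w_1 (x^2 + x) + w_2 (\dot x x^2 + 2 \dot x x)
#'       + w_3 \dot x = 0.}
#' For the SIR model (observed \eqn{I}, `w = c(beta, alpha)`):
#' \deqn{-\dot I^2 / I + \beta\alpha I^2 + \beta I \dot I + \ddot I = 0.}
#'
#' @param model_kind `"blood_tissue"` or `"sir"`.
#' @param trajectory a `trajectory` on a uniform grid.
#' @param w coefficient vector: `(w1, w2, w3)` for blood, `(beta, alpha)` for
#'   SIR.
#' @return Residual vector at the interior grid points.
#' @export
strong_io_residual <- function(model_kind, trajectory, w) {
  model_kind <- match.arg(model_kind, c("blood_tissue", "sir"))
  y <- trajectory$observed
  t <- trajectory$times
  h <- diff(t)
  if (max(abs(h - h[1L])) > 1e-8 * h[1L])
    stop("strong_io_residual requires a uniform time grid", call. = FALSE)
  h <- h[1L]
  m <- length(y)
  i <- 2:(m - 1L)
  yd <- (y[i + 1L] - y[i - 1L]) / (2 * h)
  ydd <- (y[i + 1L] - 2 * y[i] + y[i - 1L]) / h^2
  yi <- y[i]
  if (model_kind == "blood_tissue") {
    stopifnot(length(w) == 3L)
    ydd * (yi^2 + 2 * yi + 1) + w[1L] * (yi^2 + yi) +
      w[2L] * (yd * yi^2 + 2 * yd * yi) + w[3L] * yd
  } else {
    stopifnot(length(w) == 2L)
    if (any(yi <= 0))
      stop("SIR input-output equation requires I(t) > 0 on the grid",
           call. = FALSE)
    -yd^2 / yi + w[1L] * w[2L] * yi^2 + w[1L] * yi * yd + ydd
  }
}
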