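#' Compactly supported test-function families
#'
#' Three families of test (modulating) functions supported on `[-a, a]`,
#' normalized so that the continuous L2 norm on the support is 1:
#' \describe{
#'   \item{`bump`}{C-infinity bump
#'     \eqn{\phi(t) = C \exp(-\eta / (1 - (t/a)^2))}, with shape parameter
#'     \eqn{\eta} (default 9).}
#'   \item{`hartley3`}{third-order Hartley modulating function
#'     \eqn{\phi(t) = C(\mathrm{cas}(6\pi t/a) - 3\,\mathrm{cas}(4\pi t/a) +
#'     3\,\mathrm{cas}(2\pi t/a) - 1)} with
#'     \eqn{\mathrm{cas}(t) = \cos t + \sin t}.  Its value, first and second
#'     derivatives all vanish at \eqn{\pm a}.}
#'   \item{`poly12`}{12th-order polynomial
#'     \eqn{\phi(t) = C (t+a)^6 (a-t)^6}.}
#' }
#' All are extended by zero outside `[-a, a]`, so weak-form integrals over a
#' window containing the support pick up no boundary terms.
#'
#' @param family one of `"poly12"`, `"bump"`, `"hartley3"`.
#' @param a radius of support in model time units, `a > 0`.
#' @param eta bump shape parameter (ignored by the other families).
#' @return An object of class `test_function_family` with the normalization
#'   constant `C` precomputed.
#' @export
test_function_family <- function(family = c("poly12", "bump", "hartley3"),
                                 a, eta = 9) {
  family <- match.arg(family)
  stopifnot(is.numeric(a), length(a) == 1L, a > 0)
  C <- normalization_constant(family, a, eta)
  structure(list(family = family, a = a, eta = eta, C = C),
            class = "test_function_family")
}

#' @export
print.test_function_family <- function(x, ...) {
  cat("<test_function_family> ", x$family, ", a = ", x$a,
      if (x$family == "bump") paste0(", eta = ", x$eta), ", C = ",
      signif(x$C, 6), "\n", sep = "")
  invisible(x)
}

# Unnormalized phi and its first two derivatives at offsets t from the
# center; vectorized, zero outside [-a, a].
phi_raw <- function(family, a, eta, t) {
  phi <- dphi <- ddphi <- numeric(length(t))
  inside <- abs(t) < a
  ti <- t[inside]
  if (family == "bump") {
    s <- ti / a
    u <- 1 - s^2
    f <- exp(-eta / u)
    g <- -2 * eta * s / (a * u^2)                 # (log f)'
    gp <- -2 * eta * (1 + 3 * s^2) / (a^2 * u^3)  # (log f)''
    phi[inside] <- f
    dphi[inside] <- f * g
    ddphi[inside] <- f * (g^2 + gp)
  } else if (family == "hartley3") {
    cas <- function(u) cos(u) + sin(u)
    dcas <- function(u) cos(u) - sin(u)
    w <- pi / a
    phi[inside] <- cas(6 * w * ti) - 3 * cas(4 * w * ti) +
      3 * cas(2 * w * ti) - 1
    dphi[inside] <- 6 * w * dcas(6 * w * ti) - 12 * w * dcas(4 * w * ti) +
      6 * w * dcas(2 * w * ti)
    ddphi[inside] <- -(6 * w)^2 * cas(6 * w * ti) +
      3 * (4 * w)^2 * cas(4 * w * ti) - 3 * (2 * w)^2 * cas(2 * w * ti)
  } else { # poly12: (t+a)^6 (a-t)^6 = (a^2 - t^2)^6
    u <- a^2 - ti^2
    phi[inside] <- u^6
    dphi[inside] <- -12 * ti * u^5
    ddphi[inside] <- -12 * u^4 * (a^2 - 11 * ti^2)
  }
  list(phi = phi, dphi = dphi, ddphi = ddphi)
}

#' Evaluate a test function and its derivatives
#'
#' Closed-form values of \eqn{\phi}, \eqn{\phi'} and \eqn{\phi''} at offsets
#' `t` from the support center; zero outside the support.
#'
#' @param tf a [test_function_family()].
#' @param t numeric vector of offsets from the center.
#' @return List with components `phi`, `dphi`, `ddphi`.
#' @export
phi_and_derivatives <- function(tf, t) {
  stopifnot(inherits(tf, "test_function_family"))
  v <- phi_raw(tf$family, tf$a, tf$eta, t)
  lapply(v, function(z) tf$C * z)
}

#' Normalization constant of a test function
#'
#' Returns `C` such that the continuous L2 norm of \eqn{C\phi_0} on
#' `[-a, a]` is 1, where \eqn{\phi_0} is the unnormalized family member.
#' The integral \eqn{\int_{-a}^{a}\phi_0^2\,dt} is computed with 200-node
#' Gauss-Legendre quadrature (exact for the polynomial family, accurate to
#' well below 1e-10 relative for the others).
#'
#' @inheritParams test_function_family
#' @return Scalar normalization constant.
#' @export
normalization_constant <- function(family, a, eta = 9) {
  gl <- pracma::gaussLegendre(200, -a, a)
  v <- phi_raw(family, a, eta, gl$x)
  nrm2 <- sum(gl$w * v$phi^2)
  1 / sqrt(nrm2)
}

#' Place test functions on an observation grid
#'
#' Places `K` test-function centers uniformly in
#' `[T0 + a, TM - a]` so that every support lies inside the observation
#' window, and builds the weak-form integration matrices: each row holds the
#' linear functional \eqn{f \mapsto \int (d^i\phi_k/dt^i)(t)\,\hat f(t)\,dt}
#' applied to samples of an integrand \eqn{f} on the grid, where
#' \eqn{\hat f} is the cubic-spline interpolant of the samples and the
#' integral is evaluated by composite trapezoid on an `upsample`-times finer
#' grid.  On coarse observation grids this spline-assisted quadrature keeps
#' the deterministic integration error far below the measurement noise
#' (plain trapezoid on a 40-point grid leaves a bias that the reweighted
#' regression would otherwise amplify); because spline interpolation is a
#' fixed linear map of the samples, noise still propagates exactly through
#' the same matrices.
#'
#' The default `K` is `max(10 * n_params, min(64, length(times) - 2))`:
#' densely overlapping supports are informative because the generalized
#' least-squares weighting accounts for the correlation between rows, but
#' the number of rows is kept below the number of observations (the residual
#' covariance has rank at most `length(times)`) and bounded for cost.
#'
#' @param times uniform observation grid.
#' @param tf a [test_function_family()].
#' @param K number of test functions; `NULL` for the default.
#' @param n_params number of unknowns (used only for the default `K`).
#' @param upsample spline-quadrature refinement factor (grid steps per
#'   observation step).
#' @return An object of class `test_function_grid`: list with `centers`,
#'   `weights` (trapezoid weights on `times`, for reference) and `PhiQ`, a
#'   list of the three `K x length(times)` weak-integration matrices for
#'   derivative orders 0, 1, 2.
#' @export
place_test_functions <- function(times, tf, K = NULL, n_params = 3L,
                                 upsample = 8L) {
  stopifnot(inherits(tf, "test_function_family"))
  Tm <- times[length(times)]; T0 <- times[1L]
  if (2 * tf$a >= Tm - T0)
    stop("test-function support (2a = ", 2 * tf$a,
         ") does not fit inside the observation window", call. = FALSE)
  h <- diff(times)
  lo <- T0 + tf$a; hi <- Tm - tf$a
  M1 <- length(times)
  if (is.null(K))
    K <- max(10L * n_params, min(64L, M1 - 2L))
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  centers <- if (K == 1L) (lo + hi) / 2 else seq(lo, hi, length.out = K)
  # cardinal cubic-spline interpolation matrix onto the refined grid
  upsample <- max(1L, as.integer(upsample))
  fine <- seq(T0, Tm, length.out = upsample * (M1 - 1L) + 1L)
  E <- vapply(seq_len(M1), function(j) {
    v <- numeric(M1); v[j] <- 1
    stats::spline(times, v, xout = fine, method = "fmm")$y
  }, numeric(length(fine)))
  hf <- diff(fine)
  qf <- c(hf[1L] / 2, (hf[-length(hf)] + hf[-1L]) / 2, hf[length(hf)] / 2)
  QE <- E * qf  # row-scaled: t(Phi_fine) -> integration against samples
  P0 <- P1 <- P2 <- matrix(0, K, M1)
  for (k in seq_len(K)) {
    v <- phi_and_derivatives(tf, fine - centers[k])
    P0[k, ] <- crossprod(v$phi, QE)
    P1[k, ] <- crossprod(v$dphi, QE)
    P2[k, ] <- crossprod(v$ddphi, QE)
  }
  q <- c(h[1L] / 2, (h[-length(h)] + h[-1L]) / 2, h[length(h)] / 2)
  structure(list(centers = centers, weights = q, times = as.numeric(times),
                 family = tf, K = K, upsample = upsample,
                 PhiQ = list(P0, P1, P2)),
            class = "test_function_grid")
}

#' @export
print.test_function_grid <- function(x, ...) {
  cat("<test_function_grid> ", x$K, " x ", length(x$times), " (",
      x$family$family, ", a = ", x$family$a, ")\n", sep = "")
  invisible(x)
}
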