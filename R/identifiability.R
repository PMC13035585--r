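#' Summarize an ensemble of WENDy fits
#'
#' Per-parameter Monte-Carlo summaries over `D` replicate fits: mean squared
#' error \eqn{\mathrm{MSE}_i = \mathrm{mean}((\hat w_{i,k} - w_i^*)^2)},
#' its bias/variance decomposition, the average relative error
#' \eqn{\mathrm{mean}(|\hat w_{i,k} - w_i^*| / |w_i^*|)}, and the empirical
#' coverage of the confidence intervals.  Failed (NULL or non-converged)
#' fits are excluded from the statistics but counted.
#'
#' @param fits list of `wendy_fit` objects (NULL entries mark failures).
#' @param w_true true coefficient vector (nonzero componentwise).
#' @param e the observation error ratio the ensemble was generated at.
#' @return An object of class `replicate_summary`: a data frame with one row
#'   per parameter (columns `parameter`, `w_true`, `mse`, `bias`, `variance`,
#'   `rel_err`, `coverage`) and attributes `e`, `D`, `failures`.
#' @export
summarize_fits <- function(fits, w_true, e = NA_real_) {
  stopifnot(all(w_true != 0))
  ok <- vapply(fits, function(f) !is.null(f) && all(is.finite(f$w_hat)),
               logical(1))
  failures <- sum(!ok)
  if (!any(ok))
    stop("all ", length(fits), " fits failed; nothing to summarize",
         call. = FALSE)
  good <- fits[ok]
  W <- do.call(rbind, lapply(good, `[[`, "w_hat"))
  LO <- do.call(rbind, lapply(good, `[[`, "ci_low"))
  HI <- do.call(rbind, lapply(good, `[[`, "ci_high"))
  n <- length(w_true)
  pn <- names(w_true)
  if (is.null(pn)) pn <- paste0("w", seq_len(n))
  dev <- sweep(W, 2, w_true)
  mse <- colMeans(dev^2)
  bias <- colMeans(dev)
  vr <- colMeans(sweep(dev, 2, bias)^2)
  rel <- colMeans(abs(dev) / matrix(abs(w_true), nrow(W), n, byrow = TRUE))
  cov <- colMeans(sweep(LO, 2, w_true, `<=`) & sweep(HI, 2, w_true, `>=`))
  out <- data.frame(parameter = pn, w_true = as.numeric(w_true),
                    mse = unname(mse), bias = unname(bias),
                    variance = unname(vr), rel_err = unname(rel),
                    coverage = unname(cov), row.names = NULL)
  structure(out, class = c("replicate_summary", "data.frame"),
            e = e, D = length(fits), failures = failures)
}

#' (e,q)-identifiability criterion
#'
#' A model is (e,q)-identifiable when, for data generated at observation
#' error ratio `e`, the estimator MSE of every parameter satisfies
#' \eqn{\mathrm{MSE}_i \le (q\,|w_i|)^2}, i.e.
#' \eqn{\max_i \sqrt{\mathrm{MSE}_i}/|w_i| \le q}.
#'
#' `min_q()` returns that maximum, the smallest `q` at which the summarized
#' ensemble passes the criterion.
#'
#' @param summary a [summarize_fits()] result.
#' @param q estimator error ratio threshold (> 0; 0.5 = 50\%).
#' @return `is_eq_identifiable`: logical. `min_q`: scalar.
#' @export
is_eq_identifiable <- function(summary, q) {
  stopifnot(q > 0)
  min_q(summary) <= q
}

#' @rdname is_eq_identifiable
#' @export
min_q <- function(summary) {
  stopifnot(inherits(summary, "replicate_summary"))
  max(sqrt(summary$mse) / abs(summary$w_true))
}

#' Monte-Carlo (e,q)-identifiability map
#'
#' For each observation error ratio in `e_values`, generates a `D`-replicate
#' ensemble, fits every replicate with WENDy, summarizes, and marks the
#' (e,q) cell identifiable when `min_q(e) <= q`.  Rows of the map are
#' monotone in `q` by construction.
#'
#' @param config a [blood_config()] / [sir_config()] experiment.
#' @param kind noise kind.
#' @param e_values vector of observation error ratios.
#' @param q_values vector of estimator error ratio thresholds.
#' @param D replicates per error ratio.
#' @param seed base seed; error ratio `i` uses `seed + 1000 * i`.
#' @return An object of class `eq_grid`: list with `e_values`, `q_values`,
#'   the logical `identifiable` matrix (e by q), `min_q` per e, and the
#'   per-e `summaries`.
#' @export
eq_grid <- function(config, kind = "additive_gaussian", e_values, q_values,
                    D = 1000, seed = 1L) {
  stopifnot(length(e_values) >= 1L, length(q_values) >= 1L)
  summaries <- vector("list", length(e_values))
  mq <- rep(NA_real_, length(e_values))
  for (i in seq_along(e_values)) {
    res <- tryCatch(
      run_replicates(config, e_values[i], kind, D,
                     seed = as.integer(seed + 1000 * i)),
      error = function(err) {
        warning("ensemble at e = ", e_values[i], " failed: ",
                conditionMessage(err), call. = FALSE)
        NULL
      })
    if (!is.null(res)) {
      summaries[[i]] <- res$summary
      mq[i] <- min_q(res$summary)
    }
  }
  ident <- outer(mq, q_values, `<=`)
  dimnames(ident) <- list(e = paste0(100 * e_values, "%"),
                          q = paste0(100 * q_values, "%"))
  structure(list(e_values = e_values, q_values = q_values,
                 identifiable = ident, min_q = mq, summaries = summaries,
                 kind = kind, D = D, model = config$name),
            class = "eq_grid")
}

#' @export
print.eq_grid <- function(x, ...) {
  cat("<eq_grid> ", x$model, " (", x$kind, "), D = ", x$D, "\n", sep = "")
  print(data.frame(e = x$e_values, min_q = signif(x$min_q, 4)))
  invisible(x)
}

#' Parameter-space sweep of the minimum estimator error ratio
#'
#' Evaluates `min_q` over a grid of blood-model coefficient vectors
#' `(w1, w2, w3)` with `w1` fixed, at one or more observation error ratios.
#' Each cell is inverted to original rates `(k12, k21, Ve)` through the
#' coefficient map; cells with no positive-rate preimage (`w3 <= w2` or
#' `k12 <= 0`) are flagged and skipped.
#'
#' @param w2_values,w3_values coefficient grids.
#' @param w1_fixed fixed value of `w1`.
#' @param e_values observation error ratios.
#' @param D replicates per cell and error ratio.
#' @param seed base seed.
#' @param M,horizon,family,a,eta,K forwarded to [blood_config()].
#' @return Data frame with columns `w1`, `w2`, `w3`, `k12`, `k21`, `Ve`,
#'   `valid`, `e`, `min_q`.
#' @export
parameter_sweep <- function(w2_values, w3_values, w1_fixed = 30,
                            e_values = 0.05, D = 100, seed = 1L,
                            M = 40, horizon = 2, family = "poly12",
                            a = 0.52, eta = 9, K = NULL) {
  grid <- expand.grid(w2 = w2_values, w3 = w3_values)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    w <- c(w1_fixed, grid$w2[g], grid$w3[g])
    inv <- invert_coefficient_map_blood(w)
    for (i in seq_along(e_values)) {
      row <- data.frame(w1 = w[1L], w2 = w[2L], w3 = w[3L],
                        k12 = inv$k12, k21 = inv$k21, Ve = inv$Ve,
                        valid = inv$valid, e = e_values[i],
                        min_q = NA_real_)
      if (inv$valid) {
        cfg <- blood_config(M = M, horizon = horizon, k12 = inv$k12,
                            k21 = inv$k21, Ve = inv$Ve, family = family,
                            a = a, eta = eta, K = K)
        res <- tryCatch(
          run_replicates(cfg, e_values[i], "additive_gaussian", D,
                         seed = as.integer(seed + 1000 * g + i)),
          error = function(err) NULL)
        if (!is.null(res)) row$min_q <- min_q(res$summary)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
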