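#' Derived TPC parameters: maximum rate, thermal optimum, thermal breadth
#'
#' From a converged TPC fit, locates the maximum rate `r_max` and its
#' temperature `t_opt` on a dense grid refined by golden-section search,
#' and computes the thermal breadth `t_br`: the total width of the
#' temperature region where the fitted rate is at least
#' `threshold * r_max` (default 0.8, i.e. rates exceeding 80% of the rate
#' at the optimum), clipped to `[grid_low, grid_high]`. Region boundaries
#' between grid points are located by linear interpolation. Negative
#' fitted rates (e.g. quadratic tails) are clamped to 0 here — never
#' during fitting.
#'
#' The breadth region of a unimodal fit is a single interval; a
#' multimodal fit can produce several, in which case the total measure is
#' reported and `contiguous` is `FALSE`. When the super-threshold region
#' touches a grid edge (monotone curve, optimum at the boundary) the
#' result is flagged `boundary_censored`: the true breadth extends beyond
#' the assessed range and no extrapolation is attempted.
#'
#' @param fit a converged `tpc_fit` from [fit_tpc()].
#' @param grid_low,grid_high temperature range assessed (degrees C);
#'   default the fitted data's range.
#' @param grid_step grid resolution in degrees C (default 0.01).
#' @param threshold breadth threshold as a proportion of `r_max`, in
#'   (0, 1); default 0.8.
#' @return a `tpc_derived`: list with `r_max`, `t_opt`, `t_br`,
#'   `breadth_threshold`, `contiguous`, `boundary_censored`, and the
#'   breadth `intervals` (two-column matrix).
#' @export
derive_tpc_params <- function(fit, grid_low = NULL, grid_high = NULL,
                              grid_step = 0.01, threshold = 0.8) {
  if (!inherits(fit, "tpc_fit")) stop_bad("'fit' must be a tpc_fit")
  if (!fit$converged) stop_bad("cannot derive parameters from a non-converged fit")
  check_scalar_number(threshold, "threshold")
  if (threshold <= 0 || threshold >= 1)
    stop_bad("'threshold' must be in (0, 1)")
  if (is.null(grid_low)) grid_low <- min(fit$data$temperature)
  if (is.null(grid_high)) grid_high <- max(fit$data$temperature)
  check_scalar_number(grid_low, "grid_low")
  check_scalar_number(grid_high, "grid_high")
  check_scalar_number(grid_step, "grid_step", lower = 1e-6)
  if (grid_high <= grid_low) stop_bad("'grid_high' must exceed 'grid_low'")

  f <- function(t) pmax(0, evaluate_tpc(fit$spec, fit$estimates, t))
  grid <- seq(grid_low, grid_high, by = grid_step)
  if (grid[length(grid)] < grid_high) grid <- c(grid, grid_high)
  vals <- evaluate_tpc(fit$spec, fit$estimates, grid)
  if (any(!is.finite(vals)))
    stop_bad("model evaluates to non-finite rates on the grid")
  vals <- pmax(0, vals)

  i_max <- which.max(vals)
  # refine the optimum within the bracketing grid cells
  lo_b <- grid[max(1L, i_max - 1L)]
  hi_b <- grid[min(length(grid), i_max + 1L)]
  if (hi_b > lo_b) {
    opt <- stats::optimize(f, interval = c(lo_b, hi_b), maximum = TRUE,
                           tol = 1e-8)
    t_opt <- opt$maximum
    r_max <- opt$objective
    if (r_max < vals[i_max]) { t_opt <- grid[i_max]; r_max <- vals[i_max] }
  } else {
    t_opt <- grid[i_max]; r_max <- vals[i_max]
  }

  cutoff <- threshold * r_max
  above <- vals >= cutoff
  intervals <- threshold_intervals(grid, vals, above, cutoff)
  t_br <- if (nrow(intervals)) sum(intervals[, 2] - intervals[, 1]) else 0
  boundary <- nrow(intervals) > 0 &&
    (abs(intervals[1, 1] - grid_low) < 1e-9 ||
       abs(intervals[nrow(intervals), 2] - grid_high) < 1e-9)

  structure(list(r_max = r_max, t_opt = t_opt, t_br = t_br,
                 breadth_threshold = threshold,
                 contiguous = nrow(intervals) <= 1L,
                 boundary_censored = boundary,
                 intervals = intervals,
                 grid_low = grid_low, grid_high = grid_high,
                 grid_step = grid_step),
            class = "tpc_derived")
}

# contiguous runs of `above` with linearly interpolated crossings
threshold_intervals <- function(grid, vals, above, cutoff) {
  n <- length(grid)
  out <- NULL
  i <- 1L
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      left <- grid[i]
      if (i > 1L && vals[i] != vals[i - 1L])
        left <- grid[i - 1L] + (cutoff - vals[i - 1L]) /
          (vals[i] - vals[i - 1L]) * (grid[i] - grid[i - 1L])
      right <- grid[j]
      if (j < n && vals[j] != vals[j + 1L])
        right <- grid[j] + (cutoff - vals[j]) /
          (vals[j + 1L] - vals[j]) * (grid[j + 1L] - grid[j])
      out <- rbind(out, c(left, right))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(out)) out <- matrix(numeric(0), ncol = 2)
  colnames(out) <- c("low", "high")
  out
}

#' @export
print.tpc_derived <- function(x, ...) {
  cat(sprintf("r_max = %.4g, T_opt = %.3f C, T_br = %.3f C (threshold %.0f%%)\n",
              x$r_max, x$t_opt, x$t_br, 100 * x$breadth_threshold))
  if (!x$contiguous) cat("  note: non-contiguous breadth region\n")
  if (x$boundary_censored) cat("  note: breadth censored at grid boundary\n")
  invisible(x)
}

#' Residual-bootstrap confidence intervals for TPC parameters
#'
#' Resamples centred residuals with replacement, adds them to the fitted
#' values, refits the model (starting from the original estimates), and
#' recomputes the derived parameters, giving percentile confidence
#' intervals for `r_max`, `t_opt`, `t_br` and each curve parameter.
#' Residuals are variance-corrected by `sqrt(n / (n - p))` (with p curve
#' parameters) before resampling: raw residuals from a fitted model have
#' deflated variance, and resampling them uncorrected yields intervals
#' that are systematically too narrow. Refit failures are skipped and
#' counted; intervals are flagged unreliable when more than half the
#' replicates fail.
#'
#' @inheritParams derive_tpc_params
#' @param data the dataset the fit came from (defaults to `fit$data`).
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param level confidence level, default 0.95.
#' @param seed integer seed.
#' @return a `tpc_bootstrap`: list with `derived` (point estimates),
#'   `ci` (data frame: quantity, estimate, low, high), `param_ci`,
#'   `n_boot`, `n_failed`, `failure_rate`, `unreliable`, `level`, and the
#'   bootstrap `draws` matrix.
#' @export
bootstrap_tpc <- function(fit, data = NULL, n_boot = 1000, level = 0.95,
                          seed = 1, grid_low = NULL, grid_high = NULL,
                          grid_step = 0.01, threshold = 0.8) {
  if (!inherits(fit, "tpc_fit")) stop_bad("'fit' must be a tpc_fit")
  if (!fit$converged) stop_bad("cannot bootstrap a non-converged fit")
  n_boot <- check_count(n_boot, "n_boot", min = 100L)
  check_scalar_number(level, "level")
  if (level <= 0 || level >= 1) stop_bad("'level' must be in (0, 1)")
  if (is.null(data)) data <- fit$data
  data <- as_tpc_dataset(data)

  temp <- data$temperature
  spec <- fit$spec
  est0 <- fit$estimates
  fitted0 <- fit$fitted
  n <- length(temp)
  p_curve <- length(est0)
  # variance-corrected residuals: fitted-model residuals underestimate the
  # error scale by ~ (n - p)/n
  res_c <- (fit$residuals - mean(fit$residuals)) *
    sqrt(n / max(1L, n - p_curve))
  b <- spec$bounds(temp, data$rate)
  lo <- as.numeric(b$lower); hi <- as.numeric(b$upper)
  if (is.null(grid_low)) grid_low <- min(temp)
  if (is.null(grid_high)) grid_high <- max(temp)

  point <- derive_tpc_params(fit, grid_low, grid_high, grid_step, threshold)

  p <- length(est0)
  draws <- matrix(NA_real_, n_boot, 3 + p,
                  dimnames = list(NULL, c("r_max", "t_opt", "t_br",
                                          names(est0))))
  n_failed <- 0L
  with_seed(seed, {
    for (bb in seq_len(n_boot)) {
      ystar <- fitted0 + sample(res_c, n, replace = TRUE)
      rssfun <- function(par) {
        r <- spec$fun(temp, stats::setNames(par, spec$parameter_names))
        if (any(!is.finite(r))) return(1e300)
        sum((ystar - r)^2)
      }
      refit <- try_optim(rssfun, as.numeric(est0), lo, hi)
      if (is.null(refit)) { n_failed <- n_failed + 1L; next }
      estb <- stats::setNames(refit$par, spec$parameter_names)
      fb <- list(model = spec$name, spec = spec, estimates = estb,
                 converged = TRUE,
                 data = data.frame(temperature = temp, rate = ystar))
      class(fb) <- "tpc_fit"
      db <- tryCatch(derive_tpc_params(fb, grid_low, grid_high, grid_step,
                                       threshold),
                     error = function(e) NULL)
      if (is.null(db)) { n_failed <- n_failed + 1L; next }
      draws[bb, ] <- c(db$r_max, db$t_opt, db$t_br, estb)
    }
  })

  ok <- stats::complete.cases(draws)
  alpha <- (1 - level) / 2
  qs <- function(v) stats::quantile(v[ok], c(alpha, 1 - alpha), names = FALSE,
                                    type = 7)
  ci <- data.frame(quantity = c("r_max", "t_opt", "t_br"),
                   estimate = c(point$r_max, point$t_opt, point$t_br),
                   low = NA_real_, high = NA_real_)
  for (i in 1:3) { q <- qs(draws[, i]); ci$low[i] <- q[1]; ci$high[i] <- q[2] }
  param_ci <- data.frame(parameter = names(est0), estimate = as.numeric(est0),
                         low = NA_real_, high = NA_real_)
  for (i in seq_len(p)) {
    q <- qs(draws[, 3 + i]); param_ci$low[i] <- q[1]; param_ci$high[i] <- q[2]
  }

  structure(list(derived = point, ci = ci, param_ci = param_ci,
                 n_boot = n_boot, n_failed = n_failed,
                 failure_rate = n_failed / n_boot,
                 unreliable = n_failed / n_boot > 0.5,
                 level = level, draws = draws[ok, , drop = FALSE]),
            class = "tpc_bootstrap")
}

#' @export
print.tpc_bootstrap <- function(x, ...) {
  cat(sprintf("Residual bootstrap, %d replicates (%d failed%s), %.0f%% CIs:\n",
              x$n_boot, x$n_failed,
              if (x$unreliable) "; UNRELIABLE" else "", 100 * x$level))
  print(x$ci, row.names = FALSE)
  invisible(x)
}
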