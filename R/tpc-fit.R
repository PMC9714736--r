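#' Small-sample corrected Akaike Information Criterion for least-squares fits
#'
#' AICc for a model fitted by nonlinear least squares under the Gaussian
#' likelihood: `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)` with
#' `logLik = -n/2 (log(2 pi) + log(rss/n) + 1)`.
#'
#' `k` is the number of parameters entering the information criterion. By
#' the convention used throughout this package (and stated here because
#' published AICc values differ by convention), `k` counts the model's
#' curve parameters **plus one** residual-variance parameter; the caller
#' passes that total. Requires `n - k - 1 > 0`; smaller samples cannot be
#' ranked and the model must be excluded.
#'
#' @param rss residual sum of squares (> 0).
#' @param n number of observations.
#' @param k number of likelihood parameters (curve parameters + 1).
#' @return AICc (scalar). `bic_ls()` returns the Schwarz criterion
#'   `-2 logLik + k log(n)` under the same likelihood.
#' @examples
#' aicc(rss = 1, n = 10, k = 3)  # 15.35292
#' @export
aicc <- function(rss, n, k) {
  check_scalar_number(rss, "rss", lower = 0)
  n <- check_count(n, "n")
  k <- check_count(k, "k")
  if (rss <= 0) stop_bad("'rss' must be > 0 (degenerate zero-residual fit)")
  if (n - k - 1 <= 0)
    stop_bad(sprintf("AICc undefined: need n - k - 1 > 0 (n = %d, k = %d)", n, k))
  -2 * gauss_loglik(rss, n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc
#' @export
bic_ls <- function(rss, n, k) {
  check_scalar_number(rss, "rss", lower = 0)
  n <- check_count(n, "n")
  k <- check_count(k, "k")
  if (rss <= 0) stop_bad("'rss' must be > 0 (degenerate zero-residual fit)")
  -2 * gauss_loglik(rss, n) + k * log(n)
}

gauss_loglik <- function(rss, n) -n / 2 * (log(2 * pi) + log(rss / n) + 1)

#' Construct a TPC dataset
#'
#' Bundles (temperature, rate) observations — one row per biological
#' replicate — for TPC fitting. At least 5 points are required.
#'
#' @param temperature numeric, degrees C.
#' @param rate numeric, trait units (proportion for fertilization and
#'   motility, um/s for sperm velocity).
#' @param replicate_id optional identifiers, recycled if length 1.
#' @param trait_name label used in outputs.
#' @return a `tpc_dataset`: data frame with columns `temperature`, `rate`,
#'   `replicate_id` and attribute `trait_name`.
#' @export
tpc_dataset <- function(temperature, rate, replicate_id = NULL,
                        trait_name = "rate") {
  check_numeric_vector(temperature, "temperature", min_len = 5L)
  check_numeric_vector(rate, "rate", min_len = 5L)
  if (length(temperature) != length(rate))
    stop_bad("'temperature' and 'rate' must have equal length")
  if (is.null(replicate_id)) replicate_id <- seq_along(temperature)
  if (length(replicate_id) == 1L)
    replicate_id <- rep(replicate_id, length(temperature))
  out <- data.frame(temperature = temperature, rate = rate,
                    replicate_id = as.character(replicate_id),
                    stringsAsFactors = FALSE)
  attr(out, "trait_name") <- trait_name
  class(out) <- c("tpc_dataset", "data.frame")
  out
}

as_tpc_dataset <- function(data) {
  if (inherits(data, "tpc_dataset")) return(data)
  if (is.data.frame(data) && all(c("temperature", "rate") %in% names(data)))
    return(tpc_dataset(data$temperature, data$rate,
                       if ("replicate_id" %in% names(data)) data$replicate_id))
  stop_bad("'data' must be a tpc_dataset or data frame with temperature/rate")
}

#' Fit one TPC model by bounded multistart nonlinear least squares
#'
#' Minimises the residual sum of squares over the model's box constraints
#' with `n_starts` seeded starting points: the model's data-driven start
#' (thermal optimum near the argmax of the observed rates, height near the
#' maximum rate), jittered copies of it, and uniform draws within bounds.
#' Each start is polished with L-BFGS-B; Nelder-Mead (clamped to bounds)
#' is used as a fallback when the gradient-based run fails. The best
#' converged start wins.
#'
#' @param data a [tpc_dataset()] or data frame with `temperature`, `rate`.
#' @param spec a `tpc_model_spec` or model name from [tpc_model()].
#' @param n_starts number of starting points (default 10).
#' @param seed integer seed controlling the multistart draws.
#' @return a `tpc_fit`: list with `model` (name), `spec`, `estimates`
#'   (named vector), `rss`, `n`, `k` (curve parameters + 1 variance
#'   parameter, the AICc convention), `aicc`, `bic`, `converged`,
#'   `fitted`, `residuals`, `data`, and `status` (diagnostic string).
#'   `aicc`/`bic` are `NA` when `n - k - 1 <= 0` or the fit failed;
#'   such fits are excluded by [rank_tpc_models()].
#' @export
fit_tpc <- function(data, spec, n_starts = 10, seed = 1) {
  data <- as_tpc_dataset(data)
  if (is.character(spec)) spec <- tpc_model(spec)
  n_starts <- check_count(n_starts, "n_starts")
  temp <- data$temperature
  rate <- data$rate
  n <- length(temp)
  p <- length(spec$parameter_names)
  k <- p + 1L  # + residual variance
  if (n < p + 2)
    stop_bad(sprintf("model '%s' needs at least %d points, got %d",
                     spec$name, p + 2, n))

  b <- spec$bounds(temp, rate)
  lo <- as.numeric(b$lower); hi <- as.numeric(b$upper)
  rssfun <- function(par) {
    r <- spec$fun(temp, stats::setNames(par, spec$parameter_names))
    if (any(!is.finite(r))) return(1e300)
    sum((rate - r)^2)
  }

  starts <- with_seed(seed, {
    s0 <- pmin(pmax(as.numeric(spec$start(temp, rate)), lo), hi)
    out <- list(s0)
    n_jit <- min(n_starts - 1L, max(0L, floor((n_starts - 1L) / 2)))
    for (i in seq_len(n_jit)) {
      jit <- s0 + stats::rnorm(p, 0, 0.1 * pmax(abs(s0), (hi - lo) / 20))
      out[[length(out) + 1L]] <- pmin(pmax(jit, lo), hi)
    }
    while (length(out) < n_starts)
      out[[length(out) + 1L]] <- stats::runif(p, lo, hi)
    out
  })

  best <- NULL
  for (st in starts) {
    fit <- try_optim(rssfun, st, lo, hi)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }

  if (is.null(best)) {
    res <- list(model = spec$name, spec = spec, estimates = NULL, rss = NA_real_,
                n = n, k = k, aicc = NA_real_, bic = NA_real_,
                converged = FALSE, fitted = NULL, residuals = NULL,
                data = data, status = "all starts failed")
    class(res) <- "tpc_fit"
    return(res)
  }

  est <- stats::setNames(best$par, spec$parameter_names)
  fitted <- spec$fun(temp, est)
  rss <- sum((rate - fitted)^2)
  crit_ok <- (n - k - 1) > 0
  status <- "ok"
  if (!crit_ok) status <- "excluded: n - k - 1 <= 0, AICc undefined"
  # A numerically-zero RSS (noiseless data) has no finite Gaussian likelihood;
  # floor it for ranking and flag the status.
  rss_ic <- rss
  if (crit_ok && rss_ic < 1e-12 * max(1, sum(rate^2))) {
    rss_ic <- 1e-12 * max(1, sum(rate^2))
    status <- "ok (rss floored for information criteria)"
  }
  res <- list(model = spec$name, spec = spec, estimates = est, rss = rss,
              n = n, k = k,
              aicc = if (crit_ok) aicc(rss_ic, n, k) else NA_real_,
              bic = if (crit_ok) bic_ls(rss_ic, n, k) else NA_real_,
              converged = TRUE, fitted = fitted, residuals = rate - fitted,
              data = data, status = status)
  class(res) <- "tpc_fit"
  res
}

try_optim <- function(fn, start, lo, hi) {
  f <- tryCatch(
    stats::optim(start, fn, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(f) || !is.finite(f$value) || f$value >= 1e299) {
    # Nelder-Mead on the clamped objective as fallback
    fnc <- function(par) fn(pmin(pmax(par, lo), hi))
    f <- tryCatch(stats::optim(start, fnc, method = "Nelder-Mead",
                               control = list(maxit = 1000)),
                  error = function(e) NULL)
    if (is.null(f) || !is.finite(f$value) || f$value >= 1e299) return(NULL)
    f$par <- pmin(pmax(f$par, lo), hi)
  }
  f
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat(sprintf("TPC fit: %s (n = %d, k = %d)\n", x$model, x$n, x$k))
  if (x$converged) {
    cat("  estimates:", paste(sprintf("%s = %.4g", names(x$estimates),
                                      x$estimates), collapse = ", "), "\n")
    cat(sprintf("  rss = %.6g, AICc = %.4f, BIC = %.4f\n",
                x$rss, x$aicc, x$bic))
  }
  cat("  status:", x$status, "\n")
  invisible(x)
}

#' Fit and rank candidate TPC models by AICc
#'
#' Fits every candidate with [fit_tpc()] and returns the converged,
#' rankable fits sorted by ascending AICc (ties broken by fewer
#' parameters, then by model name). Fits that fail to converge or whose
#' AICc is undefined (`n - k - 1 <= 0`) are excluded from the ranking and
#' listed with reasons in the `exclusions` attribute.
#'
#' @inheritParams fit_tpc
#' @param specs list of `tpc_model_spec` objects or character vector of
#'   model names; at least 2 unless `allow_single = TRUE` callers pass one.
#' @return a `tpc_ranking`: list of `tpc_fit` in rank order, with
#'   attributes `table` (data frame: model, k, rss, aicc, bic, delta_aicc)
#'   and `exclusions` (data frame: model, reason).
#' @export
rank_tpc_models <- function(data, specs = names(tpc_models()), n_starts = 10,
                            seed = 1) {
  data <- as_tpc_dataset(data)
  if (is.character(specs)) specs <- tpc_models(specs)
  if (length(specs) < 1L) stop_bad("need at least one candidate model")
  fits <- vector("list", length(specs))
  excl <- data.frame(model = character(), reason = character(),
                     stringsAsFactors = FALSE)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    f <- tryCatch(fit_tpc(data, sp, n_starts = n_starts,
                          seed = derive_seed(seed, i)),
                  error = function(e) e)
    if (inherits(f, "error")) {
      excl <- rbind(excl, data.frame(model = sp$name,
                                     reason = conditionMessage(f)))
      fits[[i]] <- NULL
    } else fits[[i]] <- f
  }
  fits <- Filter(Negate(is.null), fits)
  keep <- vapply(fits, function(f) f$converged && is.finite(f$aicc), logical(1))
  for (f in fits[!keep])
    excl <- rbind(excl, data.frame(model = f$model, reason = f$status))
  fits <- fits[keep]
  if (length(fits) == 0L)
    stop_bad("no candidate TPC model converged with a defined AICc")
  ord <- order(vapply(fits, `[[`, numeric(1), "aicc"),
               vapply(fits, `[[`, integer(1), "k"),
               vapply(fits, `[[`, character(1), "model"))
  fits <- fits[ord]
  a <- vapply(fits, `[[`, numeric(1), "aicc")
  tab <- data.frame(model = vapply(fits, `[[`, character(1), "model"),
                    k = vapply(fits, `[[`, integer(1), "k"),
                    rss = vapply(fits, `[[`, numeric(1), "rss"),
                    aicc = a,
                    bic = vapply(fits, `[[`, numeric(1), "bic"),
                    delta_aicc = a - min(a),
                    stringsAsFactors = FALSE)
  structure(fits, class = "tpc_ranking", table = tab, exclusions = excl)
}

#' @export
print.tpc_ranking <- function(x, ...) {
  cat("TPC model ranking (ascending AICc):\n")
  print(attr(x, "table"), row.names = FALSE)
  ex <- attr(x, "exclusions")
  if (nrow(ex)) {
    cat("excluded:\n")
    print(ex, row.names = FALSE)
  }
  invisible(x)
}
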