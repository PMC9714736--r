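#' Thermal performance curve model registry
#'
#' A thermal performance curve (TPC) describes the typically unimodal
#' dependence of a biological rate (here: fertilization rate, sperm
#' curvilinear velocity, or sperm motility) on temperature. The registry
#' holds the candidate models that [rank_tpc_models()] fits and ranks by
#' small-sample AICc. Functional forms follow the parameterisations in
#' common use in the thermal-ecology literature; all take temperature in
#' degrees Celsius and return a rate in the units of the fitted trait.
#'
#' Available models: `quadratic`, `gaussian`, `modgaussian` (modified
#' gaussian with a free exponent), `briere2`, `sharpeschoolhigh`
#' (Sharpe-Schoolfield with high-temperature inactivation), `ratkowsky`,
#' `weibull`, `lactin2`, `rezende`, `flinn`.
#'
#' @param names character vector of model names; default is the full
#'   registry.
#' @return For `tpc_model()`, a `tpc_model_spec` object: a list with
#'   `name`, `parameter_names`, and functions `fun(temp, params)`,
#'   `bounds(temp, rate)` and `start(temp, rate)`. For `tpc_models()`,
#'   a named list of such objects.
#' @examples
#' spec <- tpc_model("gaussian")
#' evaluate_tpc(spec, c(rmax = 1, topt = 17.6, a = 5), 10:25)
#' @export
tpc_model <- function(names) {
  if (length(names) != 1L) stop_bad("'names' must be a single model name")
  reg <- tpc_registry()
  if (!names %in% base::names(reg))
    stop_bad(sprintf("unknown TPC model '%s'; available: %s", names,
                     paste(base::names(reg), collapse = ", ")))
  reg[[names]]
}

#' @rdname tpc_model
#' @export
tpc_models <- function(names = NULL) {
  reg <- tpc_registry()
  if (is.null(names)) return(reg)
  lapply(stats::setNames(names, names), tpc_model)
}

#' Evaluate a TPC model on a temperature grid
#'
#' @param spec a `tpc_model_spec` from [tpc_model()], or a model name.
#' @param params named or positional numeric vector, in the order of
#'   `spec$parameter_names`.
#' @param temp numeric vector of temperatures (degrees C).
#' @return numeric vector of rates, same length as `temp`. Models with a
#'   bounded thermal support return 0 outside it.
#' @export
evaluate_tpc <- function(spec, params, temp) {
  if (is.character(spec)) spec <- tpc_model(spec)
  if (!inherits(spec, "tpc_model_spec")) stop_bad("'spec' must be a tpc_model_spec")
  k <- length(spec$parameter_names)
  if (length(params) != k)
    stop_bad(sprintf("model '%s' needs %d parameters (%s)", spec$name, k,
                     paste(spec$parameter_names, collapse = ", ")))
  check_numeric_vector(as.numeric(params), "params", min_len = k)
  p <- as.numeric(params)
  names(p) <- spec$parameter_names
  r <- spec$fun(temp, p)
  r[!is.finite(r)] <- NA_real_
  r
}

# ---- registry ---------------------------------------------------------------

# Each bounds()/start() is data-driven: location parameters track the observed
# temperature range, scale parameters the rate range. start() returns the
# centre of the multistart cloud; fit_tpc() jitters around it and adds
# uniform-in-bounds draws.

tpc_registry <- function() {
  boltz <- 8.62e-5  # eV / K

  mk <- function(name, pars, fun, bounds, start) {
    structure(list(name = name, parameter_names = pars, fun = fun,
                   bounds = bounds, start = start),
              class = "tpc_model_spec")
  }

  rng <- function(temp) range(temp)
  rmax0 <- function(rate) max(abs(rate), 1e-6)
  # temperature at the (lightly smoothed) maximum observed rate
  topt0 <- function(temp, rate) {
    o <- order(temp)
    t_s <- temp[o]; r_s <- rate[o]
    agg <- tapply(r_s, t_s, mean)
    as.numeric(names(agg)[which.max(agg)])
  }

  list(
    quadratic = mk("quadratic", c("a", "b", "c"),
      fun = function(temp, p) p[["a"]] + p[["b"]] * temp + p[["c"]] * temp^2,
      bounds = function(temp, rate) {
        m <- rmax0(rate)
        list(lower = c(a = -100 * m, b = -50 * m, c = -10 * m),
             upper = c(a = 100 * m, b = 50 * m, c = 10 * m))
      },
      start = function(temp, rate) {
        cf <- tryCatch(stats::coef(stats::lm(rate ~ temp + I(temp^2))),
                       error = function(e) c(mean(rate), 0, 0))
        cf[!is.finite(cf)] <- 0
        c(a = cf[[1]], b = cf[[2]], c = cf[[3]])
      }),

    gaussian = mk("gaussian", c("rmax", "topt", "a"),
      fun = function(temp, p)
        p[["rmax"]] * exp(-0.5 * ((temp - p[["topt"]]) / p[["a"]])^2),
      bounds = function(temp, rate) {
        r <- rng(temp); w <- diff(r)
        list(lower = c(rmax = 0, topt = r[1] - w, a = 0.1),
             upper = c(rmax = 5 * rmax0(rate), topt = r[2] + w, a = 5 * w))
      },
      start = function(temp, rate)
        c(rmax = rmax0(rate), topt = topt0(temp, rate),
          a = diff(rng(temp)) / 4)),

    modgaussian = mk("modgaussian", c("rmax", "topt", "a", "b"),
      fun = function(temp, p)
        p[["rmax"]] * exp(-0.5 * (abs(temp - p[["topt"]]) / p[["a"]])^p[["b"]]),
      bounds = function(temp, rate) {
        r <- rng(temp); w <- diff(r)
        list(lower = c(rmax = 0, topt = r[1] - w, a = 0.1, b = 0.5),
             upper = c(rmax = 5 * rmax0(rate), topt = r[2] + w, a = 5 * w, b = 8))
      },
      start = function(temp, rate)
        c(rmax = rmax0(rate), topt = topt0(temp, rate),
          a = diff(rng(temp)) / 4, b = 2)),

    briere2 = mk("briere2", c("tmin", "tmax", "a", "b"),
      fun = function(temp, p) {
        r <- p[["a"]] * temp * (temp - p[["tmin"]]) *
          (pmax(p[["tmax"]] - temp, 0))^(1 / p[["b"]])
        r[temp <= p[["tmin"]] | temp >= p[["tmax"]]] <- 0
        r
      },
      bounds = function(temp, rate) {
        r <- rng(temp); w <- diff(r)
        list(lower = c(tmin = r[1] - 2 * w, tmax = r[1], a = 0, b = 0.5),
             upper = c(tmin = r[2], tmax = r[2] + 2 * w,
                       a = 10 * rmax0(rate), b = 20))
      },
      start = function(temp, rate) {
        r <- rng(temp); w <- diff(r)
        c(tmin = r[1] - w / 4, tmax = r[2] + w / 4,
          a = rmax0(rate) / max(r[2]^2 * w^(1 / 3), 1e-6), b = 3)
      }),

    sharpeschoolhigh = mk("sharpeschoolhigh", c("rtref", "e", "eh", "th"),
      fun = function(temp, p) {
        tk <- temp + 273.15; tref <- 20 + 273.15
        p[["rtref"]] * exp(p[["e"]] / boltz * (1 / tref - 1 / tk)) /
          (1 + exp(p[["eh"]] / boltz * (1 / p[["th"]] - 1 / tk)))
      },
      bounds = function(temp, rate) {
        r <- rng(temp) + 273.15
        list(lower = c(rtref = 0, e = 0.01, eh = 0.02, th = r[1] - 20),
             upper = c(rtref = 10 * rmax0(rate), e = 10, eh = 40,
                       th = r[2] + 20))
      },
      start = function(temp, rate)
        c(rtref = rmax0(rate), e = 0.6, eh = 5,
          th = topt0(temp, rate) + 273.15 + 3)),

    ratkowsky = mk("ratkowsky", c("tmin", "tmax", "a", "b"),
      fun = function(temp, p) {
        r <- (p[["a"]] * (temp - p[["tmin"]]) *
                (1 - exp(p[["b"]] * (temp - p[["tmax"]]))))^2
        r[temp <= p[["tmin"]] | temp >= p[["tmax"]]] <- 0
        r
      },
      bounds = function(temp, rate) {
        r <- rng(temp); w <- diff(r)
        list(lower = c(tmin = r[1] - 2 * w, tmax = r[1], a = 0, b = 0.01),
             upper = c(tmin = r[2], tmax = r[2] + 2 * w,
                       a = 10 * sqrt(rmax0(rate)), b = 5))
      },
      start = function(temp, rate) {
        r <- rng(temp); w <- diff(r)
        c(tmin = r[1] - w / 2, tmax = r[2] + w / 10,
          a = sqrt(rmax0(rate)) / max(w, 1), b = 0.3)
      }),

    weibull = mk("weibull", c("a", "topt", "b", "c"),
      fun = function(temp, p) {
        cc <- p[["c"]]
        base <- (temp - p[["topt"]]) / p[["b"]] + ((cc - 1) / cc)^(1 / cc)
        r <- ifelse(base > 0,
                    p[["a"]] * ((cc - 1) / cc)^((1 - cc) / cc) *
                      base^(cc - 1) * exp(-base^cc + (cc - 1) / cc),
                    0)
        r
      },
      bounds = function(temp, rate) {
        r <- rng(temp); w <- diff(r)
        list(lower = c(a = 0, topt = r[1] - w, b = 0.5, c = 1.1),
             upper = c(a = 5 * rmax0(rate), topt = r[2] + w, b = 10 * w, c = 20))
      },
      start = function(temp, rate)
        c(a = rmax0(rate), topt = topt0(temp, rate),
          b = diff(rng(temp)) / 2, c = 3)),

    lactin2 = mk("lactin2", c("a", "b", "tmax", "delta"),
      fun = function(temp, p)
        exp(p[["a"]] * temp) -
          exp(p[["a"]] * p[["tmax"]] - (p[["tmax"]] - temp) / p[["delta"]]) +
          p[["b"]],
      bounds = function(temp, rate) {
        r <- rng(temp); w <- diff(r)
        list(lower = c(a = 1e-4, b = -5 * rmax0(rate) - 1, tmax = r[1],
                       delta = 0.1),
             upper = c(a = 0.5, b = 5 * rmax0(rate) + 1, tmax = r[2] + 2 * w,
                       delta = 20))
      },
      start = function(temp, rate)
        c(a = 0.02, b = -0.5, tmax = max(temp) + 2, delta = 4)),

    rezende = mk("rezende", c("q10", "a", "b", "tth"),
      fun = function(temp, p) {
        base <- p[["b"]] * p[["q10"]]^(temp / 10)
        ifelse(temp <= p[["tth"]], base,
               base * pmax(1 - p[["a"]] * (temp - p[["tth"]])^2, 0))
      },
      bounds = function(temp, rate) {
        r <- rng(temp); w <- diff(r)
        list(lower = c(q10 = 1.01, a = 0, b = 1e-9, tth = r[1] - w),
             upper = c(q10 = 10, a = 10, b = 10 * rmax0(rate), tth = r[2] + w))
      },
      start = function(temp, rate)
        c(q10 = 2, a = 0.01, b = rmax0(rate) / 2^(topt0(temp, rate) / 10),
          tth = topt0(temp, rate))),

    flinn = mk("flinn", c("a", "b", "c"),
      fun = function(temp, p)
        1 / (1 + exp(p[["a"]] + p[["b"]] * temp + p[["c"]] * temp^2)),
      bounds = function(temp, rate) {
        list(lower = c(a = -500, b = -100, c = -10),
             upper = c(a = 500, b = 100, c = 10))
      },
      start = function(temp, rate) {
        to <- topt0(temp, rate)
        c(a = 0.05 * to^2 - 1, b = -0.1 * to, c = 0.05)
      })
  )
}
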