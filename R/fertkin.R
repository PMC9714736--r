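#' Fertilization kinetics: proportion of eggs fertilized
#'
#' Collision-kinetics model for external fertilization by broadcast
#' spawners. With sperm concentration `s0` and egg concentration `e0`
#' (counts per microlitre; 1 ul = 1 mm^3, so per-ul concentrations are
#' numerically per-mm^3), exposure time `t` (s), fertilization rate
#' constant `beta` and egg-sperm contact rate constant `beta0` (both
#' mm^3/s), the expected proportion of fertilized eggs is
#'
#' `phi = 1 - exp( -(beta * s0 / (beta0 * e0)) * (1 - exp(-beta0 * e0 * t)) )`
#'
#' Limits: `t = 0` or `s0 = 0` give 0; `t -> Inf` gives the asymptote
#' `1 - exp(-beta * s0 / (beta0 * e0))`. phi is non-decreasing in `t`,
#' `s0` and `beta`, and (at fixed `beta/beta0` ratio) non-decreasing in
#' sperm velocity: faster sperm can never reduce predicted fertilization.
#'
#' @param s0 sperm concentration, count/ul (>= 0).
#' @param e0 egg concentration, count/ul (> 0).
#' @param t exposure time, s (>= 0).
#' @param beta fertilization rate constant, mm^3/s (>= 0).
#' @param beta0 contact rate constant, mm^3/s (> 0); see
#'   [beta0_from_swimming()].
#' @return proportion in [0, 1]; vectorised over any argument.
#' @examples
#' phi_fertilized(s0 = 1, e0 = 1, t = 1e6, beta = 1, beta0 = 1) # ~ 1 - exp(-1)
#' @export
phi_fertilized <- function(s0, e0, t, beta, beta0) {
  ln <- max(length(s0), length(e0), length(t), length(beta), length(beta0))
  for (nm in c("s0", "e0", "t", "beta", "beta0")) {
    v <- get(nm)
    if (!is.numeric(v) || any(!is.finite(v)))
      stop_bad(sprintf("'%s' must be finite numeric", nm))
    if (any(v < 0)) stop_bad(sprintf("'%s' must be non-negative", nm))
  }
  if (any(e0 <= 0)) stop_bad("'e0' must be > 0")
  if (any(beta0 <= 0)) stop_bad("'beta0' must be > 0")
  s0 <- rep_len(s0, ln); e0 <- rep_len(e0, ln); t <- rep_len(t, ln)
  beta <- rep_len(beta, ln); beta0 <- rep_len(beta0, ln)
  # -expm1(-x) = 1 - exp(-x), accurate for small exposures
  inner <- -expm1(-beta0 * e0 * t)
  clamp01(-expm1(-(beta * s0 / (beta0 * e0)) * inner))
}

#' Contact rate constant from sperm swimming
#'
#' The egg-sperm contact rate constant is the volume a sperm sweeps past
#' egg cross-sections per unit time: `beta0 = upsilon * sigma0`, with
#' velocity in um/s and egg cross-sectional area in um^2. The product is
#' in um^3/s and is converted exactly to mm^3/s (1 mm^3 = 1e9 um^3).
#'
#' @param upsilon sperm velocity, um/s (>= 0).
#' @param sigma0 egg cross-sectional area, um^2 (>= 0); see
#'   [egg_cross_section()].
#' @return beta0 in mm^3/s; vectorised.
#' @examples
#' beta0_from_swimming(100, 1e4)  # 1e-3 mm^3/s
#' @export
beta0_from_swimming <- function(upsilon, sigma0) {
  if (any(!is.finite(upsilon)) || any(upsilon < 0))
    stop_bad("'upsilon' must be finite and non-negative")
  if (any(!is.finite(sigma0)) || any(sigma0 < 0))
    stop_bad("'sigma0' must be finite and non-negative")
  upsilon * sigma0 * 1e-9
}

#' Egg cross-sectional area from diameter
#'
#' `sigma0 = pi d^2 / 4` for a spherical egg of diameter `d` um. The
#' default diameter used elsewhere in the package (130 um) is an
#' illustrative value for sand-dollar-sized eggs, not a measured one.
#'
#' @param diameter egg diameter, um (> 0).
#' @return area in um^2.
#' @export
egg_cross_section <- function(diameter) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop_bad("'diameter' must be finite and positive")
  pi * diameter^2 / 4
}

#' Sperm concentration after dish dilution
#'
#' Worked helper for the common assay protocol: a sperm stock of
#' `stock_per_ml` sperm/ml, of which `added_ul` ul are pipetted into a
#' dish holding `dish_ml` ml, gives
#' `stock_per_ml * (added_ul / 1000) / (dish_ml * 1000)` sperm/ul.
#' The default (1e5 sperm/ml stock, 50 ul into an 11 ml dish) gives
#' about 0.455 sperm/ul.
#'
#' @param stock_per_ml stock concentration, sperm/ml.
#' @param added_ul volume of stock added, ul.
#' @param dish_ml total dish volume, ml.
#' @return sperm concentration in the dish, count/ul.
#' @export
dish_sperm_concentration <- function(stock_per_ml = 1e5, added_ul = 50,
                                     dish_ml = 11) {
  check_scalar_number(stock_per_ml, "stock_per_ml", lower = 0)
  check_scalar_number(added_ul, "added_ul", lower = 0)
  check_scalar_number(dish_ml, "dish_ml", lower = 1e-12)
  stock_per_ml * (added_ul / 1000) / (dish_ml * 1000)
}

#' Fit the beta/beta0 ratio to observed fertilization
#'
#' One-dimensional least squares for the ratio of the fertilization rate
#' constant to the contact rate constant: minimises
#' `sum((phi_model - phi_obs)^2)` over ratio in (0, upper]. The predicted
#' phi is monotone in the ratio, so a bounded scalar minimisation
#' (golden-section, [stats::optimize()]) suffices; no multistart is
#' needed. For a single noiseless observation the estimate equals the
#' closed-form inversion `-log(1 - phi) * e0 / (s0 * (1 - exp(-beta0 e0 t)))`.
#' Observations must not all be saturated: if every observed phi is 0 or
#' 1 the ratio is not identifiable and the fit is rejected.
#'
#' @param observations data frame with columns `measured_phi`, `s0`,
#'   `e0`, `t`, `beta0` (one row per condition).
#' @param upper upper bound for the ratio (default 10).
#' @return list with `ratio`, `se` (Gaussian curvature-based standard
#'   error, `NA` for < 2 observations or a boundary solution), `rss`,
#'   `n`, `fitted_phi`.
#' @export
fit_beta_ratio <- function(observations, upper = 10) {
  obs <- observations
  need <- c("measured_phi", "s0", "e0", "t", "beta0")
  if (!is.data.frame(obs) || !all(need %in% names(obs)))
    stop_bad(sprintf("'observations' needs columns: %s",
                     paste(need, collapse = ", ")))
  if (nrow(obs) < 1L) stop_bad("need at least one observation")
  if (any(obs$measured_phi < 0 | obs$measured_phi > 1))
    stop_bad("'measured_phi' must lie in [0, 1]")
  if (all(obs$measured_phi %in% c(0, 1)))
    stop_bad("ratio not identifiable: every observed phi is 0 or 1; need at least one interior value")
  check_scalar_number(upper, "upper", lower = 1e-12)

  pred <- function(ratio)
    phi_fertilized(obs$s0, obs$e0, obs$t, beta = ratio * obs$beta0,
                   beta0 = obs$beta0)
  ssq <- function(ratio) sum((pred(ratio) - obs$measured_phi)^2)

  # closed-form inversion of interior observations brackets the optimum
  interior <- obs$measured_phi > 0 & obs$measured_phi < 1
  inv <- -log(1 - obs$measured_phi[interior]) * obs$e0[interior] /
    (obs$s0[interior] * -expm1(-obs$beta0[interior] * obs$e0[interior] *
                                 obs$t[interior]))
  inv <- inv[is.finite(inv) & inv > 0]
  hi <- max(upper, if (length(inv)) 2 * max(inv) else 0)

  o <- stats::optimize(ssq, interval = c(0, hi), tol = 1e-12)
  ratio <- o$minimum
  rss <- ssq(ratio)
  n <- nrow(obs)
  se <- NA_real_
  if (n >= 2 && ratio > 1e-10 && ratio < hi - 1e-10) {
    h <- max(1e-6, 1e-6 * ratio)
    d2 <- (ssq(ratio + h) - 2 * rss + ssq(ratio - h)) / h^2
    sigma2 <- rss / max(1, n - 1)
    if (is.finite(d2) && d2 > 0) se <- sqrt(2 * sigma2 / d2)
  }
  list(ratio = ratio, se = se, rss = rss, n = n, fitted_phi = pred(ratio))
}

#' Modelled versus measured fertilization across conditions
#'
#' For every experimental condition (temperature, pH), predicts
#' fertilization from the kinetics model parameterised with that
#' condition's measured mean sperm velocity (`beta0 = upsilon * sigma0`)
#' and pairs it with the measured mean fertilization, reporting the
#' discrepancy `modelled - measured` and the Spearman rank correlation
#' between measured fertilization and velocity. Conditions present in
#' one table but not the other appear in the output with `NA`s rather
#' than being dropped silently.
#'
#' @param assays data frame with columns `temperature_c`, `ph`,
#'   `measured_phi` (mean fertilization proportion per condition).
#' @param velocities data frame with columns `temperature_c`, `ph`,
#'   `mean_vcl` (um/s per condition).
#' @param sigma0 egg cross-sectional area, um^2.
#' @param s0,e0,t as in [phi_fertilized()].
#' @param ratio fitted beta/beta0 ratio.
#' @return list with `table` (condition, upsilon_used, beta0, measured_phi,
#'   modelled_phi, discrepancy, matched flag) and `spearman`
#'   (rho + p for measured phi vs velocity over matched conditions).
#' @export
predict_vs_measured <- function(assays, velocities, sigma0, s0, e0, t, ratio) {
  for (nm in c("sigma0", "s0", "e0", "t", "ratio"))
    check_scalar_number(get(nm), nm, lower = 0)
  key <- function(d) paste(d$temperature_c, format_ph(d$ph), sep = "|")
  a <- assays; v <- velocities
  if (!all(c("temperature_c", "ph", "measured_phi") %in% names(a)))
    stop_bad("'assays' needs temperature_c, ph, measured_phi")
  if (!all(c("temperature_c", "ph", "mean_vcl") %in% names(v)))
    stop_bad("'velocities' needs temperature_c, ph, mean_vcl")
  keys <- union(key(a), key(v))
  ia <- match(keys, key(a)); iv <- match(keys, key(v))
  ups <- v$mean_vcl[iv]
  b0 <- beta0_from_swimming(ifelse(is.na(ups), 0, ups), sigma0)
  modelled <- rep(NA_real_, length(keys))
  okb <- !is.na(ups) & b0 > 0
  modelled[okb] <- phi_fertilized(s0, e0, t, beta = ratio * b0[okb],
                                  beta0 = b0[okb])
  modelled[!is.na(ups) & b0 == 0] <- 0
  tab <- data.frame(
    temperature_c = ifelse(is.na(ia), v$temperature_c[iv], a$temperature_c[ia]),
    ph = ifelse(is.na(ia), v$ph[iv], a$ph[ia]),
    upsilon_used_um_s = ups,
    beta0_mm3_s = ifelse(is.na(ups), NA_real_, b0),
    measured_phi = a$measured_phi[ia],
    modelled_phi = modelled,
    matched = !is.na(ia) & !is.na(iv))
  tab$discrepancy <- tab$modelled_phi - tab$measured_phi
  m <- tab$matched & !is.na(tab$measured_phi) & !is.na(tab$upsilon_used_um_s)
  sp <- if (sum(m) >= 3)
    tryCatch(spearman_rho(tab$measured_phi[m], tab$upsilon_used_um_s[m]),
             error = function(e)
               list(rho = NA_real_, p_value = NA_real_, n = sum(m)))
  else list(rho = NA_real_, p_value = NA_real_, n = sum(m))
  list(table = tab[order(tab$temperature_c, tab$ph), ], spearman = sp)
}
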