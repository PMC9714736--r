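test_that("model evaluation matches closed forms", {
  g <- tpc_model("gaussian")
  p <- c(rmax = 0.95, topt = 17.6, a = 5)
  expect_equal(evaluate_tpc(g, p, 17.6), 0.95)  # exponent zero at the optimum
  expect_equal(evaluate_tpc(g, p, 17.6 + 3), evaluate_tpc(g, p, 17.6 - 3))
  # quadratic is plain polynomial arithmetic
  q <- c(a = 0.1, b = 0.08, c = -0.002)
  tt <- seq(0, 40, by = 2.5)
  expect_equal(evaluate_tpc("quadratic", q, tt),
               0.1 + 0.08 * tt - 0.002 * tt^2, tolerance = 1e-12)
  expect_error(tpc_model("notamodel"), "unknown TPC model")
  expect_error(evaluate_tpc(g, c(1, 2), 10), "3 parameters")
})

test_that("every registry model evaluates finitely near its start values", {
  ds <- gen_gaussian_tpc_data(1, sd = 0.03)
  for (nm in names(tpc_models())) {
    sp <- tpc_model(nm)
    st <- sp$start(ds$temperature, ds$rate)
    v <- evaluate_tpc(sp, st, seq(8, 38, by = 1))
    expect_true(all(is.finite(v)), info = nm)
  }
})

test_that("AICc matches the Gaussian-likelihood closed form and its contracts", {
  expect_equal(aicc(rss = 1, n = 10, k = 3), 15.35292, tolerance = 1e-5)
  # recompute independently from the likelihood definition
  ll <- -10 / 2 * (log(2 * pi) + log(1 / 10) + 1)
  expect_equal(aicc(1, 10, 3), -2 * ll + 2 * 3 + 2 * 3 * 4 / (10 - 3 - 1),
               tolerance = 1e-12)
  expect_gt(aicc(2, 10, 3), aicc(1, 10, 3))  # monotone in rss
  expect_error(aicc(1, 4, 3), "n - k - 1")    # boundary exclusion
  expect_error(aicc(0, 10, 3), "rss")
  expect_equal(bic_ls(1, 10, 3), -2 * ll + 3 * log(10), tolerance = 1e-12)
})

test_that("noiseless gaussian data recover the generating parameters", {
  ds <- gen_gaussian_tpc_data(1, sd = 0)
  fit <- fit_tpc(ds, "gaussian", n_starts = 10, seed = 2)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["topt"]] - 17.6), 1e-3)
  expect_lt(abs(fit$estimates[["rmax"]] - 0.95), 1e-3)
  expect_lt(fit$rss, 1e-8)
})

test_that("fitting is deterministic in the seed", {
  ds <- gen_gaussian_tpc_data(5, sd = 0.05)
  f1 <- fit_tpc(ds, "modgaussian", seed = 33)
  f2 <- fit_tpc(ds, "modgaussian", seed = 33)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$rss, f2$rss)
})

test_that("constant-rate data yield the flat-limit fit, honestly flagged", {
  ds <- tpc_dataset(rep(c(8, 12, 16, 20, 24), each = 2), rep(0.5, 10))
  fit <- fit_tpc(ds, "gaussian", seed = 4)
  expect_true(fit$converged)
  # the gaussian approaches a constant only in the wide-width limit; the
  # bounded fit must get within numerical reach of the zero-residual floor
  expect_lt(fit$rss, 1e-4)
  expect_lt(abs(evaluate_tpc(fit$spec, fit$estimates, 16) - 0.5), 0.01)
})

test_that("ranking sorts by AICc, breaks ties, and is order-invariant", {
  ds <- gen_gaussian_tpc_data(7, sd = 0.02)
  r1 <- rank_tpc_models(ds, c("quadratic", "gaussian", "modgaussian"), seed = 6)
  r2 <- rank_tpc_models(ds, c("modgaussian", "quadratic", "gaussian"), seed = 6)
  nm1 <- vapply(r1, `[[`, character(1), "model")
  nm2 <- vapply(r2, `[[`, character(1), "model")
  expect_identical(nm1, nm2)
  a <- vapply(r1, `[[`, numeric(1), "aicc")
  expect_true(!is.unsorted(a))
  # single candidate comes back rank 1
  r3 <- rank_tpc_models(ds, "quadratic", seed = 6)
  expect_length(r3, 1)
  expect_identical(r3[[1]]$model, "quadratic")
})

test_that("models without AICc degrees of freedom are excluded with a reason", {
  ds <- tpc_dataset(c(8, 12, 16, 20, 24, 28), c(0.2, 0.5, 0.9, 0.8, 0.4, 0.1))
  # 4-parameter curve + variance: k = 5, n = 6 -> n - k - 1 = 0
  r <- rank_tpc_models(ds, c("gaussian", "modgaussian"), seed = 8)
  nm <- vapply(r, `[[`, character(1), "model")
  expect_false("modgaussian" %in% nm)
  ex <- attr(r, "exclusions")
  expect_true(any(grepl("modgaussian", ex$model)))
})

test_that("derived breadth matches the gaussian closed form", {
  fit <- gaussian_fit_fixture(a = 5)
  d <- derive_tpc_params(fit, grid_low = 0, grid_high = 35,
                         grid_step = 0.01, threshold = 0.8)
  expect_lt(abs(d$t_br - 2 * 5 * sqrt(2 * log(1.25))), 0.01)
  expect_lt(abs(d$t_opt - 17.6), 0.01)
  expect_lt(abs(d$r_max - 0.95), 1e-6)
  expect_true(d$contiguous)
  expect_false(d$boundary_censored)
  # breadth interval contains the optimum
  expect_true(d$intervals[1, 1] <= d$t_opt && d$t_opt <= d$intervals[1, 2])
})

test_that("breadth shrinks to zero as the threshold approaches one", {
  fit <- gaussian_fit_fixture(a = 5)
  d99 <- derive_tpc_params(fit, 0, 35, threshold = 0.999)
  expect_lt(d99$t_br, 0.5)
  expect_gt(d99$t_br, 0)
})

test_that("monotone curves are flagged boundary-censored at the grid edge", {
  tt <- rep(seq(8, 28, by = 4), each = 2)
  ds <- tpc_dataset(tt, 0.01 * tt + 0.002 * tt^2)
  fit <- fit_tpc(ds, "quadratic", seed = 10)
  d <- derive_tpc_params(fit, 8, 28, threshold = 0.8)
  expect_lt(abs(d$t_opt - 28), 0.02)
  expect_true(d$boundary_censored)
})

test_that("r_max agrees with the grid maximum of the evaluated model", {
  withr::with_seed(55, {
    for (i in 1:5) {
      ds <- gen_gaussian_tpc_data(100 + i, sd = 0.04)
      fit <- fit_tpc(ds, "gaussian", seed = i)
      d <- derive_tpc_params(fit)
      grid <- seq(min(ds$temperature), max(ds$temperature), by = 0.01)
      gmax <- max(pmax(0, evaluate_tpc(fit$spec, fit$estimates, grid)))
      expect_lt(abs(d$r_max - gmax) / max(gmax, 1e-9), 1e-6)
    }
  })
})

test_that("noiseless data give zero-width bootstrap intervals", {
  fit <- gaussian_fit_fixture()
  b <- bootstrap_tpc(fit, n_boot = 100, seed = 3, grid_low = 0,
                     grid_high = 35)
  expect_lt(max(b$ci$high - b$ci$low), 1e-6)
  expect_equal(b$failure_rate, 0)
})

test_that("bootstrap intervals are deterministic in the seed", {
  ds <- gen_gaussian_tpc_data(9, sd = 0.05)
  fit <- fit_tpc(ds, "gaussian", seed = 2)
  b1 <- bootstrap_tpc(fit, n_boot = 150, seed = 77)
  b2 <- bootstrap_tpc(fit, n_boot = 150, seed = 77)
  expect_identical(b1$ci, b2$ci)
  b3 <- bootstrap_tpc(fit, n_boot = 150, seed = 78)
  expect_false(identical(b1$ci$low, b3$ci$low))
})

test_that("bootstrap intervals cover the point estimate and honour the level", {
  ds <- gen_gaussian_tpc_data(13, sd = 0.05)
  fit <- fit_tpc(ds, "gaussian", seed = 2)
  b <- bootstrap_tpc(fit, n_boot = 200, seed = 5, level = 0.95)
  expect_true(all(b$ci$low <= b$ci$estimate + 1e-8))
  expect_true(all(b$ci$high >= b$ci$estimate - 1e-8))
  wide <- bootstrap_tpc(fit, n_boot = 200, seed = 5, level = 0.5)
  expect_true(all(wide$ci$high - wide$ci$low <= b$ci$high - b$ci$low + 1e-9))
})
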