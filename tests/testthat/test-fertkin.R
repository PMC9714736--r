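test_that("phi matches its closed-form limits", {
  expect_equal(phi_fertilized(s0 = 3, e0 = 2, t = 0, beta = 1, beta0 = 2), 0)
  expect_equal(phi_fertilized(s0 = 0, e0 = 2, t = 50, beta = 1, beta0 = 2), 0)
  # beta = beta0, s0 = e0, t -> Inf: phi = 1 - exp(-1)
  expect_equal(phi_fertilized(1, 1, 1e9, 1, 1), 1 - exp(-1),
               tolerance = 1e-12)
  # beta/beta0 = 1, s0 = e0 = 1, beta0 e0 t = 1
  expect_equal(phi_fertilized(1, 1, 1, 1, 1), 1 - exp(-(1 - exp(-1))),
               tolerance = 1e-12)
  expect_error(phi_fertilized(-1, 1, 1, 1, 1), "non-negative")
  expect_error(phi_fertilized(1, 0, 1, 1, 1), "e0")
})

test_that("phi is monotone in exposure, sperm, and rate constant", {
  withr::with_seed(61, {
    for (i in 1:25) {
      s0 <- runif(1, 0.01, 10); e0 <- runif(1, 0.01, 1)
      b0 <- 10^runif(1, -5, -2); r <- runif(1, 0.01, 2)
      tgrid <- sort(runif(30, 0, 5000))
      expect_true(all(diff(phi_fertilized(s0, e0, tgrid, r * b0, b0)) >= -1e-15))
      sgrid <- sort(runif(30, 0, 20))
      expect_true(all(diff(phi_fertilized(sgrid, e0, 900, r * b0, b0)) >= -1e-15))
      bgrid <- sort(runif(30, 0, 5)) * b0
      expect_true(all(diff(phi_fertilized(s0, e0, 900, bgrid, b0)) >= -1e-15))
    }
  })
})

test_that("phi never exceeds its asymptote and attains it for long exposure", {
  withr::with_seed(67, {
    for (i in 1:50) {
      s0 <- runif(1, 0.1, 10); e0 <- runif(1, 0.1, 10)
      b0 <- 10^runif(1, -3, -1); r <- runif(1, 0.01, 2)
      asym <- -expm1(-r * s0 / e0)
      tt <- 10^runif(20, 0, 6)
      expect_true(all(phi_fertilized(s0, e0, tt, r * b0, b0) <= asym + 1e-12))
      # beta0 e0 t >= 40 pins phi to the asymptote
      t_big <- 41 / (b0 * e0)
      expect_lt(abs(phi_fertilized(s0, e0, t_big, r * b0, b0) - asym), 1e-9)
    }
  })
})

test_that("contact rate constant does exact unit conversion and is linear", {
  expect_equal(beta0_from_swimming(0, 1e4), 0)
  expect_equal(beta0_from_swimming(100, 1e4), 1e-3)  # 1e6 um^3/s -> mm^3/s
  expect_equal(beta0_from_swimming(200, 1e4), 2 * beta0_from_swimming(100, 1e4))
  expect_equal(beta0_from_swimming(100, 2e4), 2 * beta0_from_swimming(100, 1e4))
  expect_error(beta0_from_swimming(-1, 1), "non-negative")
})

test_that("egg cross-section is the circle area", {
  expect_equal(egg_cross_section(2), pi)
  expect_equal(egg_cross_section(130), 13273.23, tolerance = 1e-7)
  expect_equal(egg_cross_section(10), egg_cross_section(5) * 4)
  expect_error(egg_cross_section(0), "positive")
})

test_that("dish dilution helper reproduces the worked protocol computation", {
  expect_equal(dish_sperm_concentration(1e5, 50, 11), 1e5 * 0.05 / 11000)
  expect_equal(dish_sperm_concentration(), 0.4545455, tolerance = 1e-6)
})

test_that("beta ratio is recovered exactly from noiseless observations", {
  b0 <- beta0_from_swimming(c(80, 150, 250, 320), egg_cross_section(130))
  truth <- 0.10
  obs <- data.frame(
    measured_phi = phi_fertilized(0.455, 0.02, 900, truth * b0, b0),
    s0 = 0.455, e0 = 0.02, t = 900, beta0 = b0)
  fit <- fit_beta_ratio(obs)
  expect_lt(abs(fit$ratio - truth), 1e-6)
  # closed-form inversion of a single observation agrees
  inv <- -log(1 - obs$measured_phi[1]) * 0.02 /
    (0.455 * (1 - exp(-b0[1] * 0.02 * 900)))
  single <- fit_beta_ratio(obs[1, ])
  expect_lt(abs(single$ratio - inv), 1e-6)
})

test_that("saturated observations are rejected as non-identifiable", {
  obs <- data.frame(measured_phi = c(0, 0, 1), s0 = 1, e0 = 1, t = 10,
                    beta0 = 1e-3)
  expect_error(fit_beta_ratio(obs), "not identifiable")
})

test_that("beta ratio estimation is consistent under binomial noise", {
  truth <- 0.25; n_eggs <- 150
  b0 <- beta0_from_swimming(seq(80, 320, length.out = 8),
                            egg_cross_section(130))
  phis <- phi_fertilized(0.455, 0.02, 900, truth * b0, b0)
  est <- withr::with_seed(71, vapply(1:100, function(i) {
    obs <- data.frame(measured_phi = rbinom(8, n_eggs, phis) / n_eggs,
                      s0 = 0.455, e0 = 0.02, t = 900, beta0 = b0)
    fit_beta_ratio(obs)$ratio
  }, numeric(1)))
  se_mean <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 3 * se_mean)
})

test_that("prediction table pairs conditions and reports gaps explicitly", {
  fert <- data.frame(temperature_c = c(8, 16, 24), ph = 7.8,
                     measured_phi = c(0.5, 0.9, 0.4))
  vel <- data.frame(temperature_c = c(8, 16, 24), ph = 7.8,
                    mean_vcl = c(250, 250, 250))
  out <- predict_vs_measured(fert, vel, sigma0 = egg_cross_section(130),
                             s0 = 0.455, e0 = 0.02, t = 900, ratio = 0.5)
  # equal velocities -> constant modelled phi
  expect_equal(length(unique(out$table$modelled_phi)), 1)
  # ratio = 0 -> modelled 0 everywhere
  zero <- predict_vs_measured(fert, vel, egg_cross_section(130),
                              0.455, 0.02, 900, ratio = 0)
  expect_true(all(zero$table$modelled_phi == 0))
  # unmatched condition appears with NA, not dropped
  vel2 <- vel[-2, ]
  gap <- predict_vs_measured(fert, vel2, egg_cross_section(130),
                             0.455, 0.02, 900, ratio = 0.5)
  expect_equal(nrow(gap$table), 3)
  expect_true(any(!gap$table$matched))
  expect_true(is.na(gap$table$modelled_phi[gap$table$temperature_c == 16]))
})
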