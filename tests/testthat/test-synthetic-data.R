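test_that("single-factor generator reproduces the sand-dollar design shape", {
  des <- design_spec()  # 12 temperatures x 3 pairs x 3 technical reps
  sim <- generate_single_factor_assay(des, truth_spec(seed = 3))
  expect_equal(nrow(sim$assay), 12 * 3 * 3)
  expect_equal(length(unique(sim$assay$pair_id)), 36)
  expect_true(all(sim$assay$n_fertilized >= 0 &
                    sim$assay$n_fertilized <= des$eggs_per_rep))
  expect_true(all(sim$assay$n_scored == 50))
  # one velocity sample per temperature x pair
  expect_equal(length(unique(sim$velocity$sample_id)), 36)
  expect_true(all(sim$velocity$velocity_um_s >= 0))
})

test_that("urchin-style 7-level design gives 21 pairs", {
  des <- design_spec(species_label = "red_urchin",
                     temperatures = c(8, 10, 12, 14, 16, 22, 28))
  sim <- generate_single_factor_assay(des, truth_spec(seed = 5))
  expect_equal(length(unique(sim$assay$pair_id)), 21)
})

test_that("degenerate truth (p = 1, no heterogeneity) fertilizes every egg", {
  des <- design_spec(temperatures = c(10, 14, 18, 22, 26))
  tru <- truth_spec(fert_tpc = list(model = "quadratic",
                                    params = c(a = 1, b = 0, c = 0)),
                    pair_sd_logit = 0, ph_effect_logit = numeric(0) ,
                    seed = 9)
  sim <- generate_single_factor_assay(des, tru)
  expect_true(all(sim$assay$n_fertilized == sim$assay$n_scored))
})

test_that("generators are deterministic in the seed and vary across seeds", {
  des <- design_spec(temperatures = c(8, 16, 24))
  s1 <- generate_single_factor_assay(des, truth_spec(seed = 11))
  s2 <- generate_single_factor_assay(des, truth_spec(seed = 11))
  s3 <- generate_single_factor_assay(des, truth_spec(seed = 12))
  expect_identical(s1$assay, s2$assay)
  expect_identical(s1$velocity, s2$velocity)
  expect_false(identical(s1$assay$n_fertilized, s3$assay$n_fertilized))
})

test_that("factorial generator nests pairs in temperature and crosses pH", {
  des <- design_spec(temperatures = c(8, 16, 24), phs = c(7.1, 7.5, 7.9))
  sim <- generate_factorial_assay(des, truth_spec(seed = 21))
  tab <- unique(sim$assay[c("temperature_c", "ph", "pair_id")])
  expect_equal(nrow(unique(tab[c("temperature_c", "ph")])), 9)
  per_pair <- split(tab, tab$pair_id)
  for (d in per_pair) {
    expect_equal(length(unique(d$temperature_c)), 1)  # one temperature
    expect_equal(sort(unique(d$ph)), c(7.1, 7.5, 7.9))  # all pH levels
  }
  counts <- table(tab$temperature_c, tab$ph)
  expect_true(all(counts == 3))
  # single-pH request is rejected
  expect_error(generate_factorial_assay(design_spec(temperatures = c(8, 16, 24)),
                                        truth_spec(seed = 1)),
               "at least 2 pH")
})

test_that("null pH effect gives equal expected fertilization across pH", {
  des <- design_spec(temperatures = c(8, 16, 24), phs = c(7.1, 7.5, 7.9),
                     n_pairs_per_temperature = 40)
  tru <- truth_spec(ph_effect_logit = c("7.1" = 0, "7.5" = 0, "7.9" = 0),
                    pair_sd_logit = 0, seed = 31)
  sim <- generate_factorial_assay(des, tru)
  prop <- sim$assay$n_fertilized / sim$assay$n_scored
  means <- tapply(prop, list(sim$assay$temperature_c, sim$assay$ph), mean)
  # within-temperature spread across pH is binomial Monte-Carlo noise only
  expect_true(all(apply(means, 1, function(r) diff(range(r))) < 0.05))
})

test_that("empirical mean fertilization converges to the truth curve", {
  temps <- c(8, 12, 16, 20, 24)
  des <- design_spec(temperatures = temps, n_pairs_per_temperature = 60)
  tru <- truth_spec(pair_sd_logit = 0, seed = 41)
  sim <- generate_single_factor_assay(des, tru)
  prop <- sim$assay$n_fertilized / sim$assay$n_scored
  emp <- tapply(prop, sim$assay$temperature_c, mean)
  truth <- 0.95 * exp(-0.5 * ((temps - 17.6) / 8)^2)
  # 60 pairs x 3 reps x 50 eggs per temperature: MC error ~ 0.005
  expect_true(all(abs(emp - truth) < 0.02))
})

test_that("non-finite truth parameters are rejected", {
  expect_error(truth_spec(fert_tpc = list(model = "gaussian",
                                          params = c(rmax = NaN, topt = 17,
                                                     a = 5))),
               "finite")
  expect_error(design_spec(temperatures = c(10, 8)), "increasing")
})

test_that("circular tracks have the requested sampling and chord geometry", {
  trs <- generate_tracks(5, mean_speed = 300, radius = 50, frame_rate = 60,
                         duration = 10, seed = 7)
  expect_length(trs, 5)
  expect_true(all(vapply(trs, function(t) length(t$x), integer(1)) == 600))
  # chord per frame matches the 2 r sin(theta/2) closed form
  tr <- trs[[1]]
  chords <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  theta <- 2 * asin((300 / 60) / (2 * 50))
  expect_equal(chords, rep(2 * 50 * sin(theta / 2), 599), tolerance = 1e-9)
  # all points at the stated radius from the track's centre
  cx <- mean(range(tr$x)); cy <- mean(range(tr$y))
  rr <- sqrt((tr$x - cx)^2 + (tr$y - cy)^2)
  expect_true(sd(rr) / mean(rr) < 0.05)
})

test_that("stationary and undersampled track requests behave per contract", {
  trs <- generate_tracks(2, mean_speed = 0, radius = 50, seed = 3)
  expect_true(all(diff(trs[[1]]$x) == 0) && all(diff(trs[[1]]$y) == 0))
  # chord >= diameter cannot be placed on the circle
  expect_error(generate_tracks(1, mean_speed = 7000, radius = 50,
                               frame_rate = 60, seed = 1), "undersampled")
})

test_that("assay CSV writers round-trip through the readers", {
  des <- design_spec(temperatures = c(8, 16, 24))
  sim <- generate_single_factor_assay(des, truth_spec(seed = 13))
  ap <- tempfile(fileext = ".csv"); vp <- tempfile(fileext = ".csv")
  write_assay_csv(sim, ap, vp)
  back <- read_assay_csv(ap)
  expect_equal(back$n_fertilized, sim$assay$n_fertilized)
  expect_equal(readLines(ap, n = 1), "# seed: 13")
  vel <- read_velocity_csv(vp)
  expect_equal(nrow(vel), nrow(sim$velocity))
})
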