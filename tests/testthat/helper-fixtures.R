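# Fixtures are built in code; nothing is read from disk.

# Independent chord-sum oracle for circular tracks: expected per-frame chord
# from the circle geometry (2 r sin(theta/2)), path length summed in a plain
# loop, never via the package's vectorised distance code.
oracle_vcl <- function(track) {
  n <- length(track$x)
  path <- 0
  for (i in 2:n)
    path <- path + sqrt((track$x[i] - track$x[i - 1])^2 +
                          (track$y[i] - track$y[i - 1])^2)
  path / ((n - 1) / track$frame_rate)
}

# (temperature, rate) data from a gaussian TPC truth, optional iid noise
gen_gaussian_tpc_data <- function(seed, sd = 0, rmax = 0.95, topt = 17.6,
                                  a = 8,
                                  temps = c(8, 10, 12, 14, 16, 18, 20, 22,
                                            24, 26, 34, 38),
                                  reps = 3) {
  tt <- rep(temps, each = reps)
  mu <- rmax * exp(-0.5 * ((tt - topt) / a)^2)
  y <- if (sd > 0) withr::with_seed(seed, mu + rnorm(length(mu), 0, sd)) else mu
  tpc_dataset(tt, y)
}

# a tpc_fit with known parameters, built through the public fitting API on
# noiseless data so estimates equal the truth to optimiser precision
gaussian_fit_fixture <- function(rmax = 0.95, topt = 17.6, a = 5,
                                 temps = seq(0, 35, by = 2.5)) {
  ds <- tpc_dataset(rep(temps, each = 2),
                    rep(rmax * exp(-0.5 * ((temps - topt) / a)^2), each = 2))
  fit_tpc(ds, "gaussian", n_starts = 6, seed = 42)
}

# balanced 3x3 factorial with configurable cell effects and noise
gen_factorial <- function(seed, n_per_cell = 3, temp_eff = c(0, 0, 0),
                          ph_eff = c(0, 0, 0), inter = 0, sd = 1) {
  temps <- c(8, 16, 24); phs <- c(7.1, 7.5, 7.9)
  g <- expand.grid(rep = seq_len(n_per_cell), temperature = temps, ph = phs)
  mu <- temp_eff[match(g$temperature, temps)] + ph_eff[match(g$ph, phs)] +
    inter * (g$temperature == 24 & g$ph == 7.1)
  y <- withr::with_seed(seed, mu + rnorm(nrow(g), 0, sd))
  factorial_dataset(y, g$temperature, g$ph)
}
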