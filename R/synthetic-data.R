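#' Assay design and generating-truth specifications
#'
#' `design_spec()` describes the layout of a fertilization / sperm-swimming
#' experiment: which temperatures and pH levels are crossed, how many
#' male-female pairs (biological replicates) per temperature, how many
#' technical replicates of how many eggs each, and the video settings for
#' sperm tracking. The packaged defaults mirror the two assay designs the
#' package targets: a single-factor thermal series (12 temperatures x 3
#' pairs x 3 technical reps of 50 eggs for sand dollars; 7 temperatures
#' for red urchins) and a 3 temperature x 3 pH factorial in which each
#' pair is tested at one temperature across all three pH levels.
#'
#' `truth_spec()` fixes the generating truth for the simulator: TPC
#' shapes for fertilization probability, mean sperm velocity and motile
#' fraction; additive pH offsets on the fertilization logit; the SD of
#' the pair-level logit shift; and the coefficient of variation of
#' individual sperm velocities. All values are synthetic, chosen for
#' qualitative realism (unimodal curves with optima near 14-18 C), not
#' estimates from any particular experiment.
#'
#' @param species_label text label written to outputs.
#' @param temperatures strictly increasing vector of water temperatures (C).
#' @param phs vector of pH levels; a single level for single-factor designs.
#' @param n_pairs_per_temperature biological replicates per temperature.
#' @param n_technical_reps technical replicates (egg subsamples) per pair.
#' @param eggs_per_rep eggs scored per technical replicate.
#' @param frame_rate video frame rate, Hz.
#' @param track_duration tracked duration per sperm, s.
#' @param n_sperm_per_sample sperm tracked per velocity sample.
#' @return a `design_spec` / `truth_spec` list.
#' @export
design_spec <- function(species_label = "sand_dollar",
                        temperatures = c(8, 10, 12, 14, 16, 18, 20, 22, 24,
                                         26, 34, 38),
                        phs = 7.82,
                        n_pairs_per_temperature = 3,
                        n_technical_reps = 3,
                        eggs_per_rep = 50,
                        frame_rate = 60,
                        track_duration = 10,
                        n_sperm_per_sample = 50) {
  check_numeric_vector(temperatures, "temperatures", min_len = 1L)
  if (is.unsorted(temperatures, strictly = TRUE))
    stop_bad("'temperatures' must be strictly increasing")
  check_numeric_vector(phs, "phs", min_len = 1L)
  n_pairs_per_temperature <- check_count(n_pairs_per_temperature,
                                         "n_pairs_per_temperature")
  n_technical_reps <- check_count(n_technical_reps, "n_technical_reps")
  eggs_per_rep <- check_count(eggs_per_rep, "eggs_per_rep")
  check_scalar_number(frame_rate, "frame_rate", lower = 1e-9)
  check_scalar_number(track_duration, "track_duration", lower = 1e-9)
  n_sperm_per_sample <- check_count(n_sperm_per_sample, "n_sperm_per_sample")
  structure(list(species_label = as.character(species_label),
                 temperatures = temperatures, phs = phs,
                 n_pairs_per_temperature = n_pairs_per_temperature,
                 n_technical_reps = n_technical_reps,
                 eggs_per_rep = eggs_per_rep, frame_rate = frame_rate,
                 track_duration = track_duration,
                 n_sperm_per_sample = n_sperm_per_sample),
            class = "design_spec")
}

#' @rdname design_spec
#' @param fert_tpc,velocity_tpc,motility_tpc lists `list(model =, params =)`
#'   understood by [evaluate_tpc()], giving the true fertilization
#'   probability, mean velocity (um/s) and motile fraction versus
#'   temperature. Probabilities and fractions are clamped to [0, 1],
#'   velocities to >= 0.
#' @param ph_effect_logit named numeric: additive shift on the
#'   fertilization logit for each pH level (name = pH as character);
#'   levels not listed get 0.
#' @param pair_sd_logit SD of the pair-level random shift on the logit.
#' @param velocity_cv coefficient of variation of individual sperm
#'   velocities around the sample mean.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @export
truth_spec <- function(fert_tpc = list(model = "gaussian",
                                       params = c(rmax = 0.95, topt = 17.6,
                                                  a = 8)),
                       velocity_tpc = list(model = "gaussian",
                                           params = c(rmax = 300, topt = 13.9,
                                                      a = 7)),
                       motility_tpc = list(model = "gaussian",
                                           params = c(rmax = 0.8, topt = 13,
                                                      a = 9)),
                       ph_effect_logit = c("7.9" = 0, "7.5" = -0.8,
                                           "7.1" = -1.6),
                       pair_sd_logit = 0.4,
                       velocity_cv = 0.2,
                       seed = 1) {
  for (nm in c("fert_tpc", "velocity_tpc", "motility_tpc")) {
    tp <- get(nm)
    if (!is.list(tp) || !all(c("model", "params") %in% names(tp)))
      stop_bad(sprintf("'%s' must be list(model =, params =)", nm))
    check_numeric_vector(as.numeric(tp$params), paste0(nm, "$params"))
  }
  check_scalar_number(pair_sd_logit, "pair_sd_logit", lower = 0)
  check_scalar_number(velocity_cv, "velocity_cv", lower = 0)
  if (length(ph_effect_logit) && is.null(names(ph_effect_logit)))
    stop_bad("'ph_effect_logit' must be named by pH level")
  check_numeric_vector(as.numeric(ph_effect_logit), "ph_effect_logit",
                       min_len = 0L)
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(fert_tpc = fert_tpc, velocity_tpc = velocity_tpc,
                 motility_tpc = motility_tpc,
                 ph_effect_logit = ph_effect_logit,
                 pair_sd_logit = pair_sd_logit, velocity_cv = velocity_cv,
                 seed = seed),
            class = "truth_spec")
}

truth_curve <- function(tp, temp, kind = c("prob", "velocity")) {
  kind <- match.arg(kind)
  v <- evaluate_tpc(tp$model, tp$params, temp)
  v[!is.finite(v)] <- 0
  if (kind == "prob") clamp01(v) else pmax(0, v)
}

ph_shift <- function(truth, ph) {
  key <- format_ph(ph)
  s <- truth$ph_effect_logit[key]
  ifelse(is.na(s), 0, as.numeric(s))
}

format_ph <- function(ph) formatC(ph, format = "fg")

#' Simulate a single-factor temperature assay
#'
#' Generates one fertilization record per temperature x pair x technical
#' replicate and one sperm velocity sample per temperature x pair, with
#' the statistical structure of a thermal series on a broadcast spawner:
#' binomial fertilization counts whose success probability is the true
#' fertilization TPC perturbed by a pair-level logit shift, and individual
#' sperm velocities drawn (truncated at 0) around the true velocity TPC
#' with Bernoulli motility from the motility TPC. Immotile sperm receive
#' a small jitter velocity below the default motility threshold.
#'
#' @param design a [design_spec()] with a single pH level.
#' @param truth a [truth_spec()]; its `seed` drives all randomness.
#' @return list with `assay` (data frame: species, temperature_c, ph,
#'   pair_id, tech_rep, n_scored, n_fertilized) and `velocity` (data
#'   frame: sample_id, species, temperature_c, ph, pair_id, velocity_um_s,
#'   motile_truth), plus attribute `seed`.
#' @export
generate_single_factor_assay <- function(design, truth) {
  stopifnot(inherits(design, "design_spec"), inherits(truth, "truth_spec"))
  if (length(design$phs) != 1L)
    stop_bad("single-factor design must have exactly one pH level")
  gen_assay(design, truth, factorial = FALSE)
}

#' Simulate the temperature x pH factorial assay
#'
#' Each male-female pair is nested in one temperature but crossed with
#' all pH levels (the design used for multi-stressor experiments); the
#' pH effect enters as an additive shift on the fertilization logit.
#' Requires a balanced request: every temperature gets the same number of
#' pairs, every pair all pH levels.
#'
#' @inheritParams generate_single_factor_assay
#' @param design a [design_spec()] with at least 2 pH levels (the
#'   reference factorial uses 3 temperatures x 3 pHs).
#' @return as [generate_single_factor_assay()]; the assay table is
#'   balanced with each pair id under exactly one temperature and all
#'   pH levels.
#' @export
generate_factorial_assay <- function(design, truth) {
  stopifnot(inherits(design, "design_spec"), inherits(truth, "truth_spec"))
  if (length(design$phs) < 2L)
    stop_bad("factorial design needs at least 2 pH levels")
  gen_assay(design, truth, factorial = TRUE)
}

gen_assay <- function(design, truth, factorial) {
  temps <- design$temperatures
  phs <- sort(design$phs)
  npair <- design$n_pairs_per_temperature
  ntech <- design$n_technical_reps
  eggs <- design$eggs_per_rep
  nsp <- design$n_sperm_per_sample

  with_seed(truth$seed, {
    assay <- list(); vel <- list(); ai <- 0L; vi <- 0L
    for (it in seq_along(temps)) {
      tt <- temps[it]
      p_fert_base <- truth_curve(truth$fert_tpc, tt, "prob")
      v_mean <- truth_curve(truth$velocity_tpc, tt, "velocity")
      p_mot <- truth_curve(truth$motility_tpc, tt, "prob")
      for (ip in seq_len(npair)) {
        pair_id <- sprintf("%s_T%02d_P%d", design$species_label, it, ip)
        shift <- stats::rnorm(1, 0, truth$pair_sd_logit)
        for (ph in phs) {
          p <- clamp01(stats::plogis(stats::qlogis(p_fert_base) + shift +
                                       ph_shift(truth, ph)))
          for (tr in seq_len(ntech)) {
            ai <- ai + 1L
            assay[[ai]] <- data.frame(
              species = design$species_label, temperature_c = tt,
              ph = ph, pair_id = pair_id, tech_rep = tr,
              n_scored = eggs,
              n_fertilized = stats::rbinom(1, eggs, p),
              stringsAsFactors = FALSE)
          }
          vi <- vi + 1L
          motile <- stats::rbinom(nsp, 1, p_mot) == 1
          v <- numeric(nsp)
          if (any(motile))
            v[motile] <- pmax(0, stats::rnorm(sum(motile), v_mean,
                                              truth$velocity_cv * v_mean))
          # immotile sperm: jitter below the tracking noise floor
          if (any(!motile)) v[!motile] <- stats::runif(sum(!motile), 0, 2)
          vel[[vi]] <- data.frame(
            sample_id = sprintf("%s_pH%s", pair_id, format_ph(ph)),
            species = design$species_label, temperature_c = tt, ph = ph,
            pair_id = pair_id, velocity_um_s = v,
            motile_truth = as.integer(motile), stringsAsFactors = FALSE)
        }
      }
    }
    out <- list(assay = do.call(rbind, assay), velocity = do.call(rbind, vel))
    attr(out, "seed") <- truth$seed
    class(out) <- if (factorial) c("factorial_assay", "assay_sim")
                  else c("single_factor_assay", "assay_sim")
    out
  })
}

#' Simulate circular sperm tracks
#'
#' Broadcast-spawner sperm swim in stereotyped circles; the simulator
#' places each track on a circle of the given radius traversed at
#' constant angular speed, with the angular step chosen so that the
#' chord-sum (curvilinear) speed equals `mean_speed` exactly:
#' `theta = 2 asin(chord / 2r)` with `chord = mean_speed / frame_rate`.
#' Point count is `round(frame_rate * duration)`. Track centres and
#' phases are randomised (seeded); `mean_speed = 0` gives stationary
#' tracks. Requests implying an angular step >= pi per frame (an
#' undersampled circle) are rejected.
#'
#' @param n_tracks number of tracks.
#' @param mean_speed target curvilinear speed, um/s.
#' @param radius circle radius, um.
#' @param frame_rate frames per second.
#' @param duration seconds tracked.
#' @param seed integer seed.
#' @return list of `sperm_track` objects (see [sperm_track()]).
#' @export
generate_tracks <- function(n_tracks, mean_speed, radius = 50,
                            frame_rate = 60, duration = 10, seed = 1) {
  n_tracks <- check_count(n_tracks, "n_tracks")
  check_scalar_number(mean_speed, "mean_speed", lower = 0)
  check_scalar_number(radius, "radius", lower = 1e-12)
  check_scalar_number(frame_rate, "frame_rate", lower = 1e-12)
  check_scalar_number(duration, "duration", lower = 1e-12)
  n_pts <- max(2L, as.integer(round(frame_rate * duration)))
  chord <- mean_speed / frame_rate
  if (chord >= 2 * radius)
    stop_bad("undersampled circle: chord per frame >= diameter; raise frame_rate or radius")
  theta <- 2 * asin(chord / (2 * radius))
  if (theta >= pi)
    stop_bad("undersampled circle: angular step per frame >= pi")
  with_seed(seed, {
    lapply(seq_len(n_tracks), function(i) {
      phase <- stats::runif(1, 0, 2 * pi)
      cx <- stats::runif(1, -500, 500)
      cy <- stats::runif(1, -500, 500)
      ang <- phase + theta * (seq_len(n_pts) - 1L)
      sperm_track(sprintf("track_%03d", i), frame_rate,
                  x = cx + radius * cos(ang), y = cy + radius * sin(ang))
    })
  })
}

#' Write simulated assay tables to CSV
#'
#' Writers for the three tabular outputs (fertilization assay, velocity
#' samples, tracks), with the generator seed recorded in a `# seed:`
#' comment line so every file is traceable. [read_assay_csv()] and
#' friends skip such comment lines.
#'
#' @param sim result of [generate_single_factor_assay()] /
#'   [generate_factorial_assay()].
#' @param assay_path,velocity_path output CSV paths (NULL to skip one).
#' @return invisibly, the paths written.
#' @export
write_assay_csv <- function(sim, assay_path = NULL, velocity_path = NULL) {
  seed <- attr(sim, "seed")
  wr <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  if (!is.null(assay_path)) wr(sim$assay, assay_path)
  if (!is.null(velocity_path)) wr(sim$velocity, velocity_path)
  invisible(c(assay_path, velocity_path))
}
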