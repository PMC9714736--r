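#' Pipeline run configuration
#'
#' Assembles and validates the configuration for a full analysis run:
#' which stages to execute, the assay design and generating truth for
#' simulation, seeds for every random stage, bootstrap sizes, the TPC
#' candidate registry, and thresholds. A config round-trips losslessly
#' through YAML via [write_run_config()] / [read_run_config()].
#'
#' @param output_dir directory for stage outputs and the manifest.
#' @param stages character subset of
#'   `c("simulate", "kinematics", "tpc", "fertkin", "factorial")`.
#' @param seed master seed; per-stage seeds are derived from it
#'   deterministically.
#' @param design,factorial_design,truth lists of arguments for
#'   [design_spec()] / [truth_spec()] (the truth's seed is derived from
#'   `seed`).
#' @param tpc_models character vector of candidate model names.
#' @param n_boot bootstrap replicates for TPC confidence intervals.
#' @param breadth_threshold thermal-breadth threshold (proportion of
#'   r_max).
#' @param motility_threshold VCL motility threshold, um/s.
#' @param kinetics list: `egg_diameter_um`, `e0_per_ul`, `t_s`, and
#'   `s0_per_ul` (default from [dish_sperm_concentration()]).
#' @return a validated `run_config` list.
#' @export
run_config <- function(output_dir = "results/run",
                       stages = c("simulate", "kinematics", "tpc",
                                  "fertkin", "factorial"),
                       seed = 1,
                       design = list(),
                       factorial_design = list(
                         temperatures = c(8, 16, 24),
                         phs = c(7.1, 7.5, 7.9)),
                       truth = list(),
                       tpc_models = c("quadratic", "gaussian", "modgaussian"),
                       n_boot = 200,
                       breadth_threshold = 0.8,
                       motility_threshold = 5,
                       kinetics = list(egg_diameter_um = 130,
                                       e0_per_ul = 0.02, t_s = 900,
                                       s0_per_ul = NULL)) {
  known <- c("simulate", "kinematics", "tpc", "fertkin", "factorial")
  if (length(stages) && !all(stages %in% known))
    stop_bad(sprintf("unknown stage(s): %s",
                     paste(setdiff(stages, known), collapse = ", ")))
  seed <- check_count(seed, "seed", min = 0L)
  n_boot <- check_count(n_boot, "n_boot", min = 100L)
  check_scalar_number(breadth_threshold, "breadth_threshold")
  if (breadth_threshold <= 0 || breadth_threshold >= 1)
    stop_bad("'breadth_threshold' must be in (0, 1)")
  check_scalar_number(motility_threshold, "motility_threshold", lower = 0)
  invisible(tpc_models(tpc_models))  # validates names
  if (is.null(kinetics$s0_per_ul))
    kinetics$s0_per_ul <- dish_sperm_concentration()
  structure(list(output_dir = output_dir, stages = stages, seed = seed,
                 design = design, factorial_design = factorial_design,
                 truth = truth, tpc_models = tpc_models, n_boot = n_boot,
                 breadth_threshold = breadth_threshold,
                 motility_threshold = motility_threshold,
                 kinetics = kinetics),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_bad(sprintf("no such file: %s", path))
  raw <- yaml::read_yaml(path)
  raw$stages <- unlist(raw$stages)
  raw$tpc_models <- unlist(raw$tpc_models)
  for (f in c("design", "factorial_design"))
    if (!is.null(raw[[f]]))
      raw[[f]] <- lapply(raw[[f]], function(x)
        if (is.list(x)) unlist(x) else x)
  do.call(run_config, raw)
}

write_json_out <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)

write_csv_out <- function(df, path) utils::write.csv(df, path, row.names = FALSE)

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate the two
#' experiments, summarise sperm kinematics, fit and rank TPC models with
#' bootstrap CIs for the derived parameters, compare kinetics-model
#' predictions with measured fertilization, and run the ART factorial
#' ANOVA — writing per-stage CSV/JSON under `config$output_dir` plus a
#' `manifest.json` recording the config hash, seeds, package version and
#' per-stage outputs. Identical configs produce byte-identical outputs;
#' the manifest deliberately contains no timestamps. Stage wall-times go
#' to the console only.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-stage messages.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  downstream <- setdiff(config$stages, "simulate")
  if (length(downstream) && !"simulate" %in% config$stages)
    stop_bad("stages depend on simulated data: enable 'simulate' or run no downstream stage")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  cfg_path <- out("config.yaml")
  write_run_config(config, cfg_path)
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("echinofert")),
                   stages = list())
  state <- list()

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    files <- fun()
    say("stage %s: %.2fs", name, proc.time()[["elapsed"]] - t0)
    manifest$stages[[name]] <<- list(status = "ok",
                                     outputs = as.character(files))
  }

  run_stage("simulate", function() {
    des <- do.call(design_spec, config$design)
    tru <- do.call(truth_spec, c(config$truth,
                                 list(seed = derive_seed(config$seed, 1))))
    sim1 <- generate_single_factor_assay(des, tru)
    fdes_args <- config$factorial_design
    fdes <- do.call(design_spec, utils::modifyList(config$design, fdes_args))
    truf <- do.call(truth_spec, c(config$truth,
                                  list(seed = derive_seed(config$seed, 2))))
    sim2 <- generate_factorial_assay(fdes, truf)
    state$sim1 <<- sim1; state$sim2 <<- sim2
    write_assay_csv(sim1, out("single_factor_assay.csv"),
                    out("single_factor_velocity.csv"))
    write_assay_csv(sim2, out("factorial_assay.csv"),
                    out("factorial_velocity.csv"))
    c("single_factor_assay.csv", "single_factor_velocity.csv",
      "factorial_assay.csv", "factorial_velocity.csv", "config.yaml")
  })

  run_stage("kinematics", function() {
    thr <- config$motility_threshold
    # track-level demonstration: circular tracks at a reference speed
    tracks <- generate_tracks(20, mean_speed = 300, radius = 50,
                              frame_rate = 60, duration = 10,
                              seed = derive_seed(config$seed, 3))
    write_track_csv(tracks, out("demo_tracks.csv"))
    smry <- summarize_sample(tracks, threshold = thr, sample_id = "demo")
    write_json_out(smry[c("sample_id", "mean_vcl", "motile_fraction",
                          "n_tracks", "threshold")],
                   out("demo_track_summary.json"))
    vel1 <- aggregate_velocity(state$sim1$velocity, threshold = thr)
    vel2 <- aggregate_velocity(state$sim2$velocity, threshold = thr)
    state$vel1 <<- vel1; state$vel2 <<- vel2
    write_csv_out(vel1, out("single_factor_vcl.csv"))
    write_csv_out(vel2, out("factorial_vcl.csv"))
    c("demo_tracks.csv", "demo_track_summary.json",
      "single_factor_vcl.csv", "factorial_vcl.csv")
  })

  run_stage("tpc", function() {
    fert <- aggregate_fertilization(state$sim1$assay)
    state$fert1 <<- fert
    ds <- tpc_dataset(fert$temperature_c, fert$fertilization_prop,
                      fert$pair_id, trait_name = "fertilization")
    rk <- rank_tpc_models(ds, config$tpc_models,
                          seed = derive_seed(config$seed, 4))
    write_csv_out(attr(rk, "table"), out("tpc_ranking.csv"))
    best <- rk[[1]]
    boot <- bootstrap_tpc(best, n_boot = config$n_boot,
                          seed = derive_seed(config$seed, 5),
                          threshold = config$breadth_threshold)
    state$tpc_best <<- best; state$tpc_boot <<- boot
    write_json_out(list(
      trait = "fertilization", model = best$model,
      estimates = as.list(best$estimates),
      aicc = best$aicc, bic = best$bic,
      derived = boot$ci, parameter_ci = boot$param_ci,
      n_boot = boot$n_boot, failure_rate = boot$failure_rate,
      breadth_threshold = config$breadth_threshold,
      seed = derive_seed(config$seed, 5)), out("tpc_fertilization.json"))
    c("tpc_ranking.csv", "tpc_fertilization.json")
  })

  run_stage("fertkin", function() {
    kin <- config$kinetics
    sigma0 <- egg_cross_section(kin$egg_diameter_um)
    fert <- state$fert1
    if (is.null(fert)) fert <- aggregate_fertilization(state$sim1$assay)
    vel <- state$vel1
    if (is.null(vel)) vel <- aggregate_velocity(state$sim1$velocity,
                                                config$motility_threshold)
    cm <- condition_means(fert, vel)
    obs <- merge(cm$fert, cm$vel, by = c("temperature_c", "ph"))
    obs <- obs[obs$mean_vcl > 0, ]
    fitdf <- data.frame(measured_phi = obs$measured_phi,
                        s0 = kin$s0_per_ul, e0 = kin$e0_per_ul, t = kin$t_s,
                        beta0 = beta0_from_swimming(obs$mean_vcl, sigma0))
    fr <- fit_beta_ratio(fitdf)
    pv <- predict_vs_measured(cm$fert, cm$vel, sigma0 = sigma0,
                              s0 = kin$s0_per_ul, e0 = kin$e0_per_ul,
                              t = kin$t_s, ratio = fr$ratio)
    tab <- pv$table
    tab$s0_per_ul <- kin$s0_per_ul; tab$e0_per_ul <- kin$e0_per_ul
    tab$t_s <- kin$t_s; tab$sigma0_um2 <- sigma0; tab$ratio <- fr$ratio
    write_csv_out(tab, out("fertkin_predictions.csv"))
    write_json_out(list(ratio = fr$ratio, se = fr$se, rss = fr$rss,
                        n = fr$n, spearman = pv$spearman),
                   out("fertkin_fit.json"))
    c("fertkin_predictions.csv", "fertkin_fit.json")
  })

  run_stage("factorial", function() {
    fert <- aggregate_fertilization(state$sim2$assay)
    fd <- factorial_dataset(fert$fertilization_prop, fert$temperature_c,
                            fert$ph, fert$pair_id)
    res <- art_anova(fd)
    ph_t <- bonferroni_pairwise(fd, "temperature")
    ph_p <- bonferroni_pairwise(fd, "ph")
    write_csv_out(res$anova, out("art_anova.csv"))
    write_csv_out(rbind(cbind(factor = "temperature", ph_t),
                        cbind(factor = "ph", ph_p)),
                  out("art_posthoc.csv"))
    write_json_out(list(anova = res$anova,
                        diagnostics = lapply(res$diagnostics, function(d)
                          list(aligned_sum = d$aligned_sum,
                               stripped_F = as.list(d$stripped_F)))),
                   out("art_anova.json"))
    c("art_anova.csv", "art_posthoc.csv", "art_anova.json")
  })

  write_json_out(manifest, out("manifest.json"))
  invisible(manifest)
}
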