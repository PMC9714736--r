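#' Read a fertilization assay CSV
#'
#' Schema: `species, temperature_c, ph, pair_id, tech_rep, n_scored,
#' n_fertilized`, one row per technical replicate; `#` comment lines
#' (e.g. the generator's seed) are skipped. Counts must be whole numbers
#' with `0 <= n_fertilized <= n_scored`; violations are reported with
#' their row numbers.
#'
#' @param path CSV path.
#' @return validated data frame in schema order.
#' @export
read_assay_csv <- function(path) {
  if (!file.exists(path)) stop_bad(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("species", "temperature_c", "ph", "pair_id", "tech_rep",
            "n_scored", "n_fertilized")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_bad(sprintf("assay CSV missing column(s): %s",
                     paste(miss, collapse = ", ")))
  for (col in c("temperature_c", "ph", "n_scored", "n_fertilized")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop_bad(sprintf("non-numeric '%s' at row(s) %s", col,
                       paste(utils::head(bad, 5), collapse = ", ")))
  }
  for (col in c("n_scored", "n_fertilized")) {
    bad <- which(df[[col]] != round(df[[col]]) | df[[col]] < 0)
    if (length(bad))
      stop_bad(sprintf("'%s' must be non-negative whole numbers; bad row(s): %s",
                       col, paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad <- which(df$n_fertilized > df$n_scored)
  if (length(bad))
    stop_bad(sprintf("n_fertilized > n_scored at row(s): %s",
                     paste(utils::head(bad, 5), collapse = ", ")))
  df[need]
}

#' @rdname read_assay_csv
#' @export
read_velocity_csv <- function(path) {
  if (!file.exists(path)) stop_bad(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "temperature_c", "ph", "velocity_um_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_bad(sprintf("velocity CSV missing column(s): %s",
                     paste(miss, collapse = ", ")))
  if (any(df$velocity_um_s < 0)) stop_bad("velocities must be >= 0")
  df
}

#' Aggregate technical replicates to biological-replicate fertilization rates
#'
#' Fertilization "rate" is the proportion of eggs fertilized. The fixed
#' aggregation order is technical -> biological -> treatment: each
#' technical replicate's proportion is `n_fertilized / n_scored`, and the
#' biological replicate (pair) value is the mean over its technical
#' replicates within a condition.
#'
#' @param assay assay data frame (schema of [read_assay_csv()]).
#' @return data frame: species, temperature_c, ph, pair_id,
#'   fertilization_prop (one row per pair x condition), with
#'   `n_tech_reps` used.
#' @export
aggregate_fertilization <- function(assay) {
  need <- c("temperature_c", "ph", "pair_id", "n_scored", "n_fertilized")
  if (!all(need %in% names(assay)))
    stop_bad("assay table lacks the technical-replicate schema")
  prop <- assay$n_fertilized / assay$n_scored
  key <- interaction(assay$temperature_c, assay$ph, assay$pair_id, drop = TRUE)
  agg <- data.frame(
    species = if ("species" %in% names(assay))
      tapply(assay$species, key, `[`, 1) else NA_character_,
    temperature_c = as.numeric(tapply(assay$temperature_c, key, `[`, 1)),
    ph = as.numeric(tapply(assay$ph, key, `[`, 1)),
    pair_id = as.character(tapply(assay$pair_id, key, `[`, 1)),
    fertilization_prop = as.numeric(tapply(prop, key, mean)),
    n_tech_reps = as.integer(tapply(prop, key, length)),
    stringsAsFactors = FALSE)
  rownames(agg) <- NULL
  agg[order(agg$temperature_c, agg$ph, agg$pair_id), ]
}

#' Aggregate simulated velocity records to per-sample summaries
#'
#' Per sample (pair x condition): mean VCL over motile sperm (those
#' above `threshold`) and the motile fraction, mirroring
#' [summarize_sample()] on raw tracks.
#'
#' @param velocity long data frame (`sample_id, temperature_c, ph,
#'   velocity_um_s`, one row per sperm).
#' @param threshold motility threshold, um/s.
#' @return data frame: sample_id, temperature_c, ph, pair_id (if
#'   present), mean_vcl, motile_fraction, n_sperm.
#' @export
aggregate_velocity <- function(velocity, threshold = 5) {
  need <- c("sample_id", "temperature_c", "ph", "velocity_um_s")
  if (!all(need %in% names(velocity)))
    stop_bad("velocity table lacks the per-sperm schema")
  key <- factor(velocity$sample_id, levels = unique(velocity$sample_id))
  mv <- function(v) { m <- v > threshold; if (any(m)) mean(v[m]) else 0 }
  agg <- data.frame(
    sample_id = levels(key),
    temperature_c = as.numeric(tapply(velocity$temperature_c, key, `[`, 1)),
    ph = as.numeric(tapply(velocity$ph, key, `[`, 1)),
    mean_vcl = as.numeric(tapply(velocity$velocity_um_s, key, mv)),
    motile_fraction = as.numeric(tapply(velocity$velocity_um_s, key,
                                        function(v) mean(v > threshold))),
    n_sperm = as.integer(tapply(velocity$velocity_um_s, key, length)),
    stringsAsFactors = FALSE)
  if ("pair_id" %in% names(velocity))
    agg$pair_id <- as.character(tapply(velocity$pair_id, key, `[`, 1))
  rownames(agg) <- NULL
  agg
}

#' Condition-level means for model-vs-measured comparison
#'
#' Averages biological replicates within each temperature x pH condition:
#' fertilization proportion and mean VCL / motile fraction.
#'
#' @param fert_by_pair output of [aggregate_fertilization()].
#' @param vel_by_sample output of [aggregate_velocity()].
#' @return list of two data frames keyed by (temperature_c, ph):
#'   `fert` with `measured_phi`, `vel` with `mean_vcl`, `motile_fraction`.
#' @export
condition_means <- function(fert_by_pair, vel_by_sample) {
  kf <- interaction(fert_by_pair$temperature_c, fert_by_pair$ph, drop = TRUE)
  fert <- data.frame(
    temperature_c = as.numeric(tapply(fert_by_pair$temperature_c, kf, `[`, 1)),
    ph = as.numeric(tapply(fert_by_pair$ph, kf, `[`, 1)),
    measured_phi = as.numeric(tapply(fert_by_pair$fertilization_prop, kf, mean)))
  kv <- interaction(vel_by_sample$temperature_c, vel_by_sample$ph, drop = TRUE)
  vel <- data.frame(
    temperature_c = as.numeric(tapply(vel_by_sample$temperature_c, kv, `[`, 1)),
    ph = as.numeric(tapply(vel_by_sample$ph, kv, `[`, 1)),
    mean_vcl = as.numeric(tapply(vel_by_sample$mean_vcl, kv, mean)),
    motile_fraction = as.numeric(tapply(vel_by_sample$motile_fraction, kv,
                                        mean)))
  rownames(fert) <- rownames(vel) <- NULL
  list(fert = fert[order(fert$temperature_c, fert$ph), ],
       vel = vel[order(vel$temperature_c, vel$ph), ])
}
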