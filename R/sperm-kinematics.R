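#' Sperm track container
#'
#' An ordered 2-D trajectory of one tracked sperm cell, as digitised from
#' video: coordinates in micrometres at a fixed frame rate. At least two
#' points are required and all coordinates must be finite.
#'
#' @param track_id identifier.
#' @param frame_rate frames per second (> 0).
#' @param x,y numeric coordinate vectors, um.
#' @return a `sperm_track` object.
#' @export
sperm_track <- function(track_id, frame_rate, x, y) {
  check_scalar_number(frame_rate, "frame_rate", lower = 1e-12)
  if (length(x) != length(y)) stop_bad("'x' and 'y' must have equal length")
  if (length(x) < 2L) stop_bad("a track needs at least 2 points")
  check_numeric_vector(x, "x", min_len = 2L)
  check_numeric_vector(y, "y", min_len = 2L)
  structure(list(track_id = as.character(track_id), frame_rate = frame_rate,
                 x = as.numeric(x), y = as.numeric(y)),
            class = "sperm_track")
}

#' Curvilinear velocity (VCL) of a sperm track
#'
#' VCL is the total point-to-point path length divided by elapsed time:
#' `sum(Euclidean steps) / ((n_points - 1) / frame_rate)`, in um/s. This
#' is the standard CASA curvilinear velocity; no smoothing is applied
#' before chord summation.
#'
#' @param track a [sperm_track()].
#' @return VCL in um/s (non-negative scalar).
#' @examples
#' tr <- sperm_track("t1", 60, x = cumsum(rep(5, 10)), y = rep(0, 10))
#' curvilinear_velocity(tr)  # 300 um/s
#' @export
curvilinear_velocity <- function(track) {
  if (!inherits(track, "sperm_track")) stop_bad("'track' must be a sperm_track")
  n <- length(track$x)
  path <- sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
  path / ((n - 1) / track$frame_rate)
}

#' Motile fraction of a velocity sample
#'
#' Fraction of sperm whose VCL strictly exceeds the movement threshold.
#' The threshold defaults to 5 um/s rather than a literal zero: under
#' tracking noise every cell shows some apparent displacement, so a small
#' positive epsilon at the digitising noise floor is required to score
#' "moving" meaningfully. Strict inequality is used.
#'
#' @param velocities numeric vector of VCLs, um/s (non-empty).
#' @param threshold movement threshold, um/s (>= 0); default 5.
#' @return proportion in [0, 1].
#' @export
motile_fraction <- function(velocities, threshold = 5) {
  check_numeric_vector(velocities, "velocities", min_len = 1L, lower = 0)
  check_scalar_number(threshold, "threshold", lower = 0)
  mean(velocities > threshold)
}

#' Summarise a set of tracks into a velocity sample
#'
#' Computes per-track VCLs, the motile fraction, and the mean VCL over
#' motile tracks only (immotile cells would otherwise drag the sample
#' mean toward the noise floor; continuously swimming cells are the
#' population of interest). Set `motile_only = FALSE` to average all
#' tracks. When no track is motile, `mean_vcl` is 0 and `all_immotile`
#' is set.
#'
#' @param tracks non-empty list of [sperm_track()] objects.
#' @param threshold movement threshold passed to [motile_fraction()].
#' @param motile_only average motile tracks only (default TRUE).
#' @param sample_id,temperature,ph metadata carried into the summary.
#' @return a `velocity_sample`: list with `sample_id`, `temperature`,
#'   `ph`, `velocities` (per-track VCLs), `motile_fraction`, `mean_vcl`,
#'   `all_immotile`, `n_tracks`.
#' @export
summarize_sample <- function(tracks, threshold = 5, motile_only = TRUE,
                             sample_id = "sample", temperature = NA_real_,
                             ph = NA_real_) {
  if (!is.list(tracks) || length(tracks) < 1L)
    stop_bad("'tracks' must be a non-empty list of sperm_track objects")
  v <- vapply(tracks, curvilinear_velocity, numeric(1))
  motile <- v > threshold
  all_immotile <- !any(motile)
  mean_vcl <- if (motile_only) {
    if (all_immotile) 0 else mean(v[motile])
  } else mean(v)
  structure(list(sample_id = as.character(sample_id),
                 temperature = temperature, ph = ph, velocities = v,
                 motile_fraction = mean(motile), mean_vcl = mean_vcl,
                 all_immotile = all_immotile, n_tracks = length(v),
                 threshold = threshold),
            class = "velocity_sample")
}

#' @export
print.velocity_sample <- function(x, ...) {
  cat(sprintf("velocity sample '%s': %d tracks, mean VCL %.1f um/s, %.0f%% motile%s\n",
              x$sample_id, x$n_tracks, x$mean_vcl, 100 * x$motile_fraction,
              if (x$all_immotile) " (all immotile)" else ""))
  invisible(x)
}

#' Read / write track tables
#'
#' Track CSVs hold columns `track_id, frame, x_um, y_um`; the frame rate
#' travels in a `# frame_rate: <Hz>` comment line (or is supplied by the
#' caller). Frames must be consecutive within a track.
#'
#' @param path CSV path.
#' @param frame_rate frames per second; overrides any header comment.
#' @return `read_track_csv()`: list of [sperm_track()];
#'   `write_track_csv()`: the path, invisibly.
#' @export
read_track_csv <- function(path, frame_rate = NULL) {
  if (!file.exists(path)) stop_bad(sprintf("no such file: %s", path))
  hdr <- readLines(path, n = 5L)
  fr_line <- grep("^#\\s*frame_rate:", hdr, value = TRUE)
  if (is.null(frame_rate)) {
    if (!length(fr_line))
      stop_bad("frame_rate not given and no '# frame_rate:' header in file")
    frame_rate <- as.numeric(sub("^#\\s*frame_rate:\\s*", "", fr_line[1]))
  }
  check_scalar_number(frame_rate, "frame_rate", lower = 1e-12)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("track_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_bad(sprintf("track CSV missing column(s): %s",
                     paste(miss, collapse = ", ")))
  lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$frame), ]
    sperm_track(d$track_id[1], frame_rate, d$x_um, d$y_um)
  })
}

#' @rdname read_track_csv
#' @param tracks list of [sperm_track()] objects sharing one frame rate.
#' @export
write_track_csv <- function(tracks, path) {
  if (!length(tracks)) stop_bad("'tracks' is empty")
  fr <- tracks[[1]]$frame_rate
  df <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(track_id = tr$track_id, frame = seq_along(tr$x) - 1L,
               x_um = tr$x, y_um = tr$y, stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate: %g", fr), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
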