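#' Two-factor response table for the multi-stressor experiment
#'
#' Container for the temperature x pH factorial: one row per biological
#' replicate (pair) per cell, with the response already averaged over
#' technical replicates (see [aggregate_fertilization()]). Balanced-ness
#' (equal cell counts) is recorded; the aligned-rank ANOVA requires it.
#'
#' @param response numeric responses (finite).
#' @param temperature factor-like temperature levels.
#' @param ph factor-like pH levels.
#' @param pair_id replicate identifiers.
#' @return a `factorial_dataset` data frame with columns `response`,
#'   `temperature`, `ph`, `pair_id` and attribute `balanced`.
#' @export
factorial_dataset <- function(response, temperature, ph, pair_id = NULL) {
  check_numeric_vector(response, "response", min_len = 2L)
  temperature <- factor(temperature)
  ph <- factor(ph)
  if (length(temperature) != length(response) || length(ph) != length(response))
    stop_bad("'temperature' and 'ph' must match 'response' in length")
  if (is.null(pair_id)) pair_id <- seq_along(response)
  counts <- table(temperature, ph)
  if (any(counts == 0)) stop_bad("empty cell(s): every temperature x pH cell needs at least one observation")
  out <- data.frame(response = response, temperature = temperature, ph = ph,
                    pair_id = as.character(pair_id), stringsAsFactors = FALSE)
  attr(out, "balanced") <- length(unique(as.vector(counts))) == 1L
  class(out) <- c("factorial_dataset", "data.frame")
  out
}

as_factorial_dataset <- function(data) {
  if (inherits(data, "factorial_dataset")) return(data)
  if (is.data.frame(data)) {
    nm <- names(data)
    tcol <- intersect(c("temperature", "temperature_c"), nm)[1]
    if (!is.na(tcol) && all(c("response", "ph") %in% nm))
      return(factorial_dataset(data$response, data[[tcol]], data$ph,
                               if ("pair_id" %in% nm) data$pair_id))
  }
  stop_bad("'data' must be a factorial_dataset or data frame with response/temperature/ph")
}

#' Align responses for one effect of a two-factor design
#'
#' The alignment step of the aligned rank transform (ART): every
#' response is stripped of all effects except the one of interest, using
#' cell-mean algebra. With cell means `m_ij`, row (temperature) means
#' `m_i.`, column (pH) means `m_.j` and grand mean `m`:
#' main effect A_i = `m_i. - m`, B_j = `m_.j - m`, interaction
#' AB_ij = `m_ij - m_i. - m_.j + m`; the aligned response is the
#' within-cell residual plus the target effect's estimate. Aligned
#' responses sum to zero by construction.
#'
#' @param data a [factorial_dataset()] (or coercible data frame).
#' @param effect `"A"` (temperature), `"B"` (pH) or `"AB"` (interaction).
#' @return numeric vector of aligned responses, same order as the rows.
#' @export
art_align <- function(data, effect = c("A", "B", "AB")) {
  data <- as_factorial_dataset(data)
  effect <- match.arg(effect)
  y <- data$response
  a <- data$temperature; b <- data$ph
  m <- mean(y)
  cell <- stats::ave(y, a, b, FUN = mean)
  ra <- stats::ave(y, a, FUN = mean)
  cb <- stats::ave(y, b, FUN = mean)
  resid <- y - cell
  est <- switch(effect,
                A = ra - m,
                B = cb - m,
                AB = cell - ra - cb + m)
  resid + est
}

# Sums of squares for a balanced two-way fixed-effects layout (direct
# cell-mean computation; b = 1 or a = 1 degenerate to one-way).
balanced_two_way_ss <- function(y, a, b) {
  m <- mean(y)
  ra <- stats::ave(y, a, FUN = mean)
  cb <- stats::ave(y, b, FUN = mean)
  cell <- stats::ave(y, a, b, FUN = mean)
  la <- nlevels(a); lb <- nlevels(b); n <- length(y)
  list(ss_a = sum((ra - m)^2), df_a = la - 1L,
       ss_b = sum((cb - m)^2), df_b = lb - 1L,
       ss_ab = sum((cell - ra - cb + m)^2), df_ab = (la - 1L) * (lb - 1L),
       ss_err = sum((y - cell)^2), df_err = n - la * lb)
}

#' Aligned rank transform (ART) factorial ANOVA
#'
#' Nonparametric two-factor ANOVA for designs where the general linear
#' model's assumptions fail, built to detect interaction as well as main
#' effects: for each effect the responses are aligned ([art_align()]),
#' converted to midranks (average ranks for ties) over the whole sample,
#' and analysed with a standard balanced two-way fixed-effects ANOVA of
#' which only the target effect's F is read off. Partial eta squared for
#' each effect is computed from its own ranked-aligned ANOVA. Alignment
#' diagnostics report the aligned-column sums (zero by construction) and
#' the "stripped" F statistics of the non-target effects on each
#' ranked-aligned set, which should be near zero for well-behaved data.
#'
#' Replicates are assumed exchangeable within cells (technical
#' replicates averaged beforehand; pairs enter only through that
#' averaging); the design must be balanced with at least 2 observations
#' per cell.
#'
#' @param data a [factorial_dataset()] (or coercible data frame).
#' @return an `art_result`: list with `anova` (data frame: effect, df1,
#'   df2, F, p_value, partial_eta_sq), `diagnostics` (aligned sums and
#'   stripped Fs), `n`, `balanced`.
#' @export
art_anova <- function(data) {
  data <- as_factorial_dataset(data)
  if (!attr(data, "balanced"))
    stop_bad("ART ANOVA requires a balanced design (equal cell counts)")
  a <- data$temperature; b <- data$ph
  n <- nrow(data)
  la <- nlevels(a); lb <- nlevels(b)
  if (n - la * lb < 1L)
    stop_bad("fewer than 1 residual degree of freedom; add replicates")

  effects <- c("A", "B", "AB")
  labels <- c(A = "temperature", B = "ph", AB = "temperature:ph")
  rows <- list(); diags <- list()
  for (ef in effects) {
    # interaction F undefined when either factor has a single level
    if (ef == "AB" && (la < 2L || lb < 2L)) next
    if (ef == "B" && lb < 2L) next
    if (ef == "A" && la < 2L) next
    al <- art_align(data, ef)
    r <- rank(al)  # midranks
    ss <- balanced_two_way_ss(r, a, b)
    ms_err <- ss$ss_err / ss$df_err
    pick <- switch(ef, A = c(ss$ss_a, ss$df_a), B = c(ss$ss_b, ss$df_b),
                   AB = c(ss$ss_ab, ss$df_ab))
    Fv <- (pick[1] / pick[2]) / ms_err
    rows[[ef]] <- data.frame(
      effect = labels[[ef]], df1 = pick[2], df2 = ss$df_err, F = Fv,
      p_value = stats::pf(Fv, pick[2], ss$df_err, lower.tail = FALSE),
      partial_eta_sq = partial_eta_squared(pick[1], ss$ss_err))
    stripped <- switch(ef,
      A = c(B = (ss$ss_b / max(1L, ss$df_b)) / ms_err,
            AB = (ss$ss_ab / max(1L, ss$df_ab)) / ms_err),
      B = c(A = (ss$ss_a / max(1L, ss$df_a)) / ms_err,
            AB = (ss$ss_ab / max(1L, ss$df_ab)) / ms_err),
      AB = c(A = (ss$ss_a / max(1L, ss$df_a)) / ms_err,
             B = (ss$ss_b / max(1L, ss$df_b)) / ms_err))
    diags[[ef]] <- list(aligned_sum = sum(al), stripped_F = stripped)
  }
  structure(list(anova = do.call(rbind, rows), diagnostics = diags,
                 n = n, balanced = TRUE),
            class = "art_result")
}

#' @export
print.art_result <- function(x, ...) {
  cat("Aligned rank transform ANOVA\n")
  tab <- x$anova
  tab$F <- round(tab$F, 4); tab$p_value <- signif(tab$p_value, 4)
  tab$partial_eta_sq <- round(tab$partial_eta_sq, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Partial eta squared
#'
#' `SS_effect / (SS_effect + SS_error)`: the proportion of variance
#' attributable to an effect after partialling out other effects.
#'
#' @param ss_effect,ss_error sums of squares (>= 0, not both 0).
#' @return proportion in [0, 1].
#' @export
partial_eta_squared <- function(ss_effect, ss_error) {
  check_scalar_number(ss_effect, "ss_effect", lower = 0)
  check_scalar_number(ss_error, "ss_error", lower = 0)
  if (ss_effect == 0 && ss_error == 0)
    stop_bad("partial eta squared undefined: both sums of squares are zero")
  ss_effect / (ss_effect + ss_error)
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean_a - mean_b) / s_p` with pooled variance
#' `((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2)`. The
#' magnitude is classified on the conventional scale (configurable):
#' very small < 0.2 <= small < 0.5 <= medium < 0.8 <= large < 1.2 <=
#' very large < 2.0 <= huge.
#'
#' @param group_a,group_b numeric vectors, each with >= 2 values.
#' @param thresholds named ascending cut points for the magnitude labels.
#' @return list with `d`, `magnitude`, `n_a`, `n_b`, `pooled_sd`.
#' @export
cohens_d <- function(group_a, group_b,
                     thresholds = c(`very small` = 0.01, small = 0.2,
                                    medium = 0.5, large = 0.8,
                                    `very large` = 1.2, huge = 2.0)) {
  check_numeric_vector(group_a, "group_a", min_len = 2L)
  check_numeric_vector(group_b, "group_b", min_len = 2L)
  na <- length(group_a); nb <- length(group_b)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 <= 0) stop_bad("pooled standard deviation is zero; d undefined")
  d <- (mean(group_a) - mean(group_b)) / sqrt(sp2)
  idx <- findInterval(abs(d), thresholds)
  magnitude <- if (idx == 0) "negligible" else names(thresholds)[idx]
  list(d = d, magnitude = magnitude, n_a = na, n_b = nb,
       pooled_sd = sqrt(sp2))
}

#' Bonferroni-adjusted pairwise posthoc contrasts
#'
#' For every pair of levels of the chosen factor: a t contrast on the
#' ART-consistent responses (aligned for that main effect, then
#' midranked, as in [art_anova()]) using the full two-way model's error
#' mean square and residual degrees of freedom — alignment subtracts
#' estimated cell effects, so a plain two-sample t test would understate
#' the error and inflate type I error. Bonferroni adjustment
#' `p_adj = min(1, m p_raw)` with m = number of pairs, and [cohens_d()]
#' on the raw responses for an effect size on the original scale.
#'
#' @param data a [factorial_dataset()] (or coercible data frame).
#' @param factor `"temperature"` or `"ph"`.
#' @return data frame: level_1, level_2, t, df, p_raw, p_adj, cohens_d,
#'   magnitude.
#' @export
bonferroni_pairwise <- function(data, factor = c("temperature", "ph")) {
  data <- as_factorial_dataset(data)
  factor <- match.arg(factor)
  f <- data[[factor]]
  if (nlevels(f) < 2L) stop_bad(sprintf("'%s' needs at least 2 levels", factor))
  effect <- if (factor == "temperature") "A" else "B"
  r <- rank(art_align(data, effect))
  ss <- balanced_two_way_ss(r, data$temperature, data$ph)
  ms_err <- ss$ss_err / ss$df_err
  levs <- levels(f)
  prs <- utils::combn(levs, 2, simplify = FALSE)
  m <- length(prs)
  out <- lapply(prs, function(pr) {
    i1 <- f == pr[1]; i2 <- f == pr[2]
    tstat <- (mean(r[i1]) - mean(r[i2])) /
      sqrt(ms_err * (1 / sum(i1) + 1 / sum(i2)))
    p_raw <- 2 * stats::pt(abs(tstat), ss$df_err, lower.tail = FALSE)
    cd <- cohens_d(data$response[i1], data$response[i2])
    data.frame(level_1 = pr[1], level_2 = pr[2],
               t = tstat, df = ss$df_err,
               p_raw = p_raw, p_adj = min(1, m * p_raw),
               cohens_d = cd$d, magnitude = cd$magnitude,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Spearman rank correlation with large-sample p value
#'
#' Pearson correlation of midranks. The p value uses the standard
#' large-sample t approximation `t = rho sqrt((n - 2) / (1 - rho^2))` on
#' n - 2 degrees of freedom (two-sided); exact permutation p values are
#' not computed. Constant input has no defined rank correlation and is
#' rejected.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  check_numeric_vector(x, "x", min_len = 3L)
  check_numeric_vector(y, "y", min_len = 3L)
  if (length(x) != length(y)) stop_bad("'x' and 'y' must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_bad("rank correlation undefined for constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = p, n = n)
}
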