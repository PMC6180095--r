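KIN_METRICS <- c("hic", "hic15", "hic36", "peak_lin_g",
                 "peak_ang_acc_rad_s2", "peak_ang_vel_rad_s",
                 "mps", "skull_stress_mpa")

#' Per-age, per-direction kinematics and tissue summary table
#'
#' Validates a data frame with one row per (age, impact direction)
#' carrying the head-injury metrics of a fall simulation campaign:
#' `age_years`, `direction` (front/back/side), `hic`, `hic15`, `hic36`,
#' `peak_lin_g`, `peak_ang_acc_rad_s2`, `peak_ang_vel_rad_s`, and
#' optionally `mps` and `skull_stress_mpa`.
#'
#' @param df A data frame with the columns above.
#' @return `df` with class `kinematics_table` prepended.
#' @export
kinematics_table <- function(df) {
  df <- as.data.frame(df)
  required <- c("age_years", "direction", "hic")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!all(df$direction %in% c("front", "back", "side")))
    stop("direction must be one of front, back, side", call. = FALSE)
  if (any(df$age_years <= 0))
    stop("ages must be positive", call. = FALSE)
  if (anyDuplicated(df[, c("age_years", "direction")]))
    stop("at most one row per (age, direction)", call. = FALSE)
  for (mcol in intersect(KIN_METRICS, names(df)))
    if (any(df[[mcol]] < 0, na.rm = TRUE))
      stop(sprintf("metric '%s' has negative values", mcol), call. = FALSE)
  class(df) <- unique(c("kinematics_table", class(df)))
  df
}

#' Maximum relative difference between impact directions
#'
#' `100 * (max - min) / max` over a set of positive per-direction values
#' of one metric — the statistic quantifying how much the impact direction
#' matters (e.g. 13.8% across the 3-year-old's front/back/side HIC values
#' versus 66.5% for rotational acceleration).
#'
#' @param values Two or more positive values.
#' @return Percentage in `[0, 100)`.
#' @examples
#' direction_difference_pct(c(877.3, 941.7, 811.5))  # 13.8
#' @export
direction_difference_pct <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("need at least two values", call. = FALSE)
  if (any(!is.finite(values) | values <= 0))
    stop("all values must be positive and finite", call. = FALSE)
  100 * (max(values) - min(values)) / max(values)
}

#' Per-age direction average of a metric
#'
#' Arithmetic mean of a metric over the impact directions present for
#' each age, with the min/max retained as range error bars.
#'
#' @param table A [kinematics_table()].
#' @param metric Name of a metric column present in the table.
#' @return A data.frame with columns `age_years`, `mean`, `min`, `max`,
#'   `n_directions`, one row per age, ordered by age.
#' @export
average_over_directions <- function(table, metric) {
  if (!inherits(table, "kinematics_table"))
    stop("`table` must be a kinematics_table", call. = FALSE)
  if (!is.character(metric) || length(metric) != 1L ||
      !metric %in% names(table) || !metric %in% KIN_METRICS)
    stop(sprintf("unknown metric '%s'", paste(metric, collapse = ",")),
         call. = FALSE)
  keep <- !is.na(table[[metric]])
  tb <- table[keep, , drop = FALSE]
  ages <- sort(unique(tb$age_years))
  out <- do.call(rbind, lapply(ages, function(a) {
    v <- tb[[metric]][tb$age_years == a]
    data.frame(age_years = a, mean = mean(v), min = min(v), max = max(v),
               n_directions = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' Fit a metric against age
#'
#' Linear model `y = a + b * age` by ordinary least squares, or
#' exponential model `y = a * exp(b * age)` by log-linear initialisation
#' followed by nonlinear least squares. R-squared is computed on the
#' original scale as `1 - SS_res / SS_tot` in both cases. Kinematic
#' metrics of playground falls decrease approximately linearly with age;
#' peak skull stress decays roughly exponentially (driven by suture
#' ossification in the youngest skulls).
#'
#' @param ages Ages in years (>= 3 points).
#' @param y Metric values (positive for the exponential model).
#' @param model `"linear"` or `"exponential"`.
#' @return An object of class `fit_result`: `model`, `params` (named
#'   `a`, `b`), `r_squared`, `fitted`.
#' @export
fit_vs_age <- function(ages, y, model = c("linear", "exponential")) {
  model <- match.arg(model)
  ages <- as.numeric(ages); y <- as.numeric(y)
  if (length(ages) != length(y) || length(ages) < 3L)
    stop("need >= 3 (age, y) points", call. = FALSE)
  if (stats::var(ages) == 0)
    stop("singular fit: all ages identical", call. = FALSE)

  if (model == "linear") {
    fit <- stats::lm(y ~ ages)
    a <- unname(stats::coef(fit)[1L]); b <- unname(stats::coef(fit)[2L])
    fitted <- a + b * ages
  } else {
    if (any(y <= 0))
      stop("exponential model requires positive y", call. = FALSE)
    lfit <- stats::lm(log(y) ~ ages)
    start <- list(a = exp(unname(stats::coef(lfit)[1L])),
                  b = unname(stats::coef(lfit)[2L]))
    nfit <- minpack.lm::nlsLM(y ~ a * exp(b * ages), start = start,
                              control = minpack.lm::nls.lm.control(maxiter = 200))
    a <- unname(stats::coef(nfit)["a"]); b <- unname(stats::coef(nfit)["b"])
    fitted <- a * exp(b * ages)
  }
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(model = model, params = c(a = a, b = b),
                 r_squared = r2, fitted = fitted),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  form <- if (x$model == "linear") "y = a + b*age" else "y = a*exp(b*age)"
  cat(sprintf("<fit_result> %s (%s): a = %.6g, b = %.6g, R^2 = %.4f\n",
              x$model, form, x$params["a"], x$params["b"], x$r_squared))
  invisible(x)
}

#' HIC corresponding to a given brain strain, via the cross-age fit
#'
#' Averages HIC and MPS over the impact directions within each age, fits
#' the direction-averaged pairs with ordinary least squares
#' `HIC = a + b * MPS`, and evaluates the line at `mps_value` — the
#' construction that maps the 0.3-strain mild-TBI threshold back onto the
#' HIC scale.
#'
#' @param table A [kinematics_table()] with `hic` and `mps` for >= 3 ages.
#' @param mps_value Strain at which to read off the HIC (default 0.3).
#' @return A list: `hic` (value of the fit at `mps_value`), `r_squared`,
#'   `params` (named `a`, `b`), and `points` (the per-age averages used).
#' @export
hic_at_mps <- function(table, mps_value = 0.3) {
  if (!inherits(table, "kinematics_table"))
    stop("`table` must be a kinematics_table", call. = FALSE)
  if (!"mps" %in% names(table))
    stop("table has no `mps` column", call. = FALSE)
  h <- average_over_directions(table, "hic")
  s <- average_over_directions(table, "mps")
  pts <- merge(data.frame(age_years = h$age_years, hic = h$mean),
               data.frame(age_years = s$age_years, mps = s$mean),
               by = "age_years")
  if (nrow(pts) < 3L)
    stop("need direction-averaged hic and mps for >= 3 ages", call. = FALSE)
  fit <- stats::lm(hic ~ mps, data = pts)
  a <- unname(stats::coef(fit)[1L]); b <- unname(stats::coef(fit)[2L])
  ss_tot <- sum((pts$hic - mean(pts$hic))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(hic = a + b * mps_value, r_squared = r2, params = c(a = a, b = b),
       points = pts)
}

#' Age-dependent HIC thresholds by tissue-response scaling
#'
#' Scales a reference HIC threshold across ages in proportion to the
#' inverse of an age-dependent tissue response:
#' `threshold(age) = reference_hic * tissue(reference_age) / tissue(age)`.
#' Ages whose tissue (e.g. peak skull stress) responds more strongly than
#' the reference age receive a proportionally lower threshold, which is
#' the rationale for stricter HIC limits for the youngest children.
#'
#' @param reference_hic Threshold at the reference age (e.g. 1000).
#' @param tissue_by_age Named numeric vector, names = ages in years,
#'   values = positive tissue responses.
#' @param reference_age Age (years) whose threshold equals
#'   `reference_hic`; must be present in `tissue_by_age`.
#' @return Named numeric vector of thresholds, same names as
#'   `tissue_by_age`.
#' @export
scale_thresholds <- function(reference_hic, tissue_by_age, reference_age) {
  if (!is.numeric(tissue_by_age) || is.null(names(tissue_by_age)))
    stop("`tissue_by_age` must be a named numeric vector", call. = FALSE)
  if (any(tissue_by_age <= 0))
    stop("tissue values must be positive", call. = FALSE)
  ref_key <- as.character(reference_age)
  if (!ref_key %in% names(tissue_by_age))
    stop(sprintf("reference age %s not present in tissue_by_age", ref_key),
         call. = FALSE)
  reference_hic * tissue_by_age[[ref_key]] / tissue_by_age
}
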