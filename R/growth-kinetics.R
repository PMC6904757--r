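#' Batch culture time course
#'
#' Container for (time, biomass, substrate) batch measurements used to
#' estimate interval-wise specific growth rates and biomass-specific
#' substrate uptake fluxes.
#'
#' @param times strictly increasing times, h (>= 2 points).
#' @param biomass biomass concentrations, gDW/L (> 0).
#' @param substrate substrate concentrations, mmol/L (>= 0).
#' @return a data frame of class `batch_time_course` with columns `time`,
#'   `biomass`, `substrate`.
#' @export
batch_time_course <- function(times, biomass, substrate) {
  stopifnot(length(times) >= 2,
            length(biomass) == length(times),
            length(substrate) == length(times))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(biomass <= 0)) stop("biomass must be positive")
  if (any(substrate < 0)) stop("substrate must be non-negative")
  structure(data.frame(time = as.numeric(times),
                       biomass = as.numeric(biomass),
                       substrate = as.numeric(substrate)),
            class = c("batch_time_course", "data.frame"))
}

#' Interval-wise specific growth rates from a batch time course
#'
#' For each interval, `mu_i = ln(x[i+1] / x[i]) / dt[i]` — the exact
#' exponential growth constant between consecutive biomass measurements.
#'
#' @param tc a [batch_time_course()].
#' @return numeric vector of length `n - 1`, 1/h.
#' @export
growth_rate_series <- function(tc) {
  n <- nrow(tc)
  log(tc$biomass[-1] / tc$biomass[-n]) / diff(tc$time)
}

#' Interval-wise substrate uptake fluxes from a batch time course
#'
#' For each interval,
#' `v_i = mu_i * (C[i+1] - C[i]) / (x[i] * (exp(mu_i * dt[i]) - 1))`,
#' the biomass-specific substrate flux under exponential growth at the
#' interval's `mu_i`. Consumption gives negative values, matching the
#' exchange-flux convention; take the absolute value when building a
#' [medium()]. As `mu_i -> 0` the expression has a removable singularity and
#' the analytic limit `(C[i+1] - C[i]) / (x[i] * dt[i])` is used for
#' `|mu_i| < 1e-9`.
#'
#' @param tc a [batch_time_course()].
#' @return numeric vector of length `n - 1`, mmol/gDW/h (negative =
#'   consumption).
#' @export
uptake_series <- function(tc) {
  n <- nrow(tc)
  mu <- growth_rate_series(tc)
  dt <- diff(tc$time)
  dC <- diff(tc$substrate)
  x <- tc$biomass[-n]
  ifelse(abs(mu) < 1e-9,
         dC / (x * dt),
         mu * dC / (x * (exp(mu * dt) - 1)))
}

#' Through-origin linear fit with Pearson correlation
#'
#' Fits `y = slope * x` with the intercept forced to zero
#' (`slope = sum(xy) / sum(x^2)`), and reports the ordinary Pearson
#' correlation of `(x, y)` with its two-sided p-value from the t transform
#' `t = R * sqrt((n - 2) / (1 - R^2))` on `n - 2` degrees of freedom.
#' This is the standard way predicted-versus-observed growth rates are
#' summarised: the slope says how far predictions are from the identity
#' line, R how tight the linear relationship is.
#'
#' @param x,y equal-length numeric vectors, `n >= 2`.
#' @return a list of class `correlation_report`: `slope`, `r`, `p_value`
#'   (`NA` when `n < 3` or R is degenerate), `n`.
#' @export
fit_through_origin <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  slope <- as.numeric(stats::coef(stats::lm(y ~ 0 + x)))
  r <- stats::cor(x, y)
  p <- NA_real_
  if (length(x) >= 3 && is.finite(r) && abs(r) < 1) {
    ct <- stats::cor.test(x, y, alternative = "two.sided", method = "pearson")
    p <- unname(ct$p.value)
  } else if (length(x) >= 3 && is.finite(r)) {
    p <- 0  # |R| == 1: perfectly collinear
  }
  structure(list(slope = slope, r = r, p_value = p, n = length(x)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> slope = %.4g, Pearson R = %.4g, p = %.3g, n = %d\n",
              x$slope, x$r, if (is.na(x$p_value)) NaN else x$p_value, x$n))
  invisible(x)
}

#' Predicted versus observed growth rates over a set of conditions
#'
#' For each condition, applies its medium to the model, runs FBA, and takes
#' the objective value as the predicted specific growth rate; the
#' predictions are then regressed through the origin against the observed
#' rates. This is the chemostat-validation workflow: uptake rates measured
#' per strain/condition become medium bounds, and the model's growth
#' predictions are confronted with the measured growth rates.
#'
#' @param model a `metabolic_model` with a biomass objective.
#' @param conditions a list of conditions, each a list with `medium` (a
#'   [medium()] or named numeric vector) and `observed` (observed growth
#'   rate, 1/h), optionally `label`; or a data frame as read by
#'   [read_conditions()].
#' @return list with `report` (a `correlation_report` of observed vs
#'   predicted) and `table` (data frame: `label`, `observed`, `predicted`,
#'   `status`).
#' @export
predicted_vs_observed <- function(model, conditions) {
  if (is.data.frame(conditions)) conditions <- conditions_from_table(conditions)
  stopifnot(length(conditions) >= 2)
  rows <- lapply(seq_along(conditions), function(i) {
    cond <- conditions[[i]]
    fba <- solve_fba(apply_medium(model, cond$medium))
    data.frame(label = if (!is.null(cond$label)) cond$label else paste0("condition_", i),
               observed = cond$observed,
               predicted = if (fba$status == "optimal") fba$objective_value else 0,
               status = fba$status,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(report = fit_through_origin(tab$observed, tab$predicted), table = tab)
}

# wide conditions table -> list of conditions. Columns: label, observed,
# then one column per exchange reaction with the uptake magnitude.
conditions_from_table <- function(df) {
  stopifnot(all(c("label", "observed") %in% names(df)))
  ex_cols <- setdiff(names(df), c("label", "observed"))
  lapply(seq_len(nrow(df)), function(i) {
    vals <- as.numeric(df[i, ex_cols])
    keep <- is.finite(vals) & vals > 0
    list(label = df$label[i],
         observed = df$observed[i],
         medium = medium(stats::setNames(vals[keep], ex_cols[keep])))
  })
}

#' Read a growth-conditions table
#'
#' Tab-separated file with columns `label`, `observed` (growth rate, 1/h)
#' and one column per exchange reaction holding that condition's uptake
#' magnitude (mmol/gDW/h; 0 or empty = not supplied).
#'
#' @param path file path.
#' @return data frame suitable for [predicted_vs_observed()].
#' @export
read_conditions <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
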