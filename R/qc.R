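## Physically-possible-limit quality control for 5-minute pyranometer series
## and numerical integration of accepted samples to daily irradiation totals.

#' Quality-control a solar irradiance sample against its physical limit
#'
#' Applies the physically-possible-limit check used in pyranometer quality
#' control: a sample is accepted only if it is strictly above 0 W/m2 and
#' strictly below its component's ceiling, which is `1.20 * I_E` for global
#' horizontal irradiance (GHI; transient cloud multireflection can push
#' ground measurements up to 20% above the extraterrestrial value) and `I_E`
#' itself for diffuse horizontal irradiance (DHI). Boundary values are
#' rejected: a night-time 0 under an `I_E` of 0 is rejected as non-positive.
#'
#' @param value measured irradiance, W/m2 (vectorised).
#' @param component `"GHI"` or `"DHI"` (recycled against `value`).
#' @param I_E extraterrestrial irradiance at the sample's instant, W/m2, >= 0.
#' @return A data frame with columns `accepted` (logical), `limit_used`
#'   (the W/m2 ceiling applied) and `reason` (`"ok"`, `"non_positive"` or
#'   `"exceeds_limit"`).
#' @seealso [integrate_daily()], [solar_toa_irradiance()]
#' @export
qc_sample <- function(value, component, I_E) {
  component <- as.character(component)
  bad <- !component %in% c("GHI", "DHI")
  if (any(bad)) {
    stop("unknown irradiance component: ", paste(unique(component[bad]), collapse = ", "))
  }
  if (any(I_E < 0)) stop("`I_E` must be non-negative")
  n <- max(length(value), length(component), length(I_E))
  value <- rep_len(value, n)
  component <- rep_len(component, n)
  I_E <- rep_len(I_E, n)

  limit <- ifelse(component == "GHI", 1.20 * I_E, I_E)
  reason <- rep("ok", n)
  reason[value >= limit] <- "exceeds_limit"
  reason[value <= 0] <- "non_positive" # non-positivity takes precedence
  data.frame(
    accepted = reason == "ok",
    limit_used = limit,
    reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Integrate accepted 5-minute samples into a daily irradiation total
#'
#' Numerically integrates the accepted samples of one calendar day and one
#' component into a daily energy total in MJ/m2: each accepted 5-minute mean
#' contributes `value * 300 s / 1e6`. Rejected samples are treated as missing
#' and contribute nothing; `coverage` reports the accepted fraction so that
#' low-coverage days can be filtered downstream.
#'
#' @param value irradiance samples, W/m2.
#' @param accepted logical vector of QC outcomes, same length as `value`.
#' @param date optional label for the day (stored as given).
#' @param component optional component label; must be a single value.
#' @param step_s sample spacing in seconds (fixed 5-minute cadence, 300 s).
#' @return A one-row data frame: `date`, `component`, `energy_mj_m2`,
#'   `n_accepted`, `n_rejected`, `coverage`.
#' @export
integrate_daily <- function(value, accepted, date = NA, component = NA_character_,
                            step_s = 300) {
  if (length(value) == 0L) stop("no samples to integrate")
  if (length(accepted) != length(value)) {
    stop("`accepted` must match `value` in length")
  }
  if (length(unique(component[!is.na(component)])) > 1L) {
    stop("samples mix irradiance components; integrate one component at a time")
  }
  energy <- sum(value[accepted]) * step_s / 1e6
  n_acc <- sum(accepted)
  data.frame(
    date = date[1L],
    component = component[1L],
    energy_mj_m2 = energy,
    n_accepted = n_acc,
    n_rejected = length(value) - n_acc,
    coverage = n_acc / length(value),
    stringsAsFactors = FALSE
  )
}

#' Quality-control and integrate a multi-day irradiance series
#'
#' Runs [qc_sample()] on every row of a 5-minute irradiance table, checks the
#' 300 s cadence within each day, and integrates accepted samples into one
#' daily total per (date, component). Days whose coverage falls below
#' `min_coverage` are dropped from the daily table (default 0: keep all days).
#'
#' @param samples data frame with columns `date` (day identifier),
#'   `decimal_hour`, `component` (`"GHI"`/`"DHI"`), `value_wm2`, and
#'   optionally `I_E` (computed from `latitude` when absent).
#' @param latitude signed site latitude, degrees; used when `I_E` is absent
#'   (requires a `day_of_year` column in that case).
#' @param min_coverage minimum accepted fraction for a day to be reported.
#' @return A list with `daily` (one row per date x component), `audit` (one
#'   row per rejected sample with its reason and limit) and `samples` (the
#'   input with QC columns appended).
#' @export
qc_integrate <- function(samples, latitude = -22.85, min_coverage = 0) {
  needed <- c("date", "decimal_hour", "component", "value_wm2")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols)) {
    stop("irradiance table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(samples) == 0L) stop("irradiance table is empty")
  if (is.null(samples$I_E)) {
    if (is.null(samples$day_of_year)) {
      stop("need either an `I_E` or a `day_of_year` column to compute limits")
    }
    samples$I_E <- solar_toa_irradiance(samples$day_of_year, samples$decimal_hour,
                                        latitude = latitude)
  }
  # enforce the fixed 5-minute cadence rather than silently reweighting
  for (d in unique(samples$date)) {
    for (comp in unique(samples$component[samples$date == d])) {
      hd <- sort(samples$decimal_hour[samples$date == d & samples$component == comp])
      if (length(hd) > 1L && any(abs(diff(hd) - 300 / 3600) > 1e-9)) {
        stop("irregular sample spacing on ", d, " (", comp, "); expected 300 s")
      }
    }
  }
  qc <- qc_sample(samples$value_wm2, samples$component, samples$I_E)
  samples <- cbind(samples, qc)

  key <- interaction(samples$date, samples$component, drop = TRUE)
  daily <- do.call(rbind, lapply(split(samples, key), function(g) {
    integrate_daily(g$value_wm2, g$accepted, date = g$date[1L],
                    component = g$component[1L])
  }))
  rownames(daily) <- NULL
  daily <- daily[daily$coverage >= min_coverage, , drop = FALSE]
  audit_cols <- intersect(c("date", "decimal_hour", "component", "value_wm2",
                            "limit_used", "reason"), names(samples))
  list(
    daily = daily,
    audit = samples[!samples$accepted, audit_cols, drop = FALSE],
    samples = samples
  )
}

#' Monthly mean and standard deviation summary
#'
#' Summarises daily records (irradiation totals, temperatures, ...) into
#' monthly mean +/- sd per variable, the layout of a field-season microclimate
#' table. Uses the sample standard deviation. Months with no records are
#' omitted with a warning.
#'
#' @param x data frame of daily records.
#' @param month name of the month column in `x`.
#' @param vars character vector of numeric columns to summarise.
#' @param by optional extra grouping column (e.g. environment).
#' @return Long-format data frame: grouping columns, `variable`, `mean`, `sd`,
#'   `n`.
#' @export
monthly_summary <- function(x, month = "month", vars, by = NULL) {
  if (!month %in% names(x)) stop("no `", month, "` column in `x`")
  months_present <- unique(x[[month]])
  if (is.factor(x[[month]])) {
    empty <- setdiff(levels(x[[month]]), as.character(months_present))
    if (length(empty)) {
      warning("months with no records omitted: ", paste(empty, collapse = ", "))
    }
  }
  groups <- if (is.null(by)) list(x[[month]]) else list(x[[by]], x[[month]])
  out <- do.call(rbind, lapply(vars, function(v) {
    agg <- aggregate(x[[v]], by = groups, FUN = function(z) {
      c(mean = mean(z), sd = stats::sd(z), n = length(z))
    })
    res <- data.frame(agg[-ncol(agg)], variable = v,
                      mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                      n = agg$x[, "n"], stringsAsFactors = FALSE)
    names(res)[seq_along(groups)] <- c(if (!is.null(by)) by, month)
    res
  }))
  rownames(out) <- NULL
  out
}
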