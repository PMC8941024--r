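## End-to-end study orchestration: synthetic or file inputs -> QC ->
## integration -> monthly summaries -> Willmott agreement -> nest geometry
## -> comparison battery -> mortality test.

#' Read an irradiance sample table from delimited text
#'
#' Validates the 5-minute irradiance CSV schema consumed by [qc_integrate()]:
#' columns `date`, `decimal_hour`, `component`, `value_wm2` (plus `I_E` or
#' `day_of_year`).
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_irradiance_csv <- function(path) {
  if (!file.exists(path)) stop("irradiance file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("date", "decimal_hour", "component", "value_wm2")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) || nrow(x) == 0L) {
    stop("`", path, "` does not match the irradiance schema ",
         "(date, decimal_hour, component, value_wm2[, I_E | day_of_year]); ",
         if (nrow(x) == 0L) "file has no rows" else
           paste("missing:", paste(missing_cols, collapse = ", ")))
  }
  x
}

#' Read a nest record table from delimited text
#'
#' Validates the nest CSV schema (environment, month, depth_cm, width_cm,
#' length_cm, height_cm, queen_alive) used by [nest_volumes()] and the
#' comparison battery.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_nests_csv <- function(path) {
  if (!file.exists(path)) stop("nest file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("environment", "month", "depth_cm", "width_cm", "length_cm",
              "height_cm", "queen_alive")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) || nrow(x) == 0L) {
    stop("`", path, "` does not match the nest schema (",
         paste(needed, collapse = ", "), "); ",
         if (nrow(x) == 0L) "file has no rows" else
           paste("missing:", paste(missing_cols, collapse = ", ")))
  }
  x
}

# route one response variable through the gate (or an override) and run the
# matching env-contrast test on the env x month factorial; the gate sees the
# cell-centred values (ANOVA assumes normal residuals, not a normal pooled
# response)
.compare_variable <- function(values, env, month, route = "auto", alpha = 0.05) {
  if (route == "auto") {
    centred <- values - stats::ave(values, env, month)
    route <- normality_gate(centred, alpha = alpha)$route
  }
  env <- factor(env, levels = c("sunny", "shaded"))
  month <- factor(month)
  if (route == "parametric") {
    fit <- two_way_anova_tukey(values, env, month, alpha = alpha)
    letters <- fit$letters$factor_a
    centre <- tapply(values, env, mean)
    spread <- tapply(values, env, stats::sd)
    p_env <- fit$anova$p_value[fit$anova$effect == "factor_a"]
    method <- "two-way ANOVA + Tukey"
  } else {
    fit <- scheirer_ray_hare(values, env, month)
    dn <- dunn_test(values, env, alpha = alpha)
    letters <- dn$letters
    centre <- tapply(values, env, stats::median)
    spread <- tapply(values, env, stats::IQR)
    p_env <- fit$p_value[fit$effect == "factor_a"]
    method <- "Scheirer-Ray-Hare + Dunn (FDR)"
  }
  list(route = route, method = method, fit = fit, p_env = p_env,
       table = data.frame(
         environment = levels(env),
         centre = as.numeric(centre[levels(env)]),
         spread = as.numeric(spread[levels(env)]),
         letter = unname(letters[levels(env)]),
         stringsAsFactors = FALSE
       ))
}

#' Run the full study pipeline
#'
#' Orchestrates a complete analysis on synthetic inputs: simulates both
#' environments' 5-minute irradiance, quality-controls and integrates it to
#' daily totals, simulates coupled temperatures, then produces the study's
#' result tables: (i) monthly microclimate means +/- sd per environment,
#' (ii) monthly Willmott agreement indices between environments and between
#' external and internal series, (iii) chamber-dimension comparisons with
#' compact letters (dimensions routed through the normality gate, volume
#' forced nonparametric, per the medians-with-Dunn convention), (iv) census
#' trajectory tables, and (v) the equal-proportions mortality test.
#'
#' @param config a [synthetic_config()] list.
#' @param seed integer seed controlling every stochastic stage.
#' @param alpha significance level for all tests and letters.
#' @param routing named character vector overriding the test route per
#'   variable (`"parametric"`, `"nonparametric"` or `"auto"`).
#' @param min_coverage minimum daily QC coverage retained (see
#'   [qc_integrate()]).
#' @return Object of class `"nestclim_study"`: list of result tables plus a
#'   run manifest (seed, parameters, stage counts).
#' @export
run_study <- function(config = synthetic_config(), seed = 1, alpha = 0.05,
                      routing = c(depth_cm = "auto", width_cm = "auto",
                                  length_cm = "auto", height_cm = "auto",
                                  volume_cm3 = "nonparametric"),
                      min_coverage = 0) {
  if (!inherits(config, "nestclim_config")) stop("`config` must come from synthetic_config()")
  set.seed(seed)
  stages <- list()

  ## microclimate: irradiance -> QC -> daily totals -> temperatures
  ## both environments share a daily weather (clearness) sequence, as the
  ## study's adjacent plots do
  ndays <- config$months * config$days_per_month
  clearness <- stats::rbeta(ndays, config$cloud_beta[1], config$cloud_beta[2])
  clim <- list()
  for (env in c("sunny", "shaded")) {
    samples <- simulate_irradiance_season(env, config, seed = NULL,
                                          clearness = clearness)
    qc <- qc_integrate(samples, latitude = config$latitude,
                       min_coverage = min_coverage)
    daily <- qc$daily
    key <- as.integer(sub(".*_day", "", daily$date))
    daily <- daily[order(key), ]
    daily$study_day <- sort(key)
    daily$month <- (daily$study_day - 1) %/% config$days_per_month + 1L
    temps <- simulate_temperatures(env, daily$energy_mj_m2, config, seed = NULL)
    clim[[env]] <- data.frame(
      environment = env, study_day = daily$study_day, month = daily$month,
      irradiation = daily$energy_mj_m2, coverage = daily$coverage,
      external = temps$external, internal = temps$internal,
      stringsAsFactors = FALSE
    )
    stages[[paste0("qc_", env)]] <- c(samples_in = nrow(samples),
                                      rejected = nrow(qc$audit),
                                      days_out = nrow(daily))
  }
  daily_climate <- rbind(clim$sunny, clim$shaded)
  rownames(daily_climate) <- NULL

  monthly_climate <- monthly_summary(
    daily_climate, month = "month",
    vars = c("internal", "external", "irradiation"), by = "environment"
  )

  ## Willmott agreement (daily series paired by study day)
  wide <- merge(clim$sunny, clim$shaded, by = c("study_day", "month"),
                suffixes = c("_sunny", "_shaded"))
  willmott_between <- monthly_willmott(wide, pairs = list(
    external = c("external_sunny", "external_shaded"),
    internal = c("internal_sunny", "internal_shaded"),
    irradiation = c("irradiation_sunny", "irradiation_shaded")
  ))
  willmott_within <- do.call(rbind, lapply(c("sunny", "shaded"), function(e) {
    w <- monthly_willmott(clim[[e]],
                          pairs = list(internal_vs_external = c("internal", "external")))
    w$pair <- paste0(w$pair, "_", e)
    w
  }))

  ## colonies: geometry + comparison battery + censuses + mortality
  col <- simulate_colonies(config, seed = NULL)
  nests <- nest_volumes(col$nests)
  vars <- c("depth_cm", "width_cm", "length_cm", "height_cm", "volume_cm3")
  comparisons <- lapply(vars, function(v) {
    route <- if (v %in% names(routing)) routing[[v]] else "auto"
    .compare_variable(nests[[v]], nests$environment, nests$month,
                      route = route, alpha = alpha)
  })
  names(comparisons) <- vars
  chamber_table <- do.call(rbind, lapply(vars, function(v) {
    cbind(variable = v, comparisons[[v]]$table,
          method = comparisons[[v]]$method,
          p_env = comparisons[[v]]$p_env)
  }))
  rownames(chamber_table) <- NULL

  census_vars <- c("eggs", "larvae", "pupae", "workers_small_medium",
                   "queen_mass_mg", "fungus_biomass_mg")
  census_table <- monthly_summary(col$census, month = "month",
                                  vars = census_vars, by = "environment")

  mt <- col$mortality
  mortality_test <- equal_proportions_test(mt$deaths[match(c("sunny", "shaded"), mt$environment)],
                                           mt$n[match(c("sunny", "shaded"), mt$environment)])
  mortality <- data.frame(
    environment = c("sunny", "shaded"),
    deaths = mt$deaths[match(c("sunny", "shaded"), mt$environment)],
    n = mt$n[match(c("sunny", "shaded"), mt$environment)],
    stringsAsFactors = FALSE
  )
  mortality$proportion <- mortality$deaths / mortality$n

  structure(list(
    monthly_climate = monthly_climate,
    daily_climate = daily_climate,
    willmott_between = willmott_between,
    willmott_within = willmott_within,
    chamber_table = chamber_table,
    comparisons = comparisons,
    census_table = census_table,
    census = col$census,
    nests = nests,
    mortality = mortality,
    mortality_test = mortality_test,
    manifest = list(seed = seed, alpha = alpha, routing = routing,
                    config = config, stages = stages,
                    package_version = as.character(utils::packageVersion("nestclim")))
  ), class = "nestclim_study")
}

#' @export
print.nestclim_study <- function(x, ...) {
  cat("Synthetic nest-microclimate study (seed", x$manifest$seed, ")\n\n")
  cat("Monthly climate (mean +/- sd):\n")
  print(format_monthly(x$monthly_climate), row.names = FALSE)
  cat("\nWillmott agreement between environments:\n")
  print(x$willmott_between, row.names = FALSE, digits = 3)
  cat("\nWillmott agreement, internal vs external:\n")
  print(x$willmott_within, row.names = FALSE, digits = 3)
  cat("\nChamber dimensions (letters: groups sharing a letter do not differ):\n")
  print(x$chamber_table, row.names = FALSE, digits = 4)
  cat("\nMortality:\n")
  print(x$mortality, row.names = FALSE)
  cat(sprintf("Equal-proportions test: X-squared = %.2f, df = %d, p = %.3g\n",
              x$mortality_test$statistic, x$mortality_test$parameter,
              x$mortality_test$p.value))
  invisible(x)
}

#' Format a monthly summary as "mean +/- sd" strings
#'
#' @param x output of [monthly_summary()].
#' @param digits digits for rounding.
#' @return Wide data frame, one column per month.
#' @export
format_monthly <- function(x, digits = 1) {
  x$cell <- sprintf("%.*f ± %.*f", digits, x$mean, digits, x$sd)
  wide <- stats::reshape(
    x[, c(setdiff(names(x), c("mean", "sd", "n", "cell")), "cell")],
    idvar = setdiff(names(x), c("mean", "sd", "n", "cell", "month")),
    timevar = "month", direction = "wide"
  )
  names(wide) <- sub("^cell\\.", "month_", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Plot monthly Willmott agreement indices
#'
#' Grouped barplot of the study's monthly Willmott indices: agreement of each
#' microclimate variable between environments, and agreement of internal vs
#' external temperature within each environment.
#'
#' @param x a `"nestclim_study"` object.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the plotted matrix.
#' @export
plot.nestclim_study <- function(x, ...) {
  w <- rbind(x$willmott_between, x$willmott_within)
  m <- tapply(w$d, list(w$pair, w$month), mean)
  op <- graphics::par(mfrow = c(1, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(m, beside = TRUE, ylim = c(0, 1),
                    xlab = "study month", ylab = "Willmott index d",
                    legend.text = rownames(m),
                    args.legend = list(x = "topright", cex = 0.7, bty = "n"),
                    ...)
  invisible(m)
}

#' Write a study's result tables to a directory
#'
#' Dumps every tabular output of [run_study()] as CSV plus a plain-text run
#' manifest. Refuses to overwrite an existing non-empty directory unless
#' `overwrite = TRUE`.
#'
#' @param study a `"nestclim_study"` object.
#' @param dir output directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite) {
    stop("`", dir, "` is not empty; pass overwrite = TRUE to replace outputs")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("monthly_climate", "daily_climate", "willmott_between",
              "willmott_within", "chamber_table", "census_table", "nests",
              "census", "mortality")
  for (t in tables) {
    utils::write.csv(study[[t]], file.path(dir, paste0(t, ".csv")),
                     row.names = FALSE)
  }
  manifest <- c(
    sprintf("nestclim %s", study$manifest$package_version),
    sprintf("seed: %d", study$manifest$seed),
    sprintf("alpha: %g", study$manifest$alpha),
    sprintf("routing: %s",
            paste(names(study$manifest$routing), study$manifest$routing,
                  sep = "=", collapse = ", ")),
    sprintf("mortality test: X-squared = %.4f, p = %.4g",
            study$mortality_test$statistic, study$mortality_test$p.value)
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
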