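## Synthetic field data: 5-minute irradiance with cloud noise and
## multireflection spikes, coupled external/internal temperatures, and
## founding-colony censuses with chamber dimensions and queen survival.
##
## Defaults emulate the study conditions: a southern-hemisphere site at
## 22.85 deg S, four months of records starting in November (day-of-year
## 305), 100 founding queens per environment, sunny monthly irradiation
## means around 17.5-21.3 MJ/m2 and shaded totals in 2-8 MJ/m2, and
## claustral-phase mortality of 0.91 (sunny) vs 0.58 (shaded).

#' Configuration for the synthetic study generators
#'
#' Bundles every tunable of the three generators with defaults calibrated to
#' the study conditions. Irradiance is multiplicative on the clear-sky
#' envelope: a daily clearness index (beta-distributed) times bounded
#' within-day noise, plus rare multireflection spikes that exceed the
#' extraterrestrial value so the quality-control rejection paths are
#' exercised. The shaded environment's series is additionally scaled by
#' `shade_transmittance`, calibrated to the measured shaded totals
#' (2-8 MJ/m2) rather than the shade screen's nominal 50% rating.
#'
#' @param latitude signed site latitude, degrees.
#' @param months number of study months.
#' @param days_per_month days per synthetic month.
#' @param start_doy day-of-year of the first study day (305 = 1 November).
#' @param nests_per_env founding queens per environment.
#' @param atm_transmittance clear-sky atmospheric transmittance.
#' @param cloud_beta shape parameters of the daily clearness beta draw.
#' @param cloud_within_sd sd of the bounded within-day transmittance noise.
#' @param spike_prob per-sample probability of a multireflection spike.
#' @param spike_range spike magnitude as a multiple of the extraterrestrial
#'   irradiance (above 1.20 so spiked GHI samples violate their QC limit).
#' @param shade_transmittance fraction of global irradiance reaching the
#'   shaded environment's sensor.
#' @param temperature per-environment temperature coupling parameters:
#'   external baseline (deg C), irradiance coupling (deg C per MJ/m2 about
#'   `mj_ref`), external noise sd, internal baseline, damping of external
#'   anomalies at 15 cm depth, internal lag (days) and internal noise sd.
#' @param mortality_p per-environment probability that a founding queen dies
#'   during the claustral phase.
#' @param census monthly mean trajectories and dispersions of the census
#'   variables; `sunny_factor` scales counts and fungus biomass down in the
#'   sunny environment. Queen mass interpolates its month-1 to month-4
#'   anchors (658.5 to 229.45 mg) linearly; fungus biomass grows
#'   log-linearly between its anchors (64.5 to 1354.9 mg).
#' @param nest_dims per-environment means and common sds (cm) of chamber
#'   depth, width, length and height (shaded chambers deeper and larger).
#' @return A list of class `"nestclim_config"`.
#' @export
synthetic_config <- function(latitude = -22.85,
                             months = 4,
                             days_per_month = 30,
                             start_doy = 305,
                             nests_per_env = 100,
                             atm_transmittance = 0.72,
                             cloud_beta = c(2.1, 1.25),
                             cloud_within_sd = 0.08,
                             spike_prob = 0.01,
                             spike_range = c(1.21, 1.35),
                             shade_transmittance = 0.25,
                             temperature = list(
                               sunny = list(ext_base = 23.7, coupling = 0.50,
                                            ext_noise_sd = 2.0, int_base = 25.6,
                                            damping = 0.20, lag = 0,
                                            int_noise_sd = 0.4),
                               shaded = list(ext_base = 22.7, coupling = 1.20,
                                             ext_noise_sd = 1.8, int_base = 23.9,
                                             damping = 0.55, lag = 0,
                                             int_noise_sd = 0.5)
                             ),
                             mortality_p = c(sunny = 0.91, shaded = 0.58),
                             census = list(
                               eggs = c(25, 70, 115.5, 100),
                               larvae = c(30, 30, 30, 30),
                               pupae = c(5, 40, 60, 70),
                               workers_small_medium = c(2, 20, 40, 55),
                               size = 8,
                               sunny_factor = 0.65,
                               queen_mass_anchors = c(658.5, 229.45),
                               queen_mass_sd = 40,
                               fungus_anchors = c(64.5, 1354.9),
                               fungus_sdlog = 0.20
                             ),
                             nest_dims = list(
                               sunny = c(depth = 9.21, width = 2.43,
                                         length = 3.34, height = 2.62),
                               shaded = c(depth = 13.18, width = 3.41,
                                          length = 4.52, height = 3.66),
                               sd = c(depth = 1.2, width = 0.35,
                                      length = 0.45, height = 0.40)
                             )) {
  cfg <- list(latitude = latitude, months = months,
              days_per_month = days_per_month, start_doy = start_doy,
              nests_per_env = nests_per_env,
              atm_transmittance = atm_transmittance, cloud_beta = cloud_beta,
              cloud_within_sd = cloud_within_sd, spike_prob = spike_prob,
              spike_range = spike_range,
              shade_transmittance = shade_transmittance,
              temperature = temperature, mortality_p = mortality_p,
              census = census, nest_dims = nest_dims)
  if (shade_transmittance <= 0 || shade_transmittance > 1) {
    stop("`shade_transmittance` must lie in (0, 1]")
  }
  if (any(mortality_p < 0 | mortality_p > 1)) {
    stop("`mortality_p` entries must be probabilities in [0, 1]")
  }
  if (spike_prob < 0 || spike_prob > 1) stop("`spike_prob` must be in [0, 1]")
  if (months < 1 || days_per_month < 1 || nests_per_env < 1) {
    stop("counts must be positive")
  }
  if (atm_transmittance <= 0 || atm_transmittance > 1) {
    stop("`atm_transmittance` must lie in (0, 1]")
  }
  class(cfg) <- "nestclim_config"
  cfg
}

# day-of-year wrapped into [1, 365]
.wrap_doy <- function(doy) ((doy - 1) %% 365) + 1

#' Simulate one day of 5-minute irradiance samples
#'
#' Generates 288 five-minute samples for one site day: the extraterrestrial
#' envelope at the site latitude, attenuated by the clear-sky transmittance
#' and a stochastic cloud transmittance (a daily clearness index with bounded
#' within-day noise), with occasional multireflection spikes above the
#' extraterrestrial value. The diffuse component (`"DHI"`) is the global
#' value scaled by a cloud-dependent diffuse fraction, so a day's DHI never
#' exceeds its GHI; in the shaded environment the whole series is scaled by
#' `shade_transmittance`.
#'
#' @param env `"sunny"` or `"shaded"`.
#' @param day_of_year integer day of year of the simulated day.
#' @param config a [synthetic_config()] list.
#' @param seed integer seed, or `NULL` to continue the current RNG stream.
#' @param component `"GHI"` or `"DHI"`; defaults to the component measured in
#'   each environment (global in the sunny plot, diffuse under the screen).
#' @param clearness optional daily clearness index in (0, 1]; drawn from the
#'   configured beta distribution when `NULL`. Passing the same value to both
#'   environments makes them share a day's weather, as adjacent field plots
#'   do.
#' @return Data frame with columns `date` (= day_of_year label),
#'   `day_of_year`, `decimal_hour`, `component`, `value_wm2`, `I_E`.
#' @export
simulate_irradiance_day <- function(env = c("sunny", "shaded"), day_of_year,
                                    config = synthetic_config(), seed = NULL,
                                    component = NULL, clearness = NULL) {
  env <- match.arg(env)
  if (!inherits(config, "nestclim_config")) stop("`config` must come from synthetic_config()")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(component)) component <- if (env == "sunny") "GHI" else "DHI"
  doy <- .wrap_doy(day_of_year)
  hd <- (seq_len(288) - 1) / 12 # 5-minute decimal hours
  I_E <- solar_toa_irradiance(doy, hd, latitude = config$latitude)

  if (is.null(clearness)) {
    clearness <- stats::rbeta(1, config$cloud_beta[1], config$cloud_beta[2])
  }
  tau <- pmin(1, pmax(0, clearness *
                        (1 + stats::rnorm(288, 0, config$cloud_within_sd))))
  value <- I_E * config$atm_transmittance * tau
  if (env == "shaded") {
    # screen-transmitted light is what the shaded sensor records (as DHI)
    value <- value * config$shade_transmittance
  } else if (component == "DHI") {
    value <- value * (0.3 + 0.7 * (1 - tau)) # cloud-dependent diffuse fraction
  }
  # multireflection spikes hit the sensor after all attenuation, so both
  # components' upper-limit rejection paths are exercised
  spike <- stats::runif(288) < config$spike_prob & I_E > 0
  value[spike] <- I_E[spike] * stats::runif(sum(spike), config$spike_range[1],
                                            config$spike_range[2])
  data.frame(
    date = sprintf("doy%03d", doy),
    day_of_year = doy,
    decimal_hour = hd,
    component = component,
    value_wm2 = value,
    I_E = I_E,
    stringsAsFactors = FALSE
  )
}

#' Simulate the full multi-month irradiance record for one environment
#'
#' Stacks [simulate_irradiance_day()] over the configured study window,
#' labelling each day with its study month.
#'
#' @inheritParams simulate_irradiance_day
#' @param clearness optional vector of daily clearness indices, one per study
#'   day; lets two environments share the same weather sequence.
#' @return Data frame of 5-minute samples with `month` and `study_day` added.
#' @export
simulate_irradiance_season <- function(env, config = synthetic_config(),
                                       seed = NULL, component = NULL,
                                       clearness = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ndays <- config$months * config$days_per_month
  if (!is.null(clearness) && length(clearness) != ndays) {
    stop("`clearness` must have one value per study day (", ndays, ")")
  }
  days <- lapply(seq_len(ndays), function(k) {
    d <- simulate_irradiance_day(env, config$start_doy + k - 1, config,
                                 seed = NULL, component = component,
                                 clearness = clearness[k])
    d$date <- sprintf("%s_day%03d", env, k)
    d$study_day <- k
    d$month <- (k - 1) %/% config$days_per_month + 1L
    d
  })
  do.call(rbind, days)
}

#' Simulate coupled external and internal (15 cm) daily temperatures
#'
#' Daily external temperature is an environment baseline plus an
#' irradiation-coupled anomaly and weather noise; the internal chamber
#' temperature at 15 cm depth is a damped, lagged transform of the external
#' anomaly with small sensor noise, so the internal series is warmer-biased
#' but much less variable than the external one.
#'
#' @param env `"sunny"` or `"shaded"`.
#' @param daily_mj numeric vector of daily irradiation totals, MJ/m2, one
#'   per study day.
#' @param config a [synthetic_config()] list.
#' @param seed integer seed, or `NULL` to continue the current RNG stream.
#' @return Data frame with `study_day`, `month`, `external`, `internal`.
#' @export
simulate_temperatures <- function(env = c("sunny", "shaded"), daily_mj,
                                  config = synthetic_config(), seed = NULL) {
  env <- match.arg(env)
  if (!is.null(seed)) set.seed(seed)
  p <- config$temperature[[env]]
  n <- length(daily_mj)
  if (n == 0L) stop("`daily_mj` is empty")
  ext <- p$ext_base + p$coupling * (daily_mj - mean(daily_mj)) +
    stats::rnorm(n, 0, p$ext_noise_sd)
  lagged <- if (p$lag > 0) {
    c(rep(p$ext_base, p$lag), ext[seq_len(n - p$lag)])
  } else ext
  int <- p$int_base + p$damping * (lagged - p$ext_base) +
    stats::rnorm(n, 0, p$int_noise_sd)
  data.frame(
    study_day = seq_len(n),
    month = (seq_len(n) - 1) %/% config$days_per_month + 1L,
    external = ext,
    internal = int
  )
}

# linear interpolation across study months between two anchor values
.month_anchor <- function(anchors, month, months) {
  anchors[1] + (anchors[2] - anchors[1]) * (month - 1) / (months - 1)
}

#' Simulate founding colonies: survival, chamber geometry and censuses
#'
#' For each environment, `nests_per_env` founding events are simulated. Each
#' queen dies during the claustral phase with the environment's mortality
#' probability; 25% of nests are excavated in each study month. Every
#' excavated nest yields chamber dimensions drawn around its environment's
#' means (shaded chambers deeper and larger); nests whose queen survived
#' additionally yield a census row: overdispersed (negative-binomial) counts
#' of eggs, larvae, pupae and small/medium workers around monthly mean
#' trajectories, a queen mass declining from its first-month anchor, and a
#' fungus-garden biomass growing between its anchors.
#'
#' @param config a [synthetic_config()] list.
#' @param seed integer seed, or `NULL` to continue the current RNG stream.
#' @return List with `nests` (one row per excavated nest: environment, month,
#'   dimensions, `queen_alive`), `census` (one row per surviving nest) and
#'   `mortality` (deaths and totals per environment).
#' @export
simulate_colonies <- function(config = synthetic_config(), seed = NULL) {
  if (!inherits(config, "nestclim_config")) stop("`config` must come from synthetic_config()")
  if (!is.null(seed)) set.seed(seed)
  cs <- config$census
  nests <- list(); census <- list()
  for (env in c("sunny", "shaded")) {
    n <- config$nests_per_env
    died <- stats::rbinom(n, 1, config$mortality_p[[env]]) == 1
    month <- rep(seq_len(config$months), length.out = n)[order(stats::runif(n))]
    mu <- config$nest_dims[[env]]
    sd <- config$nest_dims$sd
    dims <- vapply(names(mu), function(v) {
      pmax(0.2, stats::rnorm(n, mu[[v]], sd[[v]]))
    }, numeric(n))
    nest <- data.frame(
      nest_id = paste0(substr(env, 1, 2), seq_len(n)),
      environment = env,
      month = month,
      depth_cm = dims[, "depth"],
      width_cm = dims[, "width"],
      length_cm = dims[, "length"],
      height_cm = dims[, "height"],
      queen_alive = !died,
      stringsAsFactors = FALSE
    )
    nests[[env]] <- nest

    alive <- nest[nest$queen_alive, ]
    if (nrow(alive)) {
      m <- alive$month
      cf <- if (env == "sunny") cs$sunny_factor else 1
      draw_counts <- function(traj) {
        stats::rnbinom(nrow(alive), size = cs$size, mu = pmax(0.1, cf * traj[m]))
      }
      qm <- .month_anchor(cs$queen_mass_anchors, m, config$months) +
        stats::rnorm(nrow(alive), 0, cs$queen_mass_sd)
      fb <- exp(.month_anchor(log(cs$fungus_anchors), m, config$months)) *
        cf * stats::rlnorm(nrow(alive), 0, cs$fungus_sdlog)
      census[[env]] <- data.frame(
        nest_id = alive$nest_id,
        environment = env,
        month = m,
        eggs = draw_counts(cs$eggs),
        larvae = draw_counts(cs$larvae),
        pupae = draw_counts(cs$pupae),
        workers_small_medium = draw_counts(cs$workers_small_medium),
        queen_mass_mg = pmax(1, qm),
        fungus_biomass_mg = fb,
        stringsAsFactors = FALSE
      )
    }
  }
  nests <- do.call(rbind, nests)
  rownames(nests) <- NULL
  census <- do.call(rbind, census)
  if (!is.null(census)) rownames(census) <- NULL
  deaths <- tapply(!nests$queen_alive, nests$environment, sum)
  totals <- tapply(nests$queen_alive, nests$environment, length)
  list(
    nests = nests,
    census = census,
    mortality = data.frame(
      environment = names(deaths),
      deaths = as.integer(deaths),
      n = as.integer(totals),
      stringsAsFactors = FALSE
    )
  )
}
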