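cfg <- synthetic_config()

test_that("all three generators are deterministic under a fixed seed", {
  expect_identical(simulate_irradiance_day("sunny", 320, cfg, seed = 3),
                   simulate_irradiance_day("sunny", 320, cfg, seed = 3))
  mj <- runif(20, 2, 20)
  expect_identical(simulate_temperatures("shaded", mj, cfg, seed = 4),
                   simulate_temperatures("shaded", mj, cfg, seed = 4))
  expect_identical(simulate_colonies(cfg, seed = 5),
                   simulate_colonies(cfg, seed = 5))
})

test_that("spike-free clear days pass global-irradiance QC entirely", {
  clear <- synthetic_config(spike_prob = 0, cloud_within_sd = 0,
                            atm_transmittance = 1)
  day <- simulate_irradiance_day("sunny", 330, clear, seed = 1, clearness = 1)
  qc <- qc_sample(day$value_wm2, day$component, day$I_E)
  daytime <- day$I_E > 0 & day$value_wm2 > 0
  expect_true(all(qc$accepted[daytime]))
  # at clearness 1 and unit transmittance the series rides the envelope
  expect_equal(day$value_wm2[daytime], day$I_E[daytime])
})

test_that("irradiance is non-negative and DHI never exceeds GHI at a site", {
  for (s in 1:5) {
    ghi <- simulate_irradiance_day("sunny", 340, cfg, seed = s, component = "GHI")
    dhi <- simulate_irradiance_day("sunny", 340, cfg, seed = s, component = "DHI")
    expect_true(all(ghi$value_wm2 >= 0))
    expect_true(all(dhi$value_wm2 <= ghi$value_wm2 + 1e-9))
  }
})

test_that("default sunny month lands inside the observed irradiation envelope", {
  s <- simulate_irradiance_season("sunny", cfg, seed = 2)
  s <- s[s$month == 1, ]
  qc <- qc_integrate(s, latitude = cfg$latitude)
  expect_equal(nrow(qc$daily), 30)
  m <- mean(qc$daily$energy_mj_m2)
  expect_gt(m, 15)
  expect_lt(m, 25)
})

test_that("shaded daily totals fall in the measured 2-8 MJ/m2 band", {
  s <- simulate_irradiance_season("shaded", cfg, seed = 8)
  qc <- qc_integrate(s, latitude = cfg$latitude)
  monthly <- tapply(qc$daily$energy_mj_m2,
                    (as.integer(sub(".*_day", "", qc$daily$date)) - 1) %/% 30,
                    mean)
  expect_true(all(monthly > 2 & monthly < 8))
})

test_that("internal chamber temperature is a damped copy of the external", {
  mj <- runif(60, 5, 30)
  for (env in c("sunny", "shaded")) {
    t <- simulate_temperatures(env, mj, cfg, seed = 12)
    expect_lt(sd(t$internal), sd(t$external))
  }
  # no attenuation, no offset, no noise: internal == external, d == 1
  passthrough <- cfg
  passthrough$temperature$sunny <- list(ext_base = 23, coupling = 0.5,
                                        ext_noise_sd = 1, int_base = 23,
                                        damping = 1, lag = 0, int_noise_sd = 0)
  t <- simulate_temperatures("sunny", mj, passthrough, seed = 13)
  expect_equal(t$internal, t$external)
  expect_identical(willmott_index(t$internal, t$external), 1)
  expect_error(simulate_temperatures("sunny", numeric(0), cfg), "empty")
})

test_that("shaded chambers track outside temperature more closely than sunny", {
  wins <- 0
  for (s in 1:10) {
    set.seed(s)
    ndays <- 120
    clearness <- rbeta(ndays, cfg$cloud_beta[1], cfg$cloud_beta[2])
    mj_sun <- 40 * cfg$atm_transmittance * clearness
    mj_sha <- mj_sun * cfg$shade_transmittance
    ts <- simulate_temperatures("sunny", mj_sun, cfg, seed = NULL)
    th <- simulate_temperatures("shaded", mj_sha, cfg, seed = NULL)
    d_sun <- willmott_index(ts$internal, ts$external)
    d_sha <- willmott_index(th$internal, th$external)
    wins <- wins + (d_sha > d_sun)
  }
  expect_gte(wins, 9)
})

test_that("colony generator honours its survival and excavation scheme", {
  immortal <- synthetic_config(mortality_p = c(sunny = 0, shaded = 0))
  sim <- simulate_colonies(immortal, seed = 6)
  expect_true(all(sim$nests$queen_alive))
  expect_equal(sim$mortality$deaths, c(0, 0))
  expect_equal(nrow(sim$census), 200) # every nest censused
  # 25% of nests excavated per month, per environment
  expect_true(all(table(sim$nests$environment, sim$nests$month) == 25))
  expect_error(synthetic_config(mortality_p = c(sunny = 2, shaded = 0.5)),
               "probabilities")
})

test_that("mortality probabilities are recoverable from simulated colonies", {
  est <- sapply(1:30, function(s) {
    m <- simulate_colonies(cfg, seed = s)$mortality
    m$deaths[match(c("sunny", "shaded"), m$environment)] / 100
  })
  expect_equal(mean(est[1, ]), 0.91, tolerance = 0.03)
  expect_equal(mean(est[2, ]), 0.58, tolerance = 0.04)
})

test_that("the built-in shaded/sunny geometry contrast is recovered", {
  deeper <- sapply(1:20, function(s) {
    n <- simulate_colonies(cfg, seed = 1000 + s)$nests
    mean(n$depth_cm[n$environment == "shaded"]) >
      mean(n$depth_cm[n$environment == "sunny"])
  })
  expect_gte(mean(deeper), 0.95)
})

test_that("census trajectories follow their configured anchors", {
  sim <- simulate_colonies(synthetic_config(nests_per_env = 400,
                                            mortality_p = c(sunny = 0.3, shaded = 0.3)),
                           seed = 17)
  cen <- sim$census[sim$census$environment == "shaded", ]
  qm <- tapply(cen$queen_mass_mg, cen$month, mean)
  expect_equal(unname(qm[1]), 658.5, tolerance = 0.05)
  expect_equal(unname(qm[4]), 229.45, tolerance = 0.15)
  fb <- tapply(cen$fungus_biomass_mg, cen$month, median)
  expect_gt(fb[4] / fb[1], 10) # fungus garden grows by an order of magnitude
  eggs <- tapply(cen$eggs, cen$month, mean)
  expect_lt(eggs[1], eggs[3]) # fewer eggs in month 1 than month 3
  expect_true(all(sim$census$eggs >= 0) && all(sim$census$queen_mass_mg >= 0))
})
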