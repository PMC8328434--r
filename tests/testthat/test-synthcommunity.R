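test_that("nitrogen is conserved: total N follows the washout relaxation", {
  sim <- cached_default_sim()
  tn <- nitrogen_total(sim)
  cfg <- sim$config
  analytic <- cfg$n_inflow + (tn[1] - cfg$n_inflow) * exp(-cfg$dilution * sim$times)
  expect_lt(max(abs(tn - analytic) / analytic), 1e-6)
})

test_that("simulated pools stay non-negative and finite", {
  sim <- cached_default_sim()
  expect_true(all(is.finite(sim$states)))
  expect_true(all(sim$states >= 0))
})

test_that("identical config and seed give byte-identical output", {
  cfg <- sim_config(seed = 33, duration = 10)
  s1 <- simulate_chemostat(cfg)
  s2 <- simulate_chemostat(cfg)
  expect_identical(s1$states, s2$states)
  o1 <- observe(s1)
  o2 <- observe(s2)
  expect_identical(o1, o2)
})

test_that("grazer-free one-alga chemostat reaches the analytic steady state", {
  cfg <- sim_config(consumers = list(),
                    algae = list(Nav = list(mu_max = 1.1, k_n = 0.8,
                                            initial = 1e5)),
                    exudation_f = 0, duration = 300, seed = 1)
  sim <- simulate_chemostat(cfg)
  fin <- sim$states[nrow(sim$states), ]
  n_star <- cfg$dilution * 0.8 / (1.1 - cfg$dilution) # R* residual
  a_star <- (cfg$n_inflow - n_star) / cfg$quotas[["Nav"]]
  expect_equal(fin[["N"]], n_star, tolerance = 1e-3)
  expect_equal(fin[["Nav"]], a_star, tolerance = 1e-3)
})

test_that("all biota wash out when maximum growth is below dilution", {
  # washout is exponential at ~(delta - mu): from 1e5 pg C/ml it takes
  # several washout time scales to cross the detection limits
  traits <- default_traits()
  cfg <- sim_config(
    seed = 2, duration = 150,
    algae = list(Cry = list(mu_max = 0.02, k_n = 2, initial = 1e5),
                 Nav = list(mu_max = 0.03, k_n = 0.8, initial = 1e5)),
    bacteria = list(u_max = 0.15, k_doc = 5e4, k_n = 0.2, efficiency = 0.5,
                    initial = 1e4),
    consumers = list(
      Eup = list(imax = c(Cry = 0.02, Bacteria = 0.02),
                 half_saturation = 2e5,
                 assimilation = c(Cry = 0.5, Bacteria = 0.25),
                 lag_days = 0, initial = 1e5)),
    traits = traits
  )
  sim <- simulate_chemostat(cfg)
  fin <- sim$states[nrow(sim$states), ]
  profs <- taxon_profiles(traits)
  for (tx in c("Cry", "Eup")) {
    limit_carbon <- abundance_to_carbon(profs[[tx]]$detection_limit_abundance,
                                        profs[[tx]])
    expect_lt(fin[[tx]], limit_carbon)
  }
  # every biotic pool declined over the run
  start <- sim$states[1, ]
  for (tx in c("Cry", "Nav", "Bacteria", "Eup")) {
    expect_lt(fin[[tx]], start[[tx]])
  }
})

test_that("default dynamics reproduce the study's qualitative pattern", {
  sim <- cached_default_sim()
  fin <- sim$states[nrow(sim$states), ]
  start <- sim$states[1, ]
  profs <- taxon_profiles(sim$config$traits)
  # Cry grazed toward its detection limit, Nav escapes and plateaus high
  cry_limit <- abundance_to_carbon(profs$Cry$detection_limit_abundance, profs$Cry)
  expect_lt(fin[["Cry"]], cry_limit)
  expect_gt(fin[["Nav"]], start[["Nav"]])
  late <- sim$states[sim$times >= 25, "Nav"]
  expect_lt(diff(range(late)) / mean(late), 0.15) # plateau
  # nitrogen severely depleted
  expect_lt(fin[["N"]], 1.7)
})

test_that("noise-free observation equals the latent state at sample times", {
  cfg <- sim_config(seed = 4, duration = 10, observation_noise_cv = 0,
                    n_replicates = 1)
  sim <- simulate_chemostat(cfg)
  obs <- observe(sim)
  profs <- taxon_profiles(cfg$traits)
  nav <- dplyr::filter(obs, taxon == "Nav")
  idx <- vapply(nav$day, function(d) which.min(abs(sim$times - d)), integer(1))
  expect_equal(nav$biomass_pgC_per_ml, unname(sim$states[idx, "Nav"]),
               tolerance = 1e-12)
})

test_that("observation noise has the configured coefficient of variation", {
  cfg <- sim_config(seed = 12, duration = 33, observation_noise_cv = 0.1,
                    n_replicates = 4)
  sim <- simulate_chemostat(cfg)
  obs <- observe(sim)
  disp <- obs |>
    dplyr::filter(!censored, taxon == "Nav") |>
    dplyr::group_by(day) |>
    dplyr::summarise(cv = sd(biomass_pgC_per_ml) / mean(biomass_pgC_per_ml),
                     .groups = "drop")
  # replicate CV scatters around the configured 10% over many sampling days
  expect_equal(mean(disp$cv), 0.1, tolerance = 0.35)
})

test_that("below-detection observations are substituted and flagged", {
  cfg <- sim_config(seed = 6)
  sim <- simulate_chemostat(cfg)
  obs <- observe(sim)
  cry_cens <- dplyr::filter(obs, taxon == "Cry", censored)
  expect_gt(nrow(cry_cens), 0) # Cry is driven below its limit
  expect_true(all(cry_cens$abundance_per_ml == 3.3 / 2))
  eup_cens <- dplyr::filter(obs, taxon == "Eup", censored)
  if (nrow(eup_cens) > 0) {
    expect_true(all(eup_cens$abundance_per_ml == 0.25))
  }
})

test_that("net growth rate over the exponential phase recovers the configured rate", {
  # nutrient-saturated single alga, no grazers: r = mu_max - delta exactly
  cfg <- sim_config(consumers = list(),
                    algae = list(Nav = list(mu_max = 0.244, k_n = 1e-4,
                                            initial = 100)),
                    exudation_f = 0, duration = 6, observation_noise_cv = 0,
                    n_replicates = 1, seed = 8)
  sim <- simulate_chemostat(cfg)
  obs <- observe(sim)
  r <- growth_rates(dplyr::filter(obs, taxon == "Nav"), window = c(0, 5))
  expect_equal(r$r_per_day, 0.244 - 0.1, tolerance = 1e-3)
})

test_that("noisy replicate-mean growth rate is within 2 SE of the truth", {
  cfg <- sim_config(consumers = list(),
                    algae = list(Nav = list(mu_max = 0.244, k_n = 1e-4,
                                            initial = 100)),
                    exudation_f = 0, duration = 6, observation_noise_cv = 0.1,
                    n_replicates = 4, seed = 42)
  sim <- simulate_chemostat(cfg)
  # two-point rate over dt = 4 d, lognormal noise at both endpoints, 4 reps;
  # "within 2 SE" holds for ~95% of experiments, checked as coverage
  sdlog <- sqrt(log(1 + 0.1^2))
  se <- sqrt(2) * sdlog / (4 * sqrt(4))
  within_2se <- vapply(1:30, function(s) {
    obs <- dplyr::filter(observe(sim, seed = s), taxon == "Nav")
    r <- growth_rates(obs, window = c(0, 5))
    abs(mean(r$r_per_day) - 0.144) < 2 * se
  }, logical(1))
  expect_gte(mean(within_2se), 0.8)
})

test_that("bottle generator round-trips the imposed coefficients", {
  b <- generate_bottle_experiment(imax = 17.6, half_saturation = 500,
                                  prey0 = c(200, 1000, 5000),
                                  grazer_density = 10, k = 0.2)
  r <- grazing_rates(b)
  expect_equal(r$g, b$true_g, tolerance = 1e-9)
  expect_equal(r$k, rep(0.2, 3), tolerance = 1e-12)
  # estimated ingestion equals the functional response at the mean density
  expect_equal(r$ingestion_cells_per_day,
               17.6 * r$mean_prey_per_ml / (500 + r$mean_prey_per_ml),
               tolerance = 1e-9)
  # zero imax: grazed bottle identical to control
  b0 <- generate_bottle_experiment(imax = 0, half_saturation = 500,
                                   prey0 = 1000, grazer_density = 10, k = 0.1)
  expect_equal(b0$prey_grazed_end, b0$prey_control_end)
})
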