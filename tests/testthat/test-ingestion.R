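test_that("control and grazed bottle coefficients follow the exponential model", {
  expect_equal(prey_growth_coefficient(100, 100, 1), 0)
  expect_equal(prey_growth_coefficient(100, 200, 1), log(2))
  expect_equal(grazing_coefficient(0, 100, 100, 1), 0)
  expect_equal(grazing_coefficient(0, 100, 50, 1), log(2))
  # round-trip through the generator at known k and g
  b <- generate_bottle_experiment(imax = 20, half_saturation = 500,
                                  prey0 = 1000, grazer_density = 10,
                                  k = 0.3, g = 0.25)
  r <- grazing_rates(b)
  expect_equal(r$k, 0.3, tolerance = 1e-12)
  expect_equal(r$g, 0.25, tolerance = 1e-9)
  expect_error(prey_growth_coefficient(0, 10, 1), class = "chemocomp_domain_error")
})

test_that("time-averaged prey density matches a numeric integration oracle", {
  # closed form vs trapezoid integral of the exponential trajectory
  expect_equal(mean_prey_density(100, log(2), 0, 1), 100 / log(2),
               tolerance = 1e-12)
  for (net in c(-0.8, -0.1, 0.4, 1.2)) {
    expect_equal(mean_prey_density(250, net, 0, 2),
                 numeric_time_integral(250, net, 2) / 2,
                 tolerance = 1e-7)
  }
  # k = g limit
  expect_equal(mean_prey_density(123, 0.4, 0.4, 1), 123)
  # bounded by the endpoint densities
  for (net in c(-1, -0.01, 0.02, 2)) {
    m <- mean_prey_density(100, net, 0, 1)
    ends <- c(100, 100 * exp(net))
    expect_gte(m, min(ends))
    expect_lte(m, max(ends))
  }
})

test_that("time-averaged grazer density is the logarithmic mean", {
  expect_equal(mean_grazer_density(7, 7), 7)
  expect_equal(mean_grazer_density(100, 200), 100 / log(2), tolerance = 1e-12)
  # lies between geometric and arithmetic means
  set.seed(5)
  for (i in 1:25) {
    x <- runif(2, 1, 1000)
    lm_ <- mean_grazer_density(x[1], x[2])
    expect_gte(lm_, sqrt(prod(x)) - 1e-12)
    expect_lte(lm_, mean(x) + 1e-12)
  }
  expect_error(mean_grazer_density(0, 5), class = "chemocomp_domain_error")
})

test_that("clearance and ingestion follow the Frost-Heinbokel estimators", {
  # constant grazers at 10/ml, g = 0.2: clearance g/N, ingestion x mean prey
  b <- generate_bottle_experiment(imax = 1, half_saturation = 1,
                                  prey0 = 1000, grazer_density = 10,
                                  k = 0.2, g = 0.2) # k = g keeps prey constant
  r <- grazing_rates(b)
  expect_equal(r$clearance_ml_per_day, 0.2 / 10)
  expect_equal(r$ingestion_cells_per_day, 0.02 * 1000)
  # zero grazing gives zero rates
  b0 <- generate_bottle_experiment(imax = 0, half_saturation = 500,
                                   prey0 = 1000, grazer_density = 10)
  r0 <- grazing_rates(b0)
  expect_equal(r0$g, 0)
  expect_equal(r0$ingestion_cells_per_day, 0)
  # negative grazing flagged with a warning, not clamped
  bneg <- bottle_experiment(100, 100, 100, 120, 10, 10, 1)
  expect_warning(rneg <- grazing_rates(bneg), "negative")
  expect_lt(rneg$g, 0)
  expect_true(rneg$negative_grazing)
})

test_that("saturating-prey bottles recover the configured I_max within 2%", {
  b <- generate_bottle_experiment(imax = 17.6, half_saturation = 500,
                                  prey0 = 5e4, grazer_density = 10)
  r <- grazing_rates(b)
  expect_equal(r$ingestion_cells_per_day, 17.6, tolerance = 0.02)
})

test_that("functional-response fit recovers noiseless parameters", {
  dens <- c(50, 100, 250, 500, 1000, 2500, 5000, 10000)
  pts <- tibble::tibble(prey_per_ml = dens,
                        ingestion_cells_per_day = 116 * dens / (500 + dens))
  fit <- fit_functional_response(pts)
  expect_true(fit$converged)
  expect_equal(fit$imax, 116, tolerance = 1e-6)
  expect_equal(fit$half_saturation_k, 500, tolerance = 1e-6)
  # predictions are non-decreasing in prey density
  expect_true(all(diff(predict(fit, tibble::tibble(prey_per_ml = sort(dens)))) >= 0))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "imax"], 116, tolerance = 1e-6)
  expect_true(glance(fit)$imax_above_half_max)
})

test_that("degenerate functional-response inputs are handled", {
  zero <- tibble::tibble(prey_per_ml = c(100, 200, 400),
                         ingestion_cells_per_day = 0)
  fit0 <- fit_functional_response(zero)
  expect_equal(fit0$imax, 0)
  expect_true(fit0$converged)
  expect_error(
    fit_functional_response(tibble::tibble(prey_per_ml = c(1, 2),
                                           ingestion_cells_per_day = c(1, 2))),
    class = "chemocomp_fit_error")
  expect_error(
    fit_functional_response(tibble::tibble(prey_per_ml = rep(100, 5),
                                           ingestion_cells_per_day = 1:5)),
    class = "chemocomp_fit_error")
})

test_that("I_max estimation stays within 10% median error at 5% noise", {
  # bottles spanning sub- to near-saturating densities; the Frost-Heinbokel
  # chain yields the functional response at the mean densities, observed
  # with 5% lognormal error
  dens <- c(100, 250, 500, 1000, 2000, 4000, 8000, 16000)
  b <- generate_bottle_experiment(imax = 116, half_saturation = 500,
                                  prey0 = dens, grazer_density = 10)
  r <- grazing_rates(b)
  sdlog <- sqrt(log(1 + 0.05^2))
  set.seed(101)
  rel_err <- replicate(200, {
    pts <- tibble::tibble(
      prey_per_ml = r$mean_prey_per_ml,
      ingestion_cells_per_day = r$ingestion_cells_per_day *
        stats::rlnorm(length(dens), -sdlog^2 / 2, sdlog))
    fit <- fit_functional_response(pts)
    abs(fit$imax - 116) / 116
  })
  expect_lt(median(rel_err), 0.10)
})

test_that("count-level bottle noise is reproducible and propagates", {
  b1 <- generate_bottle_experiment(imax = 116, half_saturation = 500,
                                   prey0 = c(500, 2000), grazer_density = 10,
                                   noise_cv = 0.05, seed = 7)
  b2 <- generate_bottle_experiment(imax = 116, half_saturation = 500,
                                   prey0 = c(500, 2000), grazer_density = 10,
                                   noise_cv = 0.05, seed = 7)
  expect_identical(b1, b2)
  expect_false(all(b1$prey_control_end ==
                     b1$prey_control_start * exp(b1$true_k)))
})
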