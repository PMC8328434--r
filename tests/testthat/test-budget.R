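state0 <- community_state(algal_biomass_BN = 1e6, bacterial_biomass_B = 1e5,
                          euplotes_biomass_BE = 1000)
par0 <- budget_params()

test_that("required NPP compensates dilution on the algal stock", {
  expect_equal(required_npp(state0, par0), 1e5)
  expect_equal(required_npp(community_state(0, 1, 1), par0), 0)
  nodil <- budget_params(dilution_delta = 0)
  expect_equal(required_npp(state0, nodil), 0)
})

test_that("exudation follows f/(1-f) of NPP and is convex in f", {
  expect_equal(exudation(100, 0), 0)
  expect_equal(exudation(100, 0.5), 100)
  expect_equal(exudation(700, 0.3), 300) # (3/7) * 700
  f <- seq(0.05, 0.9, by = 0.05)
  e <- exudation(1, f)
  expect_true(all(diff(e) > 0))
  expect_true(all(diff(diff(e)) > 0))
  expect_error(exudation(10, 1), class = "chemocomp_domain_error")
})

test_that("closed-form production equals the geometric recursion to 1e-12", {
  # parameter sweep over admissible efficiencies and fluxes
  grid <- expand.grid(eb = c(0.2, 0.5, 0.9), ec = c(0.1, 0.5, 1),
                      ea = c(0, 5e3, 5e4, 5e5))
  for (i in seq_len(nrow(grid))) {
    p <- budget_params(bacterial_growth_efficiency_eB = grid$eb[i],
                       ciliate_assimilation_efficiency_eC = grid$ec[i])
    closed <- as.numeric(bacterial_production(grid$ea[i], state0, p))
    iter <- bacterial_production_iterative(grid$ea[i], state0, p, n_iter = 300)
    expect_equal(iter, closed, tolerance = 1e-12)
  }
})

test_that("production algebra matches the stated special cases", {
  D <- par0$dilution_delta * state0$bacterial_biomass_B
  # E_A = D: production exactly zero
  expect_equal(as.numeric(bacterial_production(D, state0, par0)), 0)
  # eB = eC = 0.5: P_B = (2/3) (E_A - D)
  expect_equal(as.numeric(bacterial_production(D + 3, state0, par0)), 2)
  for (ea in c(D + 1, D + 1e4)) {
    expect_equal(as.numeric(bacterial_production(ea, state0, par0)),
                 (2 / 3) * (ea - D))
  }
  # eC = 1: no recycling, P_B = eB (E_A - D)
  p1 <- budget_params(ciliate_assimilation_efficiency_eC = 1)
  expect_equal(as.numeric(bacterial_production(D + 10, state0, p1)), 5)
  # infeasible (E_A < D) is flagged, not clamped
  pb_neg <- bacterial_production(0, state0, par0)
  expect_lt(as.numeric(pb_neg), 0)
  expect_true(attr(pb_neg, "infeasible"))
  # divergent efficiency combination rejected at construction
  expect_error(budget_params(bacterial_growth_efficiency_eB = 1,
                             ciliate_assimilation_efficiency_eC = 0),
               class = "chemocomp_divergence_error")
})

test_that("recursion corrections form a geometric series", {
  p <- budget_params(bacterial_growth_efficiency_eB = 0.5,
                     ciliate_assimilation_efficiency_eC = 0.5)
  ea <- 5e4
  terms <- vapply(0:5, function(n)
    bacterial_production_iterative(ea, state0, p, n_iter = n), numeric(1))
  corr <- diff(terms)
  expect_equal(corr[-1] / corr[-length(corr)], rep(0.25, 4), tolerance = 1e-12)
  base <- 0.5 * (ea - 0.1 * 1e5)
  expect_equal(terms[2], base * (1 + 0.25)) # one recycling cycle
})

test_that("P/B ratio and the growth-rate diagnostic behave linearly", {
  expect_equal(pb_ratio(0, state0), 0)
  expect_equal(pb_ratio(2.6 * state0$bacterial_biomass_B, state0), 2.6)
  expect_equal(pb_ratio(7, state0) / pb_ratio(3.5, state0), 2)
  expect_error(pb_ratio(1, community_state(1, 0, 1)),
               class = "chemocomp_domain_error")
  expect_equal(implied_growth_rate(exp(1) - 1), 1)
})

test_that("consumer demand uses the stated efficiency and growth constants", {
  st <- community_state(1e6, 1e5, 1000)
  expect_equal(consumer_demand(st, par0, "max_ingestion"), 1600) # 0.4/0.25
  expect_equal(consumer_demand(st, par0, "dilution_loss"), 100)
  expect_equal(consumer_demand(st, par0, "dilution_compensation"), 400)
  zero <- community_state(1e6, 1e5, 0)
  for (k in c("max_ingestion", "dilution_loss", "dilution_compensation")) {
    expect_equal(consumer_demand(zero, par0, k), 0)
  }
})

test_that("critical exudation inverts the production curve", {
  D <- par0$dilution_delta * state0$bacterial_biomass_B
  npp <- required_npp(state0, par0)
  # target 0 with washout: f* = D / (NPP + D)
  expect_equal(critical_exudation(0, state0, par0), D / (npp + D))
  nodil_state <- community_state(1e6, 0, 1000)
  expect_equal(critical_exudation(0, nodil_state, par0), 0)
  # round trip through bacterial_production to 1e-10, vs a bisection oracle
  set.seed(21)
  for (i in 1:20) {
    st <- community_state(runif(1, 1e5, 1e7), runif(1, 1e3, 1e6),
                          runif(1, 0, 1e5))
    p <- budget_params(bacterial_growth_efficiency_eB = runif(1, 0.2, 0.9),
                       ciliate_assimilation_efficiency_eC = runif(1, 0.1, 1))
    target <- runif(1, 0, 1e5)
    fstar <- critical_exudation(target, st, p)
    round_trip <- bacterial_production(exudation(required_npp(st, p), fstar),
                                       st, p)
    expect_equal(as.numeric(round_trip), target, tolerance = 1e-10)
    oracle <- bisect_critical_f(target, required_npp(st, p),
                                p$dilution_delta * st$bacterial_biomass_B,
                                p$bacterial_growth_efficiency_eB,
                                p$ciliate_assimilation_efficiency_eC)
    expect_equal(fstar, oracle, tolerance = 1e-8)
  }
})

test_that("budget sweep tabulates fluxes and finds crossing fractions", {
  sw <- budget_sweep(state0, par0, f = seq(0.01, 0.6, by = 0.01))
  expect_s3_class(sw, "budget_sweep")
  expect_true(all(diff(sw$PB) > 0))
  g <- glance(sw)
  # crossing fraction agrees with the closed-form inverse
  expect_equal(g$f_crit_dilution_loss,
               critical_exudation(consumer_demand(state0, par0, "dilution_loss"),
                                  state0, par0),
               tolerance = 1e-3)
})
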