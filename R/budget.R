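# Microbial-loop carbon budget at chemostat equilibrium: algal exudation
# feeds bacteria, ciliates graze bacteria and excrete part of the intake,
# which is recycled back into bacterial production. The equilibrium bacterial
# production solves
#   P_B = e_B * (E_A + (1 - e_C) * P_B - D),    D = delta * B
# giving the closed form P_B = e_B (E_A - D) / (1 - e_B (1 - e_C)),
# equivalently the limit of the geometric production/consumption/excretion
# recursion.

#' Budget model parameters
#'
#' @param exudation_f Fraction `f` of gross primary production released as
#'   exudates, in `[0, 1)`. Exudates relate to net primary production by
#'   `E_A = f / (1 - f) * NPP`.
#' @param bacterial_growth_efficiency_eB Fraction of consumed carbon bacteria
#'   invest into production; default 0.5.
#' @param ciliate_assimilation_efficiency_eC Fraction of ingested bacterial
#'   carbon assimilated by ciliates (the rest is excreted and recycled);
#'   default 0.5.
#' @param dilution_delta Chemostat dilution rate, d^-1; default 0.1.
#' @param consumer_growth_efficiency Consumer (ciliate) gross growth
#'   efficiency; default 0.25.
#' @param consumer_max_growth Consumer maximum growth rate, d^-1; default 0.4.
#' @return A `budget_params` object. The recursion converges only when
#'   `eB * (1 - eC) < 1`, which is enforced.
#' @export
budget_params <- function(exudation_f = 0.3,
                          bacterial_growth_efficiency_eB = 0.5,
                          ciliate_assimilation_efficiency_eC = 0.5,
                          dilution_delta = 0.1,
                          consumer_growth_efficiency = 0.25,
                          consumer_max_growth = 0.4) {
  check_fraction(exudation_f, "exudation_f", allow_one = FALSE)
  check_fraction(bacterial_growth_efficiency_eB, "bacterial_growth_efficiency_eB")
  check_positive(bacterial_growth_efficiency_eB, "bacterial_growth_efficiency_eB")
  check_fraction(ciliate_assimilation_efficiency_eC, "ciliate_assimilation_efficiency_eC")
  check_non_negative(dilution_delta, "dilution_delta")
  check_positive(consumer_growth_efficiency, "consumer_growth_efficiency")
  check_non_negative(consumer_max_growth, "consumer_max_growth")
  eb <- bacterial_growth_efficiency_eB
  ec <- ciliate_assimilation_efficiency_eC
  if (eb * (1 - ec) >= 1) {
    abort("Recycling loop diverges: need eB * (1 - eC) < 1.",
          class = "chemocomp_divergence_error")
  }
  structure(list(exudation_f = exudation_f,
                 bacterial_growth_efficiency_eB = eb,
                 ciliate_assimilation_efficiency_eC = ec,
                 dilution_delta = dilution_delta,
                 consumer_growth_efficiency = consumer_growth_efficiency,
                 consumer_max_growth = consumer_max_growth),
            class = "budget_params")
}

#' Community standing stocks entering the budget
#'
#' @param algal_biomass_BN Biomass of the dominant alga, pg C per ml; >= 0.
#' @param bacterial_biomass_B Bacterial biomass, pg C per ml; >= 0.
#' @param euplotes_biomass_BE Consumer (bacterivorous ciliate) biomass,
#'   pg C per ml; >= 0.
#' @return A `community_state` object.
#' @export
community_state <- function(algal_biomass_BN, bacterial_biomass_B,
                            euplotes_biomass_BE) {
  check_non_negative(algal_biomass_BN, "algal_biomass_BN")
  check_non_negative(bacterial_biomass_B, "bacterial_biomass_B")
  check_non_negative(euplotes_biomass_BE, "euplotes_biomass_BE")
  structure(list(algal_biomass_BN = algal_biomass_BN,
                 bacterial_biomass_B = bacterial_biomass_B,
                 euplotes_biomass_BE = euplotes_biomass_BE),
            class = "community_state")
}

#' Net primary production required at equilibrium
#'
#' At stationary phase the dominant alga's NPP only has to compensate washout:
#' `delta * B_N` (10% of its biomass per day at the default dilution).
#'
#' @param state A [community_state()].
#' @param params A [budget_params()].
#' @return Required NPP, pg C per ml per day.
#' @export
required_npp <- function(state, params) {
  stopifnot(inherits(state, "community_state"), inherits(params, "budget_params"))
  params$dilution_delta * state$algal_biomass_BN
}

#' Algal exudation from net primary production
#'
#' With a fraction `f` of gross primary production exuded, NPP is `(1 - f)`
#' of GPP, hence `E_A = f / (1 - f) * NPP`; strictly increasing and convex in
#' `f`.
#'
#' @param npp Net primary production, pg C per ml per day; >= 0.
#' @param f Exuded fraction of GPP, in `[0, 1)`.
#' @return Exudation flux `E_A`, pg C per ml per day.
#' @export
exudation <- function(npp, f) {
  check_non_negative(npp, "npp")
  check_fraction(f, "f", allow_one = FALSE)
  f / (1 - f) * npp
}

#' Equilibrium bacterial production (closed form)
#'
#' `P_B = e_B * (E_A - D) / (1 - e_B * (1 - e_C))` with bacterial washout
#' `D = delta * B`. May be negative when exudation cannot cover washout
#' (`E_A < D`); the value is returned as-is with attribute `infeasible = TRUE`
#' rather than clamped, which preserves invertibility and makes the
#' infeasibility visible.
#'
#' @param EA Exudation flux, pg C per ml per day.
#' @param state A [community_state()] supplying the bacterial biomass.
#' @param params A [budget_params()].
#' @return Bacterial production, pg C per ml per day.
#' @export
bacterial_production <- function(EA, state, params) {
  stopifnot(inherits(state, "community_state"), inherits(params, "budget_params"))
  check_non_negative(EA, "EA")
  eb <- params$bacterial_growth_efficiency_eB
  ec <- params$ciliate_assimilation_efficiency_eC
  D <- params$dilution_delta * state$bacterial_biomass_B
  pb <- eb * (EA - D) / (1 - eb * (1 - ec))
  if (any(pb < 0)) attr(pb, "infeasible") <- TRUE
  pb
}

#' Equilibrium bacterial production (geometric recursion)
#'
#' Iterates the production/consumption/excretion cycle
#' `P^(n+1) = e_B * (E_A - D) + e_B * (1 - e_C) * P^(n)` from
#' `P^(0) = e_B * (E_A - D)`; the partial sums form a geometric series with
#' ratio `e_B * (1 - e_C)` converging to the closed form of
#' [bacterial_production()]. Kept as an independent oracle for the algebra.
#'
#' @inheritParams bacterial_production
#' @param n_iter Number of recursion steps; >= 0.
#' @return Bacterial production after `n_iter` recycling cycles.
#' @export
bacterial_production_iterative <- function(EA, state, params, n_iter = 200) {
  stopifnot(inherits(state, "community_state"), inherits(params, "budget_params"))
  check_non_negative(EA, "EA")
  check_non_negative(n_iter, "n_iter")
  eb <- params$bacterial_growth_efficiency_eB
  ec <- params$ciliate_assimilation_efficiency_eC
  D <- params$dilution_delta * state$bacterial_biomass_B
  base <- eb * (EA - D)
  p <- base
  if (n_iter > 0) {
    for (i in seq_len(n_iter)) p <- base + eb * (1 - ec) * p
  }
  p
}

#' Bacterial production-to-biomass ratio
#'
#' `P/B = P_B / B`, a turnover rate per day.
#'
#' @param PB Bacterial production, pg C per ml per day.
#' @param state A [community_state()] with `bacterial_biomass_B > 0`.
#' @return P/B, d^-1.
#' @export
pb_ratio <- function(PB, state) {
  stopifnot(inherits(state, "community_state"))
  check_positive(state$bacterial_biomass_B, "bacterial_biomass_B")
  as.numeric(PB) / state$bacterial_biomass_B
}

#' Implied bacterial growth-rate diagnostic
#'
#' `log(1 + P/B)`: the exponential rate that would produce P/B in one day.
#' Purely diagnostic; nothing downstream depends on it.
#'
#' @param pb P/B ratio, d^-1.
#' @return Implied growth rate, d^-1.
#' @export
implied_growth_rate <- function(pb) log(1 + pb)

#' Consumer carbon demand
#'
#' Carbon fluxes to compare bacterial production against:
#' * `"max_ingestion"` — the intake needed to sustain the consumer's maximum
#'   growth rate at its gross growth efficiency,
#'   `(mu_max / GE) * B_E` (1.6 x biomass per day at the defaults 0.4 / 0.25);
#' * `"dilution_loss"` — the consumer biomass washed out per day,
#'   `delta * B_E`;
#' * `"dilution_compensation"` — the intake needed to just offset washout,
#'   `(delta / GE) * B_E`.
#'
#' @param state A [community_state()].
#' @param params A [budget_params()].
#' @param kind One of `"max_ingestion"`, `"dilution_loss"`,
#'   `"dilution_compensation"`.
#' @return Demand, pg C per ml per day.
#' @export
consumer_demand <- function(state, params,
                            kind = c("max_ingestion", "dilution_loss",
                                     "dilution_compensation")) {
  stopifnot(inherits(state, "community_state"), inherits(params, "budget_params"))
  kind <- match.arg(kind)
  be <- state$euplotes_biomass_BE
  switch(kind,
         max_ingestion = params$consumer_max_growth /
           params$consumer_growth_efficiency * be,
         dilution_loss = params$dilution_delta * be,
         dilution_compensation = params$dilution_delta /
           params$consumer_growth_efficiency * be)
}

#' Critical exudation fraction for a target bacterial production
#'
#' Inverts the budget in closed form: the exudation flux that yields the
#' target production is `E_A* = D + target * (1 - e_B (1 - e_C)) / e_B`, and
#' since `E_A = f / (1 - f) * NPP` with NPP fixed by [required_npp()],
#' `f* = E_A* / (NPP + E_A*)`. The round trip
#' `bacterial_production(exudation(required_npp, f*))` recovers the target
#' exactly (monotone, hence unique inverse).
#'
#' @param target_flux Target bacterial production, pg C per ml per day; >= 0.
#' @param state A [community_state()] with positive algal biomass (so that
#'   `required_npp > 0`).
#' @param params A [budget_params()].
#' @return The critical fraction `f*` in `[0, 1)`, or `NA` with a warning when
#'   no admissible fraction exists.
#' @export
critical_exudation <- function(target_flux, state, params) {
  stopifnot(inherits(state, "community_state"), inherits(params, "budget_params"))
  check_non_negative(target_flux, "target_flux")
  npp <- required_npp(state, params)
  check_positive(npp, "required_npp(state, params)")
  eb <- params$bacterial_growth_efficiency_eB
  ec <- params$ciliate_assimilation_efficiency_eC
  D <- params$dilution_delta * state$bacterial_biomass_B
  ea_star <- D + target_flux * (1 - eb * (1 - ec)) / eb
  f_star <- ea_star / (npp + ea_star)
  if (any(f_star >= 1)) {
    warn("No admissible exudation fraction (f* >= 1); returning NA.")
    f_star[f_star >= 1] <- NA_real_
  }
  f_star
}

#' Sweep the budget over a range of exudation fractions
#'
#' Evaluates the full carbon budget (exudation, bacterial production, P/B,
#' consumer demands) on a grid of exudation fractions, the tabular form of
#' production-versus-demand comparisons.
#'
#' @param state A [community_state()].
#' @param params A [budget_params()]; its `exudation_f` is ignored in favour
#'   of the grid.
#' @param f Numeric vector of exudation fractions in `[0, 1)`; default
#'   `seq(0.01, 0.5, by = 0.01)`.
#' @return A tibble of class `budget_sweep` with columns `f`, `npp`, `EA`,
#'   `PB`, `pb_ratio`, `demand_max_ingestion`, `demand_dilution_loss`.
#' @export
budget_sweep <- function(state, params = budget_params(),
                         f = seq(0.01, 0.5, by = 0.01)) {
  check_fraction(f, "f", allow_one = FALSE)
  npp <- required_npp(state, params)
  ea <- exudation(npp, f)
  pb <- as.numeric(bacterial_production(ea, state, params))
  out <- tibble(
    f = f, npp = npp, EA = ea, PB = pb,
    pb_ratio = pb / state$bacterial_biomass_B,
    demand_max_ingestion = consumer_demand(state, params, "max_ingestion"),
    demand_dilution_loss = consumer_demand(state, params, "dilution_loss")
  )
  class(out) <- c("budget_sweep", class(out))
  out
}

#' Glance at a budget sweep
#'
#' @param x A `budget_sweep`.
#' @param ... Unused.
#' @return One-row tibble with the critical exudation fractions at which
#'   bacterial production meets the consumer's maximum ingestion and its
#'   dilution loss, and the maximum P/B over the sweep.
#' @export
glance.budget_sweep <- function(x, ...) {
  tibble(
    f_min = min(x$f), f_max = max(x$f),
    max_pb_ratio = max(x$pb_ratio),
    f_crit_max_ingestion = approx_crossing(x$f, x$PB, x$demand_max_ingestion[1]),
    f_crit_dilution_loss = approx_crossing(x$f, x$PB, x$demand_dilution_loss[1])
  )
}

approx_crossing <- function(f, pb, target) {
  if (all(pb < target) || all(pb > target)) return(NA_real_)
  stats::approx(pb, f, xout = target, ties = "ordered")$y
}

#' @export
autoplot.budget_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, c("PB", "demand_max_ingestion", "demand_dilution_loss"),
    names_to = "flux", values_to = "pgC_per_ml_per_day")
  ggplot2::ggplot(long, ggplot2::aes(.data$f, .data$pgC_per_ml_per_day,
                                     colour = .data$flux)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Exudation fraction f of GPP",
                  y = "Carbon flux (pg C ml⁻¹ d⁻¹)", colour = NULL)
}
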