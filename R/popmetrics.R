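# Population statistics on censored, replicated biomass time series: net
# growth rates, time-averaged densities, population filtration rates, phase
# decline rates and the consumer log biomass ratio.

#' Detection policy for count censoring
#'
#' When no cells of a taxon are found in a counting subsample, the observation
#' is below the detection limit; the convention is to substitute half the
#' limit (e.g. a 2-ml ciliate subsample gives a limit of 0.5 cells/ml and a
#' substitute of 0.25 cells/ml) and flag the point as censored.
#'
#' @param detection_limit Cells per ml; > 0.
#' @param substitute Cells per ml substituted for below-detection points;
#'   default half the limit; must satisfy `0 < substitute <= detection_limit`.
#' @return A `detection_policy` object.
#' @export
detection_policy <- function(detection_limit, substitute = detection_limit / 2) {
  check_positive(detection_limit, "detection_limit")
  check_positive(substitute, "substitute")
  if (substitute > detection_limit) {
    abort("`substitute` must not exceed `detection_limit`.",
          class = "chemocomp_domain_error")
  }
  structure(list(detection_limit = detection_limit, substitute = substitute),
            class = "detection_policy")
}

#' Apply detection-limit censoring to a tidy series
#'
#' Observations with abundance below the taxon's detection limit (zero counts
#' included) are replaced by the policy's substitute value and flagged in the
#' `censored` column; observations at or above the limit pass through
#' unchanged. Censored points are never silently imputed: the flag travels
#' with the table.
#'
#' @param series Tidy series tibble with columns `taxon` and
#'   `abundance_per_ml` (and optionally `biomass_pgC_per_ml`, which is
#'   recomputed for censored rows when `traits` is supplied).
#' @param policy Either a single [detection_policy()] applied to every taxon,
#'   or a named list of policies keyed by taxon (taxa without a policy are
#'   left untouched).
#' @param traits Optional trait table used to refresh `biomass_pgC_per_ml`
#'   for substituted rows.
#' @return The series with `abundance_per_ml` substituted where censored and
#'   a logical `censored` column.
#' @export
apply_detection_policy <- function(series, policy, traits = NULL) {
  stopifnot(is.data.frame(series))
  limits <- subs <- rep(NA_real_, nrow(series))
  if (inherits(policy, "detection_policy")) {
    limits[] <- policy$detection_limit
    subs[] <- policy$substitute
  } else if (is.list(policy)) {
    for (tx in names(policy)) {
      i <- series$taxon == tx
      limits[i] <- policy[[tx]]$detection_limit
      subs[i] <- policy[[tx]]$substitute
    }
  } else {
    abort("`policy` must be a detection_policy or a named list of them.",
          class = "chemocomp_domain_error")
  }
  out <- series %>%
    mutate(
      censored = !is.na(limits) & .data$abundance_per_ml < limits,
      abundance_per_ml = ifelse(.data$censored, subs, .data$abundance_per_ml)
    )
  if (!is.null(traits) && "biomass_pgC_per_ml" %in% names(out)) {
    refreshed <- series_to_carbon(out, traits)
    out$biomass_pgC_per_ml <- ifelse(out$censored,
                                     refreshed$biomass_pgC_per_ml,
                                     out$biomass_pgC_per_ml)
  }
  out
}

#' Policies per taxon from a trait table
#'
#' @param traits Trait table with `taxon` and `detection_limit_per_ml`.
#' @return Named list of [detection_policy()] for taxa with a stated limit.
#' @export
detection_policies <- function(traits = default_traits()) {
  with_limit <- filter(traits, !is.na(.data$detection_limit_per_ml))
  stats::setNames(
    purrr::map(with_limit$detection_limit_per_ml, detection_policy),
    with_limit$taxon
  )
}

#' Net population growth rate between two time points
#'
#' `r = (log(B2) - log(B1)) / (t2 - t1)` in d^-1; antisymmetric under
#' exchanging the two observations.
#'
#' @param B1,B2 Biomass (or abundance) at `t1` and `t2`; > 0.
#' @param t1,t2 Days, `t2 > t1`.
#' @return Net growth rate per day. Vectorised.
#' @export
net_growth_rate <- function(B1, B2, t1, t2) {
  check_positive(B1, "B1")
  check_positive(B2, "B2")
  if (any(t2 <= t1)) abort("`t2` must exceed `t1`.", class = "chemocomp_domain_error")
  (log(B2) - log(B1)) / (t2 - t1)
}

#' Time-averaged density between two observations
#'
#' The logarithmic mean `(C2 - C1) / (log(C2) - log(C1))`, i.e. the exact time
#' average of an exponentially changing density; identical contract to
#' [mean_grazer_density()] (single shared implementation, [log_mean()]).
#'
#' @param C1,C2 Densities, per ml; > 0.
#' @return Time-averaged density per ml.
#' @export
time_averaged_density <- function(C1, C2) log_mean(C1, C2)

#' Average population filtration rate
#'
#' `F = imax_carbon * cbar`: the carbon flux a population grazing at maximum
#' ingestion removes per ml per day.
#'
#' @param imax_carbon Maximum ingestion rate, pg C per individual per day;
#'   >= 0.
#' @param cbar Time-averaged population density, individuals per ml; >= 0.
#' @return A tibble with `filtration_pgC_per_ml_per_day` and its log10
#'   (`log10_filtration`, NA when the rate is zero), since published rates are
#'   reported as powers of ten.
#' @export
population_filtration_rate <- function(imax_carbon, cbar) {
  check_non_negative(imax_carbon, "imax_carbon")
  check_non_negative(cbar, "cbar")
  f <- imax_carbon * cbar
  tibble(filtration_pgC_per_ml_per_day = f,
         log10_filtration = ifelse(f > 0, log10(f), NA_real_))
}

#' Per-replicate net growth rates over a window
#'
#' For every (treatment, replicate, taxon) series, computes the two-point net
#' growth rate between the first and last uncensored observation inside the
#' window (matching the two-point formula used for initial growth phases),
#' plus the time-averaged abundance between the same two points.
#'
#' @param series Tidy series tibble with `day`, `treatment`, `replicate`,
#'   `taxon`, `abundance_per_ml`, optionally `biomass_pgC_per_ml` and
#'   `censored`. The biomass column is used when present, abundance otherwise.
#' @param window Length-2 numeric `(day_start, day_end)`, inclusive; default
#'   `c(0, 5)`, the typical initial growth phase.
#' @return A tibble with one row per series: `treatment`, `replicate`,
#'   `taxon`, `r_per_day`, `cbar_per_ml`, `t1`, `t2`, `lag_phase` (flag,
#'   `r_per_day < 0`).
#' @export
growth_rates <- function(series, window = c(0, 5)) {
  stopifnot(is.data.frame(series), length(window) == 2)
  if (!"censored" %in% names(series)) series$censored <- FALSE
  value_col <- if ("biomass_pgC_per_ml" %in% names(series)) "biomass_pgC_per_ml" else "abundance_per_ml"
  series %>%
    filter(.data$day >= window[1], .data$day <= window[2], !.data$censored) %>%
    group_by(.data$treatment, .data$replicate, .data$taxon) %>%
    arrange(.data$day, .by_group = TRUE) %>%
    summarise(
      r_per_day = {
        if (n() < 2) NA_real_ else {
          net_growth_rate(first(.data[[value_col]]), last(.data[[value_col]]),
                          first(.data$day), last(.data$day))
        }
      },
      cbar_per_ml = if (n() < 2) NA_real_ else
        time_averaged_density(first(.data$abundance_per_ml), last(.data$abundance_per_ml)),
      t1 = first(.data$day), t2 = last(.data$day),
      .groups = "drop"
    ) %>%
    mutate(lag_phase = .data$r_per_day < 0)
}

#' Growth-rate and filtration-rate summary table
#'
#' Aggregates [growth_rates()] over replicates (mean and standard error of r)
#' and attaches, for each grazer taxon with known maximum ingestion rates,
#' the population filtration rate on each prey as log10, computed from the
#' carbon-based I_max and the replicate-mean time-averaged grazer density.
#' Filtration rates for series in a lag phase (negative mean r) are still
#' computed but flagged, since inactive ciliates need not filter at I_max.
#'
#' @param series Tidy series tibble (see [growth_rates()]).
#' @param traits Trait table with `imax_cells_cry` / `imax_cells_nav` columns.
#' @param window Analysis window in days, default `c(0, 5)`.
#' @return A tibble with one row per treatment x taxon: `r_mean`, `r_se`,
#'   `n_replicates`, `log10_F_cry`, `log10_F_nav`, `lag_phase`.
#' @export
rate_table <- function(series, traits = default_traits(), window = c(0, 5)) {
  per_rep <- growth_rates(series, window)
  profs <- taxon_profiles(traits)
  imax_cry <- stats::setNames(traits$imax_cells_cry, traits$taxon)
  imax_nav <- stats::setNames(traits$imax_cells_nav, traits$taxon)
  per_rep %>%
    group_by(.data$treatment, .data$taxon) %>%
    summarise(
      r_mean = mean(.data$r_per_day, na.rm = TRUE),
      r_se = stats::sd(.data$r_per_day, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$r_per_day))),
      cbar_mean = mean(.data$cbar_per_ml, na.rm = TRUE),
      n_replicates = sum(!is.na(.data$r_per_day)),
      .groups = "drop"
    ) %>%
    mutate(
      log10_F_cry = purrr::map2_dbl(.data$taxon, .data$cbar_mean, function(tx, cb) {
        im <- imax_cry[[tx]]
        if (is.na(im) || is.na(cb)) return(NA_real_)
        population_filtration_rate(imax_to_carbon(im, profs$Cry), cb)$log10_filtration
      }),
      log10_F_nav = purrr::map2_dbl(.data$taxon, .data$cbar_mean, function(tx, cb) {
        im <- imax_nav[[tx]]
        if (is.na(im) || is.na(cb)) return(NA_real_)
        population_filtration_rate(imax_to_carbon(im, profs$Nav), cb)$log10_filtration
      }),
      lag_phase = .data$r_mean < 0
    )
}

#' Log-linear rate over a phase window by least squares
#'
#' Ordinary least-squares slope of `log(biomass)` versus time over the window,
#' for multi-point phases (e.g. a decline phase); requires at least 3
#' uncensored points.
#'
#' @param series Tidy series tibble for one or more series; grouped per
#'   (treatment, replicate, taxon).
#' @param window Length-2 numeric, inclusive day range.
#' @return Tibble with `treatment`, `replicate`, `taxon`, `rate_per_day`
#'   (slope), `rate_se`, `n_points`.
#' @export
phase_rate <- function(series, window) {
  stopifnot(is.data.frame(series), length(window) == 2)
  if (!"censored" %in% names(series)) series$censored <- FALSE
  value_col <- if ("biomass_pgC_per_ml" %in% names(series)) "biomass_pgC_per_ml" else "abundance_per_ml"
  sub <- series %>%
    filter(.data$day >= window[1], .data$day <= window[2], !.data$censored)
  if (nrow(sub) == 0) {
    abort("No uncensored points in the window.", class = "chemocomp_estimation_error")
  }
  sub %>%
    group_by(.data$treatment, .data$replicate, .data$taxon) %>%
    group_modify(function(d, key) {
      if (nrow(d) < 3) {
        abort(sprintf("Phase-rate estimation needs >= 3 uncensored points (got %d for %s/%s/%s).",
                      nrow(d), key$treatment, key$replicate, key$taxon),
              class = "chemocomp_estimation_error")
      }
      fit <- stats::lm(log(d[[value_col]]) ~ d$day)
      # summary.lm warns on exactly exponential (zero-residual) series
      sm <- suppressWarnings(summary(fit)$coefficients)
      tibble(rate_per_day = sm[2, 1],
             rate_se = if (nrow(sm) > 1 && nrow(d) > 2) sm[2, 2] else NA_real_,
             n_points = nrow(d))
    }) %>%
    ungroup()
}

#' Log biomass ratio of two competitors
#'
#' `log10(numerator / denominator)`; antisymmetric under swapping the
#' arguments. Censored biomasses must be substituted (not zero) before
#' calling.
#'
#' @param numerator,denominator Biomass, pg C per ml; > 0. Vectorised.
#' @return Dimensionless log10 ratio.
#' @export
log_biomass_ratio <- function(numerator, denominator) {
  check_positive(numerator, "numerator")
  check_positive(denominator, "denominator")
  log10(numerator / denominator)
}

#' Tidy log-ratio response table for two competing taxa
#'
#' Builds the response table for competition analyses: per day, treatment and
#' replicate, the log10 ratio of the two taxa's biomass. This is the tidy
#' input a mixed-model ANOVA would take (response, treatment, day, replicate);
#' the inference itself is left to external tools.
#'
#' @param series Tidy series tibble with `biomass_pgC_per_ml` (run
#'   [series_to_carbon()] and [apply_detection_policy()] first so censored
#'   values are substituted).
#' @param numerator_taxon,denominator_taxon Taxon identifiers; when the
#'   numerator is spread over several clone taxa (a polyclonal population),
#'   pass all of them — their biomass is summed.
#' @return Tibble with `day`, `treatment`, `replicate`, `log_ratio`.
#' @export
log_ratio_table <- function(series, numerator_taxon, denominator_taxon) {
  num <- series %>%
    filter(.data$taxon %in% numerator_taxon) %>%
    group_by(.data$day, .data$treatment, .data$replicate) %>%
    summarise(num_bm = sum(.data$biomass_pgC_per_ml), .groups = "drop")
  den <- series %>%
    filter(.data$taxon %in% denominator_taxon) %>%
    group_by(.data$day, .data$treatment, .data$replicate) %>%
    summarise(den_bm = sum(.data$biomass_pgC_per_ml), .groups = "drop")
  inner_join(num, den, by = c("day", "treatment", "replicate")) %>%
    mutate(log_ratio = log_biomass_ratio(.data$num_bm, .data$den_bm)) %>%
    select("day", "treatment", "replicate", "log_ratio")
}
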