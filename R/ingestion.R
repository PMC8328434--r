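# Grazing-rate estimation from paired control/grazed bottle incubations,
# in the standard Frost (1972) form with Heinbokel's time-averaged grazer
# correction, plus a Michaelis-Menten functional-response fit for I_max.

#' Assemble a bottle-experiment table
#'
#' One row per bottle pair: prey counts at start and end of the incubation in
#' the ungrazed control and in the grazed bottle, grazer counts at start and
#' end, and the incubation duration.
#'
#' @param prey_control_start,prey_control_end Prey cells per ml in the
#'   control bottle; > 0.
#' @param prey_grazed_start,prey_grazed_end Prey cells per ml in the grazed
#'   bottle; > 0.
#' @param grazer_start,grazer_end Grazers per ml; > 0.
#' @param duration Incubation length in days; > 0.
#' @return A tibble with one column per argument, class `bottle_experiment`
#'   prepended.
#' @export
bottle_experiment <- function(prey_control_start, prey_control_end,
                              prey_grazed_start, prey_grazed_end,
                              grazer_start, grazer_end, duration) {
  check_positive(prey_control_start, "prey_control_start")
  check_positive(prey_control_end, "prey_control_end")
  check_positive(prey_grazed_start, "prey_grazed_start")
  check_positive(prey_grazed_end, "prey_grazed_end")
  check_positive(grazer_start, "grazer_start")
  check_positive(grazer_end, "grazer_end")
  check_positive(duration, "duration")
  out <- tibble(
    prey_control_start = prey_control_start,
    prey_control_end = prey_control_end,
    prey_grazed_start = prey_grazed_start,
    prey_grazed_end = prey_grazed_end,
    grazer_start = grazer_start,
    grazer_end = grazer_end,
    duration = duration
  )
  class(out) <- c("bottle_experiment", class(out))
  out
}

#' Prey growth coefficient from the control bottle
#'
#' Frost's control-bottle growth constant
#' `k = log(prey_control_end / prey_control_start) / duration`; may be
#' negative if the control declined.
#'
#' @param prey_control_start,prey_control_end Control prey counts, cells/ml.
#' @param duration Days.
#' @return k in d^-1. Vectorised.
#' @export
prey_growth_coefficient <- function(prey_control_start, prey_control_end, duration) {
  check_positive(prey_control_start, "prey_control_start")
  check_positive(prey_control_end, "prey_control_end")
  check_positive(duration, "duration")
  log(prey_control_end / prey_control_start) / duration
}

#' Grazing coefficient from the grazed bottle
#'
#' Frost's grazing constant
#' `g = k - log(prey_grazed_end / prey_grazed_start) / duration`.
#'
#' @param k Control growth coefficient, d^-1.
#' @param prey_grazed_start,prey_grazed_end Grazed-bottle prey counts, cells/ml.
#' @param duration Days.
#' @return g in d^-1; negative when the grazed bottle outgrew the control.
#' @export
grazing_coefficient <- function(k, prey_grazed_start, prey_grazed_end, duration) {
  check_positive(prey_grazed_start, "prey_grazed_start")
  check_positive(prey_grazed_end, "prey_grazed_end")
  check_positive(duration, "duration")
  k - log(prey_grazed_end / prey_grazed_start) / duration
}

#' Time-averaged prey density in the grazed bottle
#'
#' Frost's time-averaged prey concentration for exponential dynamics at net
#' rate `k - g`:
#' `Cp = prey_grazed_start * (exp((k - g) * T) - 1) / ((k - g) * T)`,
#' with the continuous limit `prey_grazed_start` as `k - g -> 0`.
#'
#' @param prey_grazed_start Grazed-bottle starting prey count, cells/ml.
#' @param k,g Growth and grazing coefficients, d^-1.
#' @param duration Days.
#' @param tol Tolerance on `|k - g| * duration` below which the limit is used.
#' @return Mean prey density, cells per ml.
#' @export
mean_prey_density <- function(prey_grazed_start, k, g, duration, tol = 1e-9) {
  check_positive(prey_grazed_start, "prey_grazed_start")
  check_positive(duration, "duration")
  x <- (k - g) * duration
  ifelse(abs(x) < tol,
         prey_grazed_start,
         prey_grazed_start * (exp(x) - 1) / x)
}

#' Time-averaged grazer density
#'
#' Heinbokel-style logarithmic mean of the start and end grazer counts,
#' `(end - start) / (log(end) - log(start))`, shared with
#' [time_averaged_density()].
#'
#' @param start,end Grazers per ml; > 0.
#' @return Mean grazer density, per ml.
#' @export
mean_grazer_density <- function(start, end) log_mean(start, end)

#' Clearance and ingestion rates from a bottle table
#'
#' Data-frame-first wrapper over the Frost-Heinbokel estimators: computes per
#' bottle the control growth coefficient `k`, grazing coefficient `g`,
#' time-averaged prey and grazer densities, the clearance rate
#' `g / mean_grazer_per_ml` (ml per grazer per day) and the ingestion rate
#' `clearance * mean_prey_per_ml` (cells per grazer per day).
#'
#' Negative `g` (grazed bottle outgrowing the control) is reported as-is and
#' flagged in `negative_grazing`, never clamped.
#'
#' @param bottles A [bottle_experiment()] tibble (or any data frame with the
#'   same columns).
#' @return The input with columns `k`, `g`, `mean_prey_per_ml`,
#'   `mean_grazer_per_ml`, `clearance_ml_per_day`, `ingestion_cells_per_day`
#'   and `negative_grazing` appended.
#' @export
grazing_rates <- function(bottles) {
  out <- bottles %>%
    mutate(
      k = prey_growth_coefficient(.data$prey_control_start,
                                  .data$prey_control_end, .data$duration),
      g = grazing_coefficient(.data$k, .data$prey_grazed_start,
                              .data$prey_grazed_end, .data$duration),
      mean_prey_per_ml = mean_prey_density(.data$prey_grazed_start, .data$k,
                                           .data$g, .data$duration),
      mean_grazer_per_ml = mean_grazer_density(.data$grazer_start, .data$grazer_end),
      clearance_ml_per_day = .data$g / .data$mean_grazer_per_ml,
      ingestion_cells_per_day = .data$clearance_ml_per_day * .data$mean_prey_per_ml,
      negative_grazing = .data$g < 0
    )
  if (any(out$negative_grazing)) {
    warn(sprintf("%d bottle(s) have negative grazing coefficients (grazed bottle outgrew control).",
                 sum(out$negative_grazing)))
  }
  out
}

#' Fit a Michaelis-Menten functional response
#'
#' Nonlinear least-squares fit of `I(C) = I_max * C / (K + C)` to
#' (prey density, ingestion) points, e.g. the output of [grazing_rates()]
#' across bottles incubated at different prey densities. Initialised from a
#' reciprocal (Lineweaver-Burk) regression; `K` is bounded to
#' `(0, 10 * max(density)]`.
#'
#' @param points A data frame with columns `prey_per_ml` and
#'   `ingestion_cells_per_day`; at least 3 points at distinct densities.
#' @param exclude_negative Drop points with negative ingestion (from negative
#'   grazing coefficients) before fitting; default `TRUE`.
#' @return An object of class `functional_response_fit`: a list with `imax`
#'   (cells per grazer per day), `half_saturation_k` (cells per ml),
#'   `residual_sse`, `converged`, `n`, the fitted `model` (or `NULL` for the
#'   all-zero degenerate case) and the `data` used.
#' @examples
#' pts <- tibble::tibble(prey_per_ml = c(50, 100, 250, 500, 1000, 2500, 5000),
#'                       ingestion_cells_per_day = 116 * prey_per_ml / (500 + prey_per_ml))
#' fit <- fit_functional_response(pts)
#' generics::tidy(fit)
#' @export
fit_functional_response <- function(points, exclude_negative = TRUE) {
  stopifnot(is.data.frame(points))
  required <- c("prey_per_ml", "ingestion_cells_per_day")
  if (!all(required %in% names(points))) {
    abort("`points` needs columns prey_per_ml and ingestion_cells_per_day.",
          class = "chemocomp_schema_error")
  }
  pts <- as_tibble(points)[required]
  if (exclude_negative) pts <- filter(pts, .data$ingestion_cells_per_day >= 0)
  if (nrow(pts) < 3 || length(unique(pts$prey_per_ml)) < 3) {
    abort("Need >= 3 points at >= 3 distinct prey densities.",
          class = "chemocomp_fit_error")
  }
  check_positive(pts$prey_per_ml, "prey_per_ml")

  if (all(pts$ingestion_cells_per_day == 0)) {
    return(new_fr_fit(0, stats::median(pts$prey_per_ml), 0, TRUE, NULL, pts))
  }

  # reciprocal regression start values: 1/I = (K/Imax) (1/C) + 1/Imax
  pos <- filter(pts, .data$ingestion_cells_per_day > 0)
  lb <- stats::lm(I(1 / ingestion_cells_per_day) ~ I(1 / prey_per_ml), data = pos)
  imax0 <- 1 / stats::coef(lb)[[1]]
  k0 <- stats::coef(lb)[[2]] * imax0
  if (!is.finite(imax0) || imax0 <= 0) imax0 <- max(pts$ingestion_cells_per_day)
  kmax <- 10 * max(pts$prey_per_ml)
  if (!is.finite(k0) || k0 <= 0 || k0 > kmax) k0 <- stats::median(pts$prey_per_ml)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      ingestion_cells_per_day ~ imax * prey_per_ml / (k + prey_per_ml),
      data = pts,
      start = list(imax = imax0, k = k0),
      lower = c(imax = 0, k = 1e-12),
      upper = c(imax = Inf, k = kmax),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    return(new_fr_fit(unname(cf["imax"]), unname(cf["k"]),
                      sum(stats::residuals(fit)^2),
                      isTRUE(fit$convInfo$isConv), fit, pts))
  }
  # Levenberg-Marquardt can hit a singular gradient on noisy, flat responses;
  # fall back to direct SSE minimisation on log-parameters
  sse <- function(lp) {
    pred <- exp(lp[1]) * pts$prey_per_ml / (exp(lp[2]) + pts$prey_per_ml)
    sum((pts$ingestion_cells_per_day - pred)^2)
  }
  opt <- stats::optim(c(log(imax0), log(k0)), sse, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (exp(opt$par[2]) > kmax) opt$par[2] <- log(kmax)
  new_fr_fit(exp(opt$par[1]), exp(opt$par[2]), sse(opt$par),
             opt$convergence == 0, NULL, pts)
}

new_fr_fit <- function(imax, k, sse, converged, model, data) {
  structure(
    list(imax = imax, half_saturation_k = k, residual_sse = sse,
         converged = converged, n = nrow(data), model = model, data = data),
    class = "functional_response_fit"
  )
}

#' Predict ingestion from a fitted functional response
#'
#' @param object A `functional_response_fit`.
#' @param newdata Optional data frame with `prey_per_ml`; defaults to the
#'   training data.
#' @param ... Unused.
#' @return Predicted ingestion, cells per grazer per day.
#' @export
predict.functional_response_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data else newdata
  object$imax * d$prey_per_ml / (object$half_saturation_k + d$prey_per_ml)
}

#' @export
print.functional_response_fit <- function(x, ...) {
  cat(sprintf("<functional_response_fit> I_max = %.4g cells d^-1, K = %.4g cells ml^-1 (n = %d, %s)\n",
              x$imax, x$half_saturation_k, x$n,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Tidy a functional-response fit
#'
#' @param x A `functional_response_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error` (NA for degenerate fits).
#' @export
tidy.functional_response_fit <- function(x, ...) {
  se <- c(NA_real_, NA_real_)
  if (!is.null(x$model)) {
    se <- tryCatch(summary(x$model)$coefficients[, "Std. Error"],
                   error = function(e) se)
  }
  tibble(term = c("imax", "half_saturation_k"),
         estimate = c(x$imax, x$half_saturation_k),
         std.error = unname(se))
}

#' Glance at a functional-response fit
#'
#' @param x A `functional_response_fit`.
#' @param ... Unused.
#' @return One-row tibble with `residual_sse`, `converged`, `n`,
#'   `max_observed_ingestion` and `imax_above_half_max` (sanity report that
#'   the fitted I_max is at least half the largest observed ingestion).
#' @export
glance.functional_response_fit <- function(x, ...) {
  mx <- max(x$data$ingestion_cells_per_day)
  tibble(residual_sse = x$residual_sse, converged = x$converged, n = x$n,
         max_observed_ingestion = mx,
         imax_above_half_max = x$imax >= 0.5 * mx)
}

#' @export
autoplot.functional_response_fit <- function(object, ...) {
  grid <- tibble(prey_per_ml = seq(min(object$data$prey_per_ml) * 0.5,
                                   max(object$data$prey_per_ml) * 1.2,
                                   length.out = 200))
  grid$ingestion_cells_per_day <- predict(object, grid)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$prey_per_ml, .data$ingestion_cells_per_day)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "Prey density (cells/ml)",
                  y = "Ingestion (cells grazer⁻¹ d⁻¹)")
}
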