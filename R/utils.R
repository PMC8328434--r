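#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# shared argument checks ------------------------------------------------------

check_positive <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be finite and > 0.", what), class = "chemocomp_domain_error")
  }
  invisible(x)
}

check_non_negative <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be finite and >= 0.", what), class = "chemocomp_domain_error")
  }
  invisible(x)
}

check_fraction <- function(x, what, allow_one = TRUE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(!hi_ok)) {
    abort(sprintf("`%s` must lie in [0, %s.", what, if (allow_one) "1]" else "1)"),
          class = "chemocomp_domain_error")
  }
  invisible(x)
}

#' Logarithmic mean of two positive densities
#'
#' The time average of an exponentially changing quantity observed at two
#' points: `(c2 - c1) / (log(c2) - log(c1))`, with the continuous limit `c1`
#' when the two values coincide. Used both for the time-averaged grazer
#' density in bottle experiments and for the time-averaged ciliate density in
#' population filtration rates.
#'
#' @param c1,c2 Positive densities (any common unit); vectorised.
#' @param tol Absolute tolerance on `|log(c2) - log(c1)|` below which the
#'   analytic limit `c1` is substituted.
#' @return The logarithmic mean, same length as the inputs.
#' @examples
#' log_mean(100, 200) # 100 / log(2) times 1 ... = 144.27
#' @export
log_mean <- function(c1, c2, tol = 1e-9) {
  check_positive(c1, "c1")
  check_positive(c2, "c2")
  dl <- log(c2) - log(c1)
  out <- ifelse(abs(dl) < tol, c1, (c2 - c1) / dl)
  unname(out)
}
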