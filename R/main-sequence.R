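# Main-sequence fitting and the condition-wise vigor ratio.

#' Fit the hyperbolic main sequence of one subject
#'
#' Least-squares fit of `v = alpha * (1 - 1 / (1 + beta * x))` to all of a
#' subject's saccades (amplitude `x` in degrees, peak velocity `v` in
#' degrees/s), pooled over trials and conditions.  The expected-velocity
#' function of the fit is the reference against which condition vigor ratios
#' are computed.  Fitting uses bounded Levenberg-Marquardt with a data-driven
#' start (`alpha0 = 1.1 * max(v)`, `beta0` solved from the median-amplitude
#' point) and restarts on perturbed starts if needed.
#'
#' @param events Event tibble with `amplitude_deg` and `peak_vel_deg_s`.
#' @param min_saccades Minimum number of saccades required.
#' @param min_amplitude_range Minimum amplitude span (degrees) required for
#'   identifiability.
#' @return An object of class `main_sequence_fit` with elements `alpha`,
#'   `beta`, `n_saccades`, and `fit` (the underlying `nls` object).
#' @examples
#' x <- runif(200, 2, 15)
#' v <- main_sequence_velocity(x, 560, 0.25)
#' f <- fit_main_sequence(tibble::tibble(amplitude_deg = x,
#'                                       peak_vel_deg_s = v))
#' c(f$alpha, f$beta)
#' @export
fit_main_sequence <- function(events, min_saccades = 20,
                              min_amplitude_range = 2) {
  x <- events$amplitude_deg
  v <- events$peak_vel_deg_s
  ok <- is.finite(x) & is.finite(v) & x > 0 & v > 0
  x <- x[ok]; v <- v[ok]
  abort_if(length(x) < min_saccades,
           sprintf("Need >= %d saccades to fit the main sequence.",
                   min_saccades),
           class = "ocuvigor_fit_error")
  abort_if(diff(range(x)) < min_amplitude_range,
           "Amplitudes span too narrow a range to identify the fit.",
           class = "ocuvigor_fit_error")
  vmax <- max(v)
  alpha0 <- 1.1 * vmax
  med <- stats::median(x)
  vmed <- stats::median(v[abs(x - med) <= diff(range(x)) / 4])
  # invert v = a(1 - 1/(1 + b x)) at the median point for beta0
  r <- min(vmed / alpha0, 0.95)
  beta0 <- max(r / ((1 - r) * med), 1e-3)
  dat <- data.frame(x = x, v = v)
  fit <- NULL
  starts <- list(c(alpha0, beta0), c(1.5 * vmax, 0.5 * beta0),
                 c(1.05 * vmax, 2 * beta0))
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ a * (1 - 1 / (1 + b * x)), data = dat,
                        start = list(a = s[1], b = s[2]),
                        lower = c(1e-6, 1e-6),
                        upper = c(5 * vmax, 10),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  abort_if(is.null(fit), "Main-sequence fit failed to converge.",
           class = "ocuvigor_fit_error")
  cf <- stats::coef(fit)
  structure(list(alpha = unname(cf["a"]), beta = unname(cf["b"]),
                 n_saccades = length(x), fit = fit),
            class = "main_sequence_fit")
}

#' Expected peak velocity under a fitted main sequence
#'
#' @param object A `main_sequence_fit`.
#' @param amplitude Amplitude(s), degrees.
#' @param ... Unused.
#' @return Expected peak velocity, degrees/s.
#' @export
predict.main_sequence_fit <- function(object, amplitude, ...) {
  main_sequence_velocity(amplitude, object$alpha, object$beta)
}

#' @export
print.main_sequence_fit <- function(x, ...) {
  cat(sprintf(
    "Main-sequence fit: alpha = %.1f deg/s, beta = %.3f /deg (n = %d)\n",
    x$alpha, x$beta, x$n_saccades))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a main-sequence fit
#'
#' @param x A `main_sequence_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `std.error`).
#' @method tidy main_sequence_fit
#' @export
tidy.main_sequence_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("alpha", "beta"),
                 estimate = unname(s[, "Estimate"]),
                 std.error = unname(s[, "Std. Error"]))
}

#' @rdname tidy.main_sequence_fit
#' @return `glance()`: a one-row tibble with `alpha`, `beta`, `n_saccades`,
#'   `sigma` (residual SD).
#' @method glance main_sequence_fit
#' @export
glance.main_sequence_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, beta = x$beta,
                 n_saccades = x$n_saccades,
                 sigma = summary(x$fit)$sigma)
}

#' Condition-wise saccade vigor
#'
#' The vigor of a set of saccades is the ratio of their mean measured peak
#' velocity to the mean peak velocity expected from the subject's main
#' sequence at the same amplitudes: `mean(v) / mean(v_hat(x))`.  Ratios > 1
#' mean the condition's saccades were faster than the subject's average for
#' their size.
#'
#' @param events Event tibble for one condition (`amplitude_deg`,
#'   `peak_vel_deg_s`).
#' @param fit The subject's [fit_main_sequence()] result.
#' @return The vigor ratio (scalar); `NA` with a warning for an empty
#'   condition.
#' @export
vigor_ratio <- function(events, fit) {
  if (nrow(events) == 0) {
    rlang::warn("Empty condition: vigor is NA.")
    return(NA_real_)
  }
  mean(events$peak_vel_deg_s) /
    mean(predict(fit, events$amplitude_deg))
}
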