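#' MilkBot lactation-curve parameters
#'
#' Constructs the four-parameter description of a single lactation curve
#' under the MilkBot model
#' \deqn{y(t) = a\,\bigl(1 - \tfrac{1}{2} e^{(c-t)/b}\bigr)\, e^{-d t}}
#' where \eqn{t} is days in milk.
#'
#' @param a scale, kg/day: the theoretical maximum daily yield.
#' @param b ramp, days: controls the rate of rise in early lactation.
#' @param c offset, days: lag between parturition and the start of lactation.
#' @param d decay, 1/day: rate of senescence of production capacity.
#' @param c_bounds admissible range for the offset (days).
#'
#' @return An object of class \code{"milkbot_params"}: a named list with
#'   elements \code{a}, \code{b}, \code{c}, \code{d}.
#' @examples
#' p <- milkbot_params(a = 35, b = 29.3, c = 2.5, d = 0.00138)
#' milkbot_yield(p, 0:10)
#' @export
milkbot_params <- function(a, b, c, d, c_bounds = c(-30, 30)) {
  vals <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(vals)))
    stop("MilkBot parameters must be finite, got: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  if (a <= 0) stop("scale 'a' must be positive")
  if (b <= 0) stop("ramp 'b' must be positive")
  if (d < 0) stop("decay 'd' must be non-negative")
  if (c < c_bounds[1] || c > c_bounds[2])
    stop("offset 'c' outside admissible range [",
         c_bounds[1], ", ", c_bounds[2], "]")
  structure(list(a = a, b = b, c = c, d = d), class = "milkbot_params")
}

#' @export
print.milkbot_params <- function(x, ...) {
  cat("MilkBot parameters:\n")
  cat(sprintf("  scale  a = %.4g kg/d\n  ramp   b = %.4g d\n", x$a, x$b))
  cat(sprintf("  offset c = %.4g d\n  decay  d = %.4g /d\n", x$c, x$d))
  invisible(x)
}

as_milkbot_params <- function(p) {
  if (inherits(p, "milkbot_params")) return(p)
  p <- as.list(p)
  milkbot_params(p$a, p$b, p$c, p$d)
}

#' Predicted daily milk yield
#'
#' Evaluates the MilkBot curve at days in milk \code{t}. The raw model value
#' is returned: for \eqn{t < c - b\ln 2} it is negative (pre-lactation), and
#' no clamping is applied here; display utilities clamp at zero.
#'
#' @param params a \code{\link{milkbot_params}} object (or coercible list).
#' @param t days in milk, vectorised.
#' @return Predicted yield in kg/day, same length as \code{t}.
#' @export
milkbot_yield <- function(params, t) {
  p <- as_milkbot_params(params)
  p$a * (1 - exp((p$c - t) / p$b) / 2) * exp(-p$d * t)
}

#' Time of peak lactation
#'
#' The stationary point of the MilkBot curve in closed form,
#' \deqn{t_{peak} = c - b \ln\frac{2bd}{1+bd}.}
#' The stationary point is a genuine within-lactation peak only when
#' \eqn{bd < 1}; for \eqn{bd \ge 1} it falls at or before the offset \eqn{c}
#' (the curve is effectively monotone over the biological range) and
#' \code{peak_defined} is \code{FALSE}. With \eqn{d = 0} the curve has no
#' finite peak at all and \code{t_peak} is \code{NA}.
#'
#' @inheritParams milkbot_yield
#' @return A list with \code{t_peak} (days, \code{NA} if no finite peak) and
#'   \code{peak_defined} (logical).
#' @export
milkbot_time_to_peak <- function(params) {
  p <- as_milkbot_params(params)
  if (p$d <= 0)
    return(list(t_peak = NA_real_, peak_defined = FALSE))
  bd <- p$b * p$d
  tp <- p$c - p$b * log(2 * bd / (1 + bd))
  list(t_peak = tp, peak_defined = bd < 1)
}

#' Peak daily yield
#'
#' The curve evaluated at its stationary point:
#' \code{milkbot_yield(params, t_peak)}. \code{NA} when no finite peak
#' exists (\eqn{d = 0}).
#'
#' @inheritParams milkbot_yield
#' @return Peak yield in kg/day, or \code{NA_real_}.
#' @export
milkbot_peak_yield <- function(params) {
  p <- as_milkbot_params(params)
  tp <- milkbot_time_to_peak(p)
  if (is.na(tp$t_peak)) return(NA_real_)
  milkbot_yield(p, tp$t_peak)
}

#' Cumulative milk yield
#'
#' Exact integral of the MilkBot curve from calving to day \code{t_end}:
#' \deqn{\int_0^{T} y(t)\,dt \;=\; \frac{a(1 - e^{-dT})}{d}
#'   - \frac{a b e^{c/b}}{2(1+bd)}\bigl(1 - e^{-T(1/b + d)}\bigr),}
#' with the analytic \eqn{d \to 0} limit
#' \eqn{aT - \tfrac{1}{2} a b e^{c/b}(1 - e^{-T/b})} used when
#' \eqn{d < 10^{-12}}.
#'
#' @inheritParams milkbot_yield
#' @param t_end upper limit of integration, days (vectorised, \eqn{\ge 0}).
#' @return Cumulative yield in kg.
#' @seealso \code{\link{milkbot_m305}} for the standardized 305-day yield.
#' @export
milkbot_cumulative <- function(params, t_end) {
  p <- as_milkbot_params(params)
  if (any(t_end < 0)) stop("'t_end' must be non-negative")
  ramp_term <- p$a * p$b * exp(p$c / p$b) / (2 * (1 + p$b * p$d)) *
    (1 - exp(-t_end * (1 / p$b + p$d)))
  if (p$d < 1e-12) {
    p$a * t_end - ramp_term
  } else {
    p$a * (1 - exp(-p$d * t_end)) / p$d - ramp_term
  }
}

#' 305-day milk yield
#'
#' The standardized lactation yield: cumulative milk from calving to day 305.
#'
#' @inheritParams milkbot_yield
#' @return M305 in kg.
#' @export
milkbot_m305 <- function(params) {
  milkbot_cumulative(params, 305)
}

#' Derived lactation traits
#'
#' Computes all closed-form traits of a parameter set in one call:
#' 305-day yield, time to peak, peak yield, and the peak-defined flag.
#'
#' @inheritParams milkbot_yield
#' @return A one-row \code{data.frame} with columns \code{m305},
#'   \code{t_peak}, \code{peak_yield}, \code{peak_defined}.
#' @export
milkbot_traits <- function(params) {
  p <- as_milkbot_params(params)
  tp <- milkbot_time_to_peak(p)
  data.frame(
    m305 = milkbot_m305(p),
    t_peak = tp$t_peak,
    peak_yield = if (is.na(tp$t_peak)) NA_real_ else milkbot_yield(p, tp$t_peak),
    peak_defined = tp$peak_defined
  )
}
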