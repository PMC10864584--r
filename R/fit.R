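# Per-lactation MilkBot fitting: bounded Levenberg-Marquardt least squares
# (minpack.lm) with multi-start over jittered initial values. Ordinary
# (unweighted) least squares on the daily yields.

#' Fitting control parameters
#'
#' @param lower,upper parameter bounds, named \code{c(a, b, c, d)}.
#'   Defaults: a in (0, 120] kg/d, b in [1, 120] d, c in [-30, 30] d,
#'   d in [0, 0.02] /d -- generous envelopes around Holstein primiparous
#'   values.
#' @param n_starts number of multi-start attempts (first start from the
#'   deterministic heuristic, the rest jittered).
#' @param jitter_sd relative jitter applied to the initial values of the
#'   extra starts.
#' @param ftol,ptol convergence tolerances on relative change in the sum of
#'   squares and in the parameters.
#' @param maxiter maximum iterations per start.
#' @param min_points refuse to fit with fewer daily records than this.
#' @param seed integer used to seed the jitter stream (per-lactation offsets
#'   are added so animals get distinct but reproducible starts).
#' @return A list of class \code{"milkbot_control"}.
#' @export
milkbot_control <- function(lower = c(a = 1e-6, b = 1, c = -30, d = 0),
                            upper = c(a = 120, b = 120, c = 30, d = 0.02),
                            n_starts = 5, jitter_sd = 0.15,
                            ftol = 1e-12, ptol = 1e-12, maxiter = 500,
                            min_points = 10, seed = 1L) {
  structure(list(lower = lower, upper = upper, n_starts = n_starts,
                 jitter_sd = jitter_sd, ftol = ftol, ptol = ptol,
                 maxiter = maxiter, min_points = min_points,
                 seed = as.integer(seed)),
            class = "milkbot_control")
}

# Deterministic initial values: scale from the observed maximum, field-typical
# ramp/offset/decay for primiparous Holsteins.
milkbot_start <- function(milk_kg) {
  c(a = 1.1 * max(milk_kg), b = 25, c = 0, d = 0.0015)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Fit a MilkBot curve to one lactation
#'
#' Minimizes the sum of squared differences between observed daily yields
#' and the model curve over the admissible parameter box, by bounded
#' Levenberg-Marquardt with \code{n_starts} jittered initializations; the
#' best converged attempt wins. Derived traits are computed from the fitted
#' parameters.
#'
#' @param dim integer days in milk of the observations.
#' @param milk_kg observed daily yields, kg.
#' @param control a \code{\link{milkbot_control}}.
#' @param start_jitter_stream optional integer distinguishing this
#'   lactation's jitter sequence (used by \code{\link{fit_cohort}}).
#' @return An object of class \code{"milkbot_fit"}: list with
#'   \code{params} (\code{\link{milkbot_params}}), \code{rss}, \code{n_obs},
#'   \code{converged}, \code{traits} (from \code{\link{milkbot_traits}}) and
#'   \code{diagnostics} (iterations, termination message, start used).
#' @examples
#' p <- milkbot_params(34, 28, 2, 0.0014)
#' fit <- fit_lactation(1:305, milkbot_yield(p, 1:305))
#' unlist(fit$params)
#' @export
fit_lactation <- function(dim, milk_kg, control = milkbot_control(),
                          start_jitter_stream = 0L) {
  stopifnot(length(dim) == length(milk_kg))
  ok <- is.finite(dim) & is.finite(milk_kg)
  dim <- dim[ok]; milk_kg <- milk_kg[ok]
  if (length(dim) < control$min_points)
    stop("refusing to fit: ", length(dim), " data point(s), minimum is ",
         control$min_points, call. = FALSE)

  residual_fn <- function(par) {
    milk_kg - par["a"] * (1 - exp((par["c"] - dim) / par["b"]) / 2) *
      exp(-par["d"] * dim)
  }

  base_start <- clamp(milkbot_start(milk_kg), control$lower, control$upper)
  starts <- list(base_start)
  if (control$n_starts > 1) {
    jit_rng <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
              else if (exists(".Random.seed", globalenv()))
                rm(".Random.seed", envir = globalenv()))
      set.seed(control$seed + 1000L * (start_jitter_stream %% 1000000L))
      matrix(stats::rnorm(4 * (control$n_starts - 1), sd = control$jitter_sd),
             ncol = 4)
    })
    for (i in seq_len(control$n_starts - 1)) {
      s <- base_start * exp(jit_rng[i, ])
      s["c"] <- base_start["c"] + 5 * jit_rng[i, 3]  # c may be <= 0; additive jitter
      starts[[i + 1]] <- clamp(s, control$lower, control$upper)
    }
  }

  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = s, lower = control$lower, upper = control$upper,
        fn = residual_fn,
        control = minpack.lm::nls.lm.control(
          ftol = control$ftol, ptol = control$ptol,
          maxiter = control$maxiter)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    conv <- res$info %in% 1:4
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (conv && !best$converged && rss <= best$rss + 1e-9)) {
      best <- list(par = res$par, rss = rss, converged = conv,
                   niter = res$niter, message = res$message)
    }
  }
  if (is.null(best))
    stop("optimizer failed on every start", call. = FALSE)

  params <- milkbot_params(best$par[["a"]], best$par[["b"]],
                           best$par[["c"]], best$par[["d"]])
  structure(list(
    params = params,
    rss = best$rss,
    n_obs = length(dim),
    converged = best$converged,
    traits = milkbot_traits(params),
    diagnostics = list(iterations = best$niter, message = best$message,
                       n_starts = length(starts))
  ), class = "milkbot_fit")
}

#' @export
print.milkbot_fit <- function(x, ...) {
  cat("MilkBot fit:", x$n_obs, "observations, rss =",
      format(x$rss, digits = 6), "kg^2,",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(x$params)
  cat(sprintf("  m305 = %.1f kg, t_peak = %.2f d, peak = %.2f kg/d\n",
              x$traits$m305, x$traits$t_peak, x$traits$peak_yield))
  invisible(x)
}

#' Fit MilkBot curves for every lactation in a cohort
#'
#' @param lactations data.frame with \code{animal_id}, \code{herd_id} (one
#'   row per animal).
#' @param milkings long data.frame with \code{animal_id}, \code{dim},
#'   \code{milk_kg}.
#' @param control a \code{\link{milkbot_control}}.
#' @return A data.frame, one row per animal: identifiers, fitted
#'   \code{a, b, c, d}, \code{rss}, \code{n_obs}, \code{converged}, and the
#'   derived traits \code{m305}, \code{t_peak}, \code{peak_yield},
#'   \code{peak_defined}. Animals whose fit is refused (too few points) are
#'   omitted with a message.
#' @export
fit_cohort <- function(lactations, milkings, control = milkbot_control()) {
  split_milk <- split(milkings[c("dim", "milk_kg")], milkings$animal_id)
  rows <- vector("list", nrow(lactations))
  skipped <- character()
  for (i in seq_len(nrow(lactations))) {
    id <- lactations$animal_id[i]
    mk <- split_milk[[id]]
    if (is.null(mk) || nrow(mk) < control$min_points) {
      skipped <- c(skipped, id)
      next
    }
    f <- fit_lactation(mk$dim, mk$milk_kg, control = control,
                       start_jitter_stream = i)
    rows[[i]] <- data.frame(
      animal_id = id, herd_id = lactations$herd_id[i],
      a = f$params$a, b = f$params$b, c = f$params$c, d = f$params$d,
      rss = f$rss, n_obs = f$n_obs, converged = f$converged,
      f$traits, stringsAsFactors = FALSE)
  }
  if (length(skipped))
    message(length(skipped), " lactation(s) skipped (fewer than ",
            control$min_points, " points)")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
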