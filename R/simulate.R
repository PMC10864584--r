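# Synthetic herd-cohort generator. Emulates the statistical structure the
# analysis assumes: multiple herds with herd-level effects on milk scale,
# gestation length from a truncated-normal bulk (mean 279 d, sd 5.5 d) plus
# a rare short-GL tail, MilkBot parameters whose means depend on the GL
# category, daily yields with Gaussian observation noise clipped to the
# recordable range, and calendar structure (calving dates 2013-2018, age at
# first calving ~ 24 months). Ground truth is returned for recovery tests.

#' Simulation configuration
#'
#' Defaults describe a realistic multi-herd primiparous Holstein cohort.
#' Category-level MilkBot means follow the published per-category estimates
#' (scale 31.5-35.0 kg/d rising from the shortest-GL category to the
#' longest; ramps 29.3-29.8 d; decays 0.00125-0.00138 /d); between-animal
#' parameter SDs are set so the implied 305-day-yield SD is about 800 kg,
#' and the herd effect on scale (1.7 kg/d) corresponds to a herd SD of
#' roughly 400 kg in 305-day yield.
#'
#' @param n_herds number of herds.
#' @param animals_per_herd mean herd size (at least 1).
#' @param herd_size_dispersion negative-binomial size parameter for herd
#'   sizes; \code{Inf} (the default) gives identical herd sizes.
#' @param gl_mean,gl_sd bulk gestation-length distribution, days
#'   (normal truncated to \code{gl_range}).
#' @param gl_range admissible GL window, days.
#' @param gl_short_range support of the short-GL tail component, days.
#' @param gl_short_weight mixing weight of the short-GL component.
#' @param category_param_means data.frame (5 rows, columns
#'   \code{category, a, b, d}) of category-level MilkBot means.
#' @param c_mean mean lactation offset, days.
#' @param param_sds between-animal SDs, named \code{c(a, b, c, d)}.
#' @param herd_sd_a herd-level SD on the scale parameter, kg/d.
#' @param noise_sd_kg observation noise SD on daily milk, kg.
#' @param milk_range recordable daily-yield window; observations are
#'   clipped here (truths untouched).
#' @param afc_mean,afc_sd age at first calving, days.
#' @param calving_years calendar window for calving dates.
#' @param calving_months months (1-12) calvings may fall in; restricting
#'   this keeps tiny cohorts' calendar factors estimable.
#' @param max_dim last recorded day in milk.
#' @param missing_day_prob probability a daily record is missing.
#' @param seed integer seed; identical configs with identical seeds
#'   reproduce byte-identical cohorts.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_herds = 10,
                       animals_per_herd = 30,
                       herd_size_dispersion = Inf,
                       gl_mean = 279, gl_sd = 5.5,
                       gl_range = c(150, 297),
                       gl_short_range = c(158, 243),
                       gl_short_weight = 0.01,
                       category_param_means = default_category_params(),
                       c_mean = 2.5,
                       param_sds = c(a = 3.0, b = 2.5, c = 1.5, d = 2e-4),
                       herd_sd_a = 1.7,
                       noise_sd_kg = 2.0,
                       milk_range = c(1.0, 70.0),
                       afc_mean = 730, afc_sd = 60,
                       calving_years = c(2013, 2018),
                       calving_months = 1:12,
                       max_dim = 305,
                       missing_day_prob = 0,
                       seed = 1L) {
  if (n_herds < 1 || animals_per_herd < 1)
    stop("degenerate configuration: need at least 1 herd and 1 animal")
  if (gl_short_weight < 0 || gl_short_weight > 1)
    stop("'gl_short_weight' must lie in [0, 1]")
  if (any(param_sds < 0) || herd_sd_a < 0 || noise_sd_kg < 0)
    stop("standard deviations must be non-negative")
  structure(as.list(environment()), class = "sim_config")
}

#' Category-level MilkBot parameter means
#'
#' The default scale/ramp/decay means per gestation-length category used by
#' the cohort generator: short-GL categories have lower scale, slightly
#' longer ramp and slower decay (higher persistency) than normal-GL
#' categories.
#'
#' @return data.frame with columns \code{category}, \code{a}, \code{b},
#'   \code{d}.
#' @export
default_category_params <- function() {
  data.frame(
    category = GL_LABELS,
    a = c(31.5, 32.8, 34.5, 34.9, 35.0),
    b = c(29.8, 29.8, 29.5, 29.3, 29.3),
    d = c(0.00125, 0.00130, 0.00137, 0.00138, 0.00138),
    stringsAsFactors = FALSE
  )
}

#' Draw gestation lengths
#'
#' Mixture of the truncated-normal bulk and the uniform short-GL tail.
#' Values are continuous day counts within the admissible window; the
#' cohort generator rounds them only when emitting whole-day event dates.
#'
#' @param n number of draws.
#' @param config a \code{\link{sim_config}}.
#' @return numeric vector of length \code{n}.
#' @export
simulate_gl <- function(n, config = sim_config()) {
  stopifnot(n >= 1)
  short <- stats::runif(n) < config$gl_short_weight
  out <- numeric(n)
  n_bulk <- sum(!short)
  if (n_bulk) {
    # truncated normal by inverse-CDF
    lo <- stats::pnorm(config$gl_range[1], config$gl_mean, config$gl_sd)
    hi <- stats::pnorm(config$gl_range[2], config$gl_mean, config$gl_sd)
    u <- stats::runif(n_bulk, lo, hi)
    out[!short] <- stats::qnorm(u, config$gl_mean, config$gl_sd)
  }
  if (any(short))
    out[short] <- stats::runif(sum(short), config$gl_short_range[1],
                               config$gl_short_range[2])
  pmin(pmax(out, config$gl_range[1]), config$gl_range[2])
}

#' Simulate a herd cohort
#'
#' Generates the full raw-data bundle the pipeline consumes -- a daily
#' milkings table and a reproduction table -- together with the ground
#' truth. Per animal: GL is drawn from the configured mixture and mapped to
#' its category by the fixed reference scheme; MilkBot parameters are drawn
#' around the category means, with the herd effect added to the scale;
#' daily milk is the true curve plus Gaussian noise, clipped to the
#' recordable range at the recording step only.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{"sim_cohort"}:
#'   \describe{
#'     \item{milkings}{data.frame herd_id, animal_id, dim, milk_kg.}
#'     \item{repro}{data.frame herd_id, animal_id, birth_date,
#'       last_insemination_date, calving_date, service_type.}
#'     \item{truth}{list with \code{animals} (true params, true traits,
#'       category, herd effect per animal), \code{herd_effects}, and
#'       \code{category_trait_means} (true category-level means of the
#'       derived traits, the recoverable offsets).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  herd_ids <- sprintf("H%03d", seq_len(config$n_herds))
  herd_sizes <- if (is.infinite(config$herd_size_dispersion)) {
    rep(as.integer(config$animals_per_herd), config$n_herds)
  } else {
    pmax(1L, stats::rnbinom(config$n_herds,
                            mu = config$animals_per_herd,
                            size = config$herd_size_dispersion))
  }
  herd_eff <- stats::rnorm(config$n_herds, 0, config$herd_sd_a)
  names(herd_eff) <- herd_ids

  n <- sum(herd_sizes)
  herd <- rep(herd_ids, herd_sizes)
  animal <- sprintf("A%05d", seq_len(n))

  gl <- simulate_gl(n, config)
  gl_days <- as.integer(round(gl))
  scheme <- gl_scheme_fixed()
  category <- assign_gl_category(gl_days, scheme)

  cp <- config$category_param_means
  idx <- match(as.character(category), cp$category)
  sds <- config$param_sds
  lower_d <- 1e-5  # keep decay positive so every truth has a finite peak
  a <- pmax(5, stats::rnorm(n, cp$a[idx] + herd_eff[herd], sds["a"]))
  b <- pmax(5, stats::rnorm(n, cp$b[idx], sds["b"]))
  cc <- stats::rnorm(n, config$c_mean, sds["c"])
  d <- pmax(lower_d, stats::rnorm(n, cp$d[idx], sds["d"]))

  # calendar structure: year and month uniform over the configured window
  yrs <- seq(config$calving_years[1], config$calving_years[2])
  yr <- yrs[sample.int(length(yrs), n, replace = TRUE)]
  mos <- config$calving_months
  mo <- mos[sample.int(length(mos), n, replace = TRUE)]
  dy <- sample.int(28L, n, replace = TRUE)
  calving <- as.Date(sprintf("%d-%02d-%02d", yr, mo, dy))
  afc <- as.integer(round(stats::rnorm(n, config$afc_mean, config$afc_sd)))
  afc <- pmax(550L, afc)
  birth <- calving - afc
  insem <- calving - gl_days
  service <- sample(c("AI", "NS", "ET"), n, replace = TRUE,
                    prob = c(0.85, 0.12, 0.03))

  repro <- data.frame(
    herd_id = herd, animal_id = animal,
    birth_date = birth, last_insemination_date = insem,
    calving_date = calving, service_type = service,
    stringsAsFactors = FALSE
  )

  # daily milkings
  dims <- seq_len(config$max_dim)
  n_days <- length(dims)
  milk_list <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- if (config$missing_day_prob > 0)
      stats::runif(n_days) >= config$missing_day_prob else rep(TRUE, n_days)
    t_i <- dims[keep]
    y <- milkbot_yield(list(a = a[i], b = b[i], c = cc[i], d = d[i]), t_i)
    if (config$noise_sd_kg > 0)
      y <- y + stats::rnorm(length(t_i), 0, config$noise_sd_kg)
    y <- pmin(pmax(y, config$milk_range[1]), config$milk_range[2])
    milk_list[[i]] <- data.frame(
      herd_id = herd[i], animal_id = animal[i],
      dim = t_i, milk_kg = y, stringsAsFactors = FALSE)
  }
  milkings <- do.call(rbind, milk_list)
  rownames(milkings) <- NULL

  animals <- data.frame(
    animal_id = animal, herd_id = herd,
    gl = gl, gl_days = gl_days, category = as.character(category),
    a = a, b = b, c = cc, d = d,
    herd_effect = unname(herd_eff[herd]),
    afc = afc, stringsAsFactors = FALSE
  )
  traits <- do.call(rbind, lapply(seq_len(n), function(i)
    milkbot_traits(list(a = a[i], b = b[i], c = cc[i], d = d[i]))))
  animals <- cbind(animals, traits)

  cat_means <- stats::aggregate(
    animals[c("m305", "t_peak", "peak_yield")],
    by = list(category = animals$category), FUN = mean)

  structure(list(
    milkings = milkings, repro = repro,
    truth = list(animals = animals, herd_effects = herd_eff,
                 category_trait_means = cat_means),
    config = config
  ), class = "sim_cohort")
}

#' Simulate a per-animal trait table directly
#'
#' Lightweight generator for mixed-model studies: skips curve generation
#' and fitting, drawing one trait value per animal as
#' category mean + herd effect + residual. Categories follow the given
#' shares; month/year/AFC structure is attached so the full model formula
#' is exercised.
#'
#' @param n_herds,animals_per_herd cohort dimensions (herd sizes fixed, not
#'   random).
#' @param category_means named trait means per category; the defaults are
#'   the closed-form 305-day yields of the
#'   \code{\link{default_category_params}} means at the default offset
#'   (2.5 d), in kg.
#' @param category_shares multinomial category probabilities.
#' @param herd_sd,residual_sd variance components of the trait.
#' @param trait name for the trait column.
#' @return data.frame ready for \code{\link{fit_trait_model}}, plus a
#'   \code{"truth"} attribute with the generating means.
#' @export
simulate_trait_table <- function(n_herds = 50, animals_per_herd = 40,
                                 category_means = c(
                                   "C-I" = 7496.1, "C-II" = 7747.1,
                                   "C-III" = 8068.4, "C-IV" = 8153.0,
                                   "C-V" = 8176.4),
                                 category_shares = c(0.01, 0.04, 0.20, 0.50, 0.25),
                                 herd_sd = 400, residual_sd = 800,
                                 trait = "m305") {
  n <- n_herds * animals_per_herd
  herd <- rep(sprintf("H%03d", seq_len(n_herds)), each = animals_per_herd)
  herd_eff <- stats::rnorm(n_herds, 0, herd_sd)
  category <- sample(names(category_means), n, replace = TRUE,
                     prob = category_shares)
  y <- category_means[category] + herd_eff[match(herd, unique(herd))] +
    stats::rnorm(n, 0, residual_sd)
  out <- data.frame(
    animal_id = sprintf("A%05d", seq_len(n)), herd_id = herd,
    category = factor(category, levels = names(category_means)),
    calving_month = sample(1:12, n, replace = TRUE),
    calving_year = sample(2013:2018, n, replace = TRUE),
    afc = round(stats::rnorm(n, 730, 60)),
    stringsAsFactors = FALSE
  )
  out[[trait]] <- unname(y)
  attr(out, "truth") <- list(category_means = category_means,
                             herd_sd = herd_sd, residual_sd = residual_sd)
  out
}

#' Built-in deterministic fixtures
#'
#' Small hand-checkable datasets for tests and examples:
#' \describe{
#'   \item{"tiny"}{3 herds x 4 animals, 60 days in milk, noise 1 kg --
#'     a seconds-scale end-to-end smoke cohort.}
#'   \item{"filters"}{3 clean milking rows plus exactly one violation of
#'     each validity rule (yield below 1 kg, yield above 70 kg,
#'     DIM above 305).}
#'   \item{"five-categories"}{5 animals whose gestation lengths map
#'     one-to-one onto C-I..C-V under the fixed scheme.}
#' }
#'
#' @param name fixture name.
#' @return For "tiny", a \code{sim_cohort}; otherwise a list of data.frames.
#' @export
make_fixture <- function(name) {
  registered <- c("tiny", "filters", "five-categories")
  if (!name %in% registered)
    stop("unknown fixture '", name, "'; available: ",
         paste(registered, collapse = ", "))
  switch(name,
    tiny = simulate_cohort(sim_config(
      n_herds = 3, animals_per_herd = 10, max_dim = 150,
      noise_sd_kg = 1.0, calving_years = c(2016, 2016),
      calving_months = 6, seed = 42L)),
    filters = {
      clean <- data.frame(
        herd_id = "H1", animal_id = c("A1", "A1", "A2"),
        dim = c(10L, 11L, 50L), milk_kg = c(25.0, 1.0, 70.0),
        stringsAsFactors = FALSE)
      bad <- data.frame(
        herd_id = "H1", animal_id = c("A1", "A2", "A2"),
        dim = c(12L, 51L, 306L), milk_kg = c(0.5, 70.5, 30.0),
        stringsAsFactors = FALSE)
      list(milkings = rbind(clean, bad))
    },
    `five-categories` = {
      gl <- c(200L, 250L, 270L, 280L, 290L)
      calving <- as.Date("2016-06-01") + seq(0, 120, 30)
      list(repro = data.frame(
        herd_id = "H1", animal_id = paste0("A", 1:5),
        birth_date = calving - 730L,
        last_insemination_date = calving - gl,
        calving_date = calving,
        service_type = "AI", stringsAsFactors = FALSE))
    })
}
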