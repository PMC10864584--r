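# Multi-level mixed-model comparison of derived lactation traits across
# gestation-length categories: per trait, a linear mixed model with a random
# herd intercept and fixed calving month, calving year, GL category and an
# age-at-first-calving covariate, fitted by REML (lme4). LS-means and all
# pairwise category contrasts come from emmeans; by default p-values use the
# large-sample normal reference (cohorts are in the thousands), with a
# Satterthwaite option. The compact letter display uses the insert-absorb
# algorithm with alphabetical, insertion-ordered letters.

#' Fit the trait mixed model
#'
#' Model: \code{trait ~ category + calving_month + calving_year + afc +
#' (1 | herd_id)}, REML. Fixed-effect factors that are constant in the data
#' are dropped (with a message) so small or simulated cohorts without
#' calendar variation remain fittable. With a single herd the random
#' intercept is dropped and an ordinary linear model is fitted, with a
#' warning.
#'
#' @param trait_table data.frame with columns \code{herd_id},
#'   \code{category}, \code{calving_month}, \code{calving_year}, \code{afc}
#'   and the trait columns.
#' @param trait name of the trait column to model.
#' @return A list of class \code{"trait_model"}: \code{fit} (a
#'   \code{merMod} or \code{lm}), \code{trait}, \code{formula},
#'   \code{dropped_terms}, and \code{varcomp} (herd and residual SDs;
#'   herd SD \code{NA} for the single-herd fallback).
#' @export
fit_trait_model <- function(trait_table, trait) {
  stopifnot(trait %in% names(trait_table))
  tt <- trait_table
  tt$.y <- tt[[trait]]
  if (anyNA(tt$.y)) stop("missing values in trait '", trait, "'")
  tt$category <- factor(tt$category)
  tt$calving_month <- factor(tt$calving_month)
  tt$calving_year <- factor(tt$calving_year)
  if (nlevels(tt$category) < 2)
    stop("need at least 2 gestation-length categories, got ",
         nlevels(tt$category))

  terms <- c("category", "calving_month", "calving_year", "afc")
  constant <- vapply(terms, function(tm) length(unique(tt[[tm]])) < 2, logical(1))
  dropped <- terms[constant]
  if (length(dropped))
    message("dropping constant term(s): ", paste(dropped, collapse = ", "))
  fixed <- paste(terms[!constant], collapse = " + ")

  # identifiability checks up front: a rank-deficient fixed design means
  # collinear calendar/category terms; too few rows leave no residual df
  X <- stats::model.matrix(stats::as.formula(paste("~", fixed)), data = tt)
  if (qr(X)$rank < ncol(X)) {
    aliased <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("fixed-effect design is rank deficient (collinear: ",
         paste(aliased, collapse = ", "), ") for trait '", trait, "'")
  }
  if (nrow(tt) <= ncol(X) + 1)
    stop("too few rows (", nrow(tt), ") for ", ncol(X),
         " fixed-effect coefficients in trait '", trait, "'")

  n_herds <- length(unique(tt$herd_id))
  if (n_herds >= 2) {
    fml <- stats::as.formula(paste(".y ~", fixed, "+ (1 | herd_id)"))
    fit <- lme4::lmer(fml, data = tt, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- c(herd_sd = vc$sdcor[vc$grp == "herd_id"],
                 residual_sd = vc$sdcor[vc$grp == "Residual"])
  } else {
    warning("single herd: fitting a fixed-effects model without the herd ",
            "random intercept")
    fml <- stats::as.formula(paste(".y ~", fixed))
    fit <- stats::lm(fml, data = tt)
    varcomp <- c(herd_sd = NA_real_, residual_sd = stats::sigma(fit))
  }
  structure(list(fit = fit, trait = trait, formula = fml,
                 dropped_terms = dropped, varcomp = varcomp,
                 data = tt),
            class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat("Trait model for '", x$trait, "': ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  herd SD = %s, residual SD = %.4g\n",
              if (is.na(x$varcomp["herd_sd"])) "NA (single herd)"
              else format(x$varcomp["herd_sd"], digits = 4),
              x$varcomp["residual_sd"]))
  invisible(x)
}

emm_for <- function(model, factor_name, df_method) {
  if (!factor_name %in% all.vars(model$formula))
    stop("factor '", factor_name, "' is not in the model")
  if (inherits(model$fit, "merMod")) {
    emmeans::emmeans(model$fit, specs = factor_name, data = model$data,
                     lmer.df = df_method)
  } else {
    emmeans::emmeans(model$fit, specs = factor_name, data = model$data)
  }
}

#' Least-squares (estimated marginal) means per category
#'
#' Category means adjusted to equal weights over calving month and year and
#' to the sample mean of the age-at-first-calving covariate, with standard
#' errors from the fixed-effects covariance.
#'
#' @param model a \code{\link{fit_trait_model}} result.
#' @param factor_name factor whose levels are summarized.
#' @param df_method \code{"asymptotic"} (normal reference, default) or
#'   \code{"satterthwaite"}.
#' @return data.frame with \code{level}, \code{ls_mean}, \code{se}.
#' @export
ls_means <- function(model, factor_name = "category",
                     df_method = c("asymptotic", "satterthwaite")) {
  df_method <- match.arg(df_method)
  emm <- emm_for(model, factor_name, df_method)
  s <- as.data.frame(summary(emm))
  data.frame(level = as.character(s[[factor_name]]),
             ls_mean = s$emmean, se = s$SE, stringsAsFactors = FALSE)
}

#' All pairwise category contrasts
#'
#' Differences of LS-means for every level pair, unadjusted for
#' multiplicity by default (a Tukey adjustment is available).
#'
#' @inheritParams ls_means
#' @param adjust multiplicity adjustment passed to emmeans
#'   (default \code{"none"}).
#' @return data.frame with \code{level_1}, \code{level_2},
#'   \code{estimate} (mean of level_1 minus mean of level_2), \code{se},
#'   \code{p_value}, \code{classification}
#'   (\code{significant}/\code{tendency}/\code{none}).
#' @export
pairwise_contrasts <- function(model, factor_name = "category",
                               df_method = c("asymptotic", "satterthwaite"),
                               adjust = "none") {
  df_method <- match.arg(df_method)
  emm <- emm_for(model, factor_name, df_method)
  s <- as.data.frame(summary(emmeans::contrast(emm, method = "pairwise",
                                               adjust = adjust)))
  sides <- strsplit(as.character(s$contrast), " - ", fixed = TRUE)
  out <- data.frame(
    level_1 = vapply(sides, `[`, "", 1),
    level_2 = vapply(sides, `[`, "", 2),
    estimate = s$estimate, se = s$SE, p_value = s$p.value,
    stringsAsFactors = FALSE
  )
  # emmeans protects factor levels containing "-" by wrapping in parentheses
  out$level_1 <- gsub("^\\(|\\)$", "", out$level_1)
  out$level_2 <- gsub("^\\(|\\)$", "", out$level_2)
  out$classification <- classify_significance(out$p_value)
  out
}

#' Classify a p-value as significant, tendency or none
#'
#' Significance at \eqn{p < 0.05}; a tendency at \eqn{0.05 \le p < 0.10}
#' (the boundary 0.05 counts as a tendency, not significance).
#'
#' @param p p-value(s) in [0, 1].
#' @return character vector: \code{"significant"}, \code{"tendency"} or
#'   \code{"none"}.
#' @export
classify_significance <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  ifelse(p < 0.05, "significant", ifelse(p < 0.10, "tendency", "none"))
}

#' Compact letter display
#'
#' Assigns superscript letters to factor levels so that two levels share a
#' letter exactly when their pairwise difference is non-significant at
#' \code{alpha} (insert-absorb algorithm; letters in insertion order,
#' alphabetical).
#'
#' @param contrasts data.frame as returned by
#'   \code{\link{pairwise_contrasts}} (needs \code{level_1},
#'   \code{level_2}, \code{p_value}).
#' @param levels the level names in display order; defaults to the sorted
#'   union of the contrast levels.
#' @param alpha significance threshold.
#' @return Named character vector of letter strings, one per level.
#' @examples
#' ctr <- data.frame(level_1 = "A", level_2 = "B", p_value = 0.20)
#' compact_letter_display(ctr, levels = c("A", "B"))
#' @export
compact_letter_display <- function(contrasts, levels = NULL, alpha = 0.05) {
  if (is.null(levels))
    levels <- sort(unique(c(contrasts$level_1, contrasts$level_2)))
  k <- length(levels)
  # significance matrix: TRUE where the pair differs
  signif_mat <- matrix(FALSE, k, k, dimnames = list(levels, levels))
  for (i in seq_len(nrow(contrasts))) {
    l1 <- contrasts$level_1[i]; l2 <- contrasts$level_2[i]
    if (!(l1 %in% levels && l2 %in% levels)) next
    s <- isTRUE(contrasts$p_value[i] < alpha)
    signif_mat[l1, l2] <- s
    signif_mat[l2, l1] <- s
  }
  # insert-absorb: split every group containing a significant pair, then
  # drop groups contained in (or duplicating) another; the surviving groups
  # are the maximal mutually-non-significant sets
  absorb <- function(groups) {
    groups <- groups[order(-lengths(groups))]
    keep <- rep(TRUE, length(groups))
    for (u in seq_along(groups)) {
      if (!keep[u]) next
      for (v in seq_along(groups)) {
        if (v != u && keep[v] && all(groups[[v]] %in% groups[[u]]))
          keep[v] <- FALSE
      }
    }
    groups[keep]
  }
  groups <- list(seq_len(k))
  if (k > 1) for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (!signif_mat[i, j]) next
    hit <- vapply(groups, function(g) i %in% g && j %in% g, logical(1))
    if (!any(hit)) next
    split_groups <- unlist(lapply(groups[hit], function(g)
      list(setdiff(g, i), setdiff(g, j))), recursive = FALSE)
    groups <- absorb(c(groups[!hit], split_groups))
  }
  # order groups by their smallest member for insertion-order letters
  groups <- groups[order(vapply(groups, min, 0))]
  letter_of <- letters[seq_along(groups)]
  out <- vapply(seq_len(k), function(ix) {
    paste0(letter_of[vapply(groups, function(g) ix %in% g, logical(1))],
           collapse = "")
  }, "")
  stats::setNames(out, levels)
}

#' Compare trait LS-means across gestation-length categories
#'
#' Runs the full comparison for each requested trait: mixed-model fit,
#' LS-means, pairwise contrasts with significance classes, and compact
#' letter displays.
#'
#' @inheritParams fit_trait_model
#' @param traits trait column names (default the six standard lactation
#'   traits).
#' @param df_method,adjust passed through to the contrast machinery.
#' @return A list of class \code{"category_comparison"}: \code{comparison}
#'   (data.frame: trait, category, n, ls_mean, se, letters),
#'   \code{contrasts} (data.frame: trait + pairwise results), and
#'   \code{models} (named list of \code{\link{fit_trait_model}} objects).
#' @export
compare_categories <- function(trait_table,
                               traits = c("m305", "a", "b", "d",
                                          "t_peak", "peak_yield"),
                               df_method = c("asymptotic", "satterthwaite"),
                               adjust = "none") {
  df_method <- match.arg(df_method)
  traits <- intersect(traits, names(trait_table))
  if (!length(traits)) stop("no trait columns found in 'trait_table'")
  counts <- table(factor(trait_table$category))
  comp_rows <- list(); ctr_rows <- list(); models <- list()
  for (tr in traits) {
    tt <- trait_table[!is.na(trait_table[[tr]]), , drop = FALSE]
    if (nrow(tt) < nrow(trait_table))
      message(nrow(trait_table) - nrow(tt), " row(s) with missing '", tr,
              "' excluded from that trait's model")
    m <- fit_trait_model(tt, tr)
    lsm <- ls_means(m, df_method = df_method)
    ctr <- pairwise_contrasts(m, df_method = df_method, adjust = adjust)
    letters <- compact_letter_display(ctr, levels = lsm$level)
    comp_rows[[tr]] <- data.frame(
      trait = tr, category = lsm$level,
      n = as.integer(counts[lsm$level]),
      ls_mean = lsm$ls_mean, se = lsm$se,
      letters = letters[lsm$level], stringsAsFactors = FALSE)
    ctr_rows[[tr]] <- cbind(trait = tr, ctr)
    models[[tr]] <- m
  }
  comparison <- do.call(rbind, comp_rows); rownames(comparison) <- NULL
  contrasts <- do.call(rbind, ctr_rows); rownames(contrasts) <- NULL
  structure(list(comparison = comparison, contrasts = contrasts,
                 models = models),
            class = "category_comparison")
}

#' @export
print.category_comparison <- function(x, ...) {
  cat(render_comparison_table(x), sep = "\n")
  invisible(x)
}
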