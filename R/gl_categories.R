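# Gestation-length (GL) categorization. A cohort is split into five ordered
# categories C-I..C-V by four GL cut-points, either empirical quantiles of
# the cohort (probabilities 0.01, 0.05, 0.25, 0.75, giving nominal shares
# 1/4/20/50/25%) or a fixed reference scheme. Interval convention:
# lower-exclusive / upper-inclusive, with C-I additionally closed at the
# lower bound of the plausible GL window.

GL_LABELS <- c("C-I", "C-II", "C-III", "C-IV", "C-V")

#' Gestation-length category scheme
#'
#' @param cutpoints four non-decreasing GL cut-points in days
#'   (the upper bounds of C-I..C-IV).
#' @param source \code{"data-quantiles"} or \code{"fixed"}.
#' @param range admissible GL window, days.
#' @param probs the quantile probabilities behind a data-driven scheme
#'   (kept for provenance).
#' @return An object of class \code{"gl_scheme"}.
#' @export
gl_scheme <- function(cutpoints, source = c("fixed", "data-quantiles"),
                      range = c(150, 297), probs = NULL) {
  source <- match.arg(source)
  if (length(cutpoints) != 4) stop("exactly four cutpoints required")
  if (is.unsorted(cutpoints)) stop("cutpoints must be non-decreasing")
  if (any(cutpoints < range[1] | cutpoints > range[2]))
    stop("cutpoints must lie within [", range[1], ", ", range[2], "]")
  structure(list(cutpoints = as.numeric(cutpoints), labels = GL_LABELS,
                 source = source, range = range, probs = probs),
            class = "gl_scheme")
}

#' @export
print.gl_scheme <- function(x, ...) {
  cp <- x$cutpoints
  bounds <- c(x$range[1], cp, x$range[2])
  cat("GL category scheme (", x$source, "):\n", sep = "")
  for (i in seq_along(x$labels))
    cat(sprintf("  %-6s %s%g, %g]\n", x$labels[i],
                if (i == 1) "[" else "(", bounds[i], bounds[i + 1]))
  invisible(x)
}

#' Fixed five-category gestation-length scheme
#'
#' The reference categorization for Holstein primiparous cohorts:
#' cut-points 243, 267, 275, 283 days, i.e. C-I 150--243, C-II 244--267,
#' C-III 268--275, C-IV 276--283, C-V 284--297 (upper-inclusive).
#'
#' @return A \code{\link{gl_scheme}} with \code{source = "fixed"}.
#' @export
gl_scheme_fixed <- function() {
  gl_scheme(c(243, 267, 275, 283), source = "fixed")
}

#' Empirical quantile cut-points for GL categorization
#'
#' Computes cohort quantiles by linear interpolation of the empirical CDF
#' (the common type-7 convention). Cut-points are left unrounded by default:
#' GL distributions place several percent of the cohort on single modal
#' days, so rounding a cut-point to a whole day can move a category share
#' by that amount; \code{round = "floor"} is available where whole-day
#' cut-points are required.
#'
#' @param gl_values gestation lengths in days, all within \code{range}.
#' @param probs quantile probabilities (defaults give nominal category
#'   shares 1/4/20/50/25\%).
#' @param round \code{"none"} (default) or \code{"floor"}.
#' @param range admissible GL window.
#' @return A \code{\link{gl_scheme}} with \code{source = "data-quantiles"}.
#' @export
gl_quantile_scheme <- function(gl_values, probs = c(0.01, 0.05, 0.25, 0.75),
                               round = c("none", "floor"),
                               range = c(150, 297)) {
  round <- match.arg(round)
  if (length(gl_values) == 0) stop("'gl_values' is empty")
  if (any(probs <= 0 | probs >= 1)) stop("'probs' must lie strictly in (0, 1)")
  if (any(gl_values < range[1] | gl_values > range[2]))
    stop("GL values outside [", range[1], ", ", range[2], "]")
  cp <- stats::quantile(gl_values, probs = probs, type = 7, names = FALSE)
  if (round == "floor") cp <- floor(cp)
  gl_scheme(cp, source = "data-quantiles", range = range, probs = probs)
}

#' Assign gestation lengths to categories
#'
#' Interval membership with lower-exclusive / upper-inclusive boundaries:
#' a GL equal to a cut-point belongs to the lower category.
#'
#' @param gl gestation length(s), days.
#' @param scheme a \code{\link{gl_scheme}}.
#' @return Ordered factor with levels C-I..C-V.
#' @examples
#' s <- gl_scheme_fixed()
#' assign_gl_category(c(243, 244, 297), s)
#' @export
assign_gl_category <- function(gl, scheme = gl_scheme_fixed()) {
  stopifnot(inherits(scheme, "gl_scheme"))
  if (any(gl < scheme$range[1] | gl > scheme$range[2]))
    stop("GL outside [", scheme$range[1], ", ", scheme$range[2],
         "]; such records must be excluded upstream")
  breaks <- c(scheme$range[1] - 1e-9, scheme$cutpoints, scheme$range[2])
  cut(gl, breaks = breaks, labels = scheme$labels,
      right = TRUE, ordered_result = TRUE)
}

#' Categorize a cohort of lactations
#'
#' Annotates each lactation with its GL category and tallies category
#' counts. With \code{scheme = NULL} the quantile scheme is first computed
#' from this same cohort's \code{gl_days}.
#'
#' @param lactations data.frame with a \code{gl_days} column.
#' @param scheme a \code{\link{gl_scheme}}, or \code{NULL} for
#'   data-quantiles.
#' @param probs passed to \code{\link{gl_quantile_scheme}} when
#'   \code{scheme} is \code{NULL}.
#' @return A list with \code{lactations} (input plus \code{category}),
#'   \code{counts} (named integer vector over all five labels) and
#'   \code{scheme}.
#' @export
categorize_cohort <- function(lactations, scheme = NULL,
                              probs = c(0.01, 0.05, 0.25, 0.75)) {
  if (nrow(lactations) == 0) {
    if (is.null(scheme)) scheme <- gl_scheme_fixed()
    lactations$category <- factor(character(), levels = GL_LABELS, ordered = TRUE)
    counts <- table(lactations$category)
    return(list(lactations = lactations,
                counts = stats::setNames(as.integer(counts), names(counts)),
                scheme = scheme))
  }
  if (is.null(scheme))
    scheme <- gl_quantile_scheme(lactations$gl_days, probs = probs)
  lactations$category <- assign_gl_category(lactations$gl_days, scheme)
  counts <- table(lactations$category)
  list(lactations = lactations,
       counts = stats::setNames(as.integer(counts), names(counts)),
       scheme = scheme)
}
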