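# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks: quadrature instead of the closed-form integral,
# grid/golden-section argmax instead of the stationary-point formula,
# subset enumeration instead of insert-absorb, explicit matrix algebra
# instead of emmeans.

# adaptive quadrature of the raw curve
oracle_cumulative <- function(params, t_end) {
  stats::integrate(function(t) milkbot_yield(params, t), 0, t_end,
                   rel.tol = 1e-12, abs.tol = 1e-10)$value
}

# numeric argmax of the curve on [0, 305]
oracle_peak <- function(params) {
  o <- stats::optimize(function(t) milkbot_yield(params, t),
                       interval = c(0, 305), maximum = TRUE, tol = 1e-10)
  list(t_peak = o$maximum, peak = o$objective)
}

# random admissible parameter draws over the biologically plausible box
draw_params <- function(n) {
  data.frame(
    a = runif(n, 15, 55), b = runif(n, 10, 60),
    c = runif(n, -10, 15), d = runif(n, 1e-4, 5e-3)
  )
}

# type-7 quantile by the textbook order-statistic formula, no stats::quantile
oracle_quantile_type7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[pmin(lo + 1, length(x))] - x[lo])
}

# brute-force compact-letter groups: all maximal subsets of mutually
# non-significant levels, by subset enumeration
oracle_letter_groups <- function(levels, signif_pairs) {
  k <- length(levels)
  ns <- function(i, j) {
    !any(vapply(signif_pairs, function(p)
      setequal(p, c(levels[i], levels[j])), logical(1)))
  }
  subsets <- lapply(seq_len(2^k - 1), function(m) which(bitwAnd(m, 2^(0:(k - 1))) > 0))
  ok <- vapply(subsets, function(s) {
    all(apply(utils::combn(c(s, s[1]), 2), 2, function(p)
      p[1] == p[2] || ns(p[1], p[2])))
  }, logical(1))
  cand <- subsets[ok]
  maximal <- cand[vapply(seq_along(cand), function(i) {
    !any(vapply(seq_along(cand), function(j)
      j != i && all(cand[[i]] %in% cand[[j]]), logical(1)))
  }, logical(1))]
  lapply(maximal, function(s) levels[s])
}

# letters -> partition check: two levels share a letter iff they are in a
# common maximal non-significant group
letters_consistent <- function(letters, groups, levels) {
  share_letter <- outer(seq_along(levels), seq_along(levels),
                        Vectorize(function(i, j) {
    any(strsplit(letters[i], "")[[1]] %in% strsplit(letters[j], "")[[1]])
  }))
  share_group <- outer(seq_along(levels), seq_along(levels),
                       Vectorize(function(i, j) {
    any(vapply(groups, function(g)
      levels[i] %in% g && levels[j] %in% g, logical(1)))
  }))
  identical(share_letter, share_group)
}

# generalized least squares at fixed variance components, for a random
# herd-intercept model: V = sigma_h^2 Z Z' + sigma_e^2 I
oracle_gls <- function(X, y, herd, sd_herd, sd_res) {
  Z <- stats::model.matrix(~ 0 + factor(herd))
  V <- sd_herd^2 * tcrossprod(Z) + diag(sd_res^2, length(y))
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  beta <- solve(XtVi %*% X, XtVi %*% y)
  drop(beta)
}

sim_trait_fixture <- function(seed, ...) {
  set.seed(seed)
  simulate_trait_table(...)
}
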