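# Mixed-model trait comparison: LS-means, contrasts, significance classes
# and compact letter displays.

balanced_table <- function(mu, n_per = 20, herds = 4, resid_sd = 0,
                           seed = 1) {
  set.seed(seed)
  k <- length(mu)
  n <- n_per * k
  data.frame(
    animal_id = seq_len(n),
    herd_id = rep(sprintf("H%d", seq_len(herds)), length.out = n),
    category = factor(rep(names(mu), each = n_per)),
    calving_month = 6L, calving_year = 2016L, afc = 730,
    m305 = rep(unname(mu), each = n_per) + rnorm(n, 0, resid_sd))
}

test_that("in the OLS limit LS-means equal raw category means", {
  mu <- c("C-I" = 7000, "C-III" = 8000, "C-V" = 8100)
  tab <- balanced_table(mu, resid_sd = 50)
  m <- suppressMessages(fit_trait_model(tab, "m305"))
  lsm <- ls_means(m)
  raw <- tapply(tab$m305, tab$category, mean)
  expect_equal(lsm$ls_mean, as.numeric(raw[lsm$level]), tolerance = 1e-6)
})

test_that("fixed effects match a GLS oracle at the estimated components", {
  set.seed(31)
  tab <- simulate_trait_table(n_herds = 3, animals_per_herd = 7,
                              category_shares = c(0.2, 0.2, 0.2, 0.2, 0.2),
                              herd_sd = 300, residual_sd = 500)
  tab$calving_month <- 6L; tab$calving_year <- 2016L  # isolate the herd term
  m <- suppressMessages(fit_trait_model(tab, "m305"))
  vc <- m$varcomp
  X <- stats::model.matrix(~ category + afc, data = m$data)
  beta_gls <- oracle_gls(X, m$data$.y, m$data$herd_id,
                         vc["herd_sd"], vc["residual_sd"])
  beta_fit <- lme4::fixef(m$fit)
  expect_equal(unname(beta_fit), unname(beta_gls), tolerance = 1e-6)
})

test_that("REML recovers known variance components", {
  set.seed(32)
  tab <- simulate_trait_table(n_herds = 200, animals_per_herd = 10,
                              category_shares = c(0.2, 0.2, 0.2, 0.2, 0.2),
                              herd_sd = 400, residual_sd = 800)
  m <- fit_trait_model(tab, "m305")
  expect_lt(abs(m$varcomp["herd_sd"] / 400 - 1), 0.15)
  expect_lt(abs(m$varcomp["residual_sd"] / 800 - 1), 0.15)
})

test_that("LS-means equal explicit linear combinations of coefficients", {
  set.seed(33)
  tab <- balanced_table(c(A = 100, B = 110), n_per = 15, resid_sd = 5)
  tab$afc <- round(rnorm(30, 730, 40))
  m <- suppressMessages(fit_trait_model(tab, "m305"))
  lsm <- ls_means(m)
  # model is .y ~ category + afc (+ herd intercept); LS-mean of level B is
  # (Intercept) + categoryB + mean(afc) * beta_afc
  beta <- lme4::fixef(m$fit)
  V <- as.matrix(stats::vcov(m$fit))
  L_A <- c(1, 0, mean(tab$afc))
  L_B <- c(1, 1, mean(tab$afc))
  expect_equal(lsm$ls_mean[lsm$level == "A"], sum(L_A * beta), tolerance = 1e-8)
  expect_equal(lsm$ls_mean[lsm$level == "B"], sum(L_B * beta), tolerance = 1e-8)
  expect_equal(lsm$se[lsm$level == "B"],
               sqrt(drop(t(L_B) %*% V %*% L_B)), tolerance = 1e-6)
})

test_that("LS-means are invariant to recentring the AFC covariate", {
  set.seed(34)
  tab <- simulate_trait_table(n_herds = 5, animals_per_herd = 30,
                              category_shares = rep(0.2, 5))
  m1 <- fit_trait_model(tab, "m305")
  tab2 <- tab; tab2$afc <- tab2$afc + 100
  m2 <- fit_trait_model(tab2, "m305")
  expect_equal(ls_means(m1)$ls_mean, ls_means(m2)$ls_mean, tolerance = 1e-6)
})

test_that("single-herd data falls back to a fixed-effects model", {
  tab <- balanced_table(c(A = 100, B = 120), herds = 1, resid_sd = 4)
  expect_warning(m <- suppressMessages(fit_trait_model(tab, "m305")),
                 "single herd")
  expect_s3_class(m$fit, "lm")
  expect_true(is.na(m$varcomp["herd_sd"]))
  expect_equal(nrow(ls_means(m)), 2)
})

test_that("p-value classification uses the 0.05/0.10 bands", {
  expect_equal(classify_significance(c(0.04, 0.07, 0.05, 0.2, 0.0999)),
               c("significant", "tendency", "tendency", "none", "tendency"))
  expect_error(classify_significance(-0.1), "0, 1")
  expect_error(classify_significance(1.1), "0, 1")
})

test_that("pairwise contrasts cover all pairs and classify significance", {
  set.seed(35)
  tab <- simulate_trait_table(n_herds = 10, animals_per_herd = 40,
                              category_shares = rep(0.2, 5))
  m <- fit_trait_model(tab, "m305")
  ctr <- pairwise_contrasts(m)
  expect_equal(nrow(ctr), choose(5, 2))
  expect_setequal(ctr$classification[ctr$p_value < 0.05], "significant")
  # estimates are differences of LS-means
  lsm <- ls_means(m)
  for (i in seq_len(nrow(ctr))) {
    expect_equal(ctr$estimate[i],
                 lsm$ls_mean[lsm$level == ctr$level_1[i]] -
                   lsm$ls_mean[lsm$level == ctr$level_2[i]],
                 tolerance = 1e-8)
  }
})

test_that("compact letters reproduce canonical patterns", {
  mk <- function(l1, l2, p) data.frame(level_1 = l1, level_2 = l2, p_value = p)
  lv5 <- c("C-I", "C-II", "C-III", "C-IV", "C-V")

  # all non-significant: everyone shares a single letter
  pairs5 <- t(combn(lv5, 2))
  all_ns <- mk(pairs5[, 1], pairs5[, 2], 0.5)
  expect_equal(unname(compact_letter_display(all_ns, lv5)), rep("a", 5))

  # {C-I, C-II} vs {C-III, C-IV, C-V}: the two-block pattern
  block <- ifelse(pairs5[, 1] %in% lv5[1:2] == pairs5[, 2] %in% lv5[1:2],
                  0.5, 0.001)
  two_block <- mk(pairs5[, 1], pairs5[, 2], block)
  expect_equal(unname(compact_letter_display(two_block, lv5)),
               c("a", "a", "b", "b", "b"))

  # chain A != C, A = B, B = C: the middle level bridges both letters
  chain <- mk(c("A", "A", "B"), c("B", "C", "C"), c(0.5, 0.01, 0.5))
  expect_equal(unname(compact_letter_display(chain, c("A", "B", "C"))),
               c("a", "ab", "b"))
})

test_that("letter displays agree with brute-force maximal groups", {
  set.seed(36)
  for (rep_i in 1:25) {
    k <- sample(3:5, 1)
    lv <- LETTERS[1:k]
    pairs_m <- t(combn(lv, 2))
    p <- ifelse(runif(nrow(pairs_m)) < 0.4, 0.01, 0.5)
    ctr <- data.frame(level_1 = pairs_m[, 1], level_2 = pairs_m[, 2],
                      p_value = p)
    letters_got <- compact_letter_display(ctr, lv)
    sig_pairs <- lapply(which(p < 0.05), function(i) pairs_m[i, ])
    groups <- oracle_letter_groups(lv, sig_pairs)
    expect_true(letters_consistent(unname(letters_got), groups, lv),
                info = paste("rep", rep_i))
  }
})

test_that("compare_categories assembles the full trait comparison", {
  set.seed(37)
  tab <- simulate_trait_table(n_herds = 8, animals_per_herd = 30,
                              category_shares = rep(0.2, 5))
  tab$peak_yield <- tab$m305 / 270 + rnorm(nrow(tab), 0, 1)
  cmp <- compare_categories(tab, traits = c("m305", "peak_yield"))
  expect_s3_class(cmp, "category_comparison")
  expect_equal(nrow(cmp$comparison), 10)  # 2 traits x 5 categories
  expect_equal(nrow(cmp$contrasts), 20)   # 2 traits x 10 pairs
  expect_true(all(cmp$comparison$n > 0))
  expect_error(compare_categories(tab, traits = "nonexistent"), "no trait")
})
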