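test_that("parameter counts reproduce the five model families", {
  expect_identical(count_parameters("hodina", I = 37, K = 3), 80L)
  expect_identical(count_parameters("ie-g", I = 37, K = 3, M = 8), 52L)
  expect_identical(count_parameters("ie-g-r", I = 37, K = 3, M = 8), 53L)
  expect_identical(count_parameters("ie-s", I = 37, K = 3, M = 8), 52L)
  expect_identical(count_parameters("ie-s-r", I = 37, K = 3, M = 8), 53L)
  expect_error(count_parameters("ie-g", I = 37, K = 3), "feature count")
})

test_that("Wald tests flag coefficients at the 0.05 level", {
  w0 <- wald_test(0, 1)
  expect_equal(w0$p, 1)
  expect_false(w0$significant)
  w1 <- wald_test(-4.76, 2.34)
  expect_equal(abs(w1$z), 2.03, tolerance = 0.01)
  expect_true(w1$significant)
  w2 <- wald_test(0.49, 0.45)
  expect_equal(abs(w2$z), 1.09, tolerance = 0.01)
  expect_false(w2$significant)
  expect_error(wald_test(1, 0), "positive")
})

test_that("PPP is exact on an enumerable toy and calibrated on-model", {
  # one person, two always-guessable items at p = 0.5: every dataset gives
  # discrepancy 2, so replicated >= observed always
  q1 <- matrix(1, 2, 1, dimnames = list(NULL, "A1"))
  fake <- fake_hodina_fit(g = c(0.5, 0.5), s = c(0.49, 0.49), q = q1)
  fake$states <- list(list(zidx = 1L, g = c(0.5, 0.5), s = c(0.49, 0.49)))
  expect_equal(as.numeric(ppp(fake, matrix(c(1, 0), 1, 2), n_rep = 1)), 1)
  # a well-specified fit: PPP not extreme
  fit <- small_hodina_fit()
  dat <- small_dataset()
  p <- ppp(fit, dat$y, n_rep = 200, seed = 7)
  expect_gt(as.numeric(p), 0.05)
  expect_lt(as.numeric(p), 0.95)
  expect_false(attr(p, "flag_bad_fit"))
})

test_that("DIC follows the half-variance penalty convention", {
  expect_equal(as.numeric(dic(rep(100, 50))), 100)  # point mass: pD = 0
  d <- dic(c(10, 14))  # mean 12, sample var 8, pD 4
  expect_equal(as.numeric(d), 16)
  expect_equal(attr(d, "pD"), 4)
  expect_error(dic(5), "at least 2")
})

test_that("the two-step regression matches closed-form OLS", {
  # 6-item toy with one feature: slope = Sxy / Sxx
  zf <- matrix(c(0, 1, 2, 3, 4, 5), 6, 1, dimnames = list(NULL, "Za"))
  lgt <- c(-2.0, -1.6, -1.5, -1.1, -0.8, -0.2)
  fake <- fake_hodina_fit(g = stats::plogis(lgt), s = rep(0.1, 6))
  tab <- two_step(fake, zf, "guessing")
  sxx <- sum((zf - mean(zf))^2)
  sxy <- sum((zf - mean(zf)) * (lgt - mean(lgt)))
  expect_equal(tab$estimate[2], sxy / sxx, tolerance = 1e-12)
  # logits exactly linear in Z: R^2 = 1
  lgt2 <- -2 + 0.4 * zf[, 1]
  fake2 <- fake_hodina_fit(g = stats::plogis(lgt2), s = rep(0.1, 6))
  tab2 <- suppressWarnings(two_step(fake2, zf, "guessing"))
  expect_equal(attr(tab2, "r_squared"), 1, tolerance = 1e-9)
  expect_equal(tab2$estimate[2], 0.4, tolerance = 1e-9)
  # orthogonal feature: slope and R^2 near zero
  set.seed(8)
  zo <- matrix(rep(c(-1, 1), 8), 16, 1)
  lgo <- rep(c(-1.5, -1.5, -1.2, -1.2), 4)
  fake3 <- fake_hodina_fit(g = stats::plogis(lgo), s = rep(0.1, 16))
  tab3 <- two_step(fake3, zo, "guessing")
  expect_equal(tab3$estimate[2], 0, tolerance = 1e-9)
  # collinear features are rejected with a VIF report
  zc <- cbind(a = zf[, 1], b = 2 * zf[, 1])
  expect_error(two_step(fake, zc, "guessing"), "rank deficient")
  # only HO-DINA fits are accepted as step 1
  fake_ie <- fake; fake_ie$model <- "ie-g"
  expect_error(two_step(fake_ie, zf), "HO-DINA")
})

test_that("profile classification takes the modal draw, ties downward", {
  q <- matrix(1, 3, 2); colnames(q) <- c("A1", "A2")
  counts <- rbind(c(100, 0, 0, 0),   # all draws identical
                  c(40, 60, 0, 0),   # 60/40 split
                  c(50, 0, 50, 0))   # exact tie
  fake <- fake_hodina_fit(g = rep(0.2, 3), s = rep(0.2, 3), q = q,
                          profile_counts = counts)
  cls <- classify_profiles(fake)
  expect_equal(cls$profiles[1, ], c(0, 0), ignore_attr = TRUE)
  expect_equal(cls$profiles[2, ], c(0, 1), ignore_attr = TRUE)
  expect_equal(cls$profiles[3, ], c(0, 0), ignore_attr = TRUE)  # lower index
  expect_equal(cls$tied, 3L)
  expect_equal(cls$probability, c(1, 0.6, 0.5))
  expect_equal(cls$marginal[2, ], c(0, 0.6), ignore_attr = TRUE)
})

test_that("consistency measures agreement between fits", {
  q <- matrix(1, 5, 2)
  counts <- cbind(diag(4), 0)[, 1:4] * 100
  counts <- rbind(counts, c(0, 0, 0, 100))
  g <- c(0.1, 0.2, 0.3, 0.25, 0.15); s <- c(0.1, 0.12, 0.08, 0.2, 0.14)
  fa <- fake_hodina_fit(g, s, q = q, profile_counts = counts)
  fa$y_dim <- c(5L, 5L)
  self <- consistency(fa, fa)
  expect_equal(self$cor_g, 1)
  expect_equal(self$profile_consistency, 1)
  # flip two of five persons
  counts_b <- counts[c(2, 1, 3, 4, 5), ]
  fb <- fake_hodina_fit(g, s, q = q, profile_counts = counts_b)
  fb$y_dim <- c(5L, 5L)
  expect_equal(consistency(fa, fb)$profile_consistency, 3 / 5)
  # correlation matches the closed-form Pearson formula on a 5-point toy
  g2 <- c(0.12, 0.18, 0.33, 0.2, 0.19)
  fc <- fake_hodina_fit(g2, s, q = q, profile_counts = counts)
  fc$y_dim <- c(5L, 5L)
  r_hand <- sum((g - mean(g)) * (g2 - mean(g2))) /
    sqrt(sum((g - mean(g))^2) * sum((g2 - mean(g2))^2))
  expect_equal(consistency(fa, fc)$cor_g, r_hand, tolerance = 1e-12)
})

test_that("fit statistics work end to end on a real small fit", {
  fit <- small_hodina_fit()
  d <- dic(fit)
  expect_true(is.finite(d) && attr(d, "pD") > 0)
  expect_equal(nrow(fit$summary),
               count_parameters("hodina", 12, 2) + 0)  # 2I + 2K scalars
})
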