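test_that("truncated Beta draws follow the truncated density", {
  set.seed(1)
  x <- rtrunc_beta(1e5, 4, 8, upper = 0.4)
  expect_true(all(x > 0 & x < 0.4))
  # KS against the analytic truncated CDF
  ptrunc <- function(q) pbeta(q, 4, 8) / pbeta(0.4, 4, 8)
  expect_gt(suppressWarnings(ks.test(x, ptrunc)$p.value), 0.01)
  # counts-based conjugacy: 3 successes of 10 under Beta(1,1) -> Beta(4,8)
  set.seed(2)
  y <- rtrunc_beta(1e5, 1 + 3, 1 + 7, upper = 1)
  expect_gt(suppressWarnings(ks.test(y, function(q) pbeta(q, 4, 8))$p.value),
            0.01)
  # no data: conditional equals the truncated flat prior
  set.seed(3)
  z <- rtrunc_beta(1e5, 1, 1, upper = 0.6)
  expect_gt(suppressWarnings(ks.test(z, function(q) punif(q, 0, 0.6))$p.value),
            0.01)
  expect_error(rtrunc_beta(1, 2, 2, lower = 0.5, upper = 0.4), "empty")
})

test_that("profile conditionals match brute-force enumeration to 1e-12", {
  # 3-item, K = 2 toy with fixed parameters
  q <- rbind(c(1, 0), c(0, 1), c(1, 1))
  g <- c(0.2, 0.25, 0.15); s <- c(0.1, 0.2, 0.12)
  xi <- c(1.2, 0.8); beta <- c(0.3, -0.4); theta <- 0.7
  for (ycase in list(c(1, 0, 1), c(0, 0, 0), c(1, 1, 1))) {
    got <- profile_conditional_probs(ycase, theta, g, s, q, xi, beta)
    # independent enumeration: explicit loops, no package likelihood code
    A <- expand.grid(a2 = 0:1, a1 = 0:1)[, 2:1]  # (00,01,10,11)
    w <- numeric(4)
    for (c in 1:4) {
      a <- as.numeric(A[c, ])
      pr <- 1
      for (i in 1:3) {
        eta <- as.integer(all(a[q[i, ] == 1] == 1))
        p <- if (eta) 1 - s[i] else g[i]
        pr <- pr * (if (ycase[i] == 1) p else 1 - p)
      }
      for (k in 1:2) {
        pk <- 1 / (1 + exp(-(xi[k] * theta + beta[k])))
        pr <- pr * (if (a[k] == 1) pk else 1 - pk)
      }
      w[c] <- pr
    }
    expect_equal(got, w / sum(w), tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("a response pattern only one profile can produce is certain", {
  q <- rbind(c(1, 0), c(0, 1))
  pr <- profile_conditional_probs(c(1, 0), 0, g = c(1e-12, 1e-12),
                                  s = c(1e-12, 1e-12), q,
                                  xi = c(1, 1), beta = c(0, 0))
  expect_equal(pr[3], 1, tolerance = 1e-9)  # profile (1,0)
  # flat prior, symmetric likelihood: equal mass on the consistent profiles
  pr2 <- profile_conditional_probs(c(1, 1), 0, g = c(0.5 - 1e-9, 0.5 - 1e-9),
                                   s = c(0.5 - 1e-9, 0.5 - 1e-9), q,
                                   xi = c(1e-9, 1e-9), beta = c(0, 0))
  expect_equal(as.numeric(pr2), rep(0.25, 4), tolerance = 1e-6)
})

test_that("PSRF separates mixed from unmixed chains", {
  expect_identical(psrf(cbind(1:100, 1:100)), 1)
  set.seed(5)
  good <- cbind(rnorm(5000), rnorm(5000))
  expect_lt(psrf(good), 1.1)
  apart <- cbind(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(psrf(apart), 5)
  expect_error(psrf(cbind(rep(1, 10), rep(2, 10))), "degenerate")
  expect_error(psrf(matrix(1:10, 10, 1)), "2 chains")
})

test_that("conjugate regression update matches the closed form", {
  set.seed(6)
  Zd <- cbind(1, matrix(rnorm(10), 5, 2))
  lg <- c(-2.1, -1.4, -2.6, -1.9, -0.8)
  sigma2 <- 0.3; v0 <- 10
  draws <- t(replicate(20000, iedina:::conj_lm_draw(Zd, lg, sigma2, v0)))
  closed <- solve(crossprod(Zd) / sigma2 + diag(1 / v0, 3),
                  crossprod(Zd, lg) / sigma2)
  expect_equal(colMeans(draws), drop(closed), tolerance = 0.02,
               ignore_attr = TRUE)
  # posterior covariance matches the inverse precision
  expect_equal(cov(draws),
               solve(crossprod(Zd) / sigma2 + diag(1 / v0, 3)),
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("the sampler recovers known item parameters", {
  # low-noise generating model: posterior means close to truth
  q <- random_q_matrix(10, 2, seed = 21)
  pers <- generate_persons(1500, xi = c(1.5, 1.5), beta = c(0, 0), seed = 21)
  g <- rep(0.05, 10); s <- rep(0.05, 10)
  y <- generate_responses(pers$alpha, q, g, s, seed = 22)
  fit <- fit_dina(y, q, "hodina", iter = 600, burnin = 300, seed = 23)
  ip <- predicted_item_params(fit)
  expect_lt(max(abs(ip$g - g)), 0.03)
  expect_lt(max(abs(ip$s - s)), 0.03)
  # higher-order loading recovered at larger xi
  xi_hat <- fit$summary[grepl("^xi", fit$summary$parameter), "mean"]
  expect_lt(max(abs(xi_hat - 1.5)), 0.5)
})

test_that("every retained state satisfies the identification constraint", {
  fit <- small_hodina_fit()
  for (d in fit$draws) {
    g <- d[, grepl("^g\\[", colnames(d))]
    s <- d[, grepl("^s\\[", colnames(d))]
    expect_true(all(g + s < 1))
    expect_true(all(g > 0 & g < 1 & s > 0 & s < 1))
    xi <- d[, grepl("^xi", colnames(d))]
    expect_true(all(xi > 0))
  }
})

test_that("fits are bit-reproducible under a fixed seed", {
  dat <- small_dataset()
  f1 <- fit_dina(dat$y, dat$q, "hodina", iter = 120, burnin = 60, seed = 31)
  f2 <- fit_dina(dat$y, dat$q, "hodina", iter = 120, burnin = 60, seed = 31)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$profile_counts, f2$profile_counts)
})

test_that("model/feature combinations are checked at construction", {
  dat <- small_dataset()
  expect_error(fit_dina(dat$y, dat$q, "hodina", features = dat$z),
               "no feature matrix")
  expect_error(fit_dina(dat$y, dat$q, "ie-g"), "require a feature matrix")
  expect_error(fit_dina(dat$y, dat$q, "ie-g", features = dat$z[1:3, ]),
               "one row per item")
  expect_error(fit_dina(dat$y, dat$q, "hodina", iter = 100, burnin = 100),
               "burnin")
})

test_that("feature-linked families estimate their coefficient block", {
  dat <- small_dataset()
  fit <- fit_dina(dat$y, dat$q, "ie-g", features = dat$z[, c(1, 7)],
                  iter = 500, burnin = 250, seed = 41)
  co <- fit$summary[grepl("^coef_g", fit$summary$parameter), ]
  expect_equal(nrow(co), 3)  # intercept + 2 slopes
  ip <- predicted_item_params(fit)
  # linked g is a deterministic function of features: exactly on the link
  cf <- feature_coefficients("guessing", co$mean[1], co$mean[-1])
  expect_equal(ip$g,
               link_to_probability(linear_predictor(dat$z[, c(1, 7)], cf)),
               tolerance = 1e-12)
  # residual family also carries a residual-variance draw
  fitr <- fit_dina(dat$y, dat$q, "ie-s-r", features = dat$z[, c(1, 7)],
                   iter = 400, burnin = 200, seed = 42)
  expect_true("sigma2_eps" %in% fitr$summary$parameter)
  expect_gt(fitr$summary[fitr$summary$parameter == "sigma2_eps", "mean"], 0)
})
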