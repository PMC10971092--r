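## Metropolis-within-Gibbs estimation of the HO-DINA model and its
## item-explanatory variants. The latent profile block is drawn exactly by
## enumerating all 2^K profiles; guessing/slipping get conjugate truncated
## Beta updates where unconstrained by features; everything else is scalar
## random-walk Metropolis with Robbins-Monro adaptation during burn-in.

.MODEL_FAMILIES <- c("hodina", "ie-g", "ie-g-r", "ie-s", "ie-s-r")

#' Prior specification
#'
#' Defaults: theta ~ N(0,1) (fixed, identifies the trait scale);
#' beta_k ~ N(0, 2); xi_k ~ N(0, 2) truncated to (0, Inf); g_i, s_i ~
#' Beta(1,1) truncated to g < 1 - s; feature coefficients ~ N(0, 1e6);
#' residual variance ~ Inverse-Gamma(1, 1). `scale_is_variance` controls
#' whether the second Normal argument is read as a variance (default) or a
#' precision; the two readings differ little at these weakly informative
#' scales.
#'
#' @param beta_scale,xi_scale Normal scale parameter for the higher-order
#'   intercepts and loadings.
#' @param coeff_variance prior variance of the feature coefficients.
#' @param sigma2_shape,sigma2_rate Inverse-Gamma hyperparameters for the
#'   residual variance.
#' @param scale_is_variance read `beta_scale`/`xi_scale` as variances
#'   (`TRUE`) or precisions (`FALSE`).
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(beta_scale = 2, xi_scale = 2, coeff_variance = 1e6,
                       sigma2_shape = 1, sigma2_rate = 1,
                       scale_is_variance = TRUE) {
  stopifnot(beta_scale > 0, xi_scale > 0, coeff_variance > 0,
            sigma2_shape > 0, sigma2_rate > 0)
  v_beta <- if (scale_is_variance) beta_scale else 1 / beta_scale
  v_xi <- if (scale_is_variance) xi_scale else 1 / xi_scale
  structure(list(sd_beta = sqrt(v_beta), sd_xi = sqrt(v_xi),
                 sd_coeff = sqrt(coeff_variance),
                 v_coeff = coeff_variance,
                 sigma2_shape = sigma2_shape, sigma2_rate = sigma2_rate),
            class = "prior_spec")
}

## ---- reusable sampling primitives --------------------------------------

#' Draw from a truncated Beta distribution by inverse CDF
#'
#' Samples `Beta(a, b)` restricted to `(lower, upper)`. Used for the
#' conjugate guessing/slipping updates, whose full conditionals are
#' count-based Beta distributions truncated by the constraint g < 1 - s.
#'
#' @param n number of draws (recycled over `a`, `b`, bounds).
#' @param a,b Beta shape parameters.
#' @param lower,upper truncation bounds.
#' @return numeric vector of draws inside the bounds.
#' @export
rtrunc_beta <- function(n, a, b, lower = 0, upper = 1) {
  if (any(upper <= lower)) stop_invalid("empty truncation interval")
  plo <- stats::pbeta(lower, a, b)
  phi <- stats::pbeta(upper, a, b)
  # Guard against mass numerically indistinguishable from 0 or 1
  width <- pmax(phi - plo, 1e-300)
  u <- plo + stats::runif(n) * width
  x <- stats::qbeta(pmin(pmax(u, 1e-300), 1 - 1e-16), a, b)
  pmin(pmax(x, lower + 1e-12), upper - 1e-12)
}

#' Exact conditional distribution of a person's attribute profile
#'
#' For one person, the posterior over all `2^K` profiles given their
#' responses and the current item/higher-order parameters:
#' likelihood x higher-order prior mass, normalized in log space.
#'
#' @param y_row binary response vector (length I).
#' @param theta_j scalar ability.
#' @param g,s item parameters.
#' @param q Q-matrix.
#' @param xi,beta higher-order parameters.
#' @return probability vector over [profile_space()] rows.
#' @export
profile_conditional_probs <- function(y_row, theta_j, g, s, q, xi, beta) {
  K <- ncol(q)
  A <- profile_space(K)
  etaPat <- eta_patterns(A, q)
  lp1 <- etaPat * rep(log(1 - s), each = nrow(A)) +
    (1 - etaPat) * rep(log(g), each = nrow(A))
  lp0 <- etaPat * rep(log(s), each = nrow(A)) +
    (1 - etaPat) * rep(log(1 - g), each = nrow(A))
  ll <- drop(lp1 %*% y_row + lp0 %*% (1 - y_row))
  lprior <- log(profile_distribution(theta_j, xi, beta))[1, ]
  lw <- ll + lprior
  w <- exp(lw - max(lw))
  if (!any(w > 0)) stop_invalid("profile weights underflowed")
  w / sum(w)
}

# ideal-response pattern of every profile (2^K x I)
eta_patterns <- function(A, q) {
  need <- rowSums(q)
  (A %*% t(q) >= rep(need, each = nrow(A))) + 0
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computed from the between/within chain variances of a scalar parameter:
#' \eqn{\hat R = \sqrt{((n-1)/n \, W + B/n) / W}}. The raw estimate falls
#' marginally below 1 when chains agree closely (exactly (n-1)/n for
#' identical chains), so the reported value is floored at 1; values above
#' 1.1 are conventionally read as non-convergence.
#'
#' @param draws matrix with one column per chain (equal lengths), or a list
#'   of equal-length numeric vectors.
#' @return scalar >= 1.
#' @export
psrf <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  if (!is.matrix(draws) || ncol(draws) < 2)
    stop_invalid("psrf needs >= 2 chains of equal length")
  n <- nrow(draws)
  W <- mean(apply(draws, 2, stats::var))
  if (W == 0) {
    if (stats::var(colMeans(draws)) == 0) return(1)  # all chains constant+equal
    stop_invalid("degenerate trace: zero within-chain variance")
  }
  B_over_n <- stats::var(colMeans(draws))
  max(1, sqrt(((n - 1) / n * W + B_over_n) / W))
}

## ---- model fitting ------------------------------------------------------

#' Fit a (item-explanatory) higher-order DINA model by MCMC
#'
#' Five model families are supported. `"hodina"` leaves g and s item
#' specific. `"ie-g"`/`"ie-s"` replace the guessing/slipping parameters by
#' a deterministic logit-linear function of item features; `"ie-g-r"`/
#' `"ie-s-r"` add an item-level Normal residual on the logit scale, so the
#' linked parameter stays item specific with the linear predictor as its
#' prior mean. The constraint \eqn{g_i < 1 - s_i} is enforced in every
#' retained state; when one parameter is feature-linked the constraint is
#' imposed on the other parameter (its conditional is truncated at
#' `1 - linked`).
#'
#' One sweep updates: profiles (exact 2^K enumeration), item parameters
#' (conjugate truncated Beta, or Metropolis for linked blocks), feature
#' coefficients (random-walk Metropolis without residual; conjugate
#' Bayesian linear regression with residual), the residual variance
#' (conjugate Inverse-Gamma), then theta, xi, beta by scalar random-walk
#' Metropolis. Proposal scales adapt toward 0.44 acceptance during burn-in
#' only and are frozen afterwards.
#'
#' @param y binary persons x items response matrix.
#' @param q binary items x attributes Q-matrix.
#' @param model one of `"hodina"`, `"ie-g"`, `"ie-g-r"`, `"ie-s"`,
#'   `"ie-s-r"`.
#' @param features items x features matrix; required by the `ie-*` families
#'   and forbidden for `"hodina"`.
#' @param chains number of chains (>= 2 for PSRF).
#' @param iter,burnin,thin chain length, discarded prefix, thinning.
#' @param seed master seed; chain c runs on sub-seed `seed + c`.
#' @param priors a [prior_spec()].
#' @param keep_person_draws store full theta/profile draws (memory heavy at
#'   large J); otherwise per-person profile tallies and theta means are
#'   accumulated online.
#' @param n_joint_states number of thinned joint (profile, g, s) states
#'   retained per chain for posterior predictive checks.
#' @return object of class `dina_fit`: retained draws per chain, posterior
#'   summaries with PSRF, deviance trace, profile tallies, joint states,
#'   acceptance rates and a `converged` flag (PSRF <= 1.1 everywhere).
#'   Non-convergence is flagged, not raised.
#' @export
fit_dina <- function(y, q, model = .MODEL_FAMILIES, features = NULL,
                     chains = 2, iter = 20000, burnin = 10000, thin = 1,
                     seed = 1, priors = prior_spec(),
                     keep_person_draws = FALSE, n_joint_states = 200) {
  model <- match.arg(model)
  validate_responses(y); validate_q_matrix(q)
  if (ncol(y) != nrow(q))
    stop_invalid("y and q disagree on the number of items")
  if (model == "hodina" && !is.null(features))
    stop_invalid("the HO-DINA family takes no feature matrix; use an ie-* ",
                 "family or the two-step procedure")
  if (model != "hodina") {
    if (is.null(features))
      stop_invalid("ie-* families require a feature matrix")
    validate_features(features)
    if (nrow(features) != nrow(q))
      stop_invalid("feature matrix must have one row per item")
  }
  if (burnin >= iter) stop_invalid("burnin must be smaller than iter")
  if (chains < 2) stop_invalid("at least 2 chains are required for PSRF")

  runs <- vector("list", chains)
  for (ch in seq_len(chains)) {
    runs[[ch]] <- run_chain(y, q, model, features, iter, burnin, thin,
                            seed = as.integer(seed) + ch, priors,
                            keep_person_draws, n_joint_states)
  }

  scalars <- colnames(runs[[1]]$draws)
  draw_mats <- lapply(runs, `[[`, "draws")
  summary <- summarize_draws(draw_mats)
  converged <- all(summary$psrf <= 1.1)

  counts <- Reduce(`+`, lapply(runs, `[[`, "profile_counts"))
  theta_mean <- Reduce(`+`, lapply(runs, `[[`, "theta_sum")) /
    (chains * runs[[1]]$n_retained)

  structure(list(model = model, y_dim = dim(y), q = q, features = features,
                 draws = draw_mats,
                 deviance = lapply(runs, `[[`, "deviance"),
                 summary = summary, psrf = summary[, c("parameter", "psrf")],
                 profile_counts = counts, theta_mean = theta_mean,
                 states = do.call(c, lapply(runs, `[[`, "states")),
                 person_draws = if (keep_person_draws)
                   lapply(runs, `[[`, "person_draws"),
                 acceptance = lapply(runs, `[[`, "acceptance"),
                 settings = list(chains = chains, iter = iter,
                                 burnin = burnin, thin = thin, seed = seed,
                                 priors = priors),
                 converged = converged),
            class = "dina_fit")
}

#' @export
print.dina_fit <- function(x, ...) {
  cat("Higher-order DINA fit, family:", x$model, "\n")
  cat("  ", x$y_dim[1], "persons x", x$y_dim[2], "items,",
      ncol(x$q), "attributes\n")
  cat("  ", x$settings$chains, "chains x", x$settings$iter, "iterations (",
      x$settings$burnin, "burn-in )\n")
  cat("  max PSRF:", round(max(x$summary$psrf), 3),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  g <- x$summary[grepl("^g\\[", x$summary$parameter), "mean"]
  s <- x$summary[grepl("^s\\[", x$summary$parameter), "mean"]
  cat("  posterior-mean g in [", round(min(g), 3), ",", round(max(g), 3),
      "]; s in [", round(min(s), 3), ",", round(max(s), 3), "]\n")
  invisible(x)
}

#' Posterior summaries of a fit
#'
#' @param object a `dina_fit`.
#' @param ... unused.
#' @return data frame of mean, SD, central 95% interval and PSRF per scalar
#'   parameter.
#' @export
summary.dina_fit <- function(object, ...) object$summary

summarize_draws <- function(draw_mats) {
  scalars <- colnames(draw_mats[[1]])
  all_draws <- do.call(rbind, draw_mats)
  qs <- apply(all_draws, 2, stats::quantile, probs = c(0.025, 0.975))
  data.frame(parameter = scalars,
             mean = colMeans(all_draws),
             sd = apply(all_draws, 2, stats::sd),
             q2.5 = qs[1, ], q97.5 = qs[2, ],
             psrf = vapply(scalars, function(p)
               psrf(lapply(draw_mats, function(d) d[, p])), numeric(1)),
             row.names = NULL)
}

## ---- single chain -------------------------------------------------------

run_chain <- function(y, q, model, z, iter, burnin, thin, seed, priors,
                      keep_person_draws, n_joint_states) {
  set.seed(seed)
  J <- nrow(y); I <- ncol(y); K <- ncol(q)
  A <- profile_space(K); C <- nrow(A)
  etaPat <- eta_patterns(A, q)
  linked <- switch(model, "ie-g" = , "ie-g-r" = "g",
                   "ie-s" = , "ie-s-r" = "s", "none")
  residual <- model %in% c("ie-g-r", "ie-s-r")
  if (linked != "none") {
    Zd <- cbind(`(Intercept)` = 1, z)   # design matrix with intercept
    M1 <- ncol(Zd)
  }

  ## --- initial state (inside all constraints; dispersed via the seed) ---
  g <- rep(0.2, I); s <- rep(0.2, I)
  theta <- stats::rnorm(J)
  xi <- rep(1, K); beta <- rep(0, K)
  gamma <- NULL; sigma2 <- NULL
  if (linked != "none") {
    gamma <- rep(0, M1)
    lin <- drop(Zd %*% gamma)
    if (residual) {
      sigma2 <- 1
      # linked parameter starts at 0.2 item-wise; residuals implied
      lpar_logit <- rep(stats::qlogis(0.2), I)
    } else {
      # deterministic link: start at the all-zero coefficient value (0.5);
      # the unlinked parameter starts low so g < 1 - s holds
      if (linked == "g") { g <- stats::plogis(lin); s <- rep(0.2, I) }
      else { s <- stats::plogis(lin); g <- rep(0.2, I) }
    }
    if (residual) {
      if (linked == "g") g <- stats::plogis(lpar_logit)
      else s <- stats::plogis(lpar_logit)
    }
  }
  pk <- attribute_prob(theta, xi, beta)
  alpha0 <- matrix(stats::rbinom(J * K, 1, pk), J, K)
  zidx <- profile_index(alpha0)

  ## --- adaptive proposal scales ---
  sc_theta <- 1.0
  sc_xi <- rep(0.3, K); sc_beta <- rep(0.3, K)
  sc_gamma <- if (linked != "none" && !residual) rep(0.1, M1)
  sc_lpar <- if (residual) rep(0.5, I)
  acc <- list(theta = 0, xi = rep(0, K), beta = rep(0, K),
              gamma = if (!is.null(sc_gamma)) rep(0, M1),
              lpar = if (residual) 0)
  n_adapt_batch <- 0L

  n_retained <- (iter - burnin) %/% thin
  scalar_names <- c(paste0("g[", 1:I, "]"), paste0("s[", 1:I, "]"),
                    paste0("xi[", 1:K, "]"), paste0("beta[", 1:K, "]"),
                    if (linked != "none")
                      paste0("coef_", linked, "[", colnames(Zd), "]"),
                    if (residual) "sigma2_eps")
  draws <- matrix(NA_real_, n_retained, length(scalar_names),
                  dimnames = list(NULL, scalar_names))
  deviance <- numeric(n_retained)
  profile_counts <- matrix(0L, J, C)
  theta_sum <- numeric(J)
  state_at <- unique(round(seq(1, n_retained,
                               length.out = min(n_joint_states, n_retained))))
  states <- vector("list", length(state_at))
  person_draws <- if (keep_person_draws)
    list(theta = matrix(NA_real_, n_retained, J),
         profile = matrix(NA_integer_, n_retained, J))

  ri <- 0L
  for (it in seq_len(iter)) {
    in_burnin <- it <= burnin

    ## (1) latent profiles: exact categorical draw over 2^K profiles
    lp1 <- etaPat * rep(log(1 - s), each = C) +
      (1 - etaPat) * rep(log(g), each = C)
    lp0 <- etaPat * rep(log(s), each = C) +
      (1 - etaPat) * rep(log1p(-g), each = C)
    Lmat <- y %*% t(lp1) + (1 - y) %*% t(lp0)            # J x C
    lpk <- outer(theta, xi) + rep(beta, each = J)
    lprior <- stats::plogis(lpk, log.p = TRUE) %*% t(A) +
      stats::plogis(-lpk, log.p = TRUE) %*% t(1 - A)
    gumbel <- -log(-log(matrix(stats::runif(J * C), J, C)))
    zidx <- max.col(Lmat + lprior + gumbel, ties.method = "first")
    eta <- etaPat[zidx, , drop = FALSE]                  # J x I

    ## sufficient counts per item
    n1y1 <- colSums(eta * y);      n1 <- colSums(eta)
    n1y0 <- n1 - n1y1
    n0y1 <- colSums(y) - n1y1;     n0y0 <- (J - n1) - n0y1

    ## (2) item parameters
    if (linked == "none") {
      g <- rtrunc_beta(I, 1 + n0y1, 1 + n0y0, upper = 1 - s)
      s <- rtrunc_beta(I, 1 + n1y0, 1 + n1y1, upper = 1 - g)
    } else if (linked == "g") {
      if (!residual) {
        up <- update_coeff_mh(gamma, Zd, sc_gamma, n0y1, n0y0,
                              bound = 1 - s, priors$sd_coeff)
        gamma <- up$coef; g <- up$par; acc$gamma <- acc$gamma + up$acc
        s <- rtrunc_beta(I, 1 + n1y0, 1 + n1y1, upper = 1 - g)
      } else {
        lg <- stats::qlogis(g)
        mu <- drop(Zd %*% gamma)
        up <- update_linked_logit_mh(lg, mu, sigma2, sc_lpar, n0y1, n0y0,
                                     bound = 1 - s)
        lg <- up$logit; g <- stats::plogis(lg)
        acc$lpar <- acc$lpar + up$acc_rate
        reg <- conj_lm_draw(Zd, lg, sigma2, priors$v_coeff)
        gamma <- reg
        res <- lg - drop(Zd %*% gamma)
        sigma2 <- 1 / stats::rgamma(1, priors$sigma2_shape + I / 2,
                                    priors$sigma2_rate + sum(res^2) / 2)
        s <- rtrunc_beta(I, 1 + n1y0, 1 + n1y1, upper = 1 - g)
      }
    } else { # linked s
      if (!residual) {
        up <- update_coeff_mh(gamma, Zd, sc_gamma, n1y0, n1y1,
                              bound = 1 - g, priors$sd_coeff)
        gamma <- up$coef; s <- up$par; acc$gamma <- acc$gamma + up$acc
        g <- rtrunc_beta(I, 1 + n0y1, 1 + n0y0, upper = 1 - s)
      } else {
        ls <- stats::qlogis(s)
        mu <- drop(Zd %*% gamma)
        up <- update_linked_logit_mh(ls, mu, sigma2, sc_lpar, n1y0, n1y1,
                                     bound = 1 - g)
        ls <- up$logit; s <- stats::plogis(ls)
        acc$lpar <- acc$lpar + up$acc_rate
        gamma <- conj_lm_draw(Zd, ls, sigma2, priors$v_coeff)
        res <- ls - drop(Zd %*% gamma)
        sigma2 <- 1 / stats::rgamma(1, priors$sigma2_shape + I / 2,
                                    priors$sigma2_rate + sum(res^2) / 2)
        g <- rtrunc_beta(I, 1 + n0y1, 1 + n0y0, upper = 1 - s)
      }
    }

    ## (3) higher-order block
    amat <- A[zidx, , drop = FALSE]
    # theta: vectorized scalar MH over persons
    prop <- theta + stats::rnorm(J, 0, sc_theta)
    lr <- ho_person_loglik(prop, amat, xi, beta) -
      ho_person_loglik(theta, amat, xi, beta) +
      stats::dnorm(prop, log = TRUE) - stats::dnorm(theta, log = TRUE)
    ok <- log(stats::runif(J)) < lr
    theta[ok] <- prop[ok]
    acc$theta <- acc$theta + mean(ok)

    # xi_k, beta_k: scalar MH
    for (k in seq_len(K)) {
      xp <- xi[k] + stats::rnorm(1, 0, sc_xi[k])
      if (xp > 0) {
        lr <- ho_attr_loglik(amat[, k], theta, xp, beta[k]) -
          ho_attr_loglik(amat[, k], theta, xi[k], beta[k]) +
          stats::dnorm(xp, 0, priors$sd_xi, log = TRUE) -
          stats::dnorm(xi[k], 0, priors$sd_xi, log = TRUE)
        if (log(stats::runif(1)) < lr) { xi[k] <- xp; acc$xi[k] <- acc$xi[k] + 1 }
      }
      bp <- beta[k] + stats::rnorm(1, 0, sc_beta[k])
      lr <- ho_attr_loglik(amat[, k], theta, xi[k], bp) -
        ho_attr_loglik(amat[, k], theta, xi[k], beta[k]) +
        stats::dnorm(bp, 0, priors$sd_beta, log = TRUE) -
        stats::dnorm(beta[k], 0, priors$sd_beta, log = TRUE)
      if (log(stats::runif(1)) < lr) { beta[k] <- bp; acc$beta[k] <- acc$beta[k] + 1 }
    }

    ## (4) burn-in proposal adaptation (Robbins-Monro toward 0.44)
    if (in_burnin && it %% 50L == 0L) {
      n_adapt_batch <- n_adapt_batch + 1L
      step <- 1 / sqrt(n_adapt_batch)
      sc_theta <- sc_theta * exp(step * (acc$theta / 50 - 0.44))
      sc_xi <- sc_xi * exp(step * (acc$xi / 50 - 0.44))
      sc_beta <- sc_beta * exp(step * (acc$beta / 50 - 0.44))
      if (!is.null(sc_gamma))
        sc_gamma <- sc_gamma * exp(step * (acc$gamma / 50 - 0.44))
      if (residual)
        sc_lpar <- sc_lpar * exp(step * (acc$lpar / 50 - 0.44))
      acc <- list(theta = 0, xi = rep(0, K), beta = rep(0, K),
                  gamma = if (!is.null(sc_gamma)) rep(0, M1),
                  lpar = if (residual) 0)
    }

    ## (5) retention
    if (!in_burnin && (it - burnin) %% thin == 0L) {
      ri <- ri + 1L
      draws[ri, ] <- c(g, s, xi, beta,
                       if (linked != "none") gamma,
                       if (residual) sigma2)
      deviance[ri] <- -2 * sum(n0y1 * log(g) + n0y0 * log1p(-g) +
                               n1y0 * log(s) + n1y1 * log1p(-s))
      profile_counts[cbind(seq_len(J), zidx)] <-
        profile_counts[cbind(seq_len(J), zidx)] + 1L
      theta_sum <- theta_sum + theta
      if (ri %in% state_at)
        states[[match(ri, state_at)]] <- list(zidx = zidx, g = g, s = s)
      if (keep_person_draws) {
        person_draws$theta[ri, ] <- theta
        person_draws$profile[ri, ] <- zidx
      }
    }
  }

  list(draws = draws, deviance = deviance, profile_counts = profile_counts,
       theta_sum = theta_sum, states = states, n_retained = n_retained,
       person_draws = person_draws,
       acceptance = list(theta_scale = sc_theta, xi_scale = sc_xi,
                         beta_scale = sc_beta))
}

# log P(alpha_j. | theta_j, xi, beta) summed over attributes, per person
ho_person_loglik <- function(theta, amat, xi, beta) {
  lpk <- outer(theta, xi) + rep(beta, each = length(theta))
  rowSums(amat * stats::plogis(lpk, log.p = TRUE) +
            (1 - amat) * stats::plogis(-lpk, log.p = TRUE))
}

# log P(alpha_.k | theta, xi_k, beta_k) summed over persons, one attribute
ho_attr_loglik <- function(a_col, theta, xi_k, beta_k) {
  lp <- xi_k * theta + beta_k
  sum(a_col * stats::plogis(lp, log.p = TRUE) +
        (1 - a_col) * stats::plogis(-lp, log.p = TRUE))
}

# Componentwise random-walk MH on the coefficient vector of a
# deterministically linked item parameter. n_a/n_b are the per-item success/
# failure counts attributed to that parameter; proposals breaching the
# complement bound (the g < 1 - s constraint) are rejected outright.
update_coeff_mh <- function(coef, Zd, scales, n_a, n_b, bound, sd_coeff) {
  lin <- drop(Zd %*% coef)
  par <- stats::plogis(lin)
  ll <- sum(n_a * log(par) + n_b * log1p(-par))
  accepted <- numeric(length(coef))
  for (m in seq_along(coef)) {
    delta <- stats::rnorm(1, 0, scales[m])
    lin_p <- lin + Zd[, m] * delta
    par_p <- stats::plogis(lin_p)
    if (all(par_p < bound)) {
      ll_p <- sum(n_a * log(par_p) + n_b * log1p(-par_p))
      lr <- ll_p - ll +
        stats::dnorm(coef[m] + delta, 0, sd_coeff, log = TRUE) -
        stats::dnorm(coef[m], 0, sd_coeff, log = TRUE)
      if (log(stats::runif(1)) < lr) {
        coef[m] <- coef[m] + delta
        lin <- lin_p; par <- par_p; ll <- ll_p
        accepted[m] <- 1
      }
    }
  }
  list(coef = coef, par = par, acc = accepted)
}

# Per-item random-walk MH on the logit of the linked parameter in the
# residual models: Normal(linear predictor, sigma2) prior, Bernoulli-count
# likelihood, independent accept/reject per item (likelihood separable).
update_linked_logit_mh <- function(lg, mu, sigma2, scales, n_a, n_b, bound) {
  prop <- lg + stats::rnorm(length(lg), 0, scales)
  par <- stats::plogis(lg); par_p <- stats::plogis(prop)
  feasible <- par_p < bound
  lr <- n_a * (log(par_p) - log(par)) +
    n_b * (log1p(-par_p) - log1p(-par)) +
    stats::dnorm(prop, mu, sqrt(sigma2), log = TRUE) -
    stats::dnorm(lg, mu, sqrt(sigma2), log = TRUE)
  ok <- feasible & log(stats::runif(length(lg))) < lr
  lg[ok] <- prop[ok]
  list(logit = lg, acc_rate = mean(ok))
}

# Conjugate Bayesian linear regression draw: Normal(0, v0 I) prior on the
# coefficients, known noise variance sigma2.
conj_lm_draw <- function(Zd, resp, sigma2, v0) {
  p <- ncol(Zd)
  prec <- crossprod(Zd) / sigma2 + diag(1 / v0, p)
  R <- chol(prec)
  mean <- backsolve(R, forwardsolve(t(R), crossprod(Zd, resp) / sigma2))
  drop(mean + backsolve(R, stats::rnorm(p)))
}
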