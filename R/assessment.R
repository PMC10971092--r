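## Model-fit statistics, coefficient inference, the two-step regression
## alternative, and cross-model consistency measures.

#' Posterior predictive p-value of the standardized-residual discrepancy
#'
#' For each retained joint posterior state (profiles, g, s) the discrepancy
#' \eqn{D = \sum_{ji} (y_{ji} - p_{ji})^2 / (p_{ji}(1 - p_{ji}))} is
#' computed for the observed data and for a replicate drawn from that
#' state; the PPP is the fraction of states whose replicated discrepancy
#' is at least the observed one. Values below 0.05 are read as bad
#' model-data fit.
#'
#' @param fit a [fit_dina()] result (its stored joint states are used).
#' @param y the observed response matrix the model was fit to.
#' @param n_rep number of posterior states to use (at most the stored
#'   number).
#' @param seed seed for the replicate draws.
#' @return scalar in \[0, 1\] with attribute `flag_bad_fit` (TRUE iff
#'   PPP < 0.05).
#' @export
ppp <- function(fit, y, n_rep = 1000, seed = 1) {
  validate_responses(y)
  states <- fit$states
  if (length(states) == 0) stop_invalid("fit carries no stored joint states")
  n_rep <- min(n_rep, length(states))
  use <- states[seq_len(n_rep)]
  set.seed(seed)
  A <- profile_space(ncol(fit$q))
  etaPat <- eta_patterns(A, fit$q)
  J <- nrow(y)
  exceed <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    st <- use[[r]]
    eta <- etaPat[st$zidx, , drop = FALSE]
    p <- eta * rep(1 - st$s, each = J) + (1 - eta) * rep(st$g, each = J)
    if (any(p <= 0 | p >= 1)) stop_invalid("degenerate state probability")
    v <- p * (1 - p)
    d_obs <- sum((y - p)^2 / v)
    yrep <- matrix(stats::rbinom(length(p), 1, p), nrow = J)
    d_rep <- sum((yrep - p)^2 / v)
    exceed[r] <- d_rep >= d_obs
  }
  out <- mean(exceed)
  attr(out, "flag_bad_fit") <- out < 0.05
  out
}

#' Deviance information criterion
#'
#' `DIC = mean(D) + pD` with `pD = var(D) / 2`, where `D` is the per-
#' iteration deviance (-2 x conditional log-likelihood of the responses
#' given the sampled profiles and item parameters). The variance uses the
#' sample (n - 1) denominator. The half-variance effective-parameter form
#' is used because the discrete profile block makes a plug-in posterior
#' mean ill-defined.
#'
#' @param fit a [fit_dina()] result, or a numeric deviance trace.
#' @return scalar DIC with attributes `pD` and `mean_deviance`.
#' @export
dic <- function(fit) {
  dev <- if (inherits(fit, "dina_fit")) unlist(fit$deviance) else fit
  if (length(dev) < 2) stop_invalid("DIC needs at least 2 retained draws")
  pD <- stats::var(dev) / 2
  out <- mean(dev) + pD
  attr(out, "pD") <- pD
  attr(out, "mean_deviance") <- mean(dev)
  out
}

#' Free-parameter count of each model family
#'
#' HO-DINA: `2I + 2K` (item-specific g and s plus higher-order loadings and
#' intercepts). Feature-linked families replace one set of I item
#' parameters with M + 1 coefficients: `(M + 1) + I + 2K`, plus one for the
#' residual variance in the `-r` forms.
#'
#' @param model family name as in [fit_dina()].
#' @param I,K,M items, attributes, features.
#' @return integer count.
#' @export
count_parameters <- function(model = .MODEL_FAMILIES, I, K, M = NULL) {
  model <- match.arg(model)
  if (model == "hodina") return(as.integer(2L * I + 2L * K))
  if (is.null(M)) stop_invalid("feature count M required for ie-* families")
  base <- as.integer(M + 1L + I + 2L * K)
  if (model %in% c("ie-g-r", "ie-s-r")) base + 1L else base
}

#' Wald test of a coefficient against zero
#'
#' `z = estimate / se` with a two-sided standard-normal p-value and a
#' significance flag at 0.05. For MCMC-estimated coefficients the posterior
#' mean and posterior SD play the roles of estimate and SE.
#'
#' @param estimate,se numeric vectors (se > 0).
#' @return data frame with `estimate`, `se`, `z`, `p`, `significant`.
#' @export
wald_test <- function(estimate, se) {
  if (any(se <= 0)) stop_invalid("standard errors must be positive")
  z <- estimate / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(estimate = estimate, se = se, z = z, p = p,
             significant = p < 0.05)
}

#' Two-step feature regression on HO-DINA item-parameter estimates
#'
#' Step 1 is an HO-DINA fit; step 2 regresses the logit of the posterior-
#' mean guessing (or slipping) estimates on the item features by OLS with
#' an intercept, reporting classical standard errors, normal-reference Wald
#' tests and R-squared. This is the supported route when both item
#' parameters are to be explained by features, which a single
#' item-explanatory model cannot do.
#'
#' @param fit an HO-DINA [fit_dina()] result.
#' @param z items x features matrix.
#' @param target `"guessing"` or `"slipping"`.
#' @param logit_of_mean transform the posterior-mean parameter (default);
#'   `FALSE` uses the mean of the per-draw logits instead.
#' @return `coefficient_table`: a data frame (intercept row first) with
#'   Wald columns, plus attributes `r_squared` and `target`.
#' @export
two_step <- function(fit, z, target = c("guessing", "slipping"),
                     logit_of_mean = TRUE) {
  target <- match.arg(target)
  if (!inherits(fit, "dina_fit") || fit$model != "hodina")
    stop_invalid("the two-step procedure starts from an HO-DINA fit")
  validate_features(z)
  if (nrow(z) >= 2 && qr(cbind(1, z))$rank < ncol(z) + 1)
    stop_invalid("feature matrix is rank deficient (collinear); VIFs: ",
                 paste(round(suppressWarnings(vif(z)), 1), collapse = ", "))
  lab <- if (target == "guessing") "^g\\[" else "^s\\["
  if (logit_of_mean) {
    est <- fit$summary[grepl(lab, fit$summary$parameter), "mean"]
    lgt <- stats::qlogis(est)
  } else {
    cols <- grepl(lab, colnames(fit$draws[[1]]))
    lgt <- colMeans(stats::qlogis(do.call(rbind, fit$draws)[, cols]))
  }
  if (nrow(z) <= ncol(z) + 1)
    stop_invalid("need more items than features + 1 for OLS")
  fit_lm <- stats::lm(lgt ~ z)
  sm <- summary(fit_lm)
  tab <- wald_test(sm$coefficients[, 1], sm$coefficients[, 2])
  rownames(tab) <- c("(Intercept)",
                     colnames(z) %||% paste0("Z", seq_len(ncol(z))))
  attr(tab, "r_squared") <- sm$r.squared
  attr(tab, "target") <- target
  class(tab) <- c("coefficient_table", class(tab))
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# variance inflation factors of a feature matrix
vif <- function(z) {
  vapply(seq_len(ncol(z)), function(m) {
    r2 <- summary(stats::lm(z[, m] ~ z[, -m, drop = FALSE]))$r.squared
    1 / (1 - min(r2, 1 - 1e-12))
  }, numeric(1))
}

#' Classify persons by modal posterior profile
#'
#' Each person is assigned the attribute profile most often visited across
#' retained draws; exact ties break toward the lower profile index (the
#' tie-break is recorded in the result). Marginal posterior mastery
#' probabilities per attribute are also returned.
#'
#' @param fit a [fit_dina()] result.
#' @return list with binary `profiles` (J x K), `marginal` mastery
#'   probabilities (J x K), modal `probability` per person, and the indices
#'   of `tied` persons.
#' @export
classify_profiles <- function(fit) {
  counts <- fit$profile_counts
  A <- profile_space(ncol(fit$q))
  best <- max.col(counts, ties.method = "first")  # lower index on ties
  mx <- counts[cbind(seq_len(nrow(counts)), best)]
  tied <- which(rowSums(counts == mx) > 1)
  total <- rowSums(counts)
  list(profiles = A[best, , drop = FALSE],
       marginal = counts %*% A / total,
       probability = mx / total,
       tied = tied)
}

#' Predicted (or estimated) item parameters from a fit
#'
#' HO-DINA and the residual (`-r`) families return the posterior-mean
#' item-specific parameters. For the deterministic `ie-*` families the
#' linked parameter is predicted as the inverse logit of the posterior-mean
#' linear predictor; the unlinked parameter is its posterior mean.
#'
#' @param fit a [fit_dina()] result.
#' @return list with vectors `g` and `s`.
#' @export
predicted_item_params <- function(fit) {
  sm <- fit$summary
  g <- sm[grepl("^g\\[", sm$parameter), "mean"]
  s <- sm[grepl("^s\\[", sm$parameter), "mean"]
  if (fit$model %in% c("ie-g", "ie-s")) {
    coefs <- sm[grepl("^coef_", sm$parameter), "mean"]
    lin <- drop(cbind(1, fit$features) %*% coefs)
    if (fit$model == "ie-g") g <- stats::plogis(lin)
    else s <- stats::plogis(lin)
  }
  list(g = g, s = s)
}

#' Agreement between two fits of the same data
#'
#' Pearson correlations of the item-parameter point values (guessing and
#' slipping separately) and the proportion of persons classified into
#' identical full attribute profiles.
#'
#' @param fitA,fitB [fit_dina()] results over the same items and persons.
#' @return list with `cor_g`, `cor_s`, `profile_consistency`.
#' @export
consistency <- function(fitA, fitB) {
  if (!all(fitA$y_dim == fitB$y_dim))
    stop_invalid("fits must cover the same persons and items")
  pa <- predicted_item_params(fitA); pb <- predicted_item_params(fitB)
  ca <- classify_profiles(fitA)$profiles
  cb <- classify_profiles(fitB)$profiles
  list(cor_g = stats::cor(pa$g, pb$g),
       cor_s = stats::cor(pa$s, pb$s),
       profile_consistency = mean(rowSums(ca != cb) == 0))
}
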