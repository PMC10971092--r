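#' iedina: item-explanatory higher-order DINA models
#'
#' Cognitive diagnosis modelling in which the DINA guessing or slipping
#' parameter is decomposed on the logit scale into manifest item features.
#' See `vignette("ie-hodina-methods")` for the model account.
#'
#' @keywords internal
"_PACKAGE"

## ---- input validation helpers -----------------------------------------

stop_invalid <- function(...) {
  stop(structure(class = c("iedina_invalid_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_binary_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && !anyNA(x) && all(x == 0 | x == 1)
}

#' Validate a Q-matrix
#'
#' A Q-matrix is a binary item x attribute matrix; entry \eqn{q_{ik} = 1}
#' declares that item \eqn{i} requires mastery of attribute \eqn{k}. Every
#' item must require at least one attribute and every attribute must be
#' required by at least one item.
#'
#' @param q numeric matrix of 0/1 entries, items in rows.
#' @return `q`, invisibly, after validation. Errors on violation. Missing
#'   entries are rejected, never imputed.
#' @export
validate_q_matrix <- function(q) {
  if (!is_binary_matrix(q))
    stop_invalid("Q-matrix must be a binary 0/1 matrix with no missing entries")
  if (any(rowSums(q) == 0))
    stop_invalid("every Q-matrix row (item) must require at least one attribute")
  if (any(colSums(q) == 0))
    stop_invalid("every Q-matrix column (attribute) must be required by some item")
  invisible(q)
}

#' Validate a binary response matrix
#'
#' Responses are persons in rows, items in columns, scored 0/1. Only
#' complete data are accepted; rows with missing responses must be removed
#' by the caller before analysis.
#'
#' @param y numeric matrix of 0/1 entries.
#' @return `y`, invisibly. Errors on non-binary or missing entries.
#' @export
validate_responses <- function(y) {
  if (!is_binary_matrix(y))
    stop_invalid("response matrix must be a complete binary 0/1 matrix; ",
                 "missing responses are rejected, not imputed")
  invisible(y)
}

## ---- latent profile space ---------------------------------------------

# Enumeration cap: 2^K profiles are enumerated exactly.
.PROFILE_CAP <- 15L

#' Enumerate all attribute profiles
#'
#' Returns the \eqn{2^K \times K} binary matrix of all mastery profiles.
#' Rows are ordered by binary counting with the *last* attribute varying
#' fastest, so for K = 2 the order is (0,0), (0,1), (1,0), (1,1). Row `c`
#' is the profile with index `c` (1-based) used throughout the package.
#'
#' @param K number of attributes (capped at 15 so enumeration stays exact).
#' @return binary matrix with `2^K` rows and `K` columns.
#' @export
profile_space <- function(K) {
  K <- as.integer(K)
  if (K < 1L || K > .PROFILE_CAP)
    stop_invalid("K must be between 1 and ", .PROFILE_CAP,
                 " for exact profile enumeration")
  C <- 2L^K
  out <- matrix(0L, C, K)
  for (k in seq_len(K))
    out[, k] <- rep(rep(0:1, each = 2L^(K - k)), length.out = C)
  colnames(out) <- paste0("A", seq_len(K))
  out
}

# profile row index (1-based) of each row of a binary profile matrix
profile_index <- function(alpha) {
  K <- ncol(alpha)
  as.integer(alpha %*% 2L^((K - 1L):0L)) + 1L
}

## ---- DINA measurement model --------------------------------------------

#' Ideal responses under the conjunctive (noisy-and) rule
#'
#' \eqn{\eta_{ji} = \prod_k \alpha_{jk}^{q_{ik}}}: person `j` produces the
#' ideal (error-free) response to item `i` iff they master every attribute
#' the item requires.
#'
#' @param alpha binary persons x attributes profile matrix.
#' @param q binary items x attributes Q-matrix.
#' @return binary persons x items matrix.
#' @export
ideal_response <- function(alpha, q) {
  if (!is_binary_matrix(alpha)) stop_invalid("alpha must be a binary matrix")
  validate_q_matrix(q)
  if (ncol(alpha) != ncol(q))
    stop_invalid("alpha and q must agree on the number of attributes")
  # eta = 1 iff alpha covers the item's required attributes
  need <- rowSums(q)
  have <- alpha %*% t(q)             # persons x items, attributes covered
  out <- (have >= rep(need, each = nrow(alpha))) + 0
  dimnames(out) <- list(rownames(alpha), rownames(q))
  out
}

#' Validate DINA item parameters
#'
#' Checks \eqn{0 < g_i < 1}, \eqn{0 < s_i < 1} and the identification
#' constraint \eqn{g_i < 1 - s_i} (a non-master must have lower success
#' probability than a master).
#'
#' @param g,s numeric vectors of guessing and slipping probabilities.
#' @return invisibly, a list with `g` and `s`. Errors on violation.
#' @export
validate_item_params <- function(g, s) {
  if (length(g) != length(s)) stop_invalid("g and s must have equal length")
  if (anyNA(g) || anyNA(s) || any(g <= 0 | g >= 1) || any(s <= 0 | s >= 1))
    stop_invalid("g and s must lie strictly inside (0, 1)")
  if (any(g >= 1 - s))
    stop_invalid("identification constraint violated: g_i < 1 - s_i required")
  invisible(list(g = g, s = s))
}

#' Success probabilities given ideal responses
#'
#' \eqn{P(Y_{ji} = 1 \mid \eta_{ji}) = (1-s_i)^{\eta_{ji}} g_i^{1-\eta_{ji}}}.
#'
#' @param eta binary persons x items ideal-response matrix.
#' @param g,s item parameter vectors satisfying [validate_item_params()].
#' @return persons x items matrix of success probabilities.
#' @export
response_prob <- function(eta, g, s) {
  validate_item_params(g, s)
  if (ncol(eta) != length(g))
    stop_invalid("eta must have one column per item")
  J <- nrow(eta)
  eta * rep(1 - s, each = J) + (1 - eta) * rep(g, each = J)
}

#' DINA joint log-likelihood
#'
#' Log of
#' \eqn{\prod_j \prod_i s_i^{(1-y)\eta} (1-s_i)^{y\eta} g_i^{y(1-\eta)}
#' (1-g_i)^{(1-y)(1-\eta)}} with \eqn{\eta} derived from `alpha` and `q`.
#' Computed cell-wise in log space so it is stable at large J.
#'
#' @param y binary persons x items response matrix.
#' @param alpha binary persons x attributes profile matrix.
#' @param g,s item parameters.
#' @param q Q-matrix.
#' @return scalar log-likelihood (always <= 0 for valid inputs). If a cell
#'   probability is exactly 0 against an observed datum the result is `-Inf`
#'   with attribute `degenerate = TRUE`.
#' @export
dina_loglik <- function(y, alpha, g, s, q) {
  validate_responses(y)
  eta <- ideal_response(alpha, q)
  if (!all(dim(y) == dim(eta)))
    stop_invalid("y and alpha/q imply inconsistent dimensions")
  validate_item_params(g, s)
  p <- response_prob(eta, g, s)
  ll <- sum(y * log(p) + (1 - y) * log1p(-p))
  if (!is.finite(ll)) {
    ll <- -Inf
    attr(ll, "degenerate") <- TRUE
  }
  ll
}

## ---- higher-order attribute structure ----------------------------------

#' Attribute mastery probabilities under the higher-order trait
#'
#' \eqn{P(\alpha_{jk} = 1 \mid \theta_j) = \mathrm{logit}^{-1}(\xi_k \theta_j
#' + \beta_k)}: a unidimensional continuous trait governs all attributes
#' through a logistic link with positive loadings.
#'
#' @param theta numeric vector of person abilities (length J).
#' @param xi positive attribute loadings (length K).
#' @param beta attribute intercepts (length K).
#' @return J x K matrix of mastery probabilities, increasing in `theta`.
#' @export
attribute_prob <- function(theta, xi, beta) {
  if (length(xi) != length(beta))
    stop_invalid("xi and beta must have equal length")
  if (any(xi <= 0))
    stop_invalid("loadings xi must be strictly positive")
  stats::plogis(outer(theta, xi) + rep(beta, each = length(theta)))
}

#' Prior distribution over full attribute profiles
#'
#' Product of the independent higher-order Bernoulli masteries, enumerated
#' over all `2^K` profiles in [profile_space()] order. This is the exact
#' latent-class prior used by the profile sampler.
#'
#' @inheritParams attribute_prob
#' @return J x 2^K matrix; rows are nonnegative and sum to 1, and column
#'   marginals reproduce [attribute_prob()].
#' @export
profile_distribution <- function(theta, xi, beta) {
  K <- length(xi)
  A <- profile_space(K)
  p <- attribute_prob(theta, xi, beta)
  # log-space product over attributes, then normalize (rows already sum to 1
  # analytically; normalization guards rounding)
  lw <- log(p) %*% t(A) + log1p(-p) %*% t(1 - A)
  w <- exp(lw)
  w / rowSums(w)
}
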