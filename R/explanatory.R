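## Logit-linear decomposition of one DINA item parameter into item features.

#' Construct feature coefficients for an explanatory item parameter
#'
#' Bundles the intercept and slopes that link item features to one item
#' parameter (guessing or slipping) on the logit scale, optionally with
#' item-level residuals and their variance (the "-R" model forms).
#'
#' @param target `"guessing"` or `"slipping"` — which parameter is linked.
#' @param intercept scalar logit-scale intercept: the linked parameter's
#'   logit when all features are 0.
#' @param slopes numeric vector, one slope per feature.
#' @param residual_variance nonnegative scalar, or `NULL` for the
#'   residual-free form.
#' @param residuals optional item-level residual vector; requires
#'   `residual_variance`.
#' @return object of class `feature_coefficients`.
#' @export
feature_coefficients <- function(target = c("guessing", "slipping"),
                                 intercept, slopes,
                                 residual_variance = NULL, residuals = NULL) {
  target <- match.arg(target)
  if (!is.null(residuals) && is.null(residual_variance))
    stop_invalid("residuals require residual_variance")
  if (!is.null(residual_variance) && residual_variance < 0)
    stop_invalid("residual_variance must be nonnegative")
  structure(list(target = target,
                 intercept = as.numeric(intercept),
                 slopes = as.numeric(slopes),
                 residual_variance = residual_variance,
                 residuals = residuals),
            class = "feature_coefficients")
}

#' @export
print.feature_coefficients <- function(x, ...) {
  cat("Feature coefficients (", x$target, " parameter, logit scale)\n",
      sep = "")
  cat("  intercept:", format(x$intercept), "\n")
  cat("  slopes:   ", paste(format(x$slopes), collapse = " "), "\n")
  if (!is.null(x$residual_variance))
    cat("  residual variance:", format(x$residual_variance), "\n")
  invisible(x)
}

#' Validate an item feature matrix
#'
#' @param z numeric items x features matrix; all entries finite. Columns
#'   tagged binary via the `kind` attribute (or detected) must be 0/1.
#' @param kind optional character vector `"continuous"`/`"binary"` per
#'   column.
#' @return `z` invisibly.
#' @export
validate_features <- function(z, kind = NULL) {
  if (!is.matrix(z) || !is.numeric(z) || !all(is.finite(z)))
    stop_invalid("feature matrix must be numeric with all entries finite")
  if (!is.null(kind)) {
    if (length(kind) != ncol(z))
      stop_invalid("one kind tag per feature column required")
    for (m in which(kind == "binary"))
      if (!all(z[, m] %in% c(0, 1)))
        stop_invalid("binary-tagged feature column ", m, " is not 0/1")
  }
  invisible(z)
}

#' Logit-scale linear predictor of an item parameter
#'
#' `intercept + Z %*% slopes`, plus the item residuals when present.
#'
#' @param z items x features matrix.
#' @param coeffs a [feature_coefficients()] object.
#' @return numeric vector of logits, one per item.
#' @export
linear_predictor <- function(z, coeffs) {
  validate_features(z)
  if (ncol(z) != length(coeffs$slopes))
    stop_invalid("slope count must match feature count")
  eta <- drop(coeffs$intercept + z %*% coeffs$slopes)
  if (!is.null(coeffs$residuals)) {
    if (length(coeffs$residuals) != nrow(z))
      stop_invalid("one residual per item required")
    eta <- eta + coeffs$residuals
  }
  if (!all(is.finite(eta))) stop_invalid("non-finite linear predictor")
  eta
}

#' Inverse-logit link
#'
#' Maps logits to probabilities in (0, 1), strictly increasing.
#'
#' @param logits finite numeric vector.
#' @return probability vector.
#' @export
link_to_probability <- function(logits) {
  if (anyNA(logits)) stop_invalid("logits must be finite")
  stats::plogis(logits)
}

#' Feasibility bound for the unlinked item parameter
#'
#' When one item parameter is feature-linked its value is determined by the
#' features, so the identification constraint \eqn{g_i < 1 - s_i} must be
#' imposed on the *other* parameter: it has to stay strictly below
#' `1 - linked`. Bounds at (or numerically near) 0 leave no room for the
#' other parameter and are flagged.
#'
#' @param linked probability vector of the feature-linked parameter.
#' @return vector of exclusive upper bounds, with attribute `degenerate`
#'   marking items whose bound is effectively zero.
#' @export
feasible_complement_bound <- function(linked) {
  if (any(linked <= 0 | linked >= 1))
    stop_invalid("linked probabilities must lie in (0, 1)")
  b <- 1 - linked
  attr(b, "degenerate") <- b < 1e-8
  b
}
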