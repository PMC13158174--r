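#' Fitted ordinal regression models
#'
#' All four likelihood-based constituents return an object of class
#' `ordinal_glm` holding the family (`"continuation_ratio_backward"` or
#' `"cumulative_logit"`), the `C - 1` intercepts/thresholds `alpha`, the `p`
#' common slopes `beta` (on the original feature scale), the penalty route,
#' the selected tuning value (`lambda` or GMIFS step count), and the AIC of
#' the selected model.
#'
#' @name ordinal_glm
NULL

new_ordinal_glm <- function(family, alpha, beta, penalty, lambda_or_steps,
                            aic, C, extra = list()) {
  stopifnot(length(alpha) == C - 1L, all(is.finite(alpha)),
            all(is.finite(beta)), is.finite(aic))
  if (family == "cumulative_logit" && C > 2L && any(diff(alpha) <= 0)) {
    stop("cumulative-logit thresholds must be strictly increasing")
  }
  structure(c(list(family = family, alpha = alpha, beta = beta,
                   penalty = penalty, lambda_or_steps = lambda_or_steps,
                   aic = aic, C = as.integer(C)), extra),
            class = "ordinal_glm")
}

#' @export
print.ordinal_glm <- function(x, ...) {
  cat(sprintf("ordinal_glm [%s, %s]: C = %d, %d nonzero of %d slopes,\n",
              x$family, x$penalty, x$C, sum(abs(x$beta) > 1e-8),
              length(x$beta)))
  cat(sprintf("  selected %s = %s, AIC = %.2f\n",
              if (x$penalty == "gmifs") "step" else "lambda",
              format(x$lambda_or_steps, digits = 4), x$aic))
  invisible(x)
}

#' Class probabilities from a fitted ordinal model
#'
#' For the backward continuation-ratio family, with
#' `delta_j(x) = plogis(alpha_j + x beta)` for `j = 2..C`,
#' `P(Y = C) = delta_C`, `P(Y = j) = delta_j * prod_{k > j} (1 - delta_k)`
#' for `1 < j < C`, and `P(Y = 1) = prod_{k = 2..C} (1 - delta_k)`. For the
#' cumulative-logit family the probabilities are successive differences of
#' `plogis(alpha_c + x beta)` with `P(Y <= 0) = 0` and `P(Y <= C) = 1`.
#' Rows sum to one to within numerical rounding.
#'
#' @param model A fitted `ordinal_glm`.
#' @param X Numeric matrix with the same number of columns the model was
#'   trained on.
#' @return An `n x C` matrix of class probabilities.
#' @export
class_probabilities <- function(model, X) {
  UseMethod("class_probabilities")
}

#' @export
class_probabilities.ordinal_glm <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$beta)) {
    stop("X has ", ncol(X), " columns; model expects ", length(model$beta))
  }
  eta <- drop(X %*% model$beta)
  C <- model$C
  if (model$family == "continuation_ratio_backward") {
    # delta[, j] corresponds to cutpoint j + 1
    delta <- stats::plogis(outer(eta, model$alpha, `+`))
    probs <- matrix(0, nrow(X), C)
    probs[, C] <- delta[, C - 1L]
    surv <- 1 - delta[, C - 1L] # prod_{k > j} (1 - delta_k), built downward
    if (C > 2L) {
      for (j in (C - 1L):2L) {
        probs[, j] <- delta[, j - 1L] * surv
        surv <- surv * (1 - delta[, j - 1L])
      }
    }
    probs[, 1L] <- surv
  } else {
    cum <- stats::plogis(outer(eta, model$alpha, `+`))
    cum <- cbind(0, cum, 1)
    probs <- cum[, -1L, drop = FALSE] - cum[, -(C + 1L), drop = FALSE]
    probs[probs < 0] <- 0 # guard against rounding at extreme eta
  }
  probs
}

#' Predicted ordinal class labels
#'
#' Argmax of [class_probabilities()], with ties broken toward the lower
#' class index.
#'
#' @inheritParams class_probabilities
#' @return Integer labels in `1..C`.
#' @export
predict_class <- function(model, X) {
  probs <- class_probabilities(model, X)
  max.col(probs, ties.method = "first")
}

#' @export
predict.ordinal_glm <- function(object, newdata,
                                type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (type == "class") predict_class(object, newdata)
  else class_probabilities(object, newdata)
}

#' Serialize a fitted ordinal model to JSON
#'
#' Stores the family, thresholds, nonzero slopes as a sparse index -> value
#' map, the selected tuning value and AIC.
#'
#' @param model A fitted `ordinal_glm`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
ordinal_glm_to_json <- function(model, path = NULL) {
  nz <- which(abs(model$beta) > 1e-8)
  doc <- list(family = model$family, penalty = model$penalty,
              C = model$C, alpha = model$alpha, p = length(model$beta),
              beta_index = nz, beta_value = model$beta[nz],
              lambda_or_steps = model$lambda_or_steps, aic = model$aic)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Restore an ordinal model serialized with [ordinal_glm_to_json()]
#'
#' @param path File path or JSON string.
#' @return An `ordinal_glm`.
#' @export
ordinal_glm_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  beta <- numeric(doc$p)
  beta[doc$beta_index] <- doc$beta_value
  new_ordinal_glm(doc$family, doc$alpha, beta, doc$penalty,
                  doc$lambda_or_steps, doc$aic, doc$C)
}
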