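#' Restructure data for the backward continuation-ratio model
#'
#' The backward continuation ratio models `logit P(Y = j | Y <= j)` for
#' `j = 2..C` with cutpoint-specific intercepts and common slopes. The fit
#' reduces to one binary logistic regression on an expanded dataset: for
#' each cutpoint `j`, every sample with `y <= j` contributes a row with
#' binary response `1{y = j}`, a cutpoint indicator (carrying `alpha_j`),
#' and its original covariates.
#'
#' @param X Numeric matrix, samples x features.
#' @param y Integer labels in `1..C`.
#' @param C Number of ordinal classes; defaults to `max(y)`.
#' @return A list of class `cr_design`: `response` (binary vector),
#'   `cutpoint` (integer in `2..C` per expanded row), `row_origin` (source
#'   sample index), and `X` (the original matrix, not copied per row).
#' @export
restructure_backward_cr <- function(X, y, C = max(y)) {
  X <- as.matrix(X)
  y <- as.integer(y)
  C <- as.integer(C)
  if (C < 2L) stop("continuation ratio needs at least 2 ordinal classes")
  if (any(y < 1L | y > C)) stop("labels must lie in 1..C")
  origin <- integer(0)
  cutpoint <- integer(0)
  for (j in 2:C) {
    idx <- which(y <= j)
    origin <- c(origin, idx)
    cutpoint <- c(cutpoint, rep.int(j, length(idx)))
  }
  structure(list(response = as.integer(y[origin] == cutpoint),
                 cutpoint = cutpoint, row_origin = origin, X = X, C = C),
            class = "cr_design")
}

# expanded design matrix: C-1 cutpoint indicator columns + covariates
cr_design_matrix <- function(design, Xsource = design$X,
                             include_dummies = TRUE) {
  Xe <- Xsource[design$row_origin, , drop = FALSE]
  if (!include_dummies) return(Xe)
  C <- design$C
  dummies <- matrix(0, length(design$cutpoint), C - 1L)
  for (j in 2:C) dummies[design$cutpoint == j, j - 1L] <- 1
  colnames(dummies) <- paste0("cut", 2:C)
  cbind(dummies, Xe)
}

binomial_loglik <- function(r, mu) {
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  sum(r * log(mu) + (1 - r) * log(1 - mu))
}

#' L1-penalized backward continuation-ratio model (grid path)
#'
#' Fits the expanded binary logistic regression of
#' [restructure_backward_cr()] with an L1 penalty on the shared slopes
#' (cutpoint intercepts unpenalized) over a descending grid of lambda
#' values, and returns the grid model minimizing
#' `AIC = 2k - 2 loglik` with `k` = number of nonzero slopes plus the
#' `C - 1` intercepts. The penalized logistic path is computed by glmnet;
#' features are standardized internally and coefficients are reported on
#' the original scale.
#'
#' @param X Numeric matrix, samples x features.
#' @param y Integer labels in `1..C`.
#' @param nlambda Number of grid values (default 100).
#' @param lambda_min_ratio Smallest lambda as a fraction of the largest
#'   (default 1e-4).
#' @param lambda Optional user lambda sequence overriding the grid.
#' @return An [ordinal_glm] of family `"continuation_ratio_backward"`.
#' @export
fit_cr_l1 <- function(X, y, nlambda = 100L, lambda_min_ratio = 1e-4,
                      lambda = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  C <- max(y)
  if (length(unique(y)) < 2L) stop("y has fewer than 2 observed classes")
  design <- restructure_backward_cr(X, y, C)
  # baseline cutpoint 2 absorbed by the glmnet intercept; dummies for 3..C
  Xe <- cr_design_matrix(design, include_dummies = FALSE)
  n_dummy <- C - 2L
  if (n_dummy > 0L) {
    dummies <- matrix(0, nrow(Xe), n_dummy)
    for (j in 3:C) dummies[design$cutpoint == j, j - 2L] <- 1
    D <- cbind(dummies, Xe)
  } else {
    D <- Xe
  }
  pf <- c(rep(0, n_dummy), rep(1, ncol(X)))
  fit <- glmnet::glmnet(D, design$response, family = "binomial",
                        penalty.factor = pf, nlambda = nlambda,
                        lambda.min.ratio = lambda_min_ratio,
                        lambda = lambda, standardize = TRUE)
  mu <- stats::predict(fit, newx = D, type = "response")
  ll <- apply(mu, 2L, function(m) binomial_loglik(design$response, m))
  cf <- as.matrix(stats::coef(fit)) # (1 + n_dummy + p) x nlambda
  slopes <- cf[(2L + n_dummy):nrow(cf), , drop = FALSE]
  k <- colSums(abs(slopes) > 1e-8) + (C - 1L)
  aic <- 2 * k - 2 * ll
  best <- which.min(aic)
  a2 <- cf[1L, best]
  alpha <- a2 + c(0, if (n_dummy > 0L) cf[2L:(1L + n_dummy), best])
  new_ordinal_glm("continuation_ratio_backward", unname(alpha),
                  unname(slopes[, best]), "l1_grid", fit$lambda[best],
                  unname(aic[best]), C,
                  extra = list(lambda_path = fit$lambda,
                               aic_path = unname(aic),
                               loglik = unname(ll[best])))
}

# Proximal-gradient (FISTA with backtracking) solver for
#   min  -loglik(theta) + lambda * sum_{j in penalized} |theta_j|
# over a binary logistic model with design D and response r.
# Convergence: relative objective change < tol or max_iter iterations.
prox_logistic <- function(D, r, penalized, lambda, init = NULL,
                          tol = 1e-7, max_iter = 500L) {
  q <- ncol(D)
  theta <- if (is.null(init)) numeric(q) else init
  pen <- rep(0, q)
  pen[penalized] <- lambda
  nll <- function(th) {
    mu <- stats::plogis(drop(D %*% th))
    -binomial_loglik(r, mu)
  }
  grad <- function(th) {
    mu <- stats::plogis(drop(D %*% th))
    drop(crossprod(D, mu - r))
  }
  obj <- function(th) nll(th) + sum(pen * abs(th))
  t_step <- 1 / max(colSums(D^2) / 4) # conservative Lipschitz guess
  z <- theta
  momentum <- 1
  f_prev <- obj(theta)
  for (it in seq_len(max_iter)) {
    g <- grad(z)
    f_z <- nll(z)
    repeat {
      cand <- z - t_step * g
      cand <- sign(cand) * pmax(abs(cand) - t_step * pen, 0)
      d <- cand - z
      if (nll(cand) <= f_z + sum(g * d) + sum(d^2) / (2 * t_step) + 1e-12 ||
          t_step < 1e-14) break
      t_step <- t_step / 2
    }
    momentum_new <- (1 + sqrt(1 + 4 * momentum^2)) / 2
    z <- cand + ((momentum - 1) / momentum_new) * (cand - theta)
    theta <- cand
    momentum <- momentum_new
    f_new <- obj(theta)
    if (f_new > f_prev) { # FISTA restart on non-monotone step
      z <- theta
      momentum <- 1
    }
    if (abs(f_prev - f_new) < tol * (abs(f_prev) + 1)) break
    f_prev <- f_new
    t_step <- t_step * 1.5 # optimistic growth, backtracking will cut it
  }
  theta
}

#' Path-wise L1-penalized backward continuation-ratio model
#'
#' Same expanded-data likelihood and AIC selection as [fit_cr_l1()], but the
#' regularization path is traced by active-set continuation in the
#' predictor-corrector style: starting from `lambda_max` (the largest null
#' model gradient, where all slopes are zero), lambda is decreased to the
#' value at which the next slope enters the model (estimated from the
#' current gradients), the solution is re-optimized on the enlarged active
#' set, and KKT violations over the full feature set trigger further
#' additions before the event is accepted. This yields models spanning the
#' entire complexity range with one event per change of the active set.
#'
#' @inheritParams fit_cr_l1
#' @param lambda_min_ratio Path terminates at
#'   `lambda_min_ratio * lambda_max`.
#' @param max_events Cap on path events.
#' @return An [ordinal_glm] of family `"continuation_ratio_backward"`,
#'   penalty `"l1_path"`; the traced `lambda_path` and `aic_path` are kept
#'   as fields.
#' @export
fit_cr_l1_path <- function(X, y, lambda_min_ratio = 1e-4,
                           max_events = 500L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  C <- max(y)
  if (length(unique(y)) < 2L) stop("y has fewer than 2 observed classes")
  p <- ncol(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  design <- restructure_backward_cr(Xs, y, C)
  D <- cr_design_matrix(design) # C-1 dummies + standardized covariates
  r <- design$response
  n_alpha <- C - 1L
  slope_cols <- (n_alpha + 1L):(n_alpha + p)

  # null model: per-cutpoint intercepts have closed-form MLE
  theta <- numeric(ncol(D))
  for (j in 2:C) {
    rj <- r[design$cutpoint == j]
    theta[j - 1L] <- stats::qlogis(min(max(mean(rj), 1e-9), 1 - 1e-9))
  }
  mu <- stats::plogis(drop(D %*% theta))
  g_full <- drop(crossprod(D, mu - r))
  lambda_max <- max(abs(g_full[slope_cols]))
  lambda_min <- lambda_min_ratio * lambda_max

  active <- integer(0) # indices into 1..p
  events_lambda <- lambda_max
  events_theta <- list(theta)
  lam <- lambda_max
  for (ev in seq_len(max_events)) {
    inactive <- setdiff(seq_len(p), active)
    if (length(inactive) == 0L) break
    g_in <- abs(g_full[slope_cols])[inactive]
    lam_next <- min(lam * 0.999, max(g_in))
    if (lam_next < lambda_min) lam_next <- lambda_min
    entering <- inactive[which.max(g_in)]
    active <- sort(c(active, entering))
    # corrector: re-optimize on the active set, then sweep KKT violations
    repeat {
      cols <- c(seq_len(n_alpha), n_alpha + active)
      init <- theta[cols]
      sol <- prox_logistic(D[, cols, drop = FALSE], r,
                           penalized = which(cols > n_alpha),
                           lambda = lam_next, init = init)
      theta[] <- 0
      theta[cols] <- sol
      mu <- stats::plogis(drop(D %*% theta))
      g_full <- drop(crossprod(D, mu - r))
      viol <- setdiff(which(abs(g_full[slope_cols]) > lam_next * 1.02),
                      active)
      if (length(viol) == 0L) break
      active <- sort(c(active, viol))
    }
    active <- active[abs(theta[n_alpha + active]) > 1e-8] # drop events
    events_lambda <- c(events_lambda, lam_next)
    events_theta <- c(events_theta, list(theta))
    lam <- lam_next
    if (lam <= lambda_min || length(active) >= min(p, length(r) - C)) break
  }

  aic <- vapply(events_theta, function(th) {
    muk <- stats::plogis(drop(D %*% th))
    k <- sum(abs(th[slope_cols]) > 1e-8) + n_alpha
    2 * k - 2 * binomial_loglik(r, muk)
  }, numeric(1))
  best <- which.min(aic)
  th <- events_theta[[best]]
  beta_s <- th[slope_cols]
  beta <- beta_s / scl
  alpha <- th[seq_len(n_alpha)] - sum(beta_s * ctr / scl)
  new_ordinal_glm("continuation_ratio_backward", alpha, beta, "l1_path",
                  events_lambda[best], aic[best], C,
                  extra = list(lambda_path = events_lambda,
                               aic_path = aic,
                               first_entry = if (length(events_theta) > 1L) {
                                 which.max(abs(events_theta[[2L]][slope_cols]))
                               } else NA_integer_))
}
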