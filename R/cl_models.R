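# Cumulative-logit likelihood machinery.
#
# Model: logit P(Y <= c | x) = alpha_c + x' beta, c = 1..C-1, with strictly
# increasing thresholds. Monotonicity is preserved by the reparameterization
#   alpha_1 = zeta_1,  alpha_c = alpha_{c-1} + exp(zeta_c)  (c >= 2),
# so the optimizer works on unconstrained zeta and can never return
# non-monotone thresholds.

zeta_to_alpha <- function(zeta) {
  if (length(zeta) == 1L) return(zeta)
  cumsum(c(zeta[1L], exp(zeta[-1L])))
}

alpha_to_zeta <- function(alpha) {
  if (length(alpha) == 1L) return(alpha)
  c(alpha[1L], log(diff(alpha)))
}

# class probability of each observation under (zeta, eta), eta = Xs beta
cl_probs_obs <- function(zeta, eta, y, C) {
  alpha <- zeta_to_alpha(zeta)
  n <- length(y)
  cum <- stats::plogis(matrix(eta, n, C - 1L) +
                         matrix(alpha, n, C - 1L, byrow = TRUE))
  i <- seq_len(n)
  hi <- ifelse(y == C, 1, cum[cbind(i, pmin(y, C - 1L))])
  lo <- ifelse(y == 1L, 0, cum[cbind(i, pmax(y - 1L, 1L))])
  list(pr = pmax(hi - lo, 1e-12), cum = cum)
}

# log-likelihood only (cheap path for line searches)
cl_ll <- function(zeta, eta, y, C) {
  sum(log(cl_probs_obs(zeta, eta, y, C)$pr))
}

# log-likelihood and gradients wrt (zeta, eta) for eta = Xs beta.
# Returns ll, grad_zeta, and u = d ll / d eta (length n) so that
# grad_beta = t(Xs) %*% u.
cl_ll_parts <- function(zeta, eta, y, C) {
  po <- cl_probs_obs(zeta, eta, y, C)
  pr <- po$pr
  cum <- po$cum
  n <- length(y)
  i <- seq_len(n)
  ll <- sum(log(pr))
  f <- cum * (1 - cum) # logistic density at each threshold
  f_hi <- ifelse(y == C, 0, f[cbind(i, pmin(y, C - 1L))])
  f_lo <- ifelse(y == 1L, 0, f[cbind(i, pmax(y - 1L, 1L))])
  u <- (f_hi - f_lo) / pr
  # d ll / d alpha_c = sum_i (1{y=c} - 1{y=c+1}) f_c / p_i
  galpha <- vapply(seq_len(C - 1L), function(cc) {
    up <- y == cc
    dn <- y == cc + 1L
    sum(f[up, cc] / pr[up]) - sum(f[dn, cc] / pr[dn])
  }, numeric(1))
  gzeta <- numeric(C - 1L)
  rev_cum <- rev(cumsum(rev(galpha)))
  gzeta[1L] <- rev_cum[1L]
  if (C > 2L) gzeta[2:(C - 1L)] <- exp(zeta[2:(C - 1L)]) * rev_cum[2:(C - 1L)]
  list(ll = ll, gzeta = gzeta, u = u)
}

standardize_features <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl < 1e-12] <- 1
  list(Xs = sweep(sweep(X, 2L, ctr), 2L, scl, "/"), center = ctr,
       scale = scl)
}

# thresholds of the intercept-only MLE: logits of cumulative class
# frequencies (closed form for the saturated marginal fit)
cl_null_zeta <- function(y, C) {
  cum_freq <- cumsum(tabulate(y, C))[-C] / length(y)
  cum_freq <- pmin(pmax(cum_freq, 1e-9), 1 - 1e-9)
  alpha_to_zeta(stats::qlogis(cum_freq))
}

# FISTA with backtracking on theta = (zeta, beta), penalty lambda*||beta||_1
cl_prox_fit <- function(Xs, y, C, lambda, zeta, beta, tol = 1e-7,
                        max_iter = 500L) {
  n_alpha <- C - 1L
  p <- ncol(Xs)
  nllpen <- function(zt, bt, eta) {
    -cl_ll(zt, eta, y, C) + lambda * sum(abs(bt))
  }
  eta <- drop(Xs %*% beta)
  t_step <- 4 / max(colSums(Xs^2) + n_alpha)
  zt_z <- zeta; bt_z <- beta; eta_z <- eta
  momentum <- 1
  f_prev <- nllpen(zeta, beta, eta)
  for (it in seq_len(max_iter)) {
    parts <- cl_ll_parts(zt_z, eta_z, y, C)
    gz <- -parts$gzeta
    gb <- -drop(crossprod(Xs, parts$u))
    f_z <- -parts$ll
    repeat {
      zt_new <- zt_z - t_step * gz
      bt_new <- bt_z - t_step * gb
      bt_new <- sign(bt_new) * pmax(abs(bt_new) - t_step * lambda, 0)
      eta_new <- drop(Xs %*% bt_new)
      dz <- zt_new - zt_z; db <- bt_new - bt_z
      quad <- f_z + sum(gz * dz) + sum(gb * db) +
        (sum(dz^2) + sum(db^2)) / (2 * t_step)
      if (-cl_ll(zt_new, eta_new, y, C) <= quad + 1e-10 ||
          t_step < 1e-14) break
      t_step <- t_step / 2
    }
    momentum_new <- (1 + sqrt(1 + 4 * momentum^2)) / 2
    w <- (momentum - 1) / momentum_new
    zt_z <- zt_new + w * (zt_new - zeta)
    bt_z <- bt_new + w * (bt_new - beta)
    eta_z <- drop(Xs %*% bt_z)
    zeta <- zt_new; beta <- bt_new
    momentum <- momentum_new
    f_new <- nllpen(zeta, beta, eta_new)
    if (f_new > f_prev) { # restart momentum on non-monotone step
      zt_z <- zeta; bt_z <- beta; eta_z <- eta_new
      momentum <- 1
    }
    if (abs(f_prev - f_new) < tol * (abs(f_prev) + 1)) {
      f_prev <- f_new
      break
    }
    f_prev <- f_new
    t_step <- t_step * 1.5
  }
  list(zeta = zeta, beta = beta, nll = f_prev - lambda * sum(abs(beta)))
}

cl_finish <- function(zeta, beta_s, std, penalty, tuning, aic, C, extra) {
  beta <- beta_s / std$scale
  alpha <- zeta_to_alpha(zeta) - sum(beta_s * std$center / std$scale)
  new_ordinal_glm("cumulative_logit", alpha, beta, penalty, tuning, aic, C,
                  extra = extra)
}

#' L1-penalized cumulative-logit (proportional-odds) model
#'
#' Maximizes the cumulative-logit log-likelihood minus `lambda * ||beta||_1`
#' by proximal gradient descent with backtracking, using the
#' monotonicity-preserving threshold reparameterization described above, on
#' internally standardized features. A descending grid of `nlambda`
#' log-spaced lambda values from `lambda_max` (the largest null-model score,
#' at which all slopes are zero) down to
#' `lambda_min_ratio * lambda_max` is traversed with warm starts, and the
#' grid model minimizing `AIC = 2k - 2 loglik`
#' (`k` = nonzero slopes + `C - 1` thresholds) is returned.
#'
#' @inheritParams fit_cr_l1
#' @param aic_patience Stop traversing the grid after this many consecutive
#'   lambda values without an AIC improvement (the AIC profile along the
#'   path is near-unimodal, so continuing past a long plateau only densifies
#'   an already-rejected region); set to `Inf` to scan the whole grid.
#' @param tol Relative objective-change convergence tolerance of the inner
#'   proximal-gradient solver.
#' @param max_iter Inner iteration cap per lambda.
#' @return An [ordinal_glm] of family `"cumulative_logit"`, penalty
#'   `"l1_grid"`.
#' @export
fit_cl_l1 <- function(X, y, nlambda = 100L, lambda_min_ratio = 1e-4,
                      lambda = NULL, aic_patience = 15L, tol = 1e-7,
                      max_iter = 500L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  C <- max(y)
  if (length(unique(y)) < 2L) stop("y has fewer than 2 observed classes")
  std <- standardize_features(X)
  Xs <- std$Xs
  p <- ncol(Xs)
  zeta0 <- cl_null_zeta(y, C)
  parts0 <- cl_ll_parts(zeta0, numeric(nrow(Xs)), y, C)
  g0 <- drop(crossprod(Xs, parts0$u))
  lambda_max <- max(abs(g0))
  lambdas <- if (is.null(lambda)) {
    exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
            length.out = nlambda))
  } else {
    sort(as.numeric(lambda), decreasing = TRUE)
  }
  zeta <- zeta0
  beta <- numeric(p)
  best <- list(aic = Inf)
  aic_path <- rep(NA_real_, length(lambdas))
  stagnant <- 0L
  for (li in seq_along(lambdas)) {
    fitl <- cl_prox_fit(Xs, y, C, lambdas[li], zeta, beta, tol = tol,
                        max_iter = max_iter)
    zeta <- fitl$zeta; beta <- fitl$beta
    k <- sum(abs(beta) > 1e-8) + (C - 1L)
    aic <- 2 * k + 2 * fitl$nll
    aic_path[li] <- aic
    if (aic < best$aic) {
      best <- list(aic = aic, zeta = zeta, beta = beta,
                   lambda = lambdas[li], loglik = -fitl$nll)
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant >= aic_patience) break
    }
  }
  aic_path <- aic_path[!is.na(aic_path)]
  lambdas <- lambdas[seq_along(aic_path)]
  cl_finish(best$zeta, best$beta, std, "l1_grid", best$lambda, best$aic, C,
            extra = list(lambda_path = lambdas, aic_path = aic_path,
                         loglik = best$loglik))
}

# Newton update of the thresholds at fixed beta (small C-1 dimensional
# problem; Hessian by finite differences of the analytic gradient)
cl_update_zeta <- function(zeta, eta, y, C, max_newton = 20L, gtol = 1e-6) {
  for (nit in seq_len(max_newton)) {
    parts <- cl_ll_parts(zeta, eta, y, C)
    g <- parts$gzeta
    if (max(abs(g)) < gtol) break
    q <- length(zeta)
    H <- matrix(0, q, q)
    h <- 1e-5
    for (j in seq_len(q)) {
      zp <- zeta; zp[j] <- zp[j] + h
      H[, j] <- (cl_ll_parts(zp, eta, y, C)$gzeta - g) / h
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, g), error = function(e) g * 0.01)
    cand <- zeta - step # Newton on the concave ll (H negative definite)
    if (!all(is.finite(cand))) break
    # backtrack if the likelihood decreases
    ll_old <- parts$ll
    shrink <- 1
    repeat {
      trial <- zeta - shrink * step
      if (cl_ll(trial, eta, y, C) >= ll_old - 1e-10) {
        zeta <- trial
        break
      }
      shrink <- shrink / 2
      if (shrink < 1e-4) break
    }
    if (shrink < 1e-4) break
  }
  zeta
}

#' Cumulative-logit model with GMIFS penalization
#'
#' Generalized monotone incremental forward stagewise fitting: starting
#' from all slopes zero, each step (1) re-maximizes the likelihood in the
#' thresholds given the current slopes, (2) finds the slope with the
#' largest absolute log-likelihood gradient, and (3) increments that slope
#' by `epsilon` in the gradient's sign direction. The AIC is recorded at
#' every step (`k` = nonzero slopes + `C - 1` thresholds) and the
#' minimum-AIC step is returned. Features are standardized internally;
#' coefficients are reported on the original scale.
#'
#' @inheritParams fit_cr_l1
#' @param epsilon Increment size per step (default 0.001).
#' @param max_steps Cap on stagewise steps (default 10000).
#' @param patience Stop early after this many consecutive steps without AIC
#'   improvement (default 500).
#' @return An [ordinal_glm] of family `"cumulative_logit"`, penalty
#'   `"gmifs"`; `lambda_or_steps` holds the selected step count.
#' @export
fit_cl_gmifs <- function(X, y, epsilon = 0.001, max_steps = 10000L,
                         patience = 500L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  C <- max(y)
  if (length(unique(y)) < 2L) stop("y has fewer than 2 observed classes")
  std <- standardize_features(X)
  Xs <- std$Xs
  p <- ncol(Xs)
  zeta <- cl_null_zeta(y, C)
  beta <- numeric(p)
  eta <- numeric(nrow(Xs))
  zeta <- cl_update_zeta(zeta, eta, y, C)
  parts <- cl_ll_parts(zeta, eta, y, C)
  best <- list(aic = 2 * (C - 1L) - 2 * parts$ll, zeta = zeta, beta = beta,
               step = 0L, loglik = parts$ll)
  stagnant <- 0L
  for (s in seq_len(max_steps)) {
    g <- drop(crossprod(Xs, parts$u))
    if (!all(is.finite(g))) stop("non-finite GMIFS gradient at step ", s)
    m <- which.max(abs(g))
    beta[m] <- beta[m] + epsilon * sign(g[m])
    eta <- eta + epsilon * sign(g[m]) * Xs[, m]
    # one warm Newton step per stagewise update keeps the thresholds at
    # their conditional optimum (the likelihood moves O(epsilon) per step)
    zeta <- cl_update_zeta(zeta, eta, y, C, max_newton = 1L)
    parts <- cl_ll_parts(zeta, eta, y, C)
    aic <- 2 * (sum(abs(beta) > 1e-8) + (C - 1L)) - 2 * parts$ll
    if (aic < best$aic - 1e-10) {
      best <- list(aic = aic, zeta = zeta, beta = beta, step = s,
                   loglik = parts$ll)
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant >= patience) break
    }
  }
  cl_finish(best$zeta, best$beta, std, "gmifs", best$step, best$aic, C,
            extra = list(loglik = best$loglik, epsilon = epsilon))
}
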