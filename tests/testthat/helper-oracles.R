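# Independent oracles used across the suite. These deliberately share no
# code with the package internals: metrics by O(n^2) pair enumeration,
# likelihoods written from the model definitions and maximized with optim.

# --- brute-force ordinal metrics ------------------------------------------

brute_pair_counts <- function(y_true, y_pred) {
  n <- length(y_true)
  A <- B <- Tt <- Tp <- both <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dt <- y_true[i] - y_true[j]
      dp <- y_pred[i] - y_pred[j]
      if (dt == 0 && dp == 0) both <- both + 1L
      else if (dt == 0) Tt <- Tt + 1L
      else if (dp == 0) Tp <- Tp + 1L
      else if (sign(dt) == sign(dp)) A <- A + 1L
      else B <- B + 1L
    }
  }
  list(A = A, B = B, Tt = Tt, Tp = Tp, both = both)
}

brute_tau_b <- function(y_true, y_pred) {
  pc <- brute_pair_counts(y_true, y_pred)
  d1 <- pc$A + pc$B + pc$Tt
  d2 <- pc$A + pc$B + pc$Tp
  if (d1 == 0 || d2 == 0) return(NA_real_)
  (pc$A - pc$B) / sqrt(d1 * d2)
}

brute_gamma <- function(y_true, y_pred) {
  pc <- brute_pair_counts(y_true, y_pred)
  if (pc$A + pc$B == 0) return(NA_real_)
  (pc$A - pc$B) / (pc$A + pc$B)
}

# --- direct likelihood maximization oracles -------------------------------

# backward continuation-ratio log-likelihood, written from the conditional
# probability definition (no data expansion): theta = (alpha_2..alpha_C,
# beta_1..beta_p)
cr_direct_loglik <- function(theta, X, y, C) {
  p <- ncol(X)
  alpha <- theta[seq_len(C - 1L)]
  beta <- theta[C:(C - 1L + p)]
  eta <- drop(X %*% beta)
  ll <- 0
  for (i in seq_along(y)) {
    delta <- stats::plogis(alpha + eta[i]) # delta[m] is cutpoint m + 1
    # P(Y=j) = delta_j * prod_{k>j}(1-delta_k); P(Y=1) = prod(1-delta_k)
    pr <- numeric(C)
    for (j in seq_len(C)) {
      dj <- if (j == 1L) 1 else delta[j - 1L]
      tail <- if (j < C) prod(1 - delta[j:(C - 1L)]) else 1
      pr[j] <- if (j == 1L) prod(1 - delta) else dj * tail
    }
    ll <- ll + log(max(pr[y[i]], 1e-300))
  }
  ll
}

fit_cr_direct <- function(X, y, C = max(y)) {
  p <- ncol(X)
  init <- c(stats::qlogis(pmin(pmax(
    vapply(2:C, function(j) mean(y[y <= j] == j), numeric(1)),
    0.05), 0.95)), rep(0, p))
  opt <- stats::optim(init, function(th) -cr_direct_loglik(th, X, y, C),
                      method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(alpha = opt$par[seq_len(C - 1L)], beta = opt$par[C:(C - 1L + p)],
       loglik = -opt$value)
}

# cumulative-logit log-likelihood from the definition, theta =
# (alpha_1..alpha_{C-1}, beta); infeasible (non-monotone alpha) -> -Inf
cl_direct_loglik <- function(theta, X, y, C) {
  alpha <- theta[seq_len(C - 1L)]
  if (C > 2L && any(diff(alpha) <= 0)) return(-Inf)
  beta <- theta[C:(length(theta))]
  eta <- drop(X %*% beta)
  ll <- 0
  for (i in seq_along(y)) {
    cum <- c(0, stats::plogis(alpha + eta[i]), 1)
    ll <- ll + log(max(cum[y[i] + 1L] - cum[y[i]], 1e-300))
  }
  ll
}

fit_cl_direct <- function(X, y, C = max(y)) {
  p <- ncol(X)
  cum_freq <- pmin(pmax(cumsum(tabulate(y, C))[-C] / length(y), 0.05),
                   0.95)
  init <- c(stats::qlogis(cum_freq), rep(0, p))
  opt <- stats::optim(init, function(th) -cl_direct_loglik(th, X, y, C),
                      method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
  opt <- stats::optim(opt$par, function(th) -cl_direct_loglik(th, X, y, C),
                      method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
  list(alpha = opt$par[seq_len(C - 1L)], beta = opt$par[C:(C - 1L + p)],
       loglik = -opt$value)
}

# numeric gradient of the cumulative-logit log-likelihood in beta at beta=0
# with thresholds at their null MLE (finite differences)
cl_numeric_score <- function(X, y, C = max(y), h = 1e-6) {
  cum_freq <- cumsum(tabulate(y, C))[-C] / length(y)
  alpha <- stats::qlogis(cum_freq)
  p <- ncol(X)
  base <- cl_direct_loglik(c(alpha, rep(0, p)), X, y, C)
  vapply(seq_len(p), function(j) {
    b <- rep(0, p); b[j] <- h
    (cl_direct_loglik(c(alpha, b), X, y, C) - base) / h
  }, numeric(1))
}

# --- small data builders ---------------------------------------------------

toy_ordinal_data <- function(n = 40L, p = 1L, C = 3L, seed = 1L,
                             beta = 1.5) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  lat <- drop(X %*% rep(beta, p)) + stats::rlogis(n)
  y <- as.integer(cut(lat, stats::quantile(lat, seq(0, 1, length.out =
                                                      C + 1L)),
                      include.lowest = TRUE, labels = FALSE))
  list(X = X, y = y, C = C)
}

random_ranked_lists <- function(K, V, ids = paste0("M", seq_len(K))) {
  lapply(seq_len(V), function(v) sample(ids))
}
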