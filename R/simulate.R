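#' Simulation scenario configuration
#'
#' Bundles the parameters of the three synthetic study designs used to
#' exercise the ensemble:
#' \describe{
#'   \item{`ar1_dense`}{all `p` AR(1)-correlated predictors carry a slope of
#'     `+/- beta_magnitude` on a latent continuous outcome with logistic
#'     noise, thresholded at percentiles (scenario 1).}
#'   \item{`ar1_sparse`}{as above but only the first `n_signal` predictors
#'     carry nonzero slopes (scenario 2). With
#'     `non_proportional_odds = TRUE`, two latent scores with partly opposed
#'     coefficient vectors generate the outcome by sequential thresholding,
#'     violating proportional odds.}
#'   \item{`independent_shift`}{independent N(0,1) predictors except the
#'     first `n_signal`, whose means shift 1/3/5 across the class blocks
#'     (scenario 3).}
#' }
#'
#' @param scenario One of `"ar1_dense"`, `"ar1_sparse"`,
#'   `"independent_shift"`.
#' @param n,p Sample and feature counts (defaults 300 and 1000).
#' @param C Number of ordinal classes (default 3).
#' @param rho AR(1) correlation in `[0, 1)` (default 0.5).
#' @param beta_magnitude Absolute slope of signal features on the latent
#'   scale (default 0.7).
#' @param n_signal Number of nonzero coefficients in the sparse designs
#'   (default 10, capped at `p`).
#' @param class_probs Target class proportions, length `C`, summing to 1.
#' @param non_proportional_odds Use the two-latent-score variant
#'   (only with `ar1_sparse`).
#' @param seed Integer RNG seed; every draw in [gen_scenario()] flows
#'   from it.
#'
#' @return A list of class `sim_config`.
#' @seealso [gen_scenario()]
#' @export
sim_config <- function(scenario = c("ar1_dense", "ar1_sparse",
                                    "independent_shift"),
                       n = 300L, p = 1000L, C = 3L, rho = 0.5,
                       beta_magnitude = 0.7, n_signal = min(10L, p),
                       class_probs = rep(1 / C, C),
                       non_proportional_odds = FALSE, seed = 1L) {
  scenario <- match.arg(scenario)
  n <- as.integer(n); p <- as.integer(p); C <- as.integer(C)
  n_signal <- as.integer(n_signal)
  if (!is.finite(rho) || rho < 0 || rho >= 1) {
    stop("rho must be finite and in [0, 1)")
  }
  if (n < C) stop("n must be at least C")
  if (n_signal < 1L || n_signal > p) stop("n_signal must be in 1..p")
  if (length(class_probs) != C) stop("class_probs must have length C")
  if (abs(sum(class_probs) - 1) > 1e-12) stop("class_probs must sum to 1")
  if (non_proportional_odds && scenario == "independent_shift") {
    stop("non_proportional_odds is not supported for independent_shift")
  }
  structure(list(scenario = scenario, n = n, p = p, C = C, rho = rho,
                 beta_magnitude = beta_magnitude, n_signal = n_signal,
                 class_probs = as.numeric(class_probs),
                 non_proportional_odds = isTRUE(non_proportional_odds),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw rows from an AR(1)-correlated multivariate normal
#'
#' Each row is MVN(0, Sigma) with `Sigma[j, k] = rho^|j - k|`, generated by
#' the AR(1) recursion `X_1 ~ N(0,1)`, `X_j = rho X_{j-1} +
#' sqrt(1 - rho^2) Z_j` -- no p x p covariance matrix is ever materialized.
#'
#' @param n,p Dimensions of the returned matrix.
#' @param rho AR(1) correlation in `[0, 1)`.
#' @param seed Optional integer seed; when given, output is reproducible
#'   bit for bit.
#' @return An `n x p` numeric matrix.
#' @export
gen_ar1_predictors <- function(n, p, rho, seed = NULL) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      rho < 0 || rho >= 1) {
    stop("rho must be a finite scalar in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(stats::rnorm(n * p), as.integer(n), as.integer(p))
  if (rho == 0 || p == 1L) return(Z)
  X <- Z
  s <- sqrt(1 - rho^2)
  for (j in 2:p) X[, j] <- rho * X[, j - 1L] + s * Z[, j]
  X
}

#' Discretize a latent continuous outcome at probability blocks
#'
#' Samples are ranked by the latent score; the lowest block of size
#' `round(n * cumsum(class_probs))[1]` becomes class 1, the next block class
#' 2, and so on. With equal `class_probs` and `n = 300` this yields exactly
#' 100 samples per class. Ties in the latent score are broken by first
#' occurrence, so the mapping is deterministic.
#'
#' @param y_latent Numeric latent scores.
#' @param class_probs Target class proportions summing to 1.
#' @return Integer labels in `1..C`, monotone in `y_latent`.
#' @export
discretize_latent <- function(y_latent, class_probs) {
  n <- length(y_latent)
  if (n == 0L) stop("y_latent is empty")
  C <- length(class_probs)
  if (n < C) stop("need at least C observations")
  if (abs(sum(class_probs) - 1) > 1e-12) stop("class_probs must sum to 1")
  counts <- class_block_counts(n, class_probs)
  r <- rank(y_latent, ties.method = "first")
  upper <- cumsum(counts)
  findInterval(r, c(0, upper) + 0.5) # label c iff rank in block c
}

# round cumulative block boundaries so counts sum exactly to n
class_block_counts <- function(n, class_probs) {
  bounds <- round(cumsum(class_probs) * n)
  bounds[length(bounds)] <- n
  counts <- diff(c(0, bounds))
  if (any(counts < 1)) stop("class_probs allocate an empty class at n = ", n)
  as.integer(counts)
}

#' Generate one simulated dataset
#'
#' Implements the three study designs described in [sim_config()]. The slope
#' signs for the latent-outcome designs are i.i.d. fair-coin `+/-` per
#' coefficient, redrawn for every call, so Monte-Carlo replicates differ in
#' sign pattern as well as noise. The generating coefficients are attached as
#' `attr(, "provenance")`.
#'
#' @param config A [sim_config()].
#' @return A [labeled_dataset()] with `config$n` samples.
#' @export
gen_scenario <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n; p <- config$p; C <- config$C

  if (config$scenario == "independent_shift") {
    counts <- class_block_counts(n, config$class_probs)
    y <- rep.int(seq_len(C), counts)
    means <- 2 * seq_len(C) - 1 # 1, 3, 5 for C = 3
    X <- matrix(stats::rnorm(n * p), n, p)
    ns <- config$n_signal
    X[, seq_len(ns)] <- X[, seq_len(ns), drop = FALSE] + means[y]
    prov <- list(class_means = means, n_signal = ns)
  } else {
    X <- gen_ar1_predictors(n, p, config$rho)
    beta <- numeric(p)
    ns <- if (config$scenario == "ar1_dense") p else config$n_signal
    beta[seq_len(ns)] <- config$beta_magnitude *
      sample(c(-1, 1), ns, replace = TRUE)
    if (config$non_proportional_odds) {
      # second latent score: signs flipped on the first half of the signal
      beta2 <- beta
      flip <- seq_len(max(1L, floor(ns / 2)))
      beta2[flip] <- -beta2[flip]
      y1 <- drop(X %*% beta) + stats::rlogis(n)
      y2 <- drop(X %*% beta2) + stats::rlogis(n)
      counts <- class_block_counts(n, config$class_probs)
      y <- integer(n)
      # top block of the first score -> highest class; among the rest,
      # descend through the remaining classes on the second score
      ord1 <- order(y1, decreasing = TRUE)
      top <- ord1[seq_len(counts[C])]
      y[top] <- C
      remaining <- setdiff(seq_len(n), top)
      if (C > 2L) {
        for (cls in (C - 1L):2L) {
          ord2 <- remaining[order(y2[remaining], decreasing = TRUE)]
          blk <- ord2[seq_len(counts[cls])]
          y[blk] <- cls
          remaining <- setdiff(remaining, blk)
        }
      }
      y[remaining] <- 1L
      prov <- list(beta = beta, beta2 = beta2)
    } else {
      y_latent <- drop(X %*% beta) + stats::rlogis(n)
      y <- discretize_latent(y_latent, config$class_probs)
      prov <- list(beta = beta)
    }
  }
  out <- labeled_dataset(X, y, C = C)
  attr(out, "provenance") <- c(prov, list(config = config))
  out
}

#' Split a dataset into training and testing parts
#'
#' Simple random (unstratified) split: `round(n * train_fraction)` samples go
#' to training, the rest to testing. Set `stratified = TRUE` to split each
#' class separately in the same proportion.
#'
#' @param data A [labeled_dataset()].
#' @param train_fraction Fraction in (0, 1); default 0.8.
#' @param seed Optional integer seed.
#' @param stratified Stratify the split by class (default `FALSE`).
#' @return A list with elements `train` and `test`, both `labeled_dataset`s.
#' @export
split_train_test <- function(data, train_fraction = 0.8, seed = NULL,
                             stratified = FALSE) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data$X)
  if (stratified) {
    idx_train <- unlist(lapply(split(seq_len(n), data$y), function(ix) {
      sample(ix, round(length(ix) * train_fraction))
    }), use.names = FALSE)
  } else {
    idx_train <- sample(n, round(n * train_fraction))
  }
  idx_test <- setdiff(seq_len(n), idx_train)
  list(train = subset_samples(data, sort(idx_train)),
       test = subset_samples(data, idx_test))
}
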