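#' Sample heterogeneous score sets
#'
#' A score set partitions `[0, 1]` into `C` adjacent intervals with
#' divisions `d_1 = 0 < d_2 < ... < d_C < d_{C+1} = 1`; the class scores are
#' the probit-transformed interval midpoints
#' `s_j = qnorm((d_j + d_{j+1}) / 2)`, strictly increasing by construction.
#' Interior divisions are drawn i.i.d. Uniform(0, 1) and sorted, giving a
#' heterogeneous collection of candidate partitions.
#'
#' @param B Number of score sets.
#' @param C Number of ordinal classes (at least 2).
#' @param seed Optional integer seed.
#' @return A list of `B` score sets, each a list with `divisions`
#'   (length `C + 1`) and `scores` (length `C`).
#' @export
sample_score_sets <- function(B, C, seed = NULL) {
  if (C < 2L) stop("need at least 2 classes")
  if (B < 1L) stop("B must be positive")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(B), function(b) {
    repeat {
      inner <- sort(stats::runif(C - 1L))
      d <- c(0, inner, 1)
      if (all(diff(d) > 1e-9)) break # reject (measure-zero) duplicates
    }
    score_set(d)
  })
}

score_set <- function(divisions) {
  C <- length(divisions) - 1L
  mid <- (divisions[-(C + 1L)] + divisions[-1L]) / 2
  list(divisions = divisions, scores = stats::qnorm(mid))
}

# map continuous forest predictions back to classes: zhat falls in class j
# iff pnorm(zhat) lies in [d_j, d_{j+1}) (inverse of the score construction)
scores_to_class <- function(zhat, divisions) {
  C <- length(divisions) - 1L
  cls <- findInterval(stats::pnorm(zhat), divisions,
                      rightmost.closed = TRUE)
  pmin(pmax(cls, 1L), C)
}

#' Class-weighted Youden performance of an ordinal prediction
#'
#' One-vs-rest sensitivity and specificity per class, combined as
#' `sum_c w_c (sens_c + spec_c - 1)`. A class absent from `y_true`
#' contributes sensitivity 0 (rather than dropping out), so a forest that
#' never predicts a rare class is penalized.
#'
#' @param y_true,y_pred Equal-length label vectors in `1..C`.
#' @param class_weights Length-`C` weights summing to 1; default equal.
#' @param C Number of classes; defaults to the largest label observed.
#' @return A number in `[-1, 1]`.
#' @export
youden_performance <- function(y_true, y_pred, class_weights = NULL,
                               C = max(y_true, y_pred)) {
  check_label_pair(y_true, y_pred)
  if (is.null(class_weights)) class_weights <- rep(1 / C, C)
  if (length(class_weights) != C) stop("class_weights must have length C")
  if (abs(sum(class_weights) - 1) > 1e-8) {
    stop("class_weights must sum to 1")
  }
  val <- 0
  for (cc in seq_len(C)) {
    pos <- y_true == cc
    npos <- sum(pos)
    sens <- if (npos == 0L) 0 else sum(y_pred[pos] == cc) / npos
    nneg <- sum(!pos)
    spec <- if (nneg == 0L) 1 else sum(y_pred[!pos] != cc) / nneg
    val <- val + class_weights[cc] * (sens + spec - 1)
  }
  val
}

#' Ordinal forest configuration
#'
#' @param B Number of candidate score sets (default 100; the full-scale
#'   setting is 1000).
#' @param NT Trees per candidate regression forest (default 100; full scale
#'   500).
#' @param NF Trees in the final forest (default 500; full scale 5000).
#' @param top_k Number of best-scoring candidate forests whose divisions
#'   are averaged (default 10).
#' @param class_weights Youden weights per class; `NULL` for equal.
#' @param mtry Features tried per split; default `floor(p / 3)` at fit
#'   time (the regression-forest convention; a sqrt(p) default dilutes the
#'   many weak correlated signals this model targets).
#' @param seed Optional integer seed controlling score-set sampling and
#'   all forests.
#' @return A list of class `forest_config`.
#' @export
forest_config <- function(B = 100L, NT = 100L, NF = 500L, top_k = 10L,
                          class_weights = NULL, mtry = NULL, seed = NULL) {
  stopifnot(B >= top_k, top_k >= 1L, NT >= 1L, NF >= 1L)
  structure(list(B = as.integer(B), NT = as.integer(NT),
                 NF = as.integer(NF), top_k = as.integer(top_k),
                 class_weights = class_weights, mtry = mtry, seed = seed),
            class = "forest_config")
}

#' Fit an ordinal forest
#'
#' For each of `cfg$B` sampled score sets, the ordinal labels are replaced
#' by the corresponding scores `z_i = s_{y_i}` and a regression forest with
#' `cfg$NT` trees is grown; its out-of-bag continuous predictions are
#' mapped back to classes through the score set's divisions and scored by
#' [youden_performance()]. The divisions of the `cfg$top_k` best candidates
#' are averaged element-wise (preserving monotonicity), the scores are
#' rebuilt from the averaged divisions, and a final forest with `cfg$NF`
#' trees is trained on the resulting `z`.
#'
#' @param X Numeric matrix, samples x features.
#' @param y Integer labels in `1..C`.
#' @param cfg A [forest_config()].
#' @param C Number of classes; defaults to `max(y)`.
#' @return An object of class `ordinal_forest_fit` holding the optimized
#'   score set, the final ranger forest, and the candidate performance
#'   scores.
#' @export
fit_ordinal_forest <- function(X, y, cfg = forest_config(), C = max(y)) {
  X <- as.matrix(X)
  y <- as.integer(y)
  C <- as.integer(C)
  if (length(unique(y)) < 2L) stop("y has fewer than 2 observed classes")
  if (length(setdiff(seq_len(C), unique(y))) > 0L) {
    warning("some classes are absent from y; proceeding (bootstrap reality)")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  p <- ncol(X)
  mtry <- if (is.null(cfg$mtry)) max(1L, floor(p / 3)) else cfg$mtry
  Xdf <- as.data.frame(X)
  colnames(Xdf) <- paste0("f", seq_len(p))
  sets <- sample_score_sets(cfg$B, C)
  perf <- vapply(seq_len(cfg$B), function(b) {
    z <- sets[[b]]$scores[y]
    rf <- ranger::ranger(x = Xdf, y = z, num.trees = cfg$NT, mtry = mtry,
                         num.threads = 1L,
                         seed = sample.int(.Machine$integer.max, 1L))
    zhat <- rf$predictions # OOB
    ok <- is.finite(zhat) # samples never OOB (rare) are skipped
    youden_performance(y[ok], scores_to_class(zhat[ok],
                                              sets[[b]]$divisions),
                       class_weights = cfg$class_weights, C = C)
  }, numeric(1))
  top <- order(perf, decreasing = TRUE)[seq_len(cfg$top_k)]
  div_avg <- rowMeans(vapply(sets[top], `[[`, numeric(C + 1L), "divisions"))
  opt <- score_set(div_avg)
  z_final <- opt$scores[y]
  final <- ranger::ranger(x = Xdf, y = z_final, num.trees = cfg$NF,
                          mtry = mtry, num.threads = 1L,
                          seed = sample.int(.Machine$integer.max, 1L))
  structure(list(score_set = opt, forest = final, C = C, p = p,
                 candidate_performance = perf, cfg = cfg),
            class = "ordinal_forest_fit")
}

#' @export
print.ordinal_forest_fit <- function(x, ...) {
  cat(sprintf("ordinal_forest_fit: C = %d, p = %d, B = %d candidates,\n",
              x$C, x$p, x$cfg$B))
  cat("  optimized divisions:",
      paste(sprintf("%.3f", x$score_set$divisions), collapse = " "), "\n")
  invisible(x)
}

#' Predict ordinal classes from a fitted ordinal forest
#'
#' Every tree's continuous prediction is mapped to a class through the
#' optimized divisions; the per-class vote fractions are averaged over
#' trees and the class with the highest average vote wins (ties to the
#' lower class).
#'
#' @param model An `ordinal_forest_fit`.
#' @param X Numeric matrix with the same feature count as at fit time.
#' @param return_votes Also return the `n x C` vote-fraction matrix.
#' @return Integer labels, or a list with `class` and `votes`.
#' @export
predict_of <- function(model, X, return_votes = FALSE) {
  stopifnot(inherits(model, "ordinal_forest_fit"))
  X <- as.matrix(X)
  if (ncol(X) != model$p) {
    stop("X has ", ncol(X), " columns; model expects ", model$p)
  }
  Xdf <- as.data.frame(X)
  colnames(Xdf) <- paste0("f", seq_len(model$p))
  pa <- stats::predict(model$forest, data = Xdf, predict.all = TRUE,
                       num.threads = 1L)$predictions # n x NF
  cls <- matrix(scores_to_class(pa, model$score_set$divisions), nrow(pa))
  votes <- t(apply(cls, 1L, tabulate, nbins = model$C)) / ncol(cls)
  labels <- max.col(votes, ties.method = "first")
  if (return_votes) list(class = labels, votes = votes) else labels
}

#' @export
predict.ordinal_forest_fit <- function(object, newdata, ...) {
  predict_of(object, newdata)
}
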