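#' Ordinal evaluation metrics
#'
#' Four criteria for comparing predicted against true ordinal labels:
#' mean absolute error (MAE), Kendall's tau-b, accuracy, and the
#' Goodman-Kruskal gamma statistic. tau-b and gamma are computed from the
#' concordant/discordant pair counts A and B and the tie counts Tt (tied in
#' truth only) and Tp (tied in prediction only); pairs tied in both vectors
#' are excluded from all four counts.
#'
#' \deqn{\tau_b = (A - B) / \sqrt{(A + B + T_t)(A + B + T_p)}, \qquad
#'       \gamma = (A - B) / (A + B)}
#'
#' Either statistic is undefined (returned as `NA`) when its denominator is
#' zero, e.g. for a constant prediction vector; [rank_models()] places
#' undefined values last so a constant predictor can never win a ranking.
#'
#' @param y_true,y_pred Integer label vectors of equal length, values in
#'   `1..C` (classes mapped to equally spaced integers).
#' @return `mae()`, `accuracy()`, `kendall_tau_b()`, `gamma_statistic()`
#'   return a single number (possibly `NA` for the rank statistics).
#' @name ordinal-metrics
NULL

check_label_pair <- function(y_true, y_pred, min_n = 1L) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  if (length(y_true) < min_n) stop("need at least ", min_n, " observations")
  invisible(NULL)
}

#' @rdname ordinal-metrics
#' @export
mae <- function(y_true, y_pred) {
  check_label_pair(y_true, y_pred)
  mean(abs(as.numeric(y_true) - as.numeric(y_pred)))
}

#' @rdname ordinal-metrics
#' @export
accuracy <- function(y_true, y_pred) {
  check_label_pair(y_true, y_pred)
  mean(y_true == y_pred)
}

# Concordant/discordant/tie pair counts from the C x C contingency table.
# Runs in O(n + C^2) rather than enumerating all n(n-1)/2 pairs.
pair_counts <- function(y_true, y_pred) {
  tab <- table(factor(y_true), factor(y_pred))
  R <- nrow(tab); S <- ncol(tab)
  A <- 0; B <- 0
  for (i in seq_len(R)) {
    for (j in seq_len(S)) {
      nij <- tab[i, j]
      if (nij == 0) next
      if (i < R && j < S) {
        A <- A + nij * sum(tab[(i + 1):R, (j + 1):S])
      }
      if (i < R && j > 1) {
        B <- B + nij * sum(tab[(i + 1):R, 1:(j - 1)])
      }
    }
  }
  n <- length(y_true)
  total <- n * (n - 1) / 2
  # pairs tied in truth (same row), split into tied-in-both and truth-only
  row_tot <- rowSums(tab); col_tot <- colSums(tab)
  tied_rows <- sum(row_tot * (row_tot - 1) / 2)
  tied_cols <- sum(col_tot * (col_tot - 1) / 2)
  tied_both <- sum(tab * (tab - 1) / 2)
  Tt <- tied_rows - tied_both
  Tp <- tied_cols - tied_both
  list(A = A, B = B, Tt = Tt, Tp = Tp, tied_both = tied_both, total = total)
}

#' @rdname ordinal-metrics
#' @export
kendall_tau_b <- function(y_true, y_pred) {
  check_label_pair(y_true, y_pred, min_n = 2L)
  pc <- pair_counts(y_true, y_pred)
  den1 <- pc$A + pc$B + pc$Tt
  den2 <- pc$A + pc$B + pc$Tp
  if (den1 == 0 || den2 == 0) return(NA_real_)
  (pc$A - pc$B) / sqrt(den1 * den2)
}

#' @rdname ordinal-metrics
#' @export
gamma_statistic <- function(y_true, y_pred) {
  check_label_pair(y_true, y_pred, min_n = 2L)
  pc <- pair_counts(y_true, y_pred)
  if (pc$A + pc$B == 0) return(NA_real_)
  (pc$A - pc$B) / (pc$A + pc$B)
}

#' Evaluate all four ordinal metrics in one pass
#'
#' @inheritParams ordinal-metrics
#' @return A list of class `metric_panel` with elements `mae`, `tau_b`,
#'   `accuracy`, `gamma` (the rank statistics are `NA` when undefined) and
#'   `pair_counts` (`A`, `B`, `Tt`, `Tp`, `tied_both`, `total`).
#' @export
evaluate_panel <- function(y_true, y_pred) {
  check_label_pair(y_true, y_pred, min_n = 2L)
  pc <- pair_counts(y_true, y_pred)
  den1 <- pc$A + pc$B + pc$Tt
  den2 <- pc$A + pc$B + pc$Tp
  tau_b <- if (den1 == 0 || den2 == 0) NA_real_ else
    (pc$A - pc$B) / sqrt(den1 * den2)
  gam <- if (pc$A + pc$B == 0) NA_real_ else (pc$A - pc$B) / (pc$A + pc$B)
  structure(list(mae = mae(y_true, y_pred), tau_b = tau_b,
                 accuracy = accuracy(y_true, y_pred), gamma = gam,
                 pair_counts = pc),
            class = "metric_panel")
}

#' @export
print.metric_panel <- function(x, ...) {
  cat(sprintf("metric_panel: MAE %.4f | tau_b %s | accuracy %.4f | gamma %s\n",
              x$mae,
              ifelse(is.na(x$tau_b), "NA", sprintf("%.4f", x$tau_b)),
              x$accuracy,
              ifelse(is.na(x$gamma), "NA", sprintf("%.4f", x$gamma))))
  invisible(x)
}

#' Rank competing models on each metric
#'
#' Produces one full ranking of the models per metric: MAE ascending (lowest
#' value gets rank 1), tau-b / accuracy / gamma descending (highest value
#' gets rank 1). Exact ties are broken uniformly at random (models tied on a
#' metric receive each ordering with equal probability across calls), so a
#' seeded RNG state makes the rankings reproducible. Undefined (`NA`) tau-b
#' or gamma values rank strictly last.
#'
#' @param panels Named list of `metric_panel` objects, one per model; names
#'   are the model identifiers.
#' @param metrics Character subset of
#'   `c("mae", "tau_b", "accuracy", "gamma")`.
#' @return A named list of character vectors, one per metric, each a
#'   permutation of `names(panels)` with the best model first.
#' @export
rank_models <- function(panels,
                        metrics = c("mae", "tau_b", "accuracy", "gamma")) {
  if (length(panels) < 2L) stop("need at least two models to rank")
  if (is.null(names(panels)) || anyDuplicated(names(panels))) {
    stop("panels must be uniquely named by model identifier")
  }
  metrics <- match.arg(metrics, several.ok = TRUE)
  models <- names(panels)
  out <- lapply(metrics, function(m) {
    vals <- vapply(panels, function(p) as.numeric(p[[m]]), numeric(1))
    key <- if (m == "mae") vals else -vals
    key[is.na(key)] <- Inf # undefined ranks last
    # rank with random tie-break, then order by rank
    models[order(rank(key, ties.method = "random"))]
  })
  names(out) <- metrics
  out
}
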