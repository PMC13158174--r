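#' Spearman's footrule distance between two ranked lists
#'
#' Sum over items of the absolute difference in (1-based) position. Zero iff
#' the lists are identical; at most `floor(K^2 / 2)` for lists of length K.
#'
#' @param a,b Character (or atomic) vectors holding the same set of
#'   identifiers, best first.
#' @return A non-negative integer.
#' @export
spearman_footrule <- function(a, b) {
  if (length(a) != length(b) || !setequal(a, b) || anyDuplicated(a) ||
      anyDuplicated(b)) {
    stop("inputs must be permutations of the same identifier set")
  }
  sum(abs(match(a, b) - seq_along(a)))
}

#' Rank-aggregation configuration
#'
#' @param method `"auto"` uses exhaustive enumeration for up to
#'   `exhaustive_limit` items and the cross-entropy Monte-Carlo search
#'   beyond; `"exhaustive"` and `"cross_entropy_mc"` force one route.
#' @param exhaustive_limit Largest K for which all K! permutations are
#'   enumerated (default 7).
#' @param ce_sample_size Permutations sampled per CE iteration (default
#'   `10 * K^2`, computed at run time when `NULL`).
#' @param ce_rho_quantile Elite fraction retained per iteration.
#' @param ce_smoothing Weight of the elite empirical distribution in the
#'   probability-matrix update.
#' @param max_iterations Cap on CE iterations.
#' @param convergence_patience Stop after this many iterations without
#'   improvement of the best objective.
#' @return A list of class `agg_config`.
#' @export
agg_config <- function(method = c("auto", "exhaustive", "cross_entropy_mc"),
                       exhaustive_limit = 7L, ce_sample_size = NULL,
                       ce_rho_quantile = 0.1, ce_smoothing = 0.7,
                       max_iterations = 200L, convergence_patience = 15L) {
  method <- match.arg(method)
  stopifnot(ce_rho_quantile > 0, ce_rho_quantile <= 1,
            ce_smoothing > 0, ce_smoothing <= 1,
            max_iterations >= 1, convergence_patience >= 1)
  structure(list(method = method,
                 exhaustive_limit = as.integer(exhaustive_limit),
                 ce_sample_size = ce_sample_size,
                 ce_rho_quantile = ce_rho_quantile,
                 ce_smoothing = ce_smoothing,
                 max_iterations = as.integer(max_iterations),
                 convergence_patience = as.integer(convergence_patience)),
            class = "agg_config")
}

# all permutations of 1..k as a matrix (k! rows); k is small by construction
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- vector("list", k)
  for (pos in seq_len(k)) {
    block <- cbind(sub, k)
    if (pos < k) {
      tmp <- block[, c(seq_len(pos - 1L), k, pos:(k - 1L)), drop = FALSE]
      block <- tmp
    }
    out[[pos]] <- block
  }
  do.call(rbind, out)
}

psi_objective <- function(perm_idx, pos_lists) {
  # perm_idx: item index at each position; pos_lists: per input list, the
  # position of each item. Psi = sum_j sum_items |pos in eta - pos in E_j|.
  eta_pos <- integer(length(perm_idx))
  eta_pos[perm_idx] <- seq_along(perm_idx)
  sum(vapply(pos_lists, function(pp) sum(abs(eta_pos - pp)), numeric(1)))
}

#' Aggregate metric-wise rankings into one consensus ranking
#'
#' Finds an ordering eta of the models minimizing
#' \deqn{\Psi(\eta) = \sum_j d(\eta, E_j)} where d is Spearman's footrule
#' and the E_j are the input ranked lists. For K up to
#' `cfg$exhaustive_limit` all K! permutations are enumerated, so the
#' minimum is exact (K = 5 models means 120 candidates); larger K uses a
#' cross-entropy Monte-Carlo search over permutations. Among co-minimal
#' permutations the one whose top element most often holds position 1 in
#' the inputs wins, then ties fall back to lexicographic order -- a
#' deterministic policy so that ensemble runs are reproducible.
#'
#' @param lists List of ranked lists (character vectors, best first) over a
#'   common identifier set.
#' @param cfg An [agg_config()].
#' @return The consensus ranked list with attributes `psi` (its objective
#'   value) and `method` (route taken).
#' @export
aggregate_ranks <- function(lists, cfg = agg_config()) {
  if (length(lists) == 0L) stop("no ranked lists supplied")
  items <- lists[[1]]
  K <- length(items)
  for (l in lists) {
    if (length(l) != K || !setequal(l, items)) {
      stop("all lists must rank the same identifier set")
    }
  }
  items <- sort(items) # canonical order for index arithmetic
  pos_lists <- lapply(lists, function(l) match(items, l))

  use_exhaustive <- switch(cfg$method,
    exhaustive = TRUE,
    cross_entropy_mc = FALSE,
    auto = K <= cfg$exhaustive_limit)

  if (use_exhaustive) {
    if (K > cfg$exhaustive_limit) {
      stop("exhaustive search limited to K <= ", cfg$exhaustive_limit)
    }
    perms <- all_permutations(K)
    psis <- apply(perms, 1L, psi_objective, pos_lists = pos_lists)
    best <- which(psis == min(psis))
    cand <- perms[best, , drop = FALSE]
  } else {
    res <- ce_minimize(K, pos_lists, cfg)
    cand <- res$cand
    psis <- res$psi
  }

  if (nrow(cand) > 1L) {
    # top-1 plurality: prefer the candidate whose first element leads most
    # input lists, then lexicographic on item names
    top_counts <- vapply(seq_len(K), function(i) {
      sum(vapply(pos_lists, function(pp) pp[i] == 1L, logical(1)))
    }, numeric(1))
    score <- top_counts[cand[, 1L]]
    cand <- cand[score == max(score), , drop = FALSE]
    if (nrow(cand) > 1L) {
      keys <- apply(cand, 1L, function(ix) paste(items[ix], collapse = "\r"))
      cand <- cand[order(keys)[1L], , drop = FALSE]
    }
  }
  eta <- items[cand[1L, ]]
  attr(eta, "psi") <- psi_objective(cand[1L, ], pos_lists)
  attr(eta, "method") <- if (use_exhaustive) "exhaustive" else
    "cross_entropy_mc"
  eta
}

# Cross-entropy Monte-Carlo minimization over permutations: maintain a
# K x K matrix P of position/item weights, sample permutations position by
# position, keep the elite fraction, and blend their empirical frequencies
# back into P with smoothing weight cfg$ce_smoothing.
ce_minimize <- function(K, pos_lists, cfg) {
  M <- if (is.null(cfg$ce_sample_size)) 10L * K * K else
    as.integer(cfg$ce_sample_size)
  P <- matrix(1 / K, K, K) # P[pos, item]
  best_psi <- Inf
  best_perm <- NULL
  stagnant <- 0L
  for (it in seq_len(cfg$max_iterations)) {
    samp <- matrix(0L, M, K)
    for (m in seq_len(M)) {
      avail <- rep(TRUE, K)
      for (pos in seq_len(K)) {
        w <- P[pos, ] * avail
        pick <- sample.int(K, 1L, prob = w / sum(w))
        samp[m, pos] <- pick
        avail[pick] <- FALSE
      }
    }
    psis <- apply(samp, 1L, psi_objective, pos_lists = pos_lists)
    elite_n <- max(1L, ceiling(cfg$ce_rho_quantile * M))
    elite <- samp[order(psis)[seq_len(elite_n)], , drop = FALSE]
    if (min(psis) < best_psi) {
      best_psi <- min(psis)
      best_perm <- samp[which.min(psis), ]
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
    }
    freq <- matrix(0, K, K)
    for (pos in seq_len(K)) {
      tab <- tabulate(elite[, pos], K)
      freq[pos, ] <- tab / elite_n
    }
    P <- (1 - cfg$ce_smoothing) * P + cfg$ce_smoothing * freq
    P <- pmax(P, 1e-6) # keep support so every permutation stays reachable
    if (stagnant >= cfg$convergence_patience) break
  }
  list(cand = matrix(best_perm, 1L), psi = best_psi)
}
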