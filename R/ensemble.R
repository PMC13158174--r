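#' Ensemble configuration
#'
#' @param n_bootstraps Number of bootstrap replicates `N` (default 100).
#' @param models Character roster, a subset of
#'   `c("CR_L1", "CR_L1_path", "CL_L1", "CL_GMIFS", "OF")`, at least two.
#' @param metrics Evaluation criteria used for out-of-bag ranking, a subset
#'   of `c("mae", "tau_b", "accuracy", "gamma")`.
#' @param forest_cfg A [forest_config()] for the `OF` constituent.
#' @param glm_args Optional named list of extra arguments per GLM
#'   constituent, e.g. `list(CL_GMIFS = list(max_steps = 2000))`.
#' @param agg_cfg An [agg_config()] for the rank aggregation.
#' @param stratified_bootstrap Draw bootstrap samples within class strata
#'   (default `FALSE`, plain resampling).
#' @param vote_tie_extra Maximum additional bootstrap replicates drawn to
#'   resolve majority-vote ties at prediction time (default 50); after the
#'   cap, ties fall to the lowest tied class.
#' @param seed Master seed; per-replicate seeds are derived from it by a
#'   fixed counter scheme, so growing `N` never reshuffles earlier
#'   replicates.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_bootstraps = 100L,
                            models = c("CR_L1", "CR_L1_path", "CL_L1",
                                       "CL_GMIFS", "OF"),
                            metrics = c("mae", "tau_b", "accuracy",
                                        "gamma"),
                            forest_cfg = forest_config(),
                            glm_args = list(),
                            agg_cfg = agg_config(),
                            stratified_bootstrap = FALSE,
                            vote_tie_extra = 50L,
                            seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (length(models) < 2L) stop("the roster needs at least two models")
  if (n_bootstraps < 1L) stop("n_bootstraps must be positive")
  structure(list(n_bootstraps = as.integer(n_bootstraps), models = models,
                 metrics = metrics, forest_cfg = forest_cfg,
                 glm_args = glm_args, agg_cfg = agg_cfg,
                 stratified_bootstrap = isTRUE(stratified_bootstrap),
                 vote_tie_extra = as.integer(vote_tie_extra),
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

replicate_seed <- function(master, l) {
  as.integer((as.double(master) * 48271 + l * 7919) %% 2147483647)
}

#' Draw a bootstrap sample and its out-of-bag complement
#'
#' Samples `n` indices with replacement; the out-of-bag (OOB) set holds
#' every index not drawn (about 36.8 percent of samples in expectation).
#' An empty OOB set triggers a redraw.
#'
#' @param n Number of samples (at least 2).
#' @param seed Optional integer seed.
#' @param strata Optional label vector of length `n`; when given, sampling
#'   is done within each stratum.
#' @return A list with `boot` (length-`n` index multiset) and `oob`
#'   (sorted index set).
#' @export
bootstrap_split <- function(n, seed = NULL, strata = NULL) {
  if (n < 2L) stop("need at least 2 samples")
  if (!is.null(seed)) set.seed(seed)
  repeat {
    boot <- if (is.null(strata)) {
      sample.int(n, n, replace = TRUE)
    } else {
      unlist(lapply(split(seq_len(n), strata), function(ix) {
        sample(ix, length(ix), replace = TRUE)
      }), use.names = FALSE)
    }
    oob <- setdiff(seq_len(n), boot)
    if (length(oob) > 0L) break
  }
  list(boot = boot, oob = sort(oob))
}

fit_roster_model <- function(name, X, y, cfg) {
  args <- cfg$glm_args[[name]]
  switch(name,
    CR_L1 = do.call(fit_cr_l1, c(list(X = X, y = y), args)),
    CR_L1_path = do.call(fit_cr_l1_path, c(list(X = X, y = y), args)),
    CL_L1 = do.call(fit_cl_l1, c(list(X = X, y = y), args)),
    CL_GMIFS = do.call(fit_cl_gmifs, c(list(X = X, y = y), args)),
    OF = fit_ordinal_forest(X, y, cfg$forest_cfg),
    stop("unknown model: ", name))
}

predict_roster_model <- function(fit, X) {
  if (inherits(fit, "ordinal_forest_fit")) predict_of(fit, X)
  else predict_class(fit, X)
}

#' Run one bootstrap replicate of the ensemble algorithm
#'
#' Draws a bootstrap sample, trains every roster model on it, predicts the
#' out-of-bag samples, evaluates the four ordinal metrics, ranks the models
#' per metric (exact ties broken at random), aggregates the rankings under
#' Spearman's footrule, and returns the consensus rank-1 model together
#' with its already-fitted bootstrap classifier (no refit). A model that
#' fails to fit is excluded from the ranking with a warning; if every model
#' fails the replicate is reported as failed so the caller can redraw.
#'
#' @param train A [labeled_dataset()] with at least two observed classes.
#' @param cfg An [ensemble_config()].
#' @param replicate_seed Integer seed for this replicate.
#' @return A list with `winner` (model name), `fit` (the winning fitted
#'   model), and `provenance` (seed, OOB metric panels, per-metric ranked
#'   lists, consensus list and its footrule objective).
#' @export
run_one_bootstrap <- function(train, cfg, replicate_seed = 1L) {
  stopifnot(inherits(train, "labeled_dataset"))
  if (length(unique(train$y)) < 2L) stop("training data has one class")
  set.seed(replicate_seed)
  bs <- bootstrap_split(nrow(train$X),
                        strata = if (cfg$stratified_bootstrap) train$y)
  Xb <- train$X[bs$boot, , drop = FALSE]
  yb <- train$y[bs$boot]
  Xo <- train$X[bs$oob, , drop = FALSE]
  yo <- train$y[bs$oob]
  if (length(unique(yb)) < 2L) {
    return(list(winner = NA_character_, fit = NULL,
                provenance = list(failed = TRUE, seed = replicate_seed)))
  }
  fits <- list()
  panels <- list()
  for (name in cfg$models) {
    f <- tryCatch(fit_roster_model(name, Xb, yb, cfg),
                  error = function(e) {
                    warning("model ", name, " failed on this bootstrap: ",
                            conditionMessage(e))
                    NULL
                  })
    if (is.null(f)) next
    fits[[name]] <- f
    panels[[name]] <- evaluate_panel(yo, predict_roster_model(f, Xo))
  }
  if (length(fits) == 0L) {
    return(list(winner = NA_character_, fit = NULL,
                provenance = list(failed = TRUE, seed = replicate_seed)))
  }
  if (length(fits) == 1L) {
    winner <- names(fits)[1L]
    consensus <- winner
  } else {
    lists <- rank_models(panels, metrics = cfg$metrics)
    consensus <- aggregate_ranks(lists, cfg$agg_cfg)
    winner <- consensus[1L]
  }
  list(winner = winner, fit = fits[[winner]],
       provenance = list(failed = FALSE, seed = replicate_seed,
                         oob_size = length(bs$oob), panels = panels,
                         ranked_lists = if (length(fits) > 1L) lists,
                         consensus = as.character(consensus),
                         psi = attr(consensus, "psi")))
}

#' Fit the bootstrap ensemble classifier
#'
#' Repeats [run_one_bootstrap()] `cfg$n_bootstraps` times with
#' counter-derived seeds; the ensemble consists of the per-replicate
#' winning classifiers, which vote at prediction time. Failed replicates
#' (all models erroring, or a single-class bootstrap) are redrawn with a
#' shifted seed.
#'
#' @param train A [labeled_dataset()].
#' @param cfg An [ensemble_config()].
#' @param verbose Print the winner of each replicate.
#' @return An object of class `ordinal_ensemble`.
#' @export
fit_ensemble <- function(train, cfg = ensemble_config(), verbose = FALSE) {
  stopifnot(inherits(train, "labeled_dataset"))
  winners <- vector("list", cfg$n_bootstraps)
  for (l in seq_len(cfg$n_bootstraps)) {
    attempt <- 0L
    repeat {
      res <- run_one_bootstrap(train, cfg,
                               replicate_seed_for(cfg$seed, l, attempt))
      if (!isTRUE(res$provenance$failed)) break
      attempt <- attempt + 1L
      if (attempt > 20L) stop("bootstrap replicate ", l,
                              " failed repeatedly")
    }
    if (verbose) {
      message(sprintf("bootstrap %d/%d: winner %s (psi = %s)", l,
                      cfg$n_bootstraps, res$winner,
                      format(res$provenance$psi)))
    }
    winners[[l]] <- res
  }
  structure(list(winners = winners, cfg = cfg, C = train$C,
                 p = ncol(train$X), train = train),
            class = "ordinal_ensemble")
}

replicate_seed_for <- function(master, l, attempt = 0L) {
  replicate_seed(master, l + attempt * 1000003L)
}

#' @export
print.ordinal_ensemble <- function(x, ...) {
  tally <- table(vapply(x$winners, `[[`, character(1), "winner"))
  cat("ordinal_ensemble:", length(x$winners), "bootstrap winners,",
      x$C, "classes\n")
  print(tally)
  invisible(x)
}

#' Tally of winning model identities across bootstrap replicates
#'
#' @param model An `ordinal_ensemble`.
#' @return A named integer table over the roster.
#' @export
winner_tally <- function(model) {
  table(factor(vapply(model$winners, `[[`, character(1), "winner"),
               levels = model$cfg$models))
}

#' Predict ordinal classes by majority vote across bootstrap winners
#'
#' Each of the `N` winning classifiers predicts every test sample; the
#' modal class wins. A tied vote triggers additional bootstrap replicates
#' (up to `cfg$vote_tie_extra`) whose winners add votes until the tie
#' resolves; an unresolved tie falls to the lowest tied class.
#'
#' @param model An `ordinal_ensemble`.
#' @param X Numeric test matrix with the training feature count.
#' @param resolve_ties Set `FALSE` to skip tie-extension bootstraps and use
#'   the lowest-class fallback immediately.
#' @return Integer labels in `1..C`.
#' @export
predict_ensemble <- function(model, X, resolve_ties = TRUE) {
  stopifnot(inherits(model, "ordinal_ensemble"))
  X <- as.matrix(X)
  if (ncol(X) != model$p) {
    stop("X has ", ncol(X), " columns; model expects ", model$p)
  }
  preds <- vapply(model$winners, function(w) {
    as.integer(predict_roster_model(w$fit, X))
  }, integer(nrow(X)))
  preds <- matrix(preds, nrow = nrow(X)) # guard n = 1
  votes <- t(apply(preds, 1L, tabulate, nbins = model$C))
  is_tied <- function(v) sum(v == max(v)) > 1L
  tied <- apply(votes, 1L, is_tied)
  extra <- 0L
  while (resolve_ties && any(tied) && extra < model$cfg$vote_tie_extra) {
    extra <- extra + 1L
    res <- run_one_bootstrap(model$train, model$cfg,
                             replicate_seed_for(model$cfg$seed,
                                                length(model$winners) +
                                                  extra))
    if (isTRUE(res$provenance$failed)) next
    newp <- as.integer(predict_roster_model(res$fit, X))
    votes <- votes + t(vapply(newp, function(cl) {
      tabulate(cl, nbins = model$C)
    }, numeric(model$C)))
    tied <- apply(votes, 1L, is_tied)
  }
  max.col(votes, ties.method = "first")
}

#' @export
predict.ordinal_ensemble <- function(object, newdata, ...) {
  predict_ensemble(object, newdata, ...)
}
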