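#' Read a feature matrix and ordinal label file
#'
#' The feature file is CSV/TSV with a header row, the first column holding
#' sample identifiers and the remaining columns numeric features. The label
#' file has columns `sample_id` and `label`. Rows are aligned by identifier
#' (an order-independent join); unmatched or duplicate ids raise
#' descriptive errors. Labels must be integers; a gap in the observed label
#' set (e.g. `{1, 3}`) is accepted with a warning, `C` being the maximum
#' label.
#'
#' @param x_path Path to the feature file.
#' @param y_path Path to the label file.
#' @param sep Field separator; `NULL` picks `\\t` for `.tsv`, `,` otherwise.
#' @return A [labeled_dataset()].
#' @export
read_dataset <- function(x_path, y_path, sep = NULL) {
  pick_sep <- function(path) {
    if (!is.null(sep)) return(sep)
    if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  xdf <- utils::read.table(x_path, header = TRUE, sep = pick_sep(x_path),
                           check.names = FALSE, stringsAsFactors = FALSE)
  ydf <- utils::read.table(y_path, header = TRUE, sep = pick_sep(y_path),
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(ydf) < 2L) stop("label file needs columns (sample_id, label)")
  x_ids <- as.character(xdf[[1L]])
  y_ids <- as.character(ydf[[1L]])
  dup <- unique(c(x_ids[duplicated(x_ids)], y_ids[duplicated(y_ids)]))
  if (length(dup) > 0L) {
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  }
  unmatched <- c(setdiff(x_ids, y_ids), setdiff(y_ids, x_ids))
  if (length(unmatched) > 0L) {
    stop("sample ids present in only one file: ",
         paste(unmatched, collapse = ", "))
  }
  X <- as.matrix(xdf[, -1L, drop = FALSE])
  if (!is.numeric(X)) stop("non-numeric feature columns in ", x_path)
  rownames(X) <- x_ids
  labels <- ydf[match(x_ids, y_ids), 2L]
  if (any(labels != round(labels))) stop("labels must be integers")
  labels <- as.integer(labels)
  if (length(setdiff(seq_len(max(labels)), unique(labels))) > 0L) {
    warning("observed labels have gaps; C inferred as max label = ",
            max(labels))
  }
  suppressWarnings(labeled_dataset(X, labels, sample_ids = x_ids))
}

#' Write a labeled dataset as a feature CSV and a label CSV
#'
#' Inverse of [read_dataset()]: `<prefix>_X.csv` holds
#' `sample_id, f0001, ...` and `<prefix>_y.csv` holds `sample_id, label`.
#'
#' @param data A [labeled_dataset()].
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_dataset <- function(data, prefix) {
  stopifnot(inherits(data, "labeled_dataset"))
  p <- ncol(data$X)
  feat_names <- sprintf("f%04d", seq_len(p))
  xdf <- data.frame(sample_id = data$sample_ids, data$X,
                    check.names = FALSE)
  colnames(xdf) <- c("sample_id", feat_names)
  x_path <- paste0(prefix, "_X.csv")
  y_path <- paste0(prefix, "_y.csv")
  utils::write.csv(xdf, x_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(sample_id = data$sample_ids,
                              label = data$y),
                   y_path, row.names = FALSE, quote = FALSE)
  invisible(c(x_path, y_path))
}

#' Monte-Carlo benchmark of the ensemble and its constituents
#'
#' For each Monte-Carlo iteration: generate a scenario dataset, split it
#' 80/20, fit the requested constituent models (and optionally the full
#' ensemble) on the training part, predict the test part, and evaluate the
#' four ordinal metrics. Summaries are the mean and interquartile range per
#' method and metric across iterations; the iteration-level panels are
#' archived in the result.
#'
#' @param sim_cfg A [sim_config()]; its seed field is overridden per
#'   iteration, derived from `seed`.
#' @param ens_cfg An [ensemble_config()]; also supplies per-model settings
#'   for the standalone fits.
#' @param n_mc Number of Monte-Carlo iterations.
#' @param seed Master seed.
#' @param models Constituents to fit standalone; defaults to the ensemble
#'   roster.
#' @param include_ensemble Also fit the full ensemble each iteration
#'   (default `TRUE`; the dominant cost).
#' @param train_fraction Training share of each split (default 0.8).
#' @param verbose Print progress lines.
#' @return A list of class `benchmark_result` with `summary` (data frame:
#'   method, metric, mean, iqr, median), `panels` (list of per-iteration
#'   metric panels), and `failed` (count of failed iterations).
#' @export
run_benchmark <- function(sim_cfg, ens_cfg = ensemble_config(), n_mc = 10L,
                          seed = 1L, models = ens_cfg$models,
                          include_ensemble = TRUE, train_fraction = 0.8,
                          verbose = FALSE) {
  stopifnot(inherits(sim_cfg, "sim_config"))
  methods <- c(models, if (include_ensemble) "Ensemble")
  panels <- list()
  failed <- 0L
  for (it in seq_len(n_mc)) {
    it_seed <- replicate_seed(seed, it)
    scfg <- sim_cfg
    scfg$seed <- it_seed
    res <- tryCatch({
      data <- gen_scenario(scfg)
      parts <- split_train_test(data, train_fraction,
                                seed = it_seed + 1L)
      out <- list()
      for (name in models) {
        f <- fit_roster_model(name, parts$train$X, parts$train$y, ens_cfg)
        out[[name]] <- evaluate_panel(parts$test$y,
                                      predict_roster_model(f,
                                                           parts$test$X))
      }
      if (include_ensemble) {
        ecfg <- ens_cfg
        ecfg$seed <- it_seed + 2L
        ens <- fit_ensemble(parts$train, ecfg)
        out[["Ensemble"]] <- evaluate_panel(parts$test$y,
                                            predict_ensemble(ens,
                                                             parts$test$X))
      }
      out
    }, error = function(e) {
      warning("iteration ", it, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      failed <- failed + 1L
    } else {
      panels[[length(panels) + 1L]] <- res
      if (verbose) {
        message(sprintf("mc %d/%d done (%s)", it, n_mc,
                        paste(sprintf("%s acc %.3f", names(res),
                                      vapply(res, `[[`, numeric(1),
                                             "accuracy")),
                              collapse = ", ")))
      }
    }
  }
  metric_names <- c("mae", "tau_b", "accuracy", "gamma")
  rows <- list()
  for (m in methods) {
    for (g in metric_names) {
      vals <- vapply(panels, function(pp) as.numeric(pp[[m]][[g]]),
                     numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, metric = g, mean = mean(vals, na.rm = TRUE),
        iqr = stats::IQR(vals, na.rm = TRUE),
        median = stats::median(vals, na.rm = TRUE))
    }
  }
  structure(list(summary = do.call(rbind, rows), panels = panels,
                 failed = failed, n_mc = n_mc),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("benchmark_result over", length(x$panels), "Monte-Carlo iterations")
  if (x$failed > 0L) cat(" (", x$failed, " failed)", sep = "")
  cat(":\n")
  wide <- benchmark_table(x)
  print(wide, digits = 4)
  invisible(x)
}

#' Benchmark summary in the familiar rows-by-metrics layout
#'
#' @param result A `benchmark_result`.
#' @param stat `"mean"` (default), `"median"`, or `"iqr"`.
#' @return A data frame with one row per method and columns MAE, tau_b,
#'   Accuracy, gamma.
#' @export
benchmark_table <- function(result, stat = c("mean", "median", "iqr")) {
  stat <- match.arg(stat)
  s <- result$summary
  methods <- unique(s$method)
  out <- data.frame(Model = methods)
  for (g in c("mae", "tau_b", "accuracy", "gamma")) {
    out[[g]] <- vapply(methods, function(m) {
      s[[stat]][s$method == m & s$metric == g]
    }, numeric(1))
  }
  colnames(out) <- c("Model", "MAE", "tau_b", "Accuracy", "gamma")
  out
}
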