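## Evaluation suite: RMSE, relative base error decrease (RBED),
## identification curves for the least stable bonds, predictor
## importance, and the leave-one-protein-out protocol.

#' Base models for RBED normalisation
#'
#' `global_mean` predicts the average measured stability of the training
#' table for every occurrence. `single_predictor_tree` is a regression
#' tree grown and pruned with the same settings but a one-predictor
#' registry (e.g. `FIRST_energy` alone, the energy-only baseline).
#'
#' @param kind "global_mean" or "single_predictor_tree".
#' @param train training `hb_table`.
#' @param predictor predictor name for the single-predictor tree.
#' @param validation validation `hb_table` for pruning the
#'   single-predictor tree (skipped when `NULL`).
#' @param max_depth,min_node_size tree settings (defaults 5 / 10).
#' @return An object of class `hb_base_model`.
#' @export
base_model <- function(kind = c("global_mean", "single_predictor_tree"),
                       train, predictor = "FIRST_energy", validation = NULL,
                       max_depth = 5, min_node_size = 10) {
  kind <- match.arg(kind)
  if (kind == "global_mean") {
    obj <- list(kind = kind, mean = mean(train$y))
  } else {
    reg <- attr(train, "registry")
    reg1 <- reg[reg$name == predictor, , drop = FALSE]
    if (nrow(reg1) == 0) stop("predictor not in registry: ", predictor)
    tree <- grow_tree(train, registry = reg1, max_depth = max_depth,
                      min_node_size = min_node_size)
    if (!is.null(validation)) tree <- prune_tree(tree, validation)
    obj <- list(kind = kind, predictor = predictor, tree = tree)
  }
  structure(obj, class = "hb_base_model")
}

#' @export
predict.hb_base_model <- function(object, newdata, ...) {
  if (object$kind == "global_mean") rep(object$mean, nrow(newdata))
  else predict(object$tree, newdata)
}

predict_stability <- function(model, table) {
  if (is.numeric(model) && length(model) == nrow(table)) return(model)
  predict(model, table)
}

#' Root mean square error of a model on a table
#'
#' @param model an `hb_tree`, `hb_base_model`, or a numeric vector of
#'   precomputed predictions.
#' @param table nonempty `hb_table`.
#' @return sqrt(mean((prediction - y)^2)).
#' @export
rmse <- function(model, table) {
  if (nrow(table) == 0) stop("cannot compute RMSE on an empty table")
  sqrt(mean((predict_stability(model, table) - table$y)^2))
}

#' Relative base error decrease (percent)
#'
#' RBED = 100 * (RMSE(base) - RMSE(model)) / RMSE(base): the percent
#' reduction of RMSE relative to a base model. Positive when the model
#' beats the base; at most 100.
#'
#' @param model,base models accepted by [rmse()].
#' @param table nonempty `hb_table`.
#' @return RBED in percent.
#' @export
rbed <- function(model, base, table) {
  r0 <- rmse(base, table)
  if (r0 == 0) stop("base model has zero RMSE; RBED undefined")
  100 * (r0 - rmse(model, table)) / r0
}

#' Identification curve of the least stable occurrences
#'
#' S is the set of the `fraction` (default 10%) occurrences with the
#' smallest measured stability (ties broken by row order; |S| =
#' ceiling(fraction * n)). Occurrences are sorted in ascending order of
#' predicted stability and w(u) is the fraction of S contained in the
#' first 100*u% of that ranking. The ideal curve ranks by true y; an
#' optional base-model curve (e.g. decreasing FIRST_energy, i.e. weakest
#' bonds first) is computed from `base_scores`.
#'
#' @param model model accepted by [rmse()].
#' @param table nonempty `hb_table`.
#' @param fraction least-stable fraction defining S, in (0, 1).
#' @param grid u values; default 101 evenly spaced points in \[0, 1\].
#' @param base_scores optional numeric ranking scores for a base curve
#'   (ascending order = predicted least stable first).
#' @return object of class `hb_ident_curve`: data.frame with columns `u`,
#'   `w_model`, `w_ideal` (and `w_base`), plus attribute `fraction`.
#' @export
identification_curve <- function(model, table, fraction = 0.10,
                                 grid = seq(0, 1, length.out = 101),
                                 base_scores = NULL) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)")
  n <- nrow(table)
  if (n == 0) stop("empty table")
  k_s <- ceiling(fraction * n)
  in_s <- logical(n)
  in_s[order(table$y, seq_len(n))[seq_len(k_s)]] <- TRUE
  curve_for <- function(scores) {
    ord <- order(scores, seq_len(n))        # stable: row order breaks ties
    hits <- cumsum(in_s[ord])
    vapply(grid, function(u) {
      k <- floor(u * n + 1e-9)
      if (k == 0) 0 else hits[k] / k_s
    }, numeric(1))
  }
  out <- data.frame(u = grid,
                    w_model = curve_for(predict_stability(model, table)),
                    w_ideal = curve_for(table$y))
  if (!is.null(base_scores)) out$w_base <- curve_for(base_scores)
  structure(out, fraction = fraction,
            class = c("hb_ident_curve", "data.frame"))
}

#' Predictor importance over one or more trees
#'
#' The raw importance of predictor p in one tree is the sum over the
#' nodes split on p of w(s) * n(s), the split score times the number of
#' training occurrences falling into the node (i.e. the SSE reduction
#' contributed). Importances are averaged across trees; with
#' `scale = TRUE` they are divided by the smallest non-zero average so
#' the least important used predictor maps to exactly 1.
#'
#' @param trees an `hb_tree` or list of `hb_tree`s with compatible
#'   registries.
#' @param scale rescale so the minimum non-zero importance is 1.
#' @return named numeric vector over the registry's predictors (unused
#'   predictors have importance 0).
#' @export
predictor_importance <- function(trees, scale = TRUE) {
  if (inherits(trees, "hb_tree")) trees <- list(trees)
  reg <- trees[[1]]$registry
  acc <- matrix(0, length(trees), nrow(reg),
                dimnames = list(NULL, reg$name))
  for (i in seq_along(trees)) {
    if (!registries_compatible(reg, trees[[i]]$registry))
      stop("trees have incompatible registries")
    walk_nodes(trees[[i]]$root, function(nd) {
      if (!is.null(nd$split))
        acc[i, nd$split$predictor] <<-
          acc[i, nd$split$predictor] + nd$split$score * nd$n
    })
  }
  avg <- colMeans(acc)
  if (all(avg == 0)) return(avg[0])
  if (scale) avg <- avg / min(avg[avg > 0])
  avg
}

#' Leave-one-protein-out evaluation protocol
#'
#' For each held-out table: the remaining tables are mixed at `fraction`,
#' a validation subset is set aside by bond identity, a tree is grown and
#' pruned, and RBED against the training global-mean base is measured on
#' the held-out table. This is repeated `n_models` times with sub-seeds
#' derived from `seed`; the report gives the mean and variance of RBED
#' per held-out table.
#'
#' @param tables list of >= 2 `hb_table`s (one per protein/trajectory).
#' @param fraction per-table sampling fraction for mixing (default 0.1).
#' @param max_depth,min_node_size tree settings (defaults 5 / 10).
#' @param n_models repeats per held-out table (default 10).
#' @param validation_fraction validation share of the mixed table.
#' @param seed master seed.
#' @param base_kind base model for RBED ("global_mean" or
#'   "single_predictor_tree").
#' @param base_predictor predictor for the single-predictor base.
#' @param model_registry optional registry subset used to grow the
#'   evaluated trees (e.g. `default_registry("FIRST_energy")` for the
#'   energy-only comparison); the same seeds produce the same mixes, so
#'   two runs differing only here are directly comparable.
#' @return data.frame of class `hb_loo_report`: one row per held-out
#'   table with `held_out`, `mean_rbed`, `var_rbed`; attribute `rbed`
#'   holds the full repeats matrix.
#' @export
leave_one_protein_out <- function(tables, fraction = 0.1, max_depth = 5,
                                  min_node_size = 10, n_models = 10,
                                  validation_fraction = 0.25, seed = 1,
                                  base_kind = "global_mean",
                                  base_predictor = "FIRST_energy",
                                  model_registry = NULL) {
  stopifnot(length(tables) >= 2)
  labels <- vapply(seq_along(tables), function(j) {
    lb <- unique(tables[[j]]$protein_label)
    if (length(lb) == 1) lb else paste0("table", j)
  }, character(1))
  seeds <- matrix(derive_seeds(seed, length(tables) * n_models),
                  length(tables), n_models)
  rbed_mat <- matrix(NA_real_, length(tables), n_models,
                     dimnames = list(labels, NULL))
  for (j in seq_along(tables)) {
    held <- tables[[j]]
    rest <- tables[-j]
    for (r in seq_len(n_models)) {
      s2 <- derive_seeds(seeds[j, r], 2)
      mixed <- mix_tables(rest, fraction = fraction, seed = s2[1])
      parts <- split_validation(mixed, validation_fraction, seed = s2[2])
      tree <- grow_tree(parts$train, registry = model_registry,
                        max_depth = max_depth,
                        min_node_size = min_node_size)
      tree <- prune_tree(tree, parts$validation)
      base <- base_model(base_kind, parts$train,
                         predictor = base_predictor,
                         validation = parts$validation,
                         max_depth = max_depth,
                         min_node_size = min_node_size)
      rbed_mat[j, r] <- rbed(tree, base, held)
    }
  }
  out <- data.frame(held_out = labels,
                    mean_rbed = rowMeans(rbed_mat),
                    var_rbed = apply(rbed_mat, 1, stats::var))
  structure(out, rbed = rbed_mat,
            class = c("hb_loo_report", "data.frame"))
}
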