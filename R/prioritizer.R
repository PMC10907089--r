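#' Average precision of a ranked binary list
#'
#' `AP = mean over positive ranks k of (number of positives at ranks <= k) / k`.
#' This is the per-fold evaluation metric used during model selection; the
#' mean over cross-validation folds is the mean average precision (MAP).
#'
#' @param ranked_labels Binary vector (1 = positive) ordered from the
#'   highest-scored item down.
#' @return AP in `[0, 1]`.
#' @examples
#' average_precision(c(1, 1, 0, 0)) # 1
#' average_precision(c(1, 0, 1))    # (1/1 + 2/3) / 2
#' @export
average_precision <- function(ranked_labels) {
  y <- as.numeric(ranked_labels)
  if (!all(y %in% c(0, 1))) abort("ranked_labels must be binary")
  if (sum(y) == 0) abort("average precision is undefined without positives")
  prec_at <- cumsum(y) / seq_along(y)
  mean(prec_at[y == 1])
}

#' Balanced accuracy of a ranked binary list at a probability threshold
#'
#' Reported as a secondary metric only; model selection uses
#' [average_precision()].
#'
#' @param labels Binary vector.
#' @param prob Predicted probabilities.
#' @param threshold Classification threshold (default 0.5).
#' @return `(sensitivity + specificity) / 2`.
#' @export
balanced_accuracy <- function(labels, prob, threshold = 0.5) {
  pred <- as.numeric(prob >= threshold)
  sens <- if (sum(labels == 1) > 0) mean(pred[labels == 1] == 1) else NA_real_
  spec <- if (sum(labels == 0) > 0) mean(pred[labels == 0] == 0) else NA_real_
  (sens + spec) / 2
}

#' Model configuration for the two-step prioritizer
#'
#' @param n_folds Cross-validation folds, grouped by locus (default 5).
#' @param search_budget Random hyperparameter draws per step (default 10).
#' @param nrounds_range Boosting-round range searched (default `c(50, 300)`).
#' @param seed Seed controlling fold assignment, the hyperparameter search
#'   and xgboost itself.
#' @return A `model_config` list.
#' @export
model_config <- function(n_folds = 5, search_budget = 10,
                         nrounds_range = c(50, 300), seed = 1L) {
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  structure(list(n_folds = n_folds,
                 search_budget = check_count(search_budget, "search_budget"),
                 nrounds_range = as.integer(nrounds_range),
                 seed = as.integer(seed)),
            class = "model_config")
}

# seeded randomized hyperparameter draws (log-uniform learning rate)
draw_params <- function(budget, nrounds_range) {
  tibble(
    max_depth = sample(2:6, budget, replace = TRUE),
    eta = exp(stats::runif(budget, log(0.02), log(0.3))),
    nrounds = round(stats::runif(budget, nrounds_range[1], nrounds_range[2])),
    min_child_weight = sample(1:5, budget, replace = TRUE),
    subsample = stats::runif(budget, 0.6, 1),
    colsample_bytree = stats::runif(budget, 0.4, 1)
  )
}

# loci with positives are spread round-robin over folds so every fold can
# evaluate average precision; negative-only loci fill up the smallest folds
make_locus_folds <- function(locus_ids, labels, n_folds) {
  per_locus <- tibble(locus_id = locus_ids, label = labels) |>
    group_by(.data$locus_id) |>
    summarise(n_pos = sum(.data$label == 1), .groups = "drop")
  pos_loci <- per_locus |> filter(.data$n_pos > 0)
  neg_loci <- per_locus |> filter(.data$n_pos == 0)
  fold_of <- setNames(integer(0), character(0))
  if (nrow(pos_loci) > 0) {
    sh <- sample(pos_loci$locus_id)
    fold_of[sh] <- rep_len(seq_len(n_folds), length(sh))
  }
  if (nrow(neg_loci) > 0) {
    sh <- sample(neg_loci$locus_id)
    sizes <- tabulate(fold_of, n_folds)
    for (l in sh) {
      f <- which.min(sizes)
      fold_of[l] <- f
      sizes[f] <- sizes[f] + 1
    }
  }
  unname(fold_of[locus_ids])
}

xgb_matrix <- function(matrix, features, label = NULL) {
  X <- as.matrix(matrix[, features, drop = FALSE])
  storage.mode(X) <- "double"
  if (is.null(label)) xgboost::xgb.DMatrix(X, missing = NA)
  else xgboost::xgb.DMatrix(X, label = label, missing = NA)
}

fit_xgb <- function(dtrain, params, nrounds, pos_weight, seed) {
  xgboost::xgb.train(
    params = c(params, list(
      objective = "binary:logistic",
      scale_pos_weight = pos_weight,
      nthread = 1, seed = seed)),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

# locus-grouped CV MAP for one hyperparameter draw
cv_map <- function(matrix, features, y, fold, params_row, pos_weight, seed) {
  folds <- sort(unique(fold))
  aps <- rep(NA_real_, length(folds))
  bas <- rep(NA_real_, length(folds))
  for (i in seq_along(folds)) {
    te <- fold == folds[i]
    if (sum(y[te] == 1) == 0) next  # AP undefined; fold skipped from the mean
    dtr <- xgb_matrix(matrix[!te, ], features, y[!te])
    fit <- fit_xgb(dtr, as.list(params_row[setdiff(names(params_row), "nrounds")]),
                   params_row$nrounds, pos_weight, seed)
    pr <- stats::predict(fit, xgb_matrix(matrix[te, ], features))
    ord <- order(pr, decreasing = TRUE)
    aps[i] <- average_precision(y[te][ord])
    bas[i] <- balanced_accuracy(y[te], pr)
  }
  list(map = mean(aps, na.rm = TRUE), fold_ap = aps, fold_ba = bas)
}

#' Two-step training of the locus-to-gene prioritizer
#'
#' Step 1 fits an imbalance-weighted gradient-boosted classifier on all
#' features (`scale_pos_weight` = number of negatives / number of
#' positives) and retains the features the fitted ensemble actually uses
#' (nonzero split importance). Step 2 re-tunes and refits on the retained
#' subset. Both steps run a seeded randomized hyperparameter search scored
#' by mean average precision under locus-grouped cross-validation (all
#' genes of a locus share a fold, so the within-locus neighbourhood
#' normalisation cannot leak across the split). Missing feature values are
#' handled natively by the tree learner.
#'
#' @param matrix Neighbourhood feature matrix ([neighbourhood_transform()]).
#' @param labels Tibble with `pair_id` (or `gene_id`) and `label` in
#'   `{1, 0, NA}`; only labelled rows train.
#' @param config A [model_config()].
#' @return A `trained_prioritizer` with elements `model` (xgboost handle),
#'   `selected_features`, `features_step1`, `cv_report` (per-step, per-draw
#'   fold APs and MAP) and `manifest` (label counts, `pos_weight`, seed).
#' @export
train_two_step <- function(matrix, labels, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  if (!identical(attr(matrix, "state"), "neighbourhood")) {
    warn("matrix does not carry state 'neighbourhood'; training on it as-is")
  }
  key <- if ("pair_id" %in% names(labels)) "pair_id" else "gene_id"
  lab <- labels |> filter(!is.na(.data$label))
  dat <- matrix |> inner_join(lab |> select(dplyr::all_of(key), "label"), by = key)
  n_pos <- sum(dat$label == 1)
  n_neg <- sum(dat$label == 0)
  if (n_pos < 2 || n_neg < 2) abort("need at least 2 positive and 2 negative labels")
  small <- dat |> dplyr::count(.data$locus_id) |> filter(.data$n < 2)
  if (nrow(small) > 0) {
    warn(sprintf("%d labelled locus/loci have < 2 genes", nrow(small)))
  }
  pos_weight <- n_neg / n_pos
  features <- setdiff(names(matrix), c("pair_id", "locus_id", "gene_id"))
  y <- dat$label

  withr::with_seed(config$seed, {
    fold <- make_locus_folds(dat$locus_id, y, config$n_folds)

    run_step <- function(step, feats) {
      grid <- draw_params(config$search_budget, config$nrounds_range)
      res <- purrr::map(seq_len(nrow(grid)), function(i) {
        cv_map(dat, feats, y, fold, grid[i, ], pos_weight, config$seed)
      })
      grid$map <- purrr::map_dbl(res, "map")
      grid$fold_ap <- purrr::map(res, "fold_ap")
      grid$fold_ba <- purrr::map(res, "fold_ba")
      grid$step <- step
      best <- which.max(grid$map)
      dtr <- xgb_matrix(dat, feats, y)
      fit <- fit_xgb(dtr,
                     as.list(grid[best, c("max_depth", "eta", "min_child_weight",
                                          "subsample", "colsample_bytree")]),
                     grid$nrounds[best], pos_weight, config$seed)
      list(grid = grid, best = best, fit = fit)
    }

    s1 <- run_step(1L, features)
    imp <- xgboost::xgb.importance(model = s1$fit)
    selected <- intersect(features, imp$Feature[imp$Frequency > 0])
    if (length(selected) == 0) {
      abort("all features were eliminated in step 1", class = "l2g_no_features")
    }
    s2 <- run_step(2L, selected)

    structure(list(
      model = s2$fit,
      selected_features = selected,
      features_step1 = features,
      step1_model = s1$fit,
      cv_report = bind_rows(s1$grid, s2$grid) |>
        relocate("step") |>
        mutate(chosen = row_number() %in%
                 c(s1$best, nrow(s1$grid) + s2$best)),
      manifest = list(n_pos = n_pos, n_neg = n_neg,
                      pos_weight = pos_weight,
                      n_folds = config$n_folds,
                      seed = config$seed,
                      best_map = s2$grid$map[s2$best])
    ), class = "trained_prioritizer")
  })
}

#' @export
print.trained_prioritizer <- function(x, ...) {
  cat("<trained_prioritizer>\n")
  cat(sprintf("  labels: %d positive / %d negative (pos_weight = %.4f)\n",
              x$manifest$n_pos, x$manifest$n_neg, x$manifest$pos_weight))
  cat(sprintf("  features: %d selected of %d\n",
              length(x$selected_features), length(x$features_step1)))
  cat(sprintf("  CV MAP (final model): %.3f over %d locus-grouped folds\n",
              x$manifest$best_map, x$manifest$n_folds))
  invisible(x)
}

#' Score all locus-gene pairs with a trained prioritizer
#'
#' @param model A `trained_prioritizer`.
#' @param matrix Neighbourhood feature matrix whose columns cover the
#'   model's selected features. Rows with all-missing selected features are
#'   still scored (native missing handling).
#' @return Tibble `locus_id`, `gene_id`, `pair_id`, `probability`, sorted by
#'   locus then descending probability.
#' @export
score_genes <- function(model, matrix) {
  stopifnot(inherits(model, "trained_prioritizer"))
  missing_cols <- setdiff(model$selected_features, names(matrix))
  if (length(missing_cols) > 0) {
    abort(paste0("matrix is missing required feature column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  pr <- stats::predict(model$model, xgb_matrix(matrix, model$selected_features))
  matrix |>
    select("locus_id", "gene_id", "pair_id") |>
    mutate(probability = as.numeric(pr)) |>
    arrange(.data$locus_id, dplyr::desc(.data$probability))
}

#' Closest-gene baseline ranking MAP on the same folds
#'
#' Ranks genes within each held-out locus purely by the lead-to-gene
#' distance neighbourhood score and computes MAP over the same
#' locus-grouped folds the model used; the learned model is expected to
#' beat this baseline in informative regimes.
#'
#' @param matrix Neighbourhood matrix containing `dist_lead_gene`.
#' @param labels Labels as in [train_two_step()].
#' @param model A fitted `trained_prioritizer` (for its fold seed/config).
#' @return MAP of the closest-gene ranking.
#' @export
closest_gene_map <- function(matrix, labels, model) {
  key <- if ("pair_id" %in% names(labels)) "pair_id" else "gene_id"
  lab <- labels |> filter(!is.na(.data$label))
  dat <- matrix |> inner_join(lab |> select(dplyr::all_of(key), "label"), by = key)
  withr::with_seed(model$manifest$seed, {
    fold <- make_locus_folds(dat$locus_id, dat$label, model$manifest$n_folds)
  })
  score <- dat$dist_lead_gene  # neighbourhood score: 1 = closest
  score[is.na(score)] <- 0
  aps <- purrr::map_dbl(sort(unique(fold)), function(f) {
    te <- fold == f
    if (sum(dat$label[te] == 1) == 0) return(NA_real_)
    ord <- order(score[te], decreasing = TRUE)
    average_precision(dat$label[te][ord])
  })
  mean(aps, na.rm = TRUE)
}
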