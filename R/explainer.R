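# flatten a fitted booster into per-tree node arrays for the C++ walker;
# thresholds are rounded to float32 to match the learner's comparisons
parse_booster <- function(model, features) {
  td <- as.data.frame(xgboost::xgb.model.dt.tree(model = model))
  td$Split <- f32(td$Split)
  base_score <- as.numeric(
    xgboost::xgb.config(model)$learner$learner_model_param$base_score)
  trees <- lapply(split(td, td$Tree), function(tt) {
    tt <- tt[order(tt$Node), ]
    idx <- function(id) ifelse(is.na(id), -1L, match(id, tt$ID) - 1L)
    list(
      left = as.integer(idx(tt$Yes)),
      right = as.integer(idx(tt$No)),
      missing = as.integer(idx(tt$Missing)),
      feature = as.integer(ifelse(tt$Feature == "Leaf", -1L,
                                  match(tt$Feature, features) - 1L)),
      threshold = as.numeric(ifelse(is.na(tt$Split), 0, tt$Split)),
      value = as.numeric(ifelse(tt$Feature == "Leaf", tt$Gain, 0)),
      cover = as.numeric(tt$Cover)
    )
  })
  list(trees = unname(trees), base_margin = stats::qlogis(base_score))
}

#' Exact tree-Shapley attribution of gene scores
#'
#' Decomposes every row's score into a base value (the cover-weighted
#' expected model margin) plus one additive contribution per feature, using
#' the exact polynomial-time tree-ensemble Shapley algorithm, re-walking the
#' fitted trees with double-precision accumulation. Attribution is on the
#' margin (log-odds) scale, the only scale on which tree-path attribution is
#' exactly additive: `base_value + sum(contributions) = margin` for every
#' row, to well within 1e-6.
#'
#' @param model A `trained_prioritizer`.
#' @param matrix Neighbourhood feature matrix covering the model's selected
#'   features.
#' @return An `l2g_attribution` tibble: `pair_id`, `locus_id`, `gene_id`,
#'   `base_value`, `margin`, `probability`, then one contribution column per
#'   selected feature.
#' @export
attribute <- function(model, matrix) {
  stopifnot(inherits(model, "trained_prioritizer"))
  missing_cols <- setdiff(model$selected_features, names(matrix))
  if (length(missing_cols) > 0) {
    abort(paste0("matrix is missing required feature column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(matrix[, model$selected_features, drop = FALSE])
  storage.mode(X) <- "double"
  X[] <- f32(X)
  booster <- parse_booster(model$model, model$selected_features)
  res <- treeshap_ensemble(X, booster$trees, booster$base_margin)
  contrib <- res$contrib
  colnames(contrib) <- model$selected_features
  out <- bind_cols(
    matrix |> select("pair_id", "locus_id", "gene_id"),
    tibble(base_value = as.numeric(res$base),
           margin = as.numeric(res$margin),
           probability = stats::plogis(as.numeric(res$margin))),
    as_tibble(contrib)
  )
  resid <- abs(out$base_value + rowSums(contrib) - out$margin)
  if (any(resid > 1e-6)) {
    abort(sprintf("Shapley additivity violated (max residual %.2e)", max(resid)))
  }
  class(out) <- c("l2g_attribution", class(out))
  attr(out, "features") <- model$selected_features
  attr(out, "max_additivity_residual") <- max(resid)
  out
}

attribution_features <- function(attributions) {
  attr(attributions, "features") %||%
    setdiff(names(attributions),
            c("pair_id", "locus_id", "gene_id", "base_value", "margin",
              "probability"))
}

#' Global feature importance from Shapley attributions
#'
#' Ranks features by the mean absolute Shapley contribution across rows
#' (the ordering behind bee-swarm importance plots) and keeps the
#' per-feature contribution distribution for plotting.
#'
#' @param attributions An `l2g_attribution` from [attribute()].
#' @return Tibble `feature`, `mean_abs_contribution`, `contributions`
#'   (list-column), sorted by decreasing importance.
#' @export
global_importance <- function(attributions) {
  feats <- attribution_features(attributions)
  if (nrow(attributions) == 0) abort("no attributions supplied")
  purrr::map_dfr(feats, function(f) {
    v <- attributions[[f]]
    tibble(feature = f, mean_abs_contribution = mean(abs(v)),
           contributions = list(v))
  }) |>
    arrange(dplyr::desc(.data$mean_abs_contribution))
}

#' Waterfall decomposition of one gene's score
#'
#' The `n_top` features with the largest absolute contributions are listed
#' with signed values; all remaining features are lumped into a single
#' remainder term chosen so that additivity is preserved exactly:
#' `base_value + sum(shown) + remainder = margin`.
#'
#' @param attributions An `l2g_attribution`.
#' @param pair_id Row to decompose.
#' @param n_top Number of features to show (default 10).
#' @return Tibble `feature`, `contribution`, ordered by decreasing absolute
#'   contribution, with a final `"(remaining)"` row, plus attributes
#'   `base_value` and `margin`.
#' @export
waterfall <- function(attributions, pair_id, n_top = 10) {
  if (n_top < 1) abort("n_top must be >= 1")
  row <- attributions |> filter(.data$pair_id == !!pair_id)
  if (nrow(row) != 1) abort("pair_id not found (or not unique) in attributions")
  feats <- attribution_features(attributions)
  contrib <- unlist(row[, feats])
  ord <- order(abs(contrib), decreasing = TRUE)
  top <- utils::head(ord, n_top)
  remainder <- row$margin - row$base_value - sum(contrib[top])
  out <- bind_rows(
    tibble(feature = names(contrib)[top], contribution = unname(contrib[top])),
    tibble(feature = "(remaining)", contribution = remainder)
  )
  attr(out, "base_value") <- row$base_value
  attr(out, "margin") <- row$margin
  out
}
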