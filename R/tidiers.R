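#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained prioritizer into its feature-importance table
#'
#' @param x A `trained_prioritizer`.
#' @param ... Unused.
#' @return Tibble `feature`, `gain`, `frequency`, for the selected features
#'   of the final model.
#' @method tidy trained_prioritizer
#' @export
tidy.trained_prioritizer <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$model)
  tibble(feature = imp$Feature, gain = imp$Gain, frequency = imp$Frequency)
}

#' One-row summary of a trained prioritizer
#'
#' @param x A `trained_prioritizer`.
#' @param ... Unused.
#' @return Tibble with label counts, `pos_weight`, feature counts and the
#'   final cross-validated MAP.
#' @method glance trained_prioritizer
#' @export
glance.trained_prioritizer <- function(x, ...) {
  tibble(
    n_pos = x$manifest$n_pos, n_neg = x$manifest$n_neg,
    pos_weight = x$manifest$pos_weight,
    n_features_in = length(x$features_step1),
    n_features_selected = length(x$selected_features),
    n_folds = x$manifest$n_folds,
    cv_map = x$manifest$best_map
  )
}

#' Tidy a meta-analysis result
#'
#' @param x An `l2g_meta`.
#' @param ... Unused.
#' @return The pooled one-row tibble.
#' @method tidy l2g_meta
#' @export
tidy.l2g_meta <- function(x, ...) x$pooled

#' One-row meta-analysis summary including heterogeneity flags
#'
#' @param x An `l2g_meta`.
#' @param ... Unused.
#' @method glance l2g_meta
#' @export
glance.l2g_meta <- function(x, ...) {
  x$pooled |>
    mutate(n_outlier_flagged = sum(x$leave_one_out$outlier_flag))
}
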