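# broom-style tidiers and ggplot2 display helpers.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted regulation model
#'
#' Logistic models yield one row per coefficient; tree ensembles one row
#' per feature with its importance (impurity importance for random forests,
#' total gain for gradient boosted trees).
#'
#' @param x A `reg_model`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`.
#' @export
tidy.reg_model <- function(x, ...) {
  if (x$family == "logistic") {
    tibble(term = names(x$fitted$coef), estimate = unname(x$fitted$coef))
  } else if (x$family == "random_forest") {
    imp <- tryCatch(ranger::importance(x$fitted$fit), error = function(e) NULL)
    if (is.null(imp)) {
      tibble(term = x$feature_ids, estimate = NA_real_)
    } else {
      tibble(term = names(imp), estimate = unname(imp)) |>
        arrange(desc(.data$estimate))
    }
  } else {
    imp <- xgboost::xgb.importance(model = x$fitted$fit)
    tibble(term = imp$Feature, estimate = imp$Gain)
  }
}

#' One-row summary of a fitted regulation model
#'
#' @param x A `reg_model`.
#' @param ... Unused.
#' @return Tibble with family, feature count, training size, training
#'   prior, and inner-CV rocAUC when a grid search was run.
#' @export
glance.reg_model <- function(x, ...) {
  tibble(family = x$family, n_features = length(x$feature_ids),
         n_train = x$n_train, prior = x$prior, inner_auc = x$inner_auc)
}

#' Tidy a feature selection
#'
#' @param x A `feature_selection`.
#' @param ... Unused.
#' @return The selected-feature score tibble, in selection order, with a
#'   `rank` column.
#' @export
tidy.feature_selection <- function(x, ...) {
  out <- x$selected
  out$rank <- seq_len(nrow(out))
  out
}

#' One-row summary of a feature selection
#'
#' @param x A `feature_selection`.
#' @param ... Unused.
#' @return Tibble with counts and the selection parameters.
#' @export
glance.feature_selection <- function(x, ...) {
  tibble(n_selected = nrow(x$selected), n_redundant = nrow(x$redundant),
         n_screened_out = x$screened_out, k_max = x$k_max, p_max = x$p_max,
         redundancy_cap = x$redundancy_cap)
}

#' Lift chart of the top selected features
#'
#' Horizontal bars of the dominant-class lift of the strongest features,
#' split by the class each feature argues for - the canonical display of
#' what drives (and what argues against) miRNA regulation.
#'
#' @param object A `feature_selection`.
#' @param n_top Number of features shown per class.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_selection <- function(object, n_top = 15, ...) {
  dat <- object$selected |>
    filter(!is.na(.data$dominant_class)) |>
    mutate(lift = ifelse(.data$dominant_class == 1, .data$lift_pos, .data$lift_neg),
           class_lab = ifelse(.data$dominant_class == 1,
                              "favours regulation", "against regulation")) |>
    group_by(.data$class_lab) |>
    slice_max(.data$rig, n = n_top, with_ties = FALSE) |>
    ungroup()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$lift,
                                    y = stats::reorder(.data$feature_id, .data$lift))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~.data$class_lab, scales = "free") +
    ggplot2::labs(x = "lift of dominant class", y = NULL,
                  title = "Top ranked features by relative information gain") +
    ggplot2::theme_minimal()
}

#' Bar chart of ablation rocAUCs
#'
#' @param ablation Tibble from [ablation_run()].
#' @return A ggplot object.
#' @export
plot_ablation <- function(ablation) {
  ggplot2::ggplot(ablation,
                  ggplot2::aes(x = stats::reorder(.data$feature_set, .data$roc_auc),
                               y = .data$roc_auc)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::coord_cartesian(ylim = c(0.5, 1)) +
    ggplot2::labs(x = NULL, y = "rocAUC",
                  title = "Feature-set ablation on a shared held-out split") +
    ggplot2::theme_minimal()
}

#' Family regulated-fraction plot
#'
#' Families ordered by regulated fraction around the global prior line,
#' the display used to spot coherently regulated (kinase-like) and
#' coherently unregulated (histone/GPCR-like) families.
#'
#' @param fractions Tibble from [family_fractions()].
#' @param prior Global regulated prior drawn as a dashed line.
#' @param p_cut Only families with a two-sided binomial p below this are
#'   shown (default 1e-3).
#' @param n_max Cap on families displayed.
#' @return A ggplot object.
#' @export
plot_family_fractions <- function(fractions, prior, p_cut = 1e-3, n_max = 30) {
  dat <- fractions |>
    filter(.data$binom_p_two_sided < p_cut) |>
    slice_min(.data$binom_p_two_sided, n = n_max, with_ties = FALSE)
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = .data$fraction_regulated,
                               y = stats::reorder(.data$family_id,
                                                  .data$fraction_regulated),
                               size = .data$n_members)) +
    ggplot2::geom_point(colour = "darkorange") +
    ggplot2::geom_vline(xintercept = prior, linetype = "dashed") +
    ggplot2::labs(x = "fraction of members regulated", y = NULL, size = "members",
                  title = "Families deviating from the global regulation prior") +
    ggplot2::theme_minimal()
}
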