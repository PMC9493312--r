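# Classifier training and evaluation: stratified splits, three model
# families (logistic, random forest, gradient boosted trees), held-out and
# cross-species evaluation, feature-set ablations, proteome-wide prediction.

#' Stratified train/test split
#'
#' Splits genes into disjoint, exhaustive train and test sets, stratified by
#' the binary label (per class, `round(test_fraction * n_class)` genes go to
#' the test set). Deterministic given `seed`.
#'
#' @param genes Character vector of gene names.
#' @param labels Binary labels aligned with `genes` (any form accepted by
#'   the package's label coercion).
#' @param test_fraction Fraction held out (0 < f < 1, default 0.2).
#' @param seed Integer seed.
#' @return Tibble `gene_name`, `label`, `split` (`"train"`/`"test"`).
#' @export
split_train_test <- function(genes, labels, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  y <- align_labels(labels, genes)
  if (min(table(factor(y, levels = 0:1))) < 2) {
    stop("each class needs at least 2 members to stratify", call. = FALSE)
  }
  split <- rep("train", length(genes))
  withr::with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      n_test <- round(test_fraction * length(idx))
      split[sample(idx, n_test)] <- "test"
    }
  })
  tibble(gene_name = genes, label = y, split = split)
}

model_families <- c("logistic", "random_forest", "gradient_boosted_trees")

#' Default hyperparameter grids per model family
#'
#' @param family Model family name.
#' @return Tibble of candidate settings (one row per configuration).
#' @export
default_hyper_grid <- function(family = model_families) {
  family <- match.arg(family)
  switch(family,
    logistic = tibble(dummy = 1),
    random_forest = tidyr::expand_grid(num_trees = 300, mtry_frac = c(0.1, 0.33)),
    gradient_boosted_trees = tidyr::expand_grid(nrounds = c(50, 150),
                                                max_depth = c(3, 5), eta = 0.1)
  )
}

impute_medians <- function(x, medians = NULL) {
  if (is.null(medians)) {
    medians <- apply(x, 2, function(col) {
      m <- median(col, na.rm = TRUE)
      if (is.na(m)) 0 else m
    })
  }
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- medians[j]
  }
  list(x = x, medians = medians)
}

fit_family <- function(x, y, family, params, seed) {
  if (family == "logistic") {
    fit <- suppressWarnings(stats::glm.fit(cbind(`(Intercept)` = 1, x), y,
                                           family = stats::binomial()))
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    list(kind = "logistic", coef = coefs)
  } else if (family == "random_forest") {
    fit <- ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                          probability = TRUE,
                          num.trees = params$num_trees %||% 300,
                          mtry = max(1L, floor((params$mtry_frac %||% 0.33) * ncol(x))),
                          seed = seed, num.threads = 1)
    list(kind = "random_forest", fit = fit)
  } else {
    withr::with_seed(seed, {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth %||% 4,
                      eta = params$eta %||% 0.1,
                      nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = params$nrounds %||% 100, verbose = 0)
    })
    list(kind = "gradient_boosted_trees", fit = fit)
  }
}

predict_family <- function(fitted, x) {
  switch(fitted$kind,
    logistic = as.vector(stats::plogis(cbind(1, x) %*% fitted$coef)),
    random_forest = {
      p <- predict(fitted$fit, data = x, num.threads = 1)$predictions
      as.vector(p[, "1"])
    },
    gradient_boosted_trees = as.vector(
      predict(fitted$fit, xgboost::xgb.DMatrix(x, nthread = 1)))
  )
}

#' Train a binary regulation classifier
#'
#' Fits one of the three supported model families on a training feature
#' matrix. When a hyperparameter grid with more than one row is supplied,
#' the configuration is chosen by stratified `n_folds`-fold cross-validated
#' rocAUC computed *within the training data only*; the winning setting is
#' refit on all of it. Missing numeric values are imputed by the training
#' median (stored for prediction time).
#'
#' @param fm_train `feature_matrix` of the training genes (already projected
#'   onto the selected features).
#' @param labels Binary training labels.
#' @param family `"logistic"`, `"random_forest"`, or
#'   `"gradient_boosted_trees"`.
#' @param hyper_grid Optional tibble of candidate settings; `NULL` uses the
#'   family's single default configuration without inner CV.
#' @param inner_seed Seed for inner CV folds and stochastic learners.
#' @param n_folds Inner CV folds (default 5).
#' @return A `reg_model` object.
#' @export
train_model <- function(fm_train, labels, family = model_families,
                        hyper_grid = NULL, inner_seed = 1L, n_folds = 5L) {
  family <- match.arg(family)
  y <- align_labels(labels, fm_train$genes)
  x <- fm_train$values
  imp <- impute_medians(x)
  x <- imp$x

  grid <- hyper_grid %||% default_hyper_grid(family)[1, , drop = FALSE]
  inner_auc <- NA_real_
  if (nrow(grid) > 1L) {
    folds <- integer(length(y))
    withr::with_seed(derive_seed(inner_seed, 7L), {
      for (cls in c(0L, 1L)) {
        idx <- which(y == cls)
        folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
    })
    cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
      aucs <- vapply(seq_len(n_folds), function(f) {
        tr <- folds != f
        fit <- fit_family(x[tr, , drop = FALSE], y[tr], family,
                          as.list(grid[g, ]), derive_seed(inner_seed, f))
        roc_auc(predict_family(fit, x[!tr, , drop = FALSE]), y[!tr])
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(cv_auc)
    grid <- grid[best, , drop = FALSE]
    inner_auc <- cv_auc[best]
  }

  fitted <- fit_family(x, y, family, as.list(grid), derive_seed(inner_seed, 11L))
  structure(list(family = family, fitted = fitted,
                 feature_ids = colnames(x),
                 feature_kinds = setNames(fm_train$descriptors$kind,
                                          fm_train$descriptors$feature_id),
                 medians = imp$medians,
                 params = as.list(grid), inner_auc = inner_auc,
                 n_train = length(y), prior = mean(y)),
            class = "reg_model")
}

#' @export
print.reg_model <- function(x, ...) {
  cat(sprintf("<reg_model> %s on %d features, %d training genes (prior %.3f)\n",
              x$family, length(x$feature_ids), x$n_train, x$prior))
  invisible(x)
}

# Project a feature matrix onto a model's feature space: absent binary
# features become 0 (an unseen annotation is simply absent), absent numeric
# features take the training median.
project_matrix <- function(model, fm) {
  present <- intersect(model$feature_ids, colnames(fm$values))
  if (length(present) == 0L) {
    stop("no overlap between the model's feature space and the supplied matrix",
         call. = FALSE)
  }
  x <- matrix(0, nrow = length(fm$genes), ncol = length(model$feature_ids),
              dimnames = list(fm$genes, model$feature_ids))
  absent <- setdiff(model$feature_ids, present)
  for (f in absent) {
    if (identical(unname(model$feature_kinds[f]), "numeric")) {
      x[, f] <- model$medians[f]
    }
  }
  x[, present] <- fm$values[, present]
  impute_medians(x, model$medians)$x
}

#' Predict regulation scores
#'
#' @param object A `reg_model`.
#' @param fm A `feature_matrix` (projected automatically onto the model's
#'   feature space).
#' @param ... Unused.
#' @return Numeric scores in \[0, 1\], one per gene of `fm`.
#' @export
predict.reg_model <- function(object, fm, ...) {
  predict_family(object$fitted, project_matrix(object, fm))
}

#' Area under the ROC curve
#'
#' The probability that a uniformly random positive outscores a uniformly
#' random negative, ties counted one half (equivalent to the rank/
#' Mann-Whitney form).
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return rocAUC, or `NA` when only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate scores against binary labels
#'
#' Computes rocAUC, the confusion table at `threshold`, accuracy
#' (TP + TN) / n and F1 = 2TP / (2TP + FP + FN) (both with class 1 as
#' positive), and precision/recall of the *minority* class of the evaluated
#' labels, the convention used for species with very skewed priors.
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param labels 0/1 labels.
#' @param threshold Decision threshold (default 0.5; predicted label is 1
#'   iff score >= threshold).
#' @return One-row tibble (class `reg_evaluation`).
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  y <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  n <- length(y)
  minority <- if (sum(y == 1) <= sum(y == 0)) 1L else 0L
  if (minority == 1L) {
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  } else {
    prec <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
    rec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  }
  out <- tibble(
    n_test = n,
    prior_pos = mean(y),
    roc_auc = roc_auc(scores, y),
    minority_class = minority,
    precision_minority = prec,
    recall_minority = rec,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    accuracy = (tp + tn) / n,
    tp = tp, fp = fp, fn = fn, tn = tn,
    threshold = threshold
  )
  class(out) <- c("reg_evaluation", class(out))
  out
}

#' Evaluate a model on a held-out feature matrix
#'
#' @param model A `reg_model`.
#' @param fm Test `feature_matrix` (must not share genes with training).
#' @param labels Binary test labels.
#' @param threshold Decision threshold.
#' @return One-row `reg_evaluation` tibble.
#' @export
evaluate_model <- function(model, fm, labels, threshold = 0.5) {
  y <- align_labels(labels, fm$genes)
  evaluate_scores(predict(model, fm), y, threshold)
}

#' Cross-species evaluation
#'
#' Evaluates a model trained on one organism over the *entire* proteome of
#' another: the second organism's features are projected onto the model's
#' selected feature space (absent annotation features are treated as 0) and
#' no split is made. The report is tagged with the train/test organisms.
#'
#' @param model `reg_model` fitted on organism A.
#' @param fm_other `feature_matrix` of organism B.
#' @param labels_other Binary labels of organism B.
#' @param train_organism,test_organism Tags recorded in the report.
#' @param threshold Decision threshold.
#' @return One-row `reg_evaluation` tibble with organism columns.
#' @export
cross_species_evaluate <- function(model, fm_other, labels_other,
                                   train_organism = "A", test_organism = "B",
                                   threshold = 0.5) {
  rep_ <- evaluate_model(model, fm_other, labels_other, threshold)
  bind_cols(tibble(trained_on = train_organism, evaluated_on = test_organism),
            rep_)
}

#' Feature-set ablation on a shared split
#'
#' Trains and evaluates one model per feature set on an identical
#' train/test partition so the rocAUCs are directly comparable
#' (protein vs sequence-only vs genomic vs unified). Feature selection is
#' rerun inside each set on the training genes only.
#'
#' @param feature_sets Named list of `feature_matrix` objects over the same
#'   gene universe (e.g. `protein_full`, `protein_sequence_only`, `genomic`,
#'   `unified`).
#' @param labels Binary labels over the universe.
#' @param split Split tibble from [split_train_test()].
#' @param family Model family.
#' @param k_max,p_max,redundancy_cap Selection parameters.
#' @param seed Seed for the learners.
#' @param threshold Decision threshold.
#' @return Tibble with one evaluation row per feature set.
#' @export
ablation_run <- function(feature_sets, labels, split, family = "logistic",
                         k_max = 300L, p_max = 1e-4, redundancy_cap = 0.95,
                         seed = 1L, threshold = 0.5) {
  purrr::imap_dfr(feature_sets, function(fm, set_name) {
    fit <- fit_evaluate(fm, labels, split, family = family, k_max = k_max,
                        p_max = p_max, redundancy_cap = redundancy_cap,
                        seed = seed, threshold = threshold)
    bind_cols(tibble(feature_set = set_name, n_selected = nrow(fit$selection$selected)),
              fit$evaluation)
  })
}

#' Select features on the training genes, train, and evaluate held-out
#'
#' The package's standard in-species protocol: feature scoring and
#' selection see only the training split, the model is fit on the training
#' genes over the selected features, and the report comes from the disjoint
#' test genes. With no feature passing the screen the model degenerates to
#' the intercept (all scores equal), which evaluates to rocAUC 0.5.
#'
#' @param fm `feature_matrix` over the full universe.
#' @param labels Binary labels.
#' @param split Split tibble from [split_train_test()].
#' @param family Model family.
#' @param k_max,p_max,redundancy_cap Selection parameters.
#' @param hyper_grid Optional grid for inner CV.
#' @param seed Seed.
#' @param threshold Decision threshold.
#' @return List with `model`, `selection`, `evaluation`, `scores_test`.
#' @export
fit_evaluate <- function(fm, labels, split, family = "logistic",
                         k_max = 300L, p_max = 1e-4, redundancy_cap = 0.95,
                         hyper_grid = NULL, seed = 1L, threshold = 0.5) {
  tr_genes <- split$gene_name[split$split == "train"]
  te_genes <- split$gene_name[split$split == "test"]
  y <- setNames(split$label, split$gene_name)
  fm_tr <- subset_genes(fm, tr_genes)

  sc <- score_features(fm_tr, y[tr_genes])
  sel <- dedupe_and_select(sc, fm_tr, k_max = k_max, p_max = p_max,
                           redundancy_cap = redundancy_cap)
  if (nrow(sel$selected) == 0L) {
    prior <- mean(y[tr_genes])
    scores_te <- rep(prior, length(te_genes))
    model <- NULL
    evaluation <- evaluate_scores(scores_te, y[te_genes], threshold)
  } else {
    fm_tr_sel <- restrict_features(fm_tr, sel$selected$feature_id)
    model <- train_model(fm_tr_sel, y[tr_genes], family = family,
                         hyper_grid = hyper_grid, inner_seed = seed)
    fm_te <- subset_genes(fm, te_genes)
    scores_te <- predict(model, fm_te)
    evaluation <- evaluate_scores(scores_te, y[te_genes], threshold)
  }
  list(model = model, selection = sel, evaluation = evaluation,
       scores_test = tibble(gene_name = te_genes, score = scores_te,
                            label = unname(y[te_genes])))
}

# Keep only the given feature columns (selection order preserved).
restrict_features <- function(fm, feature_ids) {
  idx <- match(feature_ids, colnames(fm$values))
  structure(list(genes = fm$genes,
                 values = fm$values[, idx, drop = FALSE],
                 descriptors = fm$descriptors[match(feature_ids,
                                                    fm$descriptors$feature_id), ]),
            class = "feature_matrix")
}

#' Score a whole proteome and rank the predictions
#'
#' @param model A `reg_model`.
#' @param fm `feature_matrix` of the proteome to score.
#' @param known_labels Optional binary labels to carry along.
#' @param threshold Decision threshold for `predicted_label`.
#' @return Tibble `gene_name`, `score`, `predicted_label`, optional
#'   `known_label`, sorted by decreasing score (ties by gene name). The
#'   TSV export convention multiplies scores by 100.
#' @export
predict_proteome <- function(model, fm, known_labels = NULL, threshold = 0.5) {
  scores <- predict(model, fm)
  out <- tibble(gene_name = fm$genes, score = scores,
                predicted_label = as.integer(scores >= threshold))
  if (!is.null(known_labels)) {
    out$known_label <- align_labels(known_labels, fm$genes)
  }
  out |> arrange(desc(.data$score), .data$gene_name)
}

#' Write a prediction table (scores scaled to 0-100)
#'
#' @param predictions Output of [predict_proteome()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(predictions, path) {
  out <- predictions |> mutate(score = 100 * .data$score)
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Concordance of two binary label vectors (phi coefficient)
#'
#' Pearson correlation of two aligned 0/1 vectors, used to compare predicted
#' labels with an external reference labeling.
#'
#' @param predicted,reference Aligned 0/1 vectors.
#' @return Phi coefficient, or `NA` (with a warning) when either vector is
#'   constant.
#' @export
label_concordance <- function(predicted, reference) {
  if (length(predicted) != length(reference)) stop("length mismatch", call. = FALSE)
  if (length(unique(predicted)) < 2 || length(unique(reference)) < 2) {
    warning("constant label vector; concordance undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(as.numeric(predicted), as.numeric(reference))
}
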