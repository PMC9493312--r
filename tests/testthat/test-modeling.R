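test_that("stratified splits have exact class arithmetic and are seeded", {
  genes <- paste0("g", 1:100)
  y <- c(rep(1L, 75), rep(0L, 25))
  sp <- split_train_test(genes, y, 0.2, seed = 5)
  test <- sp[sp$split == "test", ]
  expect_equal(sum(test$label == 1), 15)
  expect_equal(sum(test$label == 0), 5)
  expect_identical(sp, split_train_test(genes, y, 0.2, seed = 5))
  sp2 <- split_train_test(genes, y, 0.2, seed = 6)
  expect_false(identical(sp, sp2))
  expect_equal(table(sp2$split, sp2$label), table(sp$split, sp$label))
  expect_error(split_train_test(genes[1:3], c(1L, 1L, 0L), 0.2, 1), "2 members")
})

test_that("rocAUC equals brute-force pairwise computation", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  set.seed(20)
  for (i in 1:20) {
    n <- sample(20:500, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    s <- sample(round(runif(n), 2))  # ties on purpose
    expect_equal(roc_auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
  }
  expect_true(is.na(roc_auc(runif(5), rep(1, 5))))
})

test_that("evaluation metrics follow the standard formulas", {
  scores <- c(rep(0.9, 4), rep(0.1, 6))
  labels <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)  # TP 3, FP 1, FN 2, TN 4
  ev <- evaluate_scores(scores, labels)
  expect_equal(ev$tp + ev$fp + ev$fn + ev$tn, ev$n_test)
  expect_equal(ev$precision_minority, 0.75)
  expect_equal(ev$recall_minority, 0.6)
  expect_equal(ev$f1, 2 * 3 / (2 * 3 + 1 + 2))
  expect_equal(ev$accuracy, 0.7)
  perfect <- evaluate_scores(c(0.9, 0.9, 0.1), c(1, 1, 0))
  expect_equal(perfect$roc_auc, 1)
  expect_equal(perfect$f1, 1)
})

test_that("metric formulas hold on random confusion settings", {
  set.seed(21)
  for (i in 1:50) {
    cells <- rmultinom(1, 60, runif(4, 0.05, 1))[, 1] + 1L
    tp <- cells[1]; fp <- cells[2]; fn <- cells[3]; tn <- cells[4]
    scores <- c(rep(0.9, tp + fp), rep(0.1, fn + tn))
    labels <- c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn))
    ev <- evaluate_scores(scores, labels)
    expect_equal(ev$accuracy, (tp + tn) / sum(cells), tolerance = 1e-12)
    expect_equal(ev$f1, 2 * tp / (2 * tp + fp + fn), tolerance = 1e-12)
    minority <- if (tp + fn <= fp + tn) 1 else 0
    prec <- if (minority == 1) tp / (tp + fp) else tn / (tn + fn)
    rec <- if (minority == 1) tp / (tp + fn) else tn / (tn + fp)
    expect_equal(ev$precision_minority, prec, tolerance = 1e-12)
    expect_equal(ev$recall_minority, rec, tolerance = 1e-12)
  }
})

test_that("a perfect feature is learned to training rocAUC 1", {
  y <- rep(c(1L, 0L), each = 5)
  fm <- make_fm(cbind(perfect = as.numeric(y), noise = rep(c(1, 0), 5)))
  m <- train_model(fm, label_tbl(fm$genes, y), family = "logistic")
  expect_equal(roc_auc(predict(m, fm), y), 1.0)
})

test_that("training is deterministic for every model family", {
  set.seed(22)
  n <- 120
  y <- rbinom(n, 1, 0.5)
  vals <- cbind(a = as.numeric(y == 1) * rbinom(n, 1, 0.8),
                b = rbinom(n, 1, 0.4), c = rnorm(n))
  fm <- make_fm(vals, kinds = c("binary", "binary", "numeric"))
  for (fam in c("logistic", "random_forest", "gradient_boosted_trees")) {
    m1 <- train_model(fm, label_tbl(fm$genes, y), family = fam, inner_seed = 3)
    m2 <- train_model(fm, label_tbl(fm$genes, y), family = fam, inner_seed = 3)
    expect_identical(predict(m1, fm), predict(m2, fm), info = fam)
  }
})

test_that("inner CV picks hyperparameters reproducibly", {
  set.seed(23)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  vals <- cbind(s1 = as.numeric(y == 1) * rbinom(n, 1, 0.7),
                s2 = as.numeric(y == 0) * rbinom(n, 1, 0.5),
                n1 = rbinom(n, 1, 0.5))
  fm <- make_fm(vals)
  grid <- default_hyper_grid("random_forest")
  m1 <- train_model(fm, label_tbl(fm$genes, y), "random_forest", grid, inner_seed = 9)
  m2 <- train_model(fm, label_tbl(fm$genes, y), "random_forest", grid, inner_seed = 9)
  expect_identical(m1$params, m2$params)
  expect_false(is.na(m1$inner_auc))
})

test_that("label shuffling drives held-out rocAUC to chance", {
  cfg <- generator_config(n_genes = 800, n_noise_keywords = 300, seed = 31)
  sim <- generate_proteome(cfg)
  bin <- label_tbl(sim$ground_truth$labels$gene_name,
                   sim$ground_truth$labels$regulated)
  ann <- featurize_annotations(sim$proteome, ngram_max = 1, fields = "keywords")
  fm <- assemble_features(ann, genes = sim$proteome$gene_name)
  set.seed(32)
  aucs <- vapply(1:10, function(i) {
    sh <- bin; sh$label <- sample(sh$label)
    sp <- split_train_test(sh$gene_name, sh, 0.2, seed = i)
    fit_evaluate(fm, sh, sp, seed = i)$evaluation$roc_auc
  }, numeric(1))
  expect_gte(median(aucs), 0.42)
  expect_lte(median(aucs), 0.58)
})

test_that("cross-species evaluation on the same species equals in-species", {
  set.seed(24)
  n <- 150
  y <- rbinom(n, 1, 0.6)
  vals <- cbind(f = as.numeric(y == 1) * rbinom(n, 1, 0.8),
                g = rbinom(n, 1, 0.3))
  fm <- make_fm(vals)
  m <- train_model(fm, label_tbl(fm$genes, y), "logistic")
  insp <- evaluate_model(m, fm, label_tbl(fm$genes, y))
  cross <- cross_species_evaluate(m, fm, label_tbl(fm$genes, y), "A", "A")
  expect_equal(cross$roc_auc, insp$roc_auc)
  expect_equal(cross$accuracy, insp$accuracy)
})

test_that("projection handles absent features and rejects zero overlap", {
  set.seed(25)
  n <- 100
  y <- rbinom(n, 1, 0.5)
  fm <- make_fm(cbind(f = as.numeric(y == 1), g = rbinom(n, 1, 0.4)))
  m <- train_model(fm, label_tbl(fm$genes, y), "logistic")
  # all selected features zeroed: scores constant, AUC exactly chance
  fm0 <- make_fm(cbind(f = rep(0, n), g = rep(0, n)))
  ev <- cross_species_evaluate(m, fm0, label_tbl(fm0$genes, y))
  expect_equal(ev$roc_auc, 0.5)
  fm_none <- make_fm(cbind(other = rbinom(n, 1, 0.5)))
  expect_error(cross_species_evaluate(m, fm_none, label_tbl(fm_none$genes, y)),
               "no overlap")
})

test_that("proteome predictions are sorted, consistent and order-invariant", {
  set.seed(26)
  n <- 60
  y <- rbinom(n, 1, 0.5)
  vals <- cbind(f = as.numeric(y == 1), g = rbinom(n, 1, 0.5))
  vals[1, ] <- vals[2, ]  # identical feature rows
  fm <- make_fm(vals)
  m <- train_model(fm, label_tbl(fm$genes, y), "logistic")
  pred <- predict_proteome(m, fm, known_labels = label_tbl(fm$genes, y))
  expect_true(all(diff(pred$score) <= 0))
  expect_equal(pred$score[pred$gene_name == "g1"], pred$score[pred$gene_name == "g2"])
  expect_equal(pred$predicted_label, as.integer(pred$score >= 0.5))
  perm <- sample(n)
  fm_perm <- make_fm(vals[perm, ], genes = fm$genes[perm])
  pred2 <- predict_proteome(m, fm_perm)
  expect_equal(pred2$score[match(pred$gene_name, pred2$gene_name)], pred$score)
})

test_that("label concordance is the phi coefficient", {
  expect_equal(label_concordance(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(label_concordance(c(1, 1, 0, 0), c(0, 0, 1, 1)), -1)
  expect_equal(label_concordance(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_warning(out <- label_concordance(c(1, 1, 1), c(1, 0, 1)), "constant")
  expect_true(is.na(out))
})

test_that("tidy and glance methods expose model internals", {
  set.seed(27)
  y <- rep(c(1L, 0L), each = 10)
  fm <- make_fm(cbind(f = as.numeric(y), g = rbinom(20, 1, 0.5)))
  m <- train_model(fm, label_tbl(fm$genes, y), "logistic")
  td <- tidy(m)
  expect_true(all(c("(Intercept)", "f", "g") %in% td$term))
  gl <- glance(m)
  expect_equal(gl$n_train, 20)
  expect_equal(gl$family, "logistic")
})
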