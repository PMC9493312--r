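test_that("entropy matches the closed form", {
  expect_equal(entropy_bits(c(1, 0, 1, 0)), 1.0)
  expect_equal(entropy_bits(c(1, 1, 1, 1)), 0.0)
  expect_equal(entropy_bits(c(1, 1, 1, 0)), 0.8112781, tolerance = 1e-6)
  expect_error(entropy_bits(integer(0)), "empty")
})

test_that("RIG matches oracle values and bounds", {
  expect_equal(rig(c(1, 0, 1, 1), c(1, 0, 1, 1)), 1.0)  # perfect partition
  expect_equal(rig(c(1, 0, 1, 0), c(1, 1, 0, 0)), 0.0)  # empirical independence
  expect_equal(rig(c(1, 1, 0, 0), c(1, 1, 1, 0)), 0.3836885, tolerance = 1e-6)
  expect_error(rig(c(1, 0), c(1, 1)), "pure")
})

test_that("RIG is complement-invariant and bounded on random vectors", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    f <- rbinom(n, 1, runif(1, 0.1, 0.9))
    r <- rig(f, y)
    expect_equal(r, rig(1 - f, y), tolerance = 1e-12)
    expect_gte(r, 0); expect_lte(r, 1)
  }
})

test_that("lift and support follow their definitions", {
  # prior 0.75, feature covers 4 genes all positive
  y <- c(rep(1, 12), rep(0, 4))
  f <- c(rep(1, 4), rep(0, 12))
  ls <- lift_and_support(f, y)
  expect_equal(ls$lift_pos, 1 / 0.75, tolerance = 1e-12)
  expect_equal(ls$support, 0.25)
  # all-ones feature: support 1, both lifts 1
  ls2 <- lift_and_support(rep(1, 16), y)
  expect_equal(unlist(ls2), c(support = 1, lift_pos = 1, lift_neg = 1))
  # 8 genes, 6 positive; feature on the 2 negatives
  y3 <- c(rep(1, 6), 0, 0); f3 <- c(rep(0, 6), 1, 1)
  expect_equal(lift_and_support(f3, y3)$lift_neg, 4.0)
  expect_true(is.na(lift_and_support(rep(0, 8), y3)$lift_pos))
})

test_that("the lift consistency identity holds on random data", {
  set.seed(12)
  for (i in 1:20) {
    n <- 200
    y <- rbinom(n, 1, 0.6); f <- rbinom(n, 1, 0.3)
    if (sum(f) == 0 || length(unique(y)) < 2) next
    ls <- lift_and_support(f, y)
    expect_equal(ls$lift_pos * mean(y), mean(y[f == 1]), tolerance = 1e-12)
  }
})

test_that("chi-squared screen matches the closed form and chisq.test", {
  # table [[10,40],[40,10]]: statistic 36, p ~ 1.97e-9
  f <- c(rep(1, 50), rep(0, 50))
  y <- c(rep(1, 10), rep(0, 40), rep(1, 40), rep(0, 10))
  p <- chi2_screen(f, y)
  expect_equal(p, pchisq(36, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(p, 1.97e-9, tolerance = 1e-2)
  ref <- chisq.test(table(f, y), correct = FALSE)$p.value
  expect_equal(p, ref, tolerance = 1e-12)
  # balanced independent table: statistic 0, p 1
  f2 <- rep(c(1, 0), each = 50)
  y2 <- rep(c(1, 0, 1, 0), times = c(25, 25, 25, 25))
  expect_equal(chi2_screen(f2, y2), 1)
  expect_warning(p3 <- chi2_screen(rep(0, 10), rbinom(10, 1, 0.5)), "degenerate")
  expect_equal(p3, 1)
})

test_that("chi-squared screen agrees with chisq.test on random tables", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(30:300, 1)
    f <- rbinom(n, 1, runif(1, 0.1, 0.9))
    y <- rbinom(n, 1, runif(1, 0.1, 0.9))
    if (length(unique(f)) < 2 || length(unique(y)) < 2) next
    ref <- suppressWarnings(chisq.test(table(factor(f, 0:1), factor(y, 0:1)),
                                       correct = FALSE)$p.value)
    expect_equal(chi2_screen(f, y), ref, tolerance = 1e-12)
  }
})

test_that("best_threshold finds the optimal split with ties to the left", {
  bt <- best_threshold(c(100, 200, 300, 400, 500, 600), c(0, 0, 0, 1, 1, 1))
  expect_equal(bt$threshold, 350)
  expect_equal(bt$rig, 1.0)
  expect_equal(best_threshold(c(1, 2), c(1, 0))$threshold, 1.5)
  expect_error(best_threshold(rep(3, 5), c(1, 0, 1, 0, 1)), "distinct")
})

test_that("best_threshold equals exhaustive midpoint enumeration", {
  set.seed(14)
  for (i in 1:20) {
    x <- round(rnorm(60), 1)  # force repeated values
    y <- rbinom(60, 1, plogis(x))
    if (length(unique(y)) < 2 || length(unique(x)) < 2) next
    bt <- best_threshold(x, y)
    br <- oracle_best_threshold(x, y)
    expect_equal(bt$rig, br$rig, tolerance = 1e-12)
    expect_equal(bt$threshold, br$threshold)
  }
})

test_that("score_features agrees with the scalar operations", {
  set.seed(15)
  n <- 120
  y <- rbinom(n, 1, 0.7)
  vals <- cbind(f1 = rbinom(n, 1, 0.3), f2 = rbinom(n, 1, 0.5),
                num = rnorm(n) + y)
  fm <- make_fm(vals, kinds = c("binary", "binary", "numeric"))
  sc <- score_features(fm, label_tbl(fm$genes, y))
  for (f in c("f1", "f2")) {
    i <- which(sc$feature_id == f)
    expect_equal(sc$rig[i], rig(vals[, f], y), tolerance = 1e-12)
    expect_equal(sc$chi2_p[i], suppressWarnings(chi2_screen(vals[, f], y)),
                 tolerance = 1e-12)
    expect_equal(sc$support[i], mean(vals[, f]))
  }
  i <- which(sc$feature_id == "num")
  bt <- best_threshold(vals[, "num"], y)
  expect_equal(sc$rig[i], bt$rig, tolerance = 1e-12)
  expect_equal(sc$threshold[i], bt$threshold)
})

test_that("identical and complementary columns are deduplicated", {
  set.seed(16)
  n <- 100
  y <- rbinom(n, 1, 0.5)
  a <- as.numeric(y == 1)  # perfectly informative
  vals <- cbind(A = a, B = a, C = 1 - a, D = rbinom(n, 1, 0.5))
  fm <- make_fm(vals)
  sc <- score_features(fm, label_tbl(fm$genes, y))
  sel <- dedupe_and_select(sc, fm, k_max = 10, p_max = 1)
  expect_true("A" %in% sel$selected$feature_id)
  expect_false(any(c("B", "C") %in% sel$selected$feature_id))
  expect_setequal(sel$redundant$feature_id, c("B", "C"))
  expect_equal(unique(sel$redundant$proxy), "A")
})

test_that("chi-squared screening removes insignificant features", {
  set.seed(17)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  vals <- cbind(good = as.numeric(y == 1),
                noise1 = rbinom(n, 1, 0.5), noise2 = rbinom(n, 1, 0.5))
  fm <- make_fm(vals)
  sc <- score_features(fm, label_tbl(fm$genes, y))
  sel <- dedupe_and_select(sc, fm, k_max = 10, p_max = 1e-4)
  expect_equal(sel$selected$feature_id, "good")
  expect_error(dedupe_and_select(sc, fm, k_max = 0), "positive")
})

test_that("selection is invariant to the ordering of tied candidates", {
  set.seed(18)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  vals <- sapply(1:8, function(i) rbinom(n, 1, 0.4))
  colnames(vals) <- paste0("f", 1:8)
  fm <- make_fm(vals)
  sc <- score_features(fm, label_tbl(fm$genes, y))
  sel1 <- dedupe_and_select(sc, fm, k_max = 5, p_max = 1)
  sel2 <- dedupe_and_select(sc[sample(nrow(sc)), ], fm, k_max = 5, p_max = 1)
  expect_identical(sel1$selected$feature_id, sel2$selected$feature_id)
})

test_that("highly correlated survivors are capped by the redundancy rule", {
  set.seed(19)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  base <- as.numeric(y == 1)
  near <- base; flip <- sample(n, 3); near[flip] <- 1 - near[flip]
  vals <- cbind(base = base, near = near)
  fm <- make_fm(vals)
  sc <- score_features(fm, label_tbl(fm$genes, y))
  sel_tight <- dedupe_and_select(sc, fm, k_max = 10, p_max = 1, redundancy_cap = 0.9)
  expect_equal(nrow(sel_tight$selected), 1)
  sel_loose <- dedupe_and_select(sc, fm, k_max = 10, p_max = 1, redundancy_cap = 0.999)
  expect_equal(nrow(sel_loose$selected), 2)
})
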