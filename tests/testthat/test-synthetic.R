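test_that("the generator is deterministic given its seed", {
  cfg <- generator_config(n_genes = 300, n_noise_keywords = 100, seed = 41)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$proteome, b$proteome)
  expect_identical(a$genomic, b$genomic)
  expect_identical(a$evidence, b$evidence)
  c_ <- simulate_study(generator_config(n_genes = 300, n_noise_keywords = 100,
                                        seed = 42))
  expect_false(identical(a$proteome$sequence, c_$proteome$sequence))
})

test_that("evidence round-trips to the planted labels for many seeds", {
  for (s in 1:5) {
    cfg <- generator_config(n_genes = 100, n_noise_keywords = 20, seed = s)
    sim <- generate_proteome(cfg)
    labels3 <- label_tbl(sim$ground_truth$labels$gene_name,
                         sim$ground_truth$labels$label3)
    ev <- generate_evidence(labels3, cfg$evidence_model, seed = s + 500)
    back <- assign_labels(summarize_evidence(ev, "synthetica"),
                          labels3$gene_name)
    expect_equal(back$label, labels3$label)
    # likely positives carry exactly one distinct weak experiment key
    weak0 <- labels3$gene_name[labels3$label == 0L]
    keys <- ev[ev$target_gene %in% weak0 & ev$evidence_strength == "weak", ]
    per_gene <- tapply(keys$experiment_key, keys$target_gene,
                       function(k) length(unique(k)))
    expect_true(all(per_gene == 1))
  }
})

test_that("different evidence seeds change rows but not recovered labels", {
  cfg <- generator_config(n_genes = 80, n_noise_keywords = 20, seed = 3)
  sim <- generate_proteome(cfg)
  labels3 <- label_tbl(sim$ground_truth$labels$gene_name,
                       sim$ground_truth$labels$label3)
  e1 <- generate_evidence(labels3, seed = 1)
  e2 <- generate_evidence(labels3, seed = 2)
  expect_false(identical(e1$reference_id, e2$reference_id))
  for (e in list(e1, e2)) {
    back <- assign_labels(summarize_evidence(e, "synthetica"), labels3$gene_name)
    expect_equal(back$label, labels3$label)
  }
})

test_that("empirical prevalence and planted lifts match the configuration", {
  cfg <- generator_config(seed = 43)   # n = 5000, lift 1.5, support 5-15%
  sim <- generate_proteome(cfg)
  truth <- sim$ground_truth
  y <- truth$labels$regulated
  p <- cfg$prevalence
  se_p <- sqrt(p * (1 - p) / cfg$n_genes)
  expect_lt(abs(mean(y) - p), 3 * se_p)

  kw <- featurize_annotations(sim$proteome, ngram_max = 1, fields = "keywords")
  fm <- assemble_features(kw, genes = sim$proteome$gene_name)
  lifts <- numeric(0)
  for (j in seq_len(nrow(truth$planted))) {
    pl <- truth$planted[j, ]
    col <- fm$values[, paste0("kw:", pl$feature_id)]
    cls_idx <- y == pl$dominant_class
    # attachment rate among the dominant class is lift * support
    rate <- pl$lift * pl$support
    se <- sqrt(rate * (1 - rate) / sum(cls_idx))
    expect_lt(abs(mean(col[cls_idx]) - rate), 4 * se)
    # marginal support is the configured support
    se_s <- sqrt(pl$support * (1 - pl$support) / cfg$n_genes)
    expect_lt(abs(mean(col) - pl$support), 4 * se_s)
    ls <- lift_and_support(col, as.integer(y != pl$dominant_class))
    lifts <- c(lifts, ls$lift_neg)  # lift of the dominant (negative) class
  }
  expect_lt(abs(mean(lifts) - 1.5), 0.1)
})

test_that("a null configuration plants no detectable association", {
  cfg <- generator_config(n_genes = 2000, planted_lifts = 1.0,
                          n_noise_keywords = 100, seed = 44)
  sim <- generate_proteome(cfg)
  y <- label_tbl(sim$ground_truth$labels$gene_name,
                 sim$ground_truth$labels$regulated)
  kw <- featurize_annotations(sim$proteome, ngram_max = 1, fields = "keywords")
  fm <- assemble_features(kw, genes = sim$proteome$gene_name)
  sc <- score_features(fm, y)
  planted <- paste0("kw:", sim$ground_truth$planted$feature_id)
  ps <- sc$chi2_p[sc$feature_id %in% planted]
  expect_gt(min(ps), 1e-4)          # nothing screens in
  expect_gt(mean(ps > 0.1), 0.5)    # p-values look uniform, not enriched
})

test_that("infeasible planted lifts fail loudly", {
  expect_error(
    generate_proteome(generator_config(n_genes = 100, planted_lifts = 1.5,
                                       planted_classes = rep(1L, 20),
                                       seed = 1)),
    "infeasible")
  expect_error(
    generate_proteome(generator_config(n_genes = 100, planted_lifts = 30,
                                       seed = 1)),
    "infeasible")
})

test_that("family coherence matches its closed form on size-2 families", {
  cfg <- generator_config(n_genes = 4000, n_noise_keywords = 10,
                          family_coherence = 0.6, seed = 45)
  sim <- generate_proteome(cfg)
  truth <- sim$ground_truth
  labs <- setNames(truth$labels$regulated, truth$labels$gene_name)
  tf <- sim$families[sim$families$source == "treefam", ]
  two <- truth$coherent_families$family_id[truth$coherent_families$size == 2]
  obs <- vapply(two, function(f) {
    members <- tf$gene_name[tf$family_id == f]
    length(unique(labs[members])) == 1
  }, logical(1))
  p <- cfg$prevalence; fc <- cfg$family_coherence
  expected <- fc + (1 - fc) * (p^2 + (1 - p)^2)
  se <- sqrt(expected * (1 - expected) / length(obs))
  expect_lt(abs(mean(obs) - expected), 3 * se)
})

test_that("second species shares exactly the requested planted signal", {
  cfg <- generator_config(n_genes = 1000, n_noise_keywords = 200, seed = 46)
  sim <- generate_proteome(cfg)
  b <- generate_second_species(sim, cfg, overlap = 0.3, seed = 47)
  expect_equal(b$ground_truth$shared_planted,
               sim$ground_truth$planted$feature_id[1:6])
  # retained tokens keep their association; retired ones become noise
  yb <- b$ground_truth$labels$regulated
  kw <- featurize_annotations(b$proteome, ngram_max = 1, fields = "keywords")
  fmb <- assemble_features(kw, genes = b$proteome$gene_name,
                           min_support_count = 1)
  planted_b <- b$ground_truth$planted
  retained <- planted_b[planted_b$active & planted_b$feature_id %in%
                          b$ground_truth$shared_planted, ]
  retired <- planted_b[!planted_b$active, ]
  sc <- score_features(fmb, label_tbl(b$proteome$gene_name, yb))
  rig_retained <- sc$rig[sc$feature_id %in% paste0("kw:", retained$feature_id)]
  rig_retired <- sc$rig[sc$feature_id %in% paste0("kw:", retired$feature_id)]
  expect_gt(mean(rig_retained), mean(rig_retired))
  # gene and family namespaces do not collide between species
  expect_length(intersect(b$proteome$gene_name, sim$proteome$gene_name), 0)
  expect_length(intersect(b$families$family_id, sim$families$family_id), 0)
})

test_that("written studies are readable back through the io module", {
  cfg <- generator_config(n_genes = 60, n_noise_keywords = 30, seed = 48)
  study <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_synthetic_study(study, dir)
  prot <- read_protein_table(file.path(dir, "proteome.tsv"))
  expect_equal(prot$gene_name, study$proteome$gene_name)
  expect_equal(prot$keywords, study$proteome$keywords)
  expect_equal(prot$sequence, study$proteome$sequence)
  ev <- read_evidence_table(file.path(dir, "evidence.tsv"))
  back <- assign_labels(summarize_evidence(ev, "synthetica"), prot$gene_name)
  expect_equal(back$label, study$ground_truth$labels$label3)
})
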