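# End-to-end orchestration: simulate (or ingest) -> label -> featurize ->
# rank -> train -> evaluate (-> transfer / ablation / coherence / predict),
# with every report written as TSV next to a frozen copy of the resolved
# configuration and a run log. All randomness flows from config$seed; the
# outputs carry no timestamps, so a rerun with an identical configuration
# is byte-identical.

#' Pipeline configuration
#'
#' Resolves the declarative configuration of [run_pipeline()]. Either
#' `generator` (a [generator_config()]; the default synthetic mode) or
#' `inputs` (a list of file paths: `proteome`, `evidence`, `genomic`,
#' `families`) must describe the data source.
#'
#' @param generator A [generator_config()] for synthetic mode (default).
#' @param inputs Optional list of input paths for real-data mode.
#' @param label_policy Binarization policy (see [binarize_labels()]).
#' @param feature_sets Character subset of
#'   `c("protein_full", "protein_sequence_only", "genomic", "unified")`;
#'   the first is the primary model, the rest are ablations when
#'   `do_ablation`.
#' @param ngram_max,k_range,with_utr3_ngrams Featurizer settings.
#' @param min_support_count Assembly pruning threshold.
#' @param k_max,p_max,redundancy_cap Ranking/selection parameters.
#' @param model_family,test_fraction,threshold Modeling parameters.
#' @param do_transfer,transfer_overlap Cross-species transfer stage.
#' @param do_ablation,do_coherence,do_predict Optional stages.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(generator = generator_config(),
                            inputs = NULL,
                            label_policy = "weak_as_positive",
                            feature_sets = "protein_full",
                            ngram_max = 1,
                            k_range = NULL,
                            with_utr3_ngrams = FALSE,
                            min_support_count = 5L,
                            k_max = 300L, p_max = 1e-4, redundancy_cap = 0.95,
                            model_family = "logistic",
                            test_fraction = 0.2, threshold = 0.5,
                            do_transfer = FALSE, transfer_overlap = 0.7,
                            do_ablation = FALSE, do_coherence = TRUE,
                            do_predict = TRUE,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

# Build the named feature matrices requested by the configuration.
build_feature_sets <- function(sets, proteome, genomic, cfg) {
  ann <- NULL; seq_f <- NULL; gen_f <- NULL
  need_ann <- any(sets %in% c("protein_full", "unified"))
  need_seq <- any(sets %in% c("protein_full", "protein_sequence_only", "unified"))
  need_gen <- any(sets %in% c("genomic", "unified")) && !is.null(genomic)
  if (need_ann) ann <- featurize_annotations(proteome, ngram_max = cfg$ngram_max)
  if (need_seq) seq_f <- featurize_sequences(proteome, k_range = cfg$k_range)
  if (need_gen) gen_f <- featurize_genomic(genomic,
                                           with_utr3_ngrams = cfg$with_utr3_ngrams)
  genes <- proteome$gene_name
  msc <- cfg$min_support_count
  out <- list()
  for (s in sets) {
    out[[s]] <- switch(s,
      protein_full = assemble_features(ann, seq_f, genes = genes,
                                       min_support_count = msc),
      protein_sequence_only = assemble_features(seq_f, genes = genes,
                                                min_support_count = msc),
      genomic = if (!is.null(gen_f)) assemble_features(gen_f, genes = genes,
                                                       min_support_count = msc),
      unified = assemble_features(ann, seq_f, gen_f, genes = genes,
                                  min_support_count = msc)
    )
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Run the full analysis pipeline
#'
#' Executes every configured stage and writes all reports under `out_dir`:
#' `labels.tsv`, `feature_scores.tsv`, `selected_features.tsv`,
#' `evaluation.tsv`, optional `transfer.tsv` / `ablation.tsv` /
#' `coherence.tsv` + `family_fractions.tsv` / `predictions.tsv`, the frozen
#' `run_config.yaml` and a `run_log.txt` with the gene counts at every
#' filter. Any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  seed <- config$seed
  say("run seed: %d", seed)

  # --- ingest / simulate ---------------------------------------------------
  study <- stage("ingest", {
    if (!is.null(config$inputs)) {
      proteome <- read_protein_table(config$inputs$proteome)
      evidence <- read_evidence_table(config$inputs$evidence)
      genomic <- if (!is.null(config$inputs$genomic)) {
        readr::read_tsv(config$inputs$genomic, show_col_types = FALSE, progress = FALSE)
      }
      families <- if (!is.null(config$inputs$families)) {
        readr::read_tsv(config$inputs$families, show_col_types = FALSE, progress = FALSE)
      }
      list(proteome = proteome, evidence = evidence, genomic = genomic,
           families = families, config = config$generator)
    } else {
      simulate_study(config$generator)
    }
  })
  say("genes in: %d", nrow(study$proteome))
  proteome <- stage("filter", filter_proteome(study$proteome, "reviewed"))
  say("genes after reviewed filter: %d (filtered out %d)",
      nrow(proteome), nrow(study$proteome) - nrow(proteome))

  # --- label ---------------------------------------------------------------
  labels <- stage("label", {
    summaries <- summarize_evidence(study$evidence,
                                    organism = unique(proteome$organism)[1])
    assign_labels(summaries, proteome$gene_name)
  })
  binary <- binarize_labels(labels, config$label_policy)
  write_label_table(labels, binary, file.path(out_dir, "labels.tsv"))
  say("labels: %d positive, %d likely-positive, %d negative; %d analyzed under policy %s",
      sum(labels$label == 1), sum(labels$label == 0), sum(labels$label == -1),
      nrow(binary), config$label_policy)
  proteome <- proteome[proteome$gene_name %in% binary$gene_name, ]
  genomic <- study$genomic
  if (!is.null(genomic)) genomic <- genomic[genomic$gene_name %in% binary$gene_name, ]

  # --- featurize -----------------------------------------------------------
  sets <- unique(c(config$feature_sets,
                   if (config$do_ablation) c("protein_full", "protein_sequence_only",
                                             "genomic", "unified")))
  fms <- stage("featurize", build_feature_sets(sets, proteome, genomic, config))
  main_set <- config$feature_sets[1]
  fm <- fms[[main_set]]
  say("feature matrix (%s): %d genes x %d features", main_set,
      length(fm$genes), ncol(fm$values))

  # --- split / rank / train / evaluate ------------------------------------
  split <- stage("split", split_train_test(binary$gene_name, binary,
                                           config$test_fraction,
                                           derive_seed(seed, 1L)))
  fit <- stage("train", fit_evaluate(fm, binary, split,
                                     family = config$model_family,
                                     k_max = config$k_max, p_max = config$p_max,
                                     redundancy_cap = config$redundancy_cap,
                                     seed = derive_seed(seed, 2L),
                                     threshold = config$threshold))
  tr_genes <- split$gene_name[split$split == "train"]
  scores_all <- stage("rank", score_features(subset_genes(fm, tr_genes),
                                             binary[binary$gene_name %in% tr_genes, ]))
  write_feature_report(scores_all, file.path(out_dir, "feature_scores.tsv"))
  write_feature_report(fit$selection, file.path(out_dir, "selected_features.tsv"))
  say("selected %d features (screened out %d, %d redundant); model family: %s",
      nrow(fit$selection$selected), fit$selection$screened_out,
      nrow(fit$selection$redundant), config$model_family)
  readr::write_tsv(fit$evaluation, file.path(out_dir, "evaluation.tsv"),
                   progress = FALSE)
  say("held-out rocAUC: %.4f", fit$evaluation$roc_auc)

  results <- list(study = study, labels = labels, binary = binary, split = split,
                  fit = fit)

  # --- transfer ------------------------------------------------------------
  if (config$do_transfer && is.null(config$inputs)) {
    transfer <- stage("transfer", {
      second <- generate_second_species(study, config$generator,
                                        config$transfer_overlap,
                                        seed = derive_seed(seed, 3L))
      labels_b <- tibble(gene_name = second$ground_truth$labels$gene_name,
                         label = second$ground_truth$labels$regulated)
      ann_b <- featurize_annotations(second$proteome, ngram_max = config$ngram_max)
      seq_b <- featurize_sequences(second$proteome, k_range = config$k_range)
      fm_b <- assemble_features(ann_b, seq_b, genes = second$proteome$gene_name,
                                min_support_count = config$min_support_count)
      cross_species_evaluate(fit$model, fm_b, labels_b,
                             train_organism = config$generator$organism,
                             test_organism = "second_species",
                             threshold = config$threshold)
    })
    readr::write_tsv(transfer, file.path(out_dir, "transfer.tsv"), progress = FALSE)
    say("transfer rocAUC at overlap %.2f: %.4f", config$transfer_overlap,
        transfer$roc_auc)
    results$transfer <- transfer
  }

  # --- ablation ------------------------------------------------------------
  if (config$do_ablation) {
    ablation <- stage("ablation", {
      ablation_run(fms, binary, split, family = config$model_family,
                   k_max = config$k_max, p_max = config$p_max,
                   redundancy_cap = config$redundancy_cap,
                   seed = derive_seed(seed, 4L), threshold = config$threshold)
    })
    readr::write_tsv(ablation, file.path(out_dir, "ablation.tsv"), progress = FALSE)
    results$ablation <- ablation
  }

  # --- coherence -----------------------------------------------------------
  if (config$do_coherence && !is.null(study$families)) {
    coh <- stage("coherence", {
      list(fractions = family_fractions(binary, study$families, "treefam"),
           coherence = coherence_test(binary, study$families, "treefam"),
           unmatched = unmatched_family_report(binary, study$families, "treefam"))
    })
    readr::write_tsv(coh$fractions, file.path(out_dir, "family_fractions.tsv"),
                     progress = FALSE)
    readr::write_tsv(coh$coherence, file.path(out_dir, "coherence.tsv"),
                     progress = FALSE)
    readr::write_tsv(coh$unmatched, file.path(out_dir, "unmatched_families.tsv"),
                     progress = FALSE)
    say("family coherence: %.3f over %d families (one-sided p = %.3g)",
        coh$coherence$coherence_fraction, coh$coherence$n_families_tested,
        coh$coherence$binom_p_one_sided)
    results$coherence <- coh
  }

  # --- proteome-wide predictions ------------------------------------------
  if (config$do_predict && !is.null(fit$model)) {
    preds <- stage("predict", predict_proteome(fit$model, fm, binary,
                                               threshold = config$threshold))
    write_prediction_table(preds, file.path(out_dir, "predictions.tsv"))
    results$predictions <- preds
  }

  # --- freeze config + log -------------------------------------------------
  frozen <- config
  frozen$generator <- unclass(frozen$generator)
  yaml::write_yaml(lapply(unclass(frozen), function(x) {
    if (is.null(x)) NA else x
  }), file.path(out_dir, "run_config.yaml"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}
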