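# Self-contained synthetic study generator: proteomes, evidence tables,
# genomic tables and family maps with planted, parameterized ground truth.
# The planted-feature scheme is calibrated so that the configured lift is
# exactly the quantity lift_and_support() estimates: a feature with overall
# support s and lift l for its dominant class c is attached with probability
# l*s given label c and s*(1 - l*P(c))/(1 - P(c)) otherwise, keeping the
# marginal support at s.

AA_BASE_FREQ <- c(A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.036,
                  G = 0.066, H = 0.026, I = 0.044, K = 0.058, L = 0.100,
                  M = 0.021, N = 0.036, P = 0.063, Q = 0.048, R = 0.056,
                  S = 0.083, T = 0.053, V = 0.060, W = 0.012, Y = 0.027)

STRONG_TYPES <- c("Luciferase reporter assay", "Western blot", "qRT-PCR")
WEAK_TYPES <- c("CLIP-Seq", "HITS-CLIP", "pSILAC", "Microarray")

#' Synthetic study configuration
#'
#' Collects every parameter of the generator with the package's default
#' study conditions: 5,000 genes at a 0.75 regulated prevalence (the
#' human-like prior), 20 planted keyword features of lift 1.5 with support
#' drawn in 5-15%, 2,000 label-independent noise keywords, power-law family
#' sizes with 90% family coverage and coherence 0.9, log-normal protein
#' lengths shifted shorter for unregulated genes, a lysine composition
#' excess in regulated proteins, and a longer 3'-UTR for regulated genes.
#'
#' @param n_genes Number of genes.
#' @param prevalence Regulated fraction in (0, 1).
#' @param n_planted_features Number of informative planted keywords.
#' @param planted_lifts Lift of each planted feature for its dominant class
#'   (recycled to `n_planted_features`).
#' @param planted_classes Optional dominant classes (0/1) per planted
#'   feature; `NULL` auto-assigns a feasible class per feature (alternating
#'   where both classes are feasible; lift l for class c requires
#'   l * P(c) <= 1 and l * support <= 1).
#' @param planted_support Range the marginal support of each planted
#'   feature is drawn from.
#' @param n_noise_keywords Label-independent keywords.
#' @param noise_support Support range of noise keywords.
#' @param family_exponent,family_max_size Truncated power law of family
#'   sizes (most families are singletons).
#' @param family_coherence Probability that a family is generated coherent
#'   (all members share one label draw); 0 gives fully independent labels.
#' @param fraction_unfamilied Fraction of genes with no family.
#' @param unfamilied_prevalence Regulated prevalence among unfamilied genes
#'   (default: the global prevalence).
#' @param weak_single_prob Probability that a regulated gene is observed
#'   with only a single weak experiment (three-way label 0).
#' @param seq_meanlog,seq_sdlog Log-normal protein length parameters
#'   (residues).
#' @param length_shift_unregulated Added to `seq_meanlog` for unregulated
#'   genes (negative = shorter).
#' @param composition_shift Named residue -> added composition fraction in
#'   regulated proteins.
#' @param utr3_meanlog,utr3_sdlog Log-normal 3'-UTR length parameters (nt).
#' @param utr3_length_shift Added to `utr3_meanlog` for regulated genes.
#' @param n_go_terms_per_branch,go_mean_per_gene Noise GO vocabulary size
#'   and mean annotations per gene per branch.
#' @param evidence_model List with `strong_prob` (chance a positive gene
#'   carries strong evidence), `extra_weak_mean` (Poisson mean of weak
#'   experiments beyond the required two), `dup_prob` (chance a weak row is
#'   duplicated verbatim).
#' @param organism Organism tag written on every record.
#' @param seed Integer seed; every downstream draw is derived from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_genes = 5000L,
                             prevalence = 0.75,
                             n_planted_features = 20L,
                             planted_lifts = 1.5,
                             planted_classes = NULL,
                             planted_support = c(0.05, 0.15),
                             n_noise_keywords = 2000L,
                             noise_support = c(0.005, 0.05),
                             family_exponent = 2.5,
                             family_max_size = 50L,
                             family_coherence = 0.9,
                             fraction_unfamilied = 0.1,
                             unfamilied_prevalence = NULL,
                             weak_single_prob = 0.1,
                             seq_meanlog = 6.0,
                             seq_sdlog = 0.55,
                             length_shift_unregulated = -0.25,
                             composition_shift = c(K = 0.010),
                             utr3_meanlog = 6.3,
                             utr3_sdlog = 0.8,
                             utr3_length_shift = 0.5,
                             n_go_terms_per_branch = 100L,
                             go_mean_per_gene = 2,
                             evidence_model = list(strong_prob = 0.5,
                                                   extra_weak_mean = 1,
                                                   dup_prob = 0.3),
                             organism = "synthetica",
                             seed = 1L) {
  stopifnot(prevalence > 0, prevalence < 1,
            family_coherence >= 0, family_coherence <= 1,
            fraction_unfamilied >= 0, fraction_unfamilied < 1,
            weak_single_prob >= 0, weak_single_prob < 1)
  cfg <- list(n_genes = as.integer(n_genes), prevalence = prevalence,
              n_planted_features = as.integer(n_planted_features),
              planted_lifts = rep_len(planted_lifts, n_planted_features),
              planted_classes = planted_classes,
              planted_support = planted_support,
              n_noise_keywords = as.integer(n_noise_keywords),
              noise_support = noise_support,
              family_exponent = family_exponent,
              family_max_size = as.integer(family_max_size),
              family_coherence = family_coherence,
              fraction_unfamilied = fraction_unfamilied,
              unfamilied_prevalence = unfamilied_prevalence %||% prevalence,
              weak_single_prob = weak_single_prob,
              seq_meanlog = seq_meanlog, seq_sdlog = seq_sdlog,
              length_shift_unregulated = length_shift_unregulated,
              composition_shift = composition_shift,
              utr3_meanlog = utr3_meanlog, utr3_sdlog = utr3_sdlog,
              utr3_length_shift = utr3_length_shift,
              n_go_terms_per_branch = as.integer(n_go_terms_per_branch),
              go_mean_per_gene = go_mean_per_gene,
              evidence_model = evidence_model,
              organism = organism, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

# Assign a feasible dominant class to each planted feature. Lift l for
# class c requires l*P(c) <= 1 (so the complement rate stays nonnegative)
# and l*s <= 1.
plant_classes <- function(lifts, supports, prevalence, requested = NULL) {
  p_of <- function(cls) ifelse(cls == 1L, prevalence, 1 - prevalence)
  feasible <- function(cls, j) {
    lifts[j] * p_of(cls) <= 1 + 1e-12 && lifts[j] * supports[j] <= 1 + 1e-12
  }
  n <- length(lifts)
  classes <- integer(n)
  prefer <- rep_len(c(1L, 0L), n)
  for (j in seq_len(n)) {
    cls <- if (!is.null(requested)) requested[j] else prefer[j]
    if (!feasible(cls, j)) {
      if (!is.null(requested)) {
        stop(sprintf("planted feature %d infeasible: lift %.3g for class %d at prevalence",
                     j, lifts[j], cls), call. = FALSE)
      }
      cls <- 1L - cls
      if (!feasible(cls, j)) {
        stop(sprintf("planted feature %d infeasible for either class (lift %.3g)",
                     j, lifts[j]), call. = FALSE)
      }
    }
    classes[j] <- cls
  }
  classes
}

# Draw family sizes from a truncated power law until `target` genes are
# covered; the last family is trimmed to fit.
draw_family_sizes <- function(target, exponent, max_size) {
  if (target <= 0) return(integer(0))
  probs <- (1:max_size)^(-exponent)
  sizes <- integer(0)
  while (sum(sizes) < target) {
    sizes <- c(sizes, sample.int(max_size, 64L, replace = TRUE, prob = probs))
  }
  cum <- cumsum(sizes)
  k <- which(cum >= target)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (cum[k] - target)
  sizes[sizes > 0]
}

# Core generator. `planted` is a tibble (feature_id, lift, support,
# dominant_class, active); inactive features are attached at their support
# independently of the label. `noise` is a tibble (feature_id, support).
gen_proteome_impl <- function(cfg, planted, noise, gene_prefix = "GENE",
                              id_tag = "") {
  n <- cfg$n_genes
  genes <- sprintf("%s%05d", gene_prefix, seq_len(n))

  # --- families and labels -------------------------------------------------
  n_fam_genes <- round((1 - cfg$fraction_unfamilied) * n)
  sizes <- draw_family_sizes(n_fam_genes, cfg$family_exponent, cfg$family_max_size)
  fam_ids <- sprintf("TF%s%05d", id_tag, seq_along(sizes))
  familied_idx <- sample.int(n, n_fam_genes)
  fam_of <- rep(NA_character_, n)
  fam_of[familied_idx] <- rep(fam_ids, sizes)

  coherent <- stats::rbinom(length(sizes), 1, cfg$family_coherence) == 1
  names(coherent) <- fam_ids
  regulated <- integer(n)
  fam_label <- stats::rbinom(length(sizes), 1, cfg$prevalence)
  names(fam_label) <- fam_ids
  for_fam <- !is.na(fam_of)
  is_coh <- coherent[fam_of[for_fam]]
  regulated[for_fam] <- ifelse(is_coh, fam_label[fam_of[for_fam]],
                               stats::rbinom(sum(for_fam), 1, cfg$prevalence))
  regulated[!for_fam] <- stats::rbinom(sum(!for_fam), 1, cfg$unfamilied_prevalence)

  # --- keywords ------------------------------------------------------------
  p_of <- function(cls) ifelse(cls == 1L, cfg$prevalence, 1 - cfg$prevalence)
  kw_inc <- matrix(FALSE, n, nrow(planted) + nrow(noise))
  tokens <- c(planted$feature_id, noise$feature_id)
  for (j in seq_len(nrow(planted))) {
    l <- planted$lift[j]; s <- planted$support[j]; cls <- planted$dominant_class[j]
    if (planted$active[j]) {
      p_dom <- l * s
      p_other <- s * (1 - l * p_of(cls)) / (1 - p_of(cls))
      if (p_dom > 1 || p_other < 0) {
        stop("infeasible lift*support for planted feature ", planted$feature_id[j],
             call. = FALSE)
      }
      pr <- ifelse(regulated == cls, p_dom, p_other)
    } else {
      pr <- rep(s, n)
    }
    kw_inc[, j] <- stats::runif(n) < pr
  }
  for (j in seq_len(nrow(noise))) {
    kw_inc[, nrow(planted) + j] <- stats::runif(n) < noise$support[j]
  }
  hits <- which(kw_inc, arr.ind = TRUE)
  keywords <- rep(list(character(0)), n)
  if (nrow(hits)) {
    by_gene <- split(tokens[hits[, 2]], hits[, 1])
    keywords[as.integer(names(by_gene))] <- lapply(by_gene, sort)
  }

  # --- GO terms (label-independent noise vocabulary) -----------------------
  go_branch <- function(tag) {
    pool <- sprintf("GO:%s%04d", tag, seq_len(cfg$n_go_terms_per_branch))
    counts <- stats::rpois(n, cfg$go_mean_per_gene)
    counts <- pmin(counts, length(pool))
    idx <- which(counts > 0)
    out <- rep(list(character(0)), n)
    out[idx] <- lapply(counts[idx], function(k) sort(sample(pool, k)))
    out
  }

  # --- sequences -----------------------------------------------------------
  meanlog <- cfg$seq_meanlog + ifelse(regulated == 1, 0, cfg$length_shift_unregulated)
  len <- pmax(50L, as.integer(round(stats::rlnorm(n, meanlog, cfg$seq_sdlog))))
  comp_for <- function(reg) {
    f <- AA_BASE_FREQ
    if (reg && length(cfg$composition_shift)) {
      f[names(cfg$composition_shift)] <- f[names(cfg$composition_shift)] +
        cfg$composition_shift
    }
    f / sum(f)
  }
  sequences <- character(n)
  mw <- numeric(n)
  for (reg in c(0L, 1L)) {
    idx <- which(regulated == reg)
    if (!length(idx)) next
    total <- sum(len[idx])
    res <- sample(names(AA_BASE_FREQ), total, replace = TRUE, prob = comp_for(reg == 1L))
    grp <- rep(seq_along(idx), len[idx])
    sequences[idx] <- vapply(split(res, grp), paste, character(1), collapse = "")
    mw[idx] <- as.vector(rowsum(AA_MASS[res], grp)) + 18.02
  }

  # --- free-text annotations ----------------------------------------------
  organs <- c("muscle", "heart", "brain", "testis", "liver", "kidney", "lung")
  tissue <- rep(NA_character_, n)
  has_tissue <- stats::runif(n) < 0.4
  n_org <- pmin(1L + stats::rpois(sum(has_tissue), 0.8), length(organs))
  tissue[has_tissue] <- vapply(n_org, function(k) {
    paste("Expressed in", paste(sample(organs, k), collapse = " and "))
  }, character(1))
  disease <- ifelse(stats::runif(n) < 0.2,
                    sprintf("Disease D%03d", sample.int(300, n, replace = TRUE)),
                    NA_character_)
  ptm_counts <- stats::rpois(n, 1.5)
  ptm <- lapply(ptm_counts, function(k) {
    if (k == 0) character(0) else sprintf("Modified residue M%02d", sort(sample.int(40, k)))
  })

  # UniProt-style family names mirror the TreeFam partition.
  upfam_of <- ifelse(is.na(fam_of), NA_character_, sub("^TF", "FAM", fam_of))
  fam_sets <- ifelse(is.na(upfam_of), list(character(0)),
                     lapply(upfam_of, function(f) if (is.na(f)) character(0) else f))

  proteome <- tibble(
    accession = sprintf("P%05d", seq_len(n)),
    gene_name = genes,
    organism = cfg$organism,
    sequence = sequences,
    length = len,
    molecular_weight = mw,
    reviewed = TRUE,
    protein_existence_evidence = TRUE,
    is_fragment = FALSE,
    keywords = keywords,
    go_mf = go_branch("MF"),
    go_bp = go_branch("BP"),
    go_cc = go_branch("CC"),
    families = fam_sets,
    ptm_annotations = ptm,
    tissue_specificity = tissue,
    disease = disease,
    pharmaceutical = NA_character_
  )

  # --- genomic table -------------------------------------------------------
  utr3_meanlog <- cfg$utr3_meanlog + ifelse(regulated == 1, cfg$utr3_length_shift, 0)
  utr3 <- as.integer(round(stats::rlnorm(n, utr3_meanlog, cfg$utr3_sdlog)))
  utr3[stats::runif(n) < 0.05] <- 0L  # a few genes without an annotated 3'-UTR
  utr5 <- as.integer(round(stats::rlnorm(n, 5.0, 0.7)))
  cds <- 3L * len + 3L
  transcript <- cds + utr5 + utr3
  nt_a <- stats::rbinom(n, transcript, 0.28)
  nt_c <- stats::rbinom(n, transcript - nt_a, 0.22 / 0.72)
  nt_g <- stats::rbinom(n, transcript - nt_a - nt_c, 0.22 / 0.50)
  nt_t <- transcript - nt_a - nt_c - nt_g
  start_pos <- sample.int(2e8L, n, replace = TRUE)
  utr3_seq <- vapply(pmin(utr3, 400L), function(L) {
    if (L == 0) "" else paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                              collapse = "")
  }, character(1))
  genomic <- tibble(
    gene_name = genes,
    transcript_length = transcript,
    cds_length = cds,
    utr5_length = utr5,
    utr3_length = utr3,
    n_splice_variants = stats::rpois(n, 3),
    chromosome = sample(paste0("chr", c(1:22, "X")), n, replace = TRUE),
    start_pos = start_pos,
    end_pos = start_pos + transcript + as.integer(stats::rpois(n, 2e4)),
    nt_A = nt_a, nt_C = nt_c, nt_G = nt_g, nt_T = nt_t,
    utr3_sequence = utr3_seq
  )

  families <- bind_rows(
    tibble(gene_name = genes[for_fam], family_id = fam_of[for_fam],
           source = "treefam"),
    tibble(gene_name = genes[for_fam], family_id = upfam_of[for_fam],
           source = "uniprot")
  )

  label3 <- ifelse(regulated == 1,
                   ifelse(stats::runif(n) < cfg$weak_single_prob, 0L, 1L),
                   -1L)

  truth <- list(
    labels = tibble(gene_name = genes, regulated = regulated, label3 = label3),
    planted = planted,
    coherent_families = tibble(family_id = fam_ids, coherent = unname(coherent),
                               size = sizes)
  )
  list(proteome = proteome, genomic = genomic, families = families,
       ground_truth = truth)
}

#' Generate a synthetic proteome with planted ground truth
#'
#' Draws labels (with family-level coherence), planted and noise keyword
#' annotations, label-shifted sequences, a genomic attribute table, and a
#' family map, all deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return List with `proteome`, `genomic`, `families` (long tibble with
#'   `source` in treefam/uniprot), and `ground_truth` (true labels, planted
#'   feature parameters, per-family coherence flags).
#' @export
generate_proteome <- function(config) {
  withr::with_seed(config$seed, {
    supports <- stats::runif(config$n_planted_features,
                             config$planted_support[1], config$planted_support[2])
    classes <- plant_classes(config$planted_lifts, supports, config$prevalence,
                             config$planted_classes)
    planted <- tibble(
      feature_id = sprintf("PKW%03d", seq_len(config$n_planted_features)),
      lift = config$planted_lifts, support = supports,
      dominant_class = classes, active = TRUE)
    noise <- tibble(
      feature_id = sprintf("NKW%04d", seq_len(config$n_noise_keywords)),
      support = stats::runif(config$n_noise_keywords,
                             config$noise_support[1], config$noise_support[2]))
    gen_proteome_impl(config, planted, noise)
  })
}

#' Generate an evidence table consistent with three-way labels
#'
#' Encodes the labeling rules in reverse: positives (1) receive strong
#' evidence or at least two unique weak experiments, likely positives (0)
#' exactly one unique weak experiment (possibly duplicated verbatim),
#' negatives (-1) no row. Round-tripping through [summarize_evidence()] and
#' [assign_labels()] reproduces the input labels exactly.
#'
#' @param labels Tibble `gene_name`, `label` in -1/0/1 (e.g.
#'   `ground_truth$labels` with `label3`).
#' @param evidence_model List(`strong_prob`, `extra_weak_mean`, `dup_prob`);
#'   see [generator_config()].
#' @param seed Integer seed.
#' @param organism Organism tag.
#' @return Evidence tibble in the dialect of [read_evidence_table()].
#' @export
generate_evidence <- function(labels, evidence_model = list(strong_prob = 0.5,
                                                            extra_weak_mean = 1,
                                                            dup_prob = 0.3),
                              seed = 1L, organism = "synthetica") {
  sp <- evidence_model$strong_prob %||% 0.5
  ew <- evidence_model$extra_weak_mean %||% 1
  dp <- evidence_model$dup_prob %||% 0.3
  if (sp < 0 || sp > 1 || ew < 0 || dp < 0 || dp > 1) {
    stop("evidence model violates the label guarantee", call. = FALSE)
  }
  withr::with_seed(seed, {
    pos <- labels$gene_name[labels$label == 1L]
    weakly <- labels$gene_name[labels$label == 0L]

    use_strong <- stats::runif(length(pos)) < sp
    n_strong <- ifelse(use_strong, 1L + stats::rpois(length(pos), 0.5), 0L)
    n_weak <- ifelse(use_strong, stats::rpois(length(pos), 0.7),
                     2L + stats::rpois(length(pos), ew))

    ref_counter <- 0L
    next_refs <- function(k) {
      refs <- sprintf("REF%06d", ref_counter + seq_len(k))
      ref_counter <<- ref_counter + k
      refs
    }
    strong_rows <- tibble(
      target_gene = rep(pos, n_strong),
      evidence_strength = "strong",
      experiment = sample(STRONG_TYPES, sum(n_strong), replace = TRUE),
      reference_id = next_refs(sum(n_strong)))
    weak_genes <- c(rep(pos, n_weak), weakly)
    weak_rows <- tibble(
      target_gene = weak_genes,
      evidence_strength = "weak",
      experiment = sample(WEAK_TYPES, length(weak_genes), replace = TRUE),
      reference_id = next_refs(length(weak_genes)))
    dup <- weak_rows[stats::runif(nrow(weak_rows)) < dp, , drop = FALSE]

    out <- bind_rows(strong_rows, weak_rows, dup)
    out$mirna_id <- sprintf("syn-miR-%03d", sample.int(300L, nrow(out), replace = TRUE))
    out$organism <- organism
    out$experiment_key <- paste0(trim_fold(out$experiment), "::", out$reference_id)
    out[, c("mirna_id", "target_gene", "organism", "evidence_strength",
            "experiment", "reference_id", "experiment_key")]
  })
}

#' Generate a second species sharing part of the first one's signal
#'
#' Produces an independent synthetic proteome whose planted signal overlaps
#' the first species' by the requested fraction: `round(overlap * n)` of
#' the planted keywords keep their feature-label association (same token,
#' lift, support, dominant class); the remaining original tokens become
#' label-independent noise at their original support, replaced by fresh
#' planted tokens private to the second species. Label-linked numeric
#' shifts (protein length, residue composition, 3'-UTR length) are scaled
#' by `overlap` as well, so `overlap = 0` carries no transferable signal of
#' any kind and `overlap = 1` reproduces the first species' conditions.
#' The noise keyword vocabulary is shared.
#'
#' @param first Output of [generate_proteome()] or [simulate_study()]
#'   (must carry `ground_truth$planted`).
#' @param config The [generator_config()] the first species was built with.
#' @param overlap Fraction of shared planted signal in \[0, 1\].
#' @param seed Integer seed for the second species.
#' @return Same structure as [generate_proteome()], with gene names
#'   prefixed `BGENE`.
#' @export
generate_second_species <- function(first, config, overlap, seed = 2L) {
  stopifnot(overlap >= 0, overlap <= 1)
  planted_a <- first$ground_truth$planted
  n_keep <- round(overlap * nrow(planted_a))

  cfg_b <- config
  cfg_b$seed <- as.integer(seed)
  cfg_b$length_shift_unregulated <- config$length_shift_unregulated * overlap
  cfg_b$composition_shift <- config$composition_shift * overlap
  cfg_b$utr3_length_shift <- config$utr3_length_shift * overlap

  withr::with_seed(seed, {
    kept <- planted_a[seq_len(n_keep), , drop = FALSE]
    retired <- planted_a[setdiff(seq_len(nrow(planted_a)), seq_len(n_keep)), ,
                         drop = FALSE]
    retired$active <- FALSE
    n_new <- nrow(planted_a) - n_keep
    fresh <- if (n_new > 0) {
      supports <- stats::runif(n_new, config$planted_support[1],
                               config$planted_support[2])
      lifts <- retired$lift
      tibble(feature_id = sprintf("PKWB%03d", seq_len(n_new)),
             lift = lifts, support = supports,
             dominant_class = plant_classes(lifts, supports, config$prevalence),
             active = TRUE)
    } else {
      planted_a[0, ]
    }
    planted_b <- bind_rows(kept, retired, fresh)
    noise <- tibble(
      feature_id = sprintf("NKW%04d", seq_len(config$n_noise_keywords)),
      support = stats::runif(config$n_noise_keywords,
                             config$noise_support[1], config$noise_support[2]))
    out <- gen_proteome_impl(cfg_b, planted_b, noise, gene_prefix = "BGENE",
                             id_tag = "B")
  })
  out$ground_truth$shared_planted <- planted_a$feature_id[seq_len(n_keep)]
  out
}

#' Simulate a complete study (proteome + evidence)
#'
#' Convenience wrapper: [generate_proteome()] followed by
#' [generate_evidence()] on the true three-way labels.
#'
#' @param config A [generator_config()].
#' @return The [generate_proteome()] list plus `evidence` and `config`.
#' @export
simulate_study <- function(config) {
  out <- generate_proteome(config)
  labels3 <- tibble(gene_name = out$ground_truth$labels$gene_name,
                    label = out$ground_truth$labels$label3)
  out$evidence <- generate_evidence(labels3, config$evidence_model,
                                    seed = derive_seed(config$seed, 101L),
                                    organism = config$organism)
  out$config <- config
  out
}

#' Write a simulated study in the package's tabular dialects
#'
#' Writes the proteome TSV (+ FASTA), evidence TSV, genomic TSV, family TSV
#' and ground-truth TSV, readable back by the io functions.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_protein_table(study$proteome, file.path(dir, "proteome.tsv"),
                      fasta_path = file.path(dir, "proteome.fasta"))
  ev_out <- study$evidence[, c("mirna_id", "target_gene", "organism",
                               "experiment", "reference_id")]
  names(ev_out)[names(ev_out) == "experiment"] <- "experiments"
  readr::write_tsv(ev_out, file.path(dir, "evidence.tsv"), progress = FALSE)
  readr::write_tsv(study$genomic, file.path(dir, "genomic.tsv"), progress = FALSE)
  readr::write_tsv(study$families, file.path(dir, "families.tsv"), progress = FALSE)
  readr::write_tsv(study$ground_truth$labels, file.path(dir, "ground_truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}
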