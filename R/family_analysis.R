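# Regulation coherence within gene families: per-family regulated fractions
# with exact binomial enrichment, the mode-assignment coherence statistic
# and its one-sided binomial significance against an analytic null.

#' Exact two-sided binomial p-value (double smaller tail)
#'
#' `min(1, 2 * min(P(X <= x), P(X >= x)))` for X ~ Binomial(n, p). This
#' doubling-of-the-smaller-tail definition is used throughout the family
#' analyses.
#'
#' @param x Observed successes.
#' @param n Trials.
#' @param p Null success probability.
#' @return p-value in (0, 1].
#' @export
binom_p_two_sided <- function(x, n, p) {
  lower <- stats::pbinom(x, n, p)
  upper <- stats::pbinom(x - 1, n, p, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Exact one-sided ("greater") binomial p-value
#'
#' @inheritParams binom_p_two_sided
#' @return `P(X >= x)` for X ~ Binomial(n, p).
#' @export
binom_p_greater <- function(x, n, p) {
  stats::pbinom(x - 1, n, p, lower.tail = FALSE)
}

# Normalize a family assignment to a long (gene_name, family_id) tibble.
family_long <- function(families, family_source = NULL) {
  fam <- families
  if (!is.null(family_source) && "source" %in% names(fam)) {
    fam <- fam[fam$source == family_source, , drop = FALSE]
  }
  stopifnot(all(c("gene_name", "family_id") %in% names(fam)))
  distinct(fam, .data$gene_name, .data$family_id)
}

#' Per-family regulated fractions with enrichment tests
#'
#' For every family: member count, regulated count and fraction, and the
#' exact two-sided binomial p-value of that count against the global
#' regulated prior. Genes belonging to several families are counted in each;
#' family members missing from the label universe are dropped with a
#' warning, and families left empty are omitted.
#'
#' @param labels Binary labels (tibble `gene_name`/`label`).
#' @param families Long family map (`gene_name`, `family_id`, optional
#'   `source`).
#' @param family_source Optional source filter (e.g. `"treefam"`,
#'   `"uniprot"`).
#' @param prior Null regulated fraction; default the mean label over the
#'   universe.
#' @return Tibble `family_id`, `n_members`, `n_regulated`,
#'   `fraction_regulated`, `binom_p_two_sided`.
#' @export
family_fractions <- function(labels, families, family_source = NULL,
                             prior = NULL) {
  fam <- family_long(families, family_source)
  known <- fam$gene_name %in% labels$gene_name
  if (any(!known)) {
    warning(sprintf("%d family member(s) missing from the label universe dropped",
                    sum(!known)), call. = FALSE)
    fam <- fam[known, , drop = FALSE]
  }
  prior <- prior %||% mean(labels$label)
  fam |>
    left_join(labels, by = "gene_name") |>
    group_by(.data$family_id) |>
    summarise(n_members = n(), n_regulated = sum(.data$label), .groups = "drop") |>
    mutate(fraction_regulated = .data$n_regulated / .data$n_members,
           binom_p_two_sided = binom_p_two_sided(.data$n_regulated,
                                                 .data$n_members, prior)) |>
    arrange(.data$binom_p_two_sided, .data$family_id)
}

# Expected per-member success probability of mode assignment for a family
# of size s whose labels are iid Bernoulli(p); ties go to the global
# majority label g.
mode_null_rate <- function(s, p, g) {
  k <- 0:s
  pk <- stats::dbinom(k, s, p)
  mode_lab <- ifelse(k > s - k, 1L, ifelse(k < s - k, 0L, g))
  matches <- ifelse(mode_lab == 1L, k, s - k)
  sum(pk * matches) / s
}

#' Family regulation-coherence test
#'
#' Over families with at least `min_size` members: (1) the coherence
#' fraction, i.e. the share of families whose members all carry the same
#' label; (2) the mode-assignment statistic - each gene's label is
#' predicted by its family's majority label (ties resolved toward the
#' global majority), and successes are genes predicted correctly. Genes in
#' several qualifying families contribute one trial only, through their
#' lexicographically first family, to keep the binomial test's trials
#' independent of multiplicity. (3) A one-sided ("greater") exact binomial
#' test of the successes against the analytic null rate: the expected
#' success probability when labels are assigned independently at the global
#' prior, computed per family size and averaged with trial weights. A
#' label-shuffling null is available via [coherence_null_simulation()].
#'
#' @inheritParams family_fractions
#' @param min_size Minimum family size (default 2).
#' @return One-row tibble (class `coherence_result`): `n_families_tested`,
#'   `n_coherent`, `coherence_fraction`, `mode_successes`, `mode_trials`,
#'   `null_rate`, `binom_p_one_sided`.
#' @export
coherence_test <- function(labels, families, family_source = NULL,
                           min_size = 2L) {
  fam <- family_long(families, family_source) |>
    filter(.data$gene_name %in% labels$gene_name) |>
    left_join(labels, by = "gene_name")
  sizes <- fam |> count(.data$family_id, name = "n_members")
  qual <- sizes$family_id[sizes$n_members >= min_size]
  if (length(qual) == 0L) stop("no family of size >= min_size", call. = FALSE)
  fam <- fam |> filter(.data$family_id %in% qual)

  by_fam <- fam |>
    group_by(.data$family_id) |>
    summarise(n_members = n(), n_pos = sum(.data$label), .groups = "drop") |>
    mutate(coherent = .data$n_pos == 0L | .data$n_pos == .data$n_members)

  prior <- mean(labels$label)
  g <- if (prior >= 0.5) 1L else 0L
  fam_mode <- by_fam |>
    mutate(mode_label = ifelse(.data$n_pos > .data$n_members - .data$n_pos, 1L,
                               ifelse(.data$n_pos < .data$n_members - .data$n_pos,
                                      0L, g)))

  trials <- fam |>
    arrange(.data$family_id) |>
    distinct(.data$gene_name, .keep_all = TRUE) |>
    left_join(fam_mode[, c("family_id", "mode_label", "n_members")],
              by = "family_id")
  successes <- sum(trials$label == trials$mode_label)

  null_by_size <- vapply(sort(unique(trials$n_members)), function(s) {
    mode_null_rate(s, prior, g)
  }, numeric(1))
  names(null_by_size) <- sort(unique(trials$n_members))
  null_rate <- mean(null_by_size[as.character(trials$n_members)])

  out <- tibble(
    n_families_tested = nrow(by_fam),
    n_coherent = sum(by_fam$coherent),
    coherence_fraction = sum(by_fam$coherent) / nrow(by_fam),
    mode_successes = successes,
    mode_trials = nrow(trials),
    null_rate = null_rate,
    binom_p_one_sided = binom_p_greater(successes, nrow(trials), null_rate)
  )
  class(out) <- c("coherence_result", class(out))
  out
}

#' Label-shuffling null for the coherence test
#'
#' Re-runs [coherence_test()] on `n_shuffle` global permutations of the
#' labels over genes, returning the one-sided p-value of each replicate -
#' an empirical cross-check of the analytic null rate.
#'
#' @inheritParams coherence_test
#' @param n_shuffle Number of label permutations.
#' @param seed Integer seed.
#' @return Numeric vector of `n_shuffle` p-values.
#' @export
coherence_null_simulation <- function(labels, families, family_source = NULL,
                                      min_size = 2L, n_shuffle = 200L,
                                      seed = 1L) {
  withr::with_seed(seed, {
    vapply(seq_len(n_shuffle), function(i) {
      shuffled <- labels
      shuffled$label <- sample(shuffled$label)
      coherence_test(shuffled, families, family_source, min_size)$binom_p_one_sided
    }, numeric(1))
  })
}

#' Regulation among genes without any family assignment
#'
#' Compares the unregulated fraction of genes lacking a family with that of
#' genes carrying at least one, including an exact two-sided binomial test
#' of the unmatched group's unregulated count against the global unregulated
#' fraction.
#'
#' @inheritParams family_fractions
#' @return Tibble with one row per group (`matched`, `unmatched`) and the
#'   test columns on the unmatched row.
#' @export
unmatched_family_report <- function(labels, families, family_source = NULL) {
  fam <- family_long(families, family_source)
  matched <- labels$gene_name %in% fam$gene_name
  global_unreg <- mean(labels$label == 0)
  mk <- function(group, idx) {
    n <- sum(idx)
    n_unreg <- sum(labels$label[idx] == 0)
    tibble(group = group, n = n, n_unregulated = n_unreg,
           fraction_unregulated = if (n > 0) n_unreg / n else NA_real_)
  }
  out <- bind_rows(mk("matched", matched), mk("unmatched", !matched)) |>
    mutate(global_fraction_unregulated = global_unreg,
           ratio_vs_global = .data$fraction_unregulated / global_unreg)
  out$binom_p_two_sided <- NA_real_
  if (out$n[out$group == "unmatched"] > 0) {
    i <- which(out$group == "unmatched")
    out$binom_p_two_sided[i] <- binom_p_two_sided(out$n_unregulated[i],
                                                  out$n[i], global_unreg)
  }
  out
}
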