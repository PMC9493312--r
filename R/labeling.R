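#' Summarize per-gene experimental evidence
#'
#' Collapses evidence rows into one summary per target gene: the number of
#' strong-evidence rows and the number of *unique* weak experiments, where
#' uniqueness is decided on `experiment_key` (experiment descriptor plus
#' reference), so repeated reports of the same weak experiment count once.
#'
#' @param evidence Evidence tibble from [read_evidence_table()] or
#'   [generate_evidence()].
#' @param organism Optional organism tag; when given, only rows with an
#'   exactly matching organism contribute.
#' @return Tibble with `gene_name`, `n_strong`, `n_unique_weak`.
#' @export
summarize_evidence <- function(evidence, organism = NULL) {
  ev <- evidence
  if (!is.null(organism)) ev <- ev[!is.na(ev$organism) & ev$organism == organism, ]
  if (nrow(ev) == 0L) {
    return(tibble(gene_name = character(0), n_strong = integer(0),
                  n_unique_weak = integer(0)))
  }
  ev |>
    group_by(gene_name = .data$target_gene) |>
    summarise(
      n_strong = sum(.data$evidence_strength == "strong"),
      n_unique_weak = n_distinct(.data$experiment_key[.data$evidence_strength == "weak"]),
      .groups = "drop"
    )
}

#' Assign three-way miRNA-regulation labels
#'
#' A gene is a positive (`1`, miRNA regulated) when it has at least one
#' strong-evidence experiment or at least two unique weak experiments; a
#' likely positive (`0`) when its only support is a single unique weak
#' experiment; and a negative (`-1`) when it has no evidence row at all.
#' Every gene of `universe` receives exactly one label; summarized genes
#' outside the universe are dropped with a warning.
#'
#' @param summaries Output of [summarize_evidence()].
#' @param universe Character vector of gene names defining the proteome
#'   analyzed.
#' @return Tibble `gene_name`, `label` (integer in -1/0/1), `n_strong`,
#'   `n_unique_weak`, in `universe` order.
#' @export
assign_labels <- function(summaries, universe) {
  outside <- setdiff(summaries$gene_name, universe)
  if (length(outside)) {
    warning(sprintf("%d evidence gene(s) outside the universe dropped", length(outside)),
            call. = FALSE)
    summaries <- summaries[summaries$gene_name %in% universe, ]
  }
  out <- tibble(gene_name = universe) |>
    left_join(summaries, by = "gene_name") |>
    mutate(
      n_strong = ifelse(is.na(.data$n_strong), 0L, .data$n_strong),
      n_unique_weak = ifelse(is.na(.data$n_unique_weak), 0L, .data$n_unique_weak),
      label = case_when(
        .data$n_strong >= 1L | .data$n_unique_weak >= 2L ~ 1L,
        .data$n_unique_weak == 1L ~ 0L,
        TRUE ~ -1L
      )
    )
  out[, c("gene_name", "label", "n_strong", "n_unique_weak")]
}

#' Binarize three-way labels for modeling
#'
#' Converts the -1/0/1 label into the 0/1 target used by the classifiers.
#' `weak_as_positive` (the default downstream treatment) maps likely
#' positives to 1; `exclude_weak` drops them (reported to improve models);
#' `weak_as_negative` folds them into the negatives.
#'
#' @param labels Tibble from [assign_labels()].
#' @param policy One of `"weak_as_positive"`, `"exclude_weak"`,
#'   `"weak_as_negative"`.
#' @return Tibble `gene_name`, `label` (0/1), aligned with the (possibly
#'   subset) gene list.
#' @export
binarize_labels <- function(labels,
                            policy = c("weak_as_positive", "exclude_weak",
                                       "weak_as_negative")) {
  policy <- tryCatch(match.arg(policy),
                     error = function(e) stop("unknown binarization policy: ",
                                              policy[1], call. = FALSE))
  out <- labels
  if (policy == "exclude_weak") out <- out[out$label != 0L, ]
  bin <- switch(policy,
    weak_as_positive = as.integer(out$label %in% c(1L, 0L)),
    exclude_weak = as.integer(out$label == 1L),
    weak_as_negative = as.integer(out$label == 1L)
  )
  tibble(gene_name = out$gene_name, label = bin)
}

#' Write the per-gene label table
#'
#' @param labels Output of [assign_labels()].
#' @param binary Output of [binarize_labels()] on the same labels.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(labels, binary, path) {
  out <- labels |>
    left_join(binary |> rename(binary_label = "label"), by = "gene_name")
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}
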