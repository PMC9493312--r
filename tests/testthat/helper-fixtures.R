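# Shared fixture builders (all data generated in code).

# Wrap a plain numeric matrix as a feature_matrix object.
make_fm <- function(values, kinds = NULL, genes = NULL) {
  genes <- genes %||% (rownames(values) %||% paste0("g", seq_len(nrow(values))))
  rownames(values) <- genes
  kinds <- kinds %||% rep("binary", ncol(values))
  structure(list(
    genes = genes,
    values = values,
    descriptors = tibble::tibble(feature_id = colnames(values),
                                 source = "test", kind = kinds,
                                 generator_tag = "test", complexity = 1L)),
    class = "feature_matrix")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

label_tbl <- function(genes, labels) tibble::tibble(gene_name = genes, label = labels)

# A minimal protein tibble with the full canonical column set.
mini_proteome <- function(n = 3) {
  tibble::tibble(
    accession = sprintf("P%03d", seq_len(n)),
    gene_name = sprintf("G%03d", seq_len(n)),
    organism = "test",
    sequence = rep("MKKLV", n),
    length = 5L,
    molecular_weight = 600,
    reviewed = TRUE,
    protein_existence_evidence = TRUE,
    is_fragment = FALSE,
    keywords = rep(list(character(0)), n),
    go_mf = rep(list(character(0)), n),
    go_bp = rep(list(character(0)), n),
    go_cc = rep(list(character(0)), n),
    families = rep(list(character(0)), n),
    ptm_annotations = rep(list(character(0)), n),
    tissue_specificity = NA_character_,
    disease = NA_character_,
    pharmaceutical = NA_character_
  )
}

# The 50-gene evidence fixture covering every labeling rule branch:
# 10 strong-evidence genes, 10 with two unique weak experiments, 10 with a
# duplicated single weak experiment, 10 with one weak experiment, 10 silent.
evidence_fixture_50 <- function() {
  genes <- sprintf("EG%02d", 1:50)
  mk <- function(gene, strength, exp, ref) {
    tibble::tibble(mirna_id = "syn-miR-001", target_gene = gene,
                   organism = "test", evidence_strength = strength,
                   experiment = exp, reference_id = ref,
                   experiment_key = paste0(toupper(exp), "::", ref))
  }
  rows <- list()
  for (g in genes[1:10]) rows[[length(rows) + 1]] <- mk(g, "strong", "Western blot", paste0("S", g))
  for (g in genes[11:20]) {
    rows[[length(rows) + 1]] <- mk(g, "weak", "CLIP-Seq", paste0("W1", g))
    rows[[length(rows) + 1]] <- mk(g, "weak", "pSILAC", paste0("W2", g))
  }
  for (g in genes[21:30]) {
    dup <- mk(g, "weak", "CLIP-Seq", paste0("D", g))
    rows[[length(rows) + 1]] <- dup
    rows[[length(rows) + 1]] <- dup
  }
  for (g in genes[31:40]) rows[[length(rows) + 1]] <- mk(g, "weak", "Microarray", paste0("U", g))
  list(evidence = dplyr::bind_rows(rows), genes = genes,
       expected = c(rep(1L, 10), rep(1L, 10), rep(0L, 10), rep(0L, 10), rep(-1L, 10)))
}
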