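# Feature generation. Every featurizer returns a long tibble
# (gene_name, feature_id, value, source, kind, generator_tag, complexity);
# binary features are emitted only where present (value 1), numeric features
# for every gene that has the underlying field. assemble_features() turns the
# long form into a gene x feature matrix.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Average residue masses (Da); used for molecular weight when the input
# table does not provide one.
AA_MASS <- c(A = 71.08, C = 103.14, D = 115.09, E = 129.12, F = 147.18,
             G = 57.05, H = 137.14, I = 113.16, K = 128.17, L = 113.16,
             M = 131.19, N = 114.10, P = 97.12, Q = 128.13, R = 156.19,
             S = 87.08, T = 101.10, V = 99.13, W = 186.21, Y = 163.18)

feature_row <- function(gene, id, value, source, kind, tag, complexity = 1L) {
  tibble(gene_name = gene, feature_id = id, value = value, source = source,
         kind = kind, generator_tag = tag, complexity = complexity)
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Protein sequence features
#'
#' Emits, per protein: numeric length and molecular weight, the 20 canonical
#' per-residue composition fractions (denominator is the full sequence
#' length, so ambiguity codes X/B/Z/U leave the fractions summing below 1)
#' and per-residue counts; and a binary presence feature for every k-mer
#' actually observed, for k in `k_range`. Set `k_range = NULL` to skip
#' k-mers (composition and length only).
#'
#' @param proteins Protein tibble with `gene_name` and `sequence` (and
#'   optionally `molecular_weight`).
#' @param k_range Integer pair `c(kmin, kmax)` or `NULL`.
#' @return Long feature tibble.
#' @export
featurize_sequences <- function(proteins, k_range = c(1, 3)) {
  seqs <- proteins$sequence
  if (any(is.na(seqs) | !nzchar(seqs))) {
    stop("empty sequence for gene(s): ",
         paste(head(proteins$gene_name[is.na(seqs) | !nzchar(seqs)], 5), collapse = ", "),
         call. = FALSE)
  }
  genes <- proteins$gene_name
  n <- length(genes)
  len <- nchar(seqs)

  chars <- strsplit(seqs, "", fixed = TRUE)
  counts <- vapply(chars, function(ch) tabulate(factor(ch, levels = AA20), nbins = 20L),
                   numeric(20))  # 20 x n
  fracs <- sweep(counts, 2, len, "/")

  mw <- proteins$molecular_weight %||% rep(NA_real_, n)
  if (all(is.na(mw))) mw <- colSums(counts * AA_MASS[AA20]) + 18.02

  num <- bind_rows(
    feature_row(genes, "length", as.numeric(len), "sequence", "numeric", "seq_length"),
    feature_row(genes, "molecular_weight", mw, "sequence", "numeric", "seq_mw"),
    tibble(gene_name = rep(genes, each = 20L),
           feature_id = rep(paste0("aa_frac:", AA20), n),
           value = as.numeric(fracs),
           source = "sequence", kind = "numeric",
           generator_tag = "aa_composition", complexity = 1L),
    tibble(gene_name = rep(genes, each = 20L),
           feature_id = rep(paste0("aa_count:", AA20), n),
           value = as.numeric(counts),
           source = "sequence", kind = "numeric",
           generator_tag = "aa_count", complexity = 1L)
  )

  if (is.null(k_range)) return(num)
  ks <- seq.int(k_range[1], k_range[2])
  km <- purrr::map2_dfr(genes, seqs, function(g, s) {
    mers <- unlist(lapply(ks, kmer_set, seq = s), use.names = FALSE)
    if (!length(mers)) return(NULL)
    feature_row(g, paste0("kmer:", mers), 1, "sequence", "binary", "seq_kmer")
  })
  bind_rows(num, km)
}

#' Annotation features
#'
#' Generates binary incidence features from a protein's curated annotations:
#' one per keyword, one per unordered keyword pair (when `ngram_max >= 2`),
#' one per GO term in each branch, one per family membership, non-emptiness
#' flags for PTM/disease/tissue/pharmaceutical fields, substring indicators
#' for organs in the tissue-specificity free text, plus numeric counts of
#' keywords, GO terms per branch, and PTM annotations.
#'
#' @param proteins Protein tibble.
#' @param ngram_max Keyword n-gram order; 1 disables pairs, 2 (default)
#'   adds all unordered keyword pairs.
#' @param organ_lexicon Organs searched in the tissue text (case-insensitive
#'   substring match).
#' @param fields Subset of feature families to emit; default all.
#' @return Long feature tibble.
#' @export
featurize_annotations <- function(proteins, ngram_max = 2,
                                  organ_lexicon = c("muscle", "heart", "brain", "testis"),
                                  fields = c("keywords", "pairs", "go", "families",
                                             "flags", "counts", "tissue")) {
  fields <- match.arg(fields, several.ok = TRUE)
  genes <- proteins$gene_name
  parts <- list()

  from_sets <- function(col, prefix, tag, complexity = 1L) {
    sets <- proteins[[col]]
    nper <- lengths(sets)
    if (sum(nper) == 0L) return(NULL)
    feature_row(rep(genes, nper), paste0(prefix, unlist(sets, use.names = FALSE)),
                1, "annotation", "binary", tag, complexity)
  }

  if ("keywords" %in% fields) parts$kw <- from_sets("keywords", "kw:", "keyword")
  if ("pairs" %in% fields && ngram_max >= 2) {
    parts$pairs <- purrr::map2_dfr(genes, proteins$keywords, function(g, kws) {
      kws <- sort(unique(kws))
      if (length(kws) < 2) return(NULL)
      cmb <- utils::combn(kws, 2)
      feature_row(g, paste0("kwpair:", cmb[1, ], "+", cmb[2, ]),
                  1, "annotation", "binary", "keyword_pair", 2L)
    })
  }
  if ("go" %in% fields) {
    parts$go_mf <- from_sets("go_mf", "go_mf:", "go_term")
    parts$go_bp <- from_sets("go_bp", "go_bp:", "go_term")
    parts$go_cc <- from_sets("go_cc", "go_cc:", "go_term")
  }
  if ("families" %in% fields) parts$fam <- from_sets("families", "fam:", "family")

  if ("flags" %in% fields) {
    flag <- function(x) as.numeric(
      if (is.list(x)) lengths(x) > 0 else !is.na(x) & nzchar(trimws(x)))
    flag_cols <- c(ptm = "ptm_annotations", disease = "disease",
                   tissue = "tissue_specificity", pharmaceutical = "pharmaceutical")
    parts$flags <- purrr::imap_dfr(flag_cols, function(col, nm) {
      if (!col %in% names(proteins)) return(NULL)
      v <- flag(proteins[[col]])
      feature_row(genes[v == 1], paste0("nonEmpty(", nm, ")"), 1,
                  "annotation", "binary", "nonempty_flag")
    })
  }

  if ("counts" %in% fields) {
    parts$counts <- bind_rows(
      feature_row(genes, "n_keywords", lengths(proteins$keywords),
                  "annotation", "numeric", "count"),
      feature_row(genes, "n_go_mf", lengths(proteins$go_mf), "annotation", "numeric", "count"),
      feature_row(genes, "n_go_bp", lengths(proteins$go_bp), "annotation", "numeric", "count"),
      feature_row(genes, "n_go_cc", lengths(proteins$go_cc), "annotation", "numeric", "count"),
      feature_row(genes, "n_ptm", lengths(proteins$ptm_annotations),
                  "annotation", "numeric", "count")
    )
  }

  if ("tissue" %in% fields && "tissue_specificity" %in% names(proteins)) {
    txt <- tolower(proteins$tissue_specificity %|NA|% "")
    parts$tissue <- purrr::map_dfr(organ_lexicon, function(org) {
      hit <- grepl(org, txt, fixed = TRUE)
      feature_row(genes[hit], paste0("tissue:", org), 1,
                  "annotation", "binary", "tissue_substring")
    })
  }

  bind_rows(parts)
}

#' Genomic features
#'
#' Numeric transcript/CDS/UTR lengths, splice-variant count, chromosomal
#' start/end and per-base nucleotide counts; binary chromosome identity and
#' `has_utr3`; optionally binary presence of every 3'-UTR n-gram for the
#' requested size ranges (the two-to-four and five-to-six windows by
#' default). Genes lacking a 3'-UTR sequence are skipped for n-grams with a
#' warning.
#'
#' @param genomic Genomic attribute tibble (one row per gene).
#' @param with_utr3_ngrams Emit 3'-UTR n-gram presence features?
#' @param ngram_ranges List of integer pairs of n-gram sizes.
#' @return Long feature tibble.
#' @export
featurize_genomic <- function(genomic, with_utr3_ngrams = FALSE,
                              ngram_ranges = list(c(2, 4), c(5, 6))) {
  genes <- genomic$gene_name
  num_cols <- c("transcript_length", "cds_length", "utr5_length", "utr3_length",
                "n_splice_variants", "start_pos", "end_pos")
  parts <- list(
    num = purrr::map_dfr(intersect(num_cols, names(genomic)), function(col) {
      feature_row(genes, paste0("g:", col), as.numeric(genomic[[col]]),
                  "genomic", "numeric", "genomic_numeric")
    })
  )
  base_cols <- grep("^nt_", names(genomic), value = TRUE)
  if (length(base_cols)) {
    parts$nt <- purrr::map_dfr(base_cols, function(col) {
      feature_row(genes, paste0("g:", col), as.numeric(genomic[[col]]),
                  "genomic", "numeric", "nt_count")
    })
  }
  if ("chromosome" %in% names(genomic)) {
    parts$chrom <- feature_row(genes, paste0("chrom:", genomic$chromosome), 1,
                               "genomic", "binary", "chromosome")
  }
  if ("utr3_length" %in% names(genomic)) {
    has3 <- !is.na(genomic$utr3_length) & genomic$utr3_length > 0
    parts$has3 <- feature_row(genes[has3], "has_utr3", 1, "genomic", "binary",
                              "has_utr3")
  }
  if (with_utr3_ngrams) {
    if (!"utr3_sequence" %in% names(genomic)) {
      warning("utr3_sequence column absent; 3'-UTR n-grams skipped", call. = FALSE)
    } else {
      seqs <- genomic$utr3_sequence
      absent <- is.na(seqs) | !nzchar(seqs)
      if (any(absent)) {
        warning(sprintf("3'-UTR sequence absent for %d gene(s); n-grams omitted there",
                        sum(absent)), call. = FALSE)
      }
      ks <- sort(unique(unlist(lapply(ngram_ranges, function(r) seq.int(r[1], r[2])))))
      parts$ngrams <- purrr::map2_dfr(genes[!absent], seqs[!absent], function(g, s) {
        mers <- unlist(lapply(ks, kmer_set, seq = s), use.names = FALSE)
        if (!length(mers)) return(NULL)
        feature_row(g, paste0("utr3gram:", mers), 1, "genomic", "binary",
                    "utr3_ngram")
      })
    }
  }
  bind_rows(parts)
}

#' Assemble long feature tibbles into a feature matrix
#'
#' Unions the feature ids across all inputs over a shared gene universe.
#' Binary features absent for a gene become 0; numeric features absent for a
#' gene become `NA` with a companion `is_missing(<id>)` binary column.
#' Binary columns with fewer than `min_support_count` positive genes, and
#' constant columns of either kind, are pruned. A feature id reported with
#' conflicting kinds is an error.
#'
#' @param ... One or more long feature tibbles.
#' @param genes Gene universe (default: union of genes seen).
#' @param min_support_count Minimum positive genes for a binary column.
#' @return A `feature_matrix` object: list with `genes`, numeric matrix
#'   `values` (genes x features), and a `descriptors` tibble.
#' @export
assemble_features <- function(..., genes = NULL, min_support_count = 5L) {
  long <- bind_rows(...)
  if (nrow(long) == 0L) stop("no features to assemble", call. = FALSE)
  genes <- genes %||% unique(long$gene_name)

  desc <- long |>
    distinct(.data$feature_id, .data$source, .data$kind, .data$generator_tag,
             .data$complexity)
  if (anyDuplicated(desc$feature_id)) {
    dup <- unique(desc$feature_id[duplicated(desc$feature_id)])
    kinds <- desc |> filter(.data$feature_id %in% dup) |>
      distinct(.data$feature_id, .data$kind)
    if (anyDuplicated(kinds$feature_id)) {
      stop("conflicting kind for feature id(s): ",
           paste(unique(kinds$feature_id[duplicated(kinds$feature_id)]), collapse = ", "),
           call. = FALSE)
    }
    desc <- desc |> distinct(.data$feature_id, .keep_all = TRUE)
  }
  desc <- desc |> arrange(.data$feature_id)

  gi <- match(long$gene_name, genes)
  keep_rows <- !is.na(gi)
  fi <- match(long$feature_id, desc$feature_id)

  m <- matrix(NA_real_, nrow = length(genes), ncol = nrow(desc),
              dimnames = list(genes, desc$feature_id))
  is_bin <- desc$kind == "binary"
  m[, is_bin] <- 0
  m[cbind(gi[keep_rows], fi[keep_rows])] <- long$value[keep_rows]

  # Companion missingness indicators for partially observed numeric features.
  miss <- is.na(m[, !is_bin, drop = FALSE])
  part <- colSums(miss) > 0 & colSums(miss) < length(genes)
  if (any(part)) {
    comp <- miss[, part, drop = FALSE] * 1
    colnames(comp) <- paste0("is_missing(", colnames(comp), ")")
    m <- cbind(m, comp)
    desc <- bind_rows(desc, tibble(
      feature_id = colnames(comp), source = "derived", kind = "binary",
      generator_tag = "is_missing", complexity = 1L))
    ord <- order(desc$feature_id)
    desc <- desc[ord, ]
    m <- m[, ord, drop = FALSE]
  }

  # Prune: low-support binaries and constant columns of either kind.
  # Missingness companions are kept whenever informative (non-constant):
  # they document the numeric column next to them rather than stand alone.
  is_bin <- desc$kind == "binary"
  is_companion <- desc$generator_tag == "is_missing"
  pos <- colSums(m == 1, na.rm = TRUE)
  rng <- apply(m, 2, function(col) {
    v <- col[!is.na(col)]
    if (!length(v)) 0 else max(v) - min(v)
  })
  drop <- (is_bin & !is_companion &
             (pos < min_support_count | pos == nrow(m))) | rng == 0
  m <- m[, !drop, drop = FALSE]
  desc <- desc[!drop, ]

  structure(list(genes = genes, values = m, descriptors = desc),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d genes x %d features (%d binary, %d numeric)\n",
              length(x$genes), ncol(x$values),
              sum(x$descriptors$kind == "binary"),
              sum(x$descriptors$kind == "numeric")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Convert a feature matrix to a tibble
#'
#' @param x A `feature_matrix`.
#' @param ... Unused.
#' @return Tibble with `gene_name` followed by one column per feature.
#' @export
as_tibble.feature_matrix <- function(x, ...) {
  bind_cols(tibble(gene_name = x$genes), as_tibble(x$values, .name_repair = "minimal"))
}

#' Restrict a feature matrix to a subset of genes
#'
#' @param fm A `feature_matrix`.
#' @param genes Genes to keep (order preserved as given).
#' @return A `feature_matrix` over `genes`.
#' @export
subset_genes <- function(fm, genes) {
  idx <- match(genes, fm$genes)
  if (anyNA(idx)) stop("unknown gene(s) in subset", call. = FALSE)
  structure(list(genes = genes, values = fm$values[idx, , drop = FALSE],
                 descriptors = fm$descriptors),
            class = "feature_matrix")
}

#' Write a feature matrix as sparse triplets plus descriptors
#'
#' @param fm A `feature_matrix`.
#' @param path Triplet TSV path (gene, feature_id, value; zeros of binary
#'   features are omitted).
#' @param descriptor_path Optional descriptor TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path, descriptor_path = NULL) {
  long <- as_tibble(fm) |>
    tidyr::pivot_longer(-"gene_name", names_to = "feature_id", values_to = "value") |>
    left_join(fm$descriptors[, c("feature_id", "kind")], by = "feature_id") |>
    filter(!(.data$kind == "binary" & .data$value == 0), !is.na(.data$value)) |>
    select("gene_name", "feature_id", "value")
  readr::write_tsv(long, path, progress = FALSE)
  if (!is.null(descriptor_path)) {
    readr::write_tsv(fm$descriptors, descriptor_path, progress = FALSE)
  }
  invisible(path)
}
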