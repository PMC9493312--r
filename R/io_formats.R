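#' @import dplyr
#' @import tibble
#' @importFrom rlang .data
#' @importFrom stats median na.omit predict quantile rbinom rlnorm rpois runif setNames
#' @importFrom utils head
NULL

# Canonical column names of the protein table dialect written by
# write_protein_table(). A column map translates other exports (e.g. a
# UniProtKB tab-delimited download) onto these names.
protein_canonical_cols <- c(
  "accession", "gene_name", "organism", "sequence", "length",
  "molecular_weight", "reviewed", "protein_existence_evidence",
  "is_fragment", "keywords", "go_mf", "go_bp", "go_cc", "families",
  "ptm_annotations", "tissue_specificity", "disease", "pharmaceutical"
)

set_cols <- c("keywords", "go_mf", "go_bp", "go_cc", "families",
              "ptm_annotations")

#' Column map for UniProtKB tab-delimited exports
#'
#' Maps the header names of a UniProtKB "download as TSV" export onto the
#' canonical column names used throughout the package. Pass the result (after
#' editing if your export used different custom columns) as `column_map` to
#' [read_protein_table()].
#'
#' @return Named character vector: canonical name -> export header.
#' @export
uniprot_column_map <- function() {
  c(accession = "Entry",
    gene_name = "Gene Names (primary)",
    organism = "Organism",
    sequence = "Sequence",
    length = "Length",
    molecular_weight = "Mass",
    reviewed = "Reviewed",
    protein_existence_evidence = "Protein existence",
    is_fragment = "Fragment",
    keywords = "Keywords",
    go_mf = "Gene Ontology (molecular function)",
    go_bp = "Gene Ontology (biological process)",
    go_cc = "Gene Ontology (cellular component)",
    families = "Protein families",
    ptm_annotations = "Post-translational modification",
    tissue_specificity = "Tissue specificity",
    disease = "Involvement in disease",
    pharmaceutical = "Pharmaceutical use")
}

split_set_cell <- function(x, delim = ";") {
  lapply(x, function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
    parts <- trimws(strsplit(cell, delim, fixed = TRUE)[[1]])
    parts[nzchar(parts)]
  })
}

collapse_set_cell <- function(x, delim = "; ") {
  vapply(x, function(s) paste(s, collapse = delim), character(1))
}

parse_flag <- function(x, true_words = c("true", "yes", "reviewed", "1",
                                         "fragment", "evidence at protein level",
                                         "experimental")) {
  lx <- tolower(trimws(as.character(x)))
  out <- lx %in% true_words
  out[is.na(x) | !nzchar(lx)] <- FALSE
  out
}

#' Read a protein annotation table
#'
#' Reads a delimited protein table (the package's canonical dialect or any
#' export translated via `column_map`) into one row per protein. Set-valued
#' cells (keywords, GO terms, families, PTM annotations) are split on
#' `set_delim` into list-columns. Sequences may instead be supplied as a
#' FASTA file keyed by accession (`format = "fasta+tabular"`).
#'
#' Rows whose length cell is present but not parseable as a number are
#' skipped with a warning reporting the row indices; proteins with an empty
#' gene-name cell are retained with `gene_name = NA`.
#'
#' @param path Path to a tab- or comma-delimited table (delimiter sniffed
#'   from the extension: `.csv` means comma, anything else tab).
#' @param format `"tabular"` (sequence column in the table) or
#'   `"fasta+tabular"` (sequences read from `fasta_path`).
#' @param column_map Named character vector mapping canonical column names to
#'   the file's header names; defaults to the canonical names themselves.
#' @param fasta_path FASTA file with record ids equal to accessions; only
#'   used for `format = "fasta+tabular"`.
#' @param set_delim Delimiter of set-valued cells (default `";"`).
#' @return A tibble of protein records with list-columns for set-valued
#'   fields.
#' @export
read_protein_table <- function(path,
                               format = c("tabular", "fasta+tabular"),
                               column_map = NULL,
                               fasta_path = NULL,
                               set_delim = ";") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)

  map <- column_map %||% setNames(protein_canonical_cols, protein_canonical_cols)
  if (!"accession" %in% names(map)) {
    stop("column_map must provide an `accession` entry", call. = FALSE)
  }
  if (!map[["accession"]] %in% names(raw)) {
    stop("missing mandatory column: ", map[["accession"]], call. = FALSE)
  }

  get_col <- function(canon) {
    src <- map[canon]
    if (!is.na(src) && !is.null(src) && src %in% names(raw)) raw[[src]] else rep(NA_character_, nrow(raw))
  }

  out <- tibble(
    accession = trimws(get_col("accession")),
    gene_name = trimws(get_col("gene_name")),
    organism = get_col("organism"),
    sequence = get_col("sequence"),
    length_raw = get_col("length"),
    molecular_weight = suppressWarnings(as.numeric(gsub(",", "", get_col("molecular_weight")))),
    reviewed = parse_flag(get_col("reviewed")),
    protein_existence_evidence = parse_flag(get_col("protein_existence_evidence")),
    is_fragment = parse_flag(get_col("is_fragment")),
    tissue_specificity = get_col("tissue_specificity"),
    disease = get_col("disease"),
    pharmaceutical = get_col("pharmaceutical")
  )
  for (sc in set_cols) out[[sc]] <- split_set_cell(get_col(sc), set_delim)
  out$gene_name[!nzchar(out$gene_name %|NA|% "")] <- NA_character_

  if (format == "fasta+tabular") {
    if (is.null(fasta_path)) stop("fasta_path required for fasta+tabular", call. = FALSE)
    seqs <- read_fasta_named(fasta_path)
    out$sequence <- unname(seqs[out$accession])
  }

  # Malformed numeric length cells (non-empty, non-numeric) invalidate the row.
  len <- suppressWarnings(as.numeric(out$length_raw))
  malformed <- !is.na(out$length_raw) & nzchar(trimws(out$length_raw)) & is.na(len)
  if (any(malformed)) {
    warning(sprintf("skipped %d unparsable row(s) at index: %s",
                    sum(malformed), paste(which(malformed), collapse = ", ")),
            call. = FALSE)
    out <- out[!malformed, , drop = FALSE]
    len <- len[!malformed]
  }
  out$length <- as.integer(len)
  has_seq <- !is.na(out$sequence) & nzchar(out$sequence)
  out$length[has_seq] <- nchar(out$sequence[has_seq])
  out$length_raw <- NULL

  out[, c("accession", "gene_name", "organism", "sequence", "length",
          "molecular_weight", "reviewed", "protein_existence_evidence",
          "is_fragment", set_cols, "tissue_specificity", "disease",
          "pharmaceutical")]
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

read_fasta_named <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    grp <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = "")
    setNames(unname(seqs), ids)
  }
}

#' Write a protein table in the canonical dialect
#'
#' @param proteins Protein tibble as returned by [read_protein_table()].
#' @param path Output TSV path.
#' @param fasta_path Optional FASTA output for the sequences.
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(proteins, path, fasta_path = NULL) {
  out <- proteins
  for (sc in intersect(set_cols, names(out))) {
    out[[sc]] <- collapse_set_cell(out[[sc]])
  }
  readr::write_tsv(out, path, na = "", progress = FALSE)
  if (!is.null(fasta_path)) {
    keep <- !is.na(proteins$sequence)
    writeLines(paste0(">", proteins$accession[keep], "\n", proteins$sequence[keep]),
               fasta_path)
  }
  invisible(path)
}

#' Default experiment-type vocabulary
#'
#' Maps experiment descriptors of miRNA-target evidence rows to `"strong"`
#' (targeted, low-throughput validation) or `"weak"` (high-throughput
#' screens). Shipped as an editable table in
#' `system.file("extdata/support_vocabulary.tsv", package = "protomir")`;
#' matching is case-insensitive on the trimmed descriptor.
#'
#' @return Named character vector: experiment descriptor -> strength.
#' @export
default_support_vocabulary <- function() {
  path <- system.file("extdata", "support_vocabulary.tsv", package = "protomir")
  tab <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  setNames(tab$strength, trim_fold(tab$experiment))
}

#' Read a miRNA-target evidence table
#'
#' Reads an evidence export (CSV or TSV) with one row per reported
#' miRNA-target interaction. The experiments cell may contain several
#' descriptors separated by `"//"`; each becomes its own evidence record.
#' Every descriptor is mapped to strong/weak through `vocabulary`; an
#' unmapped descriptor is an error listing the offending values. The
#' `experiment_key` identifying a unique experiment is the upper-cased
#' descriptor joined to the reference id with `"::"`.
#'
#' @param path CSV/TSV file.
#' @param vocabulary Named character vector descriptor -> `"strong"|"weak"`;
#'   default [default_support_vocabulary()].
#' @param column_map Named character vector for the five canonical columns
#'   `mirna_id`, `target_gene`, `organism`, `experiments`, `reference_id`.
#' @return Tibble of evidence records (`mirna_id`, `target_gene`, `organism`,
#'   `evidence_strength`, `experiment`, `reference_id`, `experiment_key`).
#'   Duplicate rows are retained; de-duplication is the labeling stage's job.
#' @export
read_evidence_table <- function(path, vocabulary = default_support_vocabulary(),
                                column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  canon <- c("mirna_id", "target_gene", "organism", "experiments", "reference_id")
  map <- column_map %||% setNames(canon, canon)
  missing <- setdiff(canon, names(map)[map %in% names(raw)])
  missing <- setdiff(missing, "organism")  # organism optional in some exports
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(map[missing], collapse = ", "),
         call. = FALSE)
  }
  org <- if (map["organism"] %in% names(raw)) raw[[map["organism"]]] else NA_character_

  base <- tibble(
    mirna_id = raw[[map["mirna_id"]]],
    target_gene = trimws(raw[[map["target_gene"]]]),
    organism = org,
    experiments = raw[[map["experiments"]]],
    reference_id = raw[[map["reference_id"]]]
  )
  long <- tidyr::separate_rows(base, "experiments", sep = "//")
  long$experiment <- trimws(long$experiments)
  long$experiments <- NULL
  key <- trim_fold(long$experiment)
  strength <- unname(vocabulary[key])
  if (anyNA(strength)) {
    bad <- sort(unique(long$experiment[is.na(strength)]))
    stop("unknown experiment descriptor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  long$evidence_strength <- strength
  long$experiment_key <- paste0(key, "::", long$reference_id)
  long[, c("mirna_id", "target_gene", "organism", "evidence_strength",
           "experiment", "reference_id", "experiment_key")]
}

#' Filter a proteome by curation policy
#'
#' `"reviewed"` keeps proteins that are reviewed, have experimental evidence
#' of existence, are not fragments, and carry a primary gene name - the
#' curated analysis set. `"all_full_length"` only drops fragments and
#' proteins without a gene name, for poorly annotated organisms where the
#' full-length proteome is used.
#'
#' @param proteins Protein tibble.
#' @param policy `"reviewed"` or `"all_full_length"`.
#' @return Filtered tibble (input is not modified).
#' @export
filter_proteome <- function(proteins, policy = c("reviewed", "all_full_length")) {
  policy <- match.arg(policy)
  keep <- !proteins$is_fragment & !is.na(proteins$gene_name)
  if (policy == "reviewed") {
    keep <- keep & proteins$reviewed & proteins$protein_existence_evidence
  }
  proteins[keep, , drop = FALSE]
}

#' Strict gene-name mapping across resources
#'
#' Maps external gene names onto protein accessions by exact, case-folded,
#' whitespace-trimmed match on the primary gene name. Names carried by more
#' than one accession, and (after matching) accessions claimed by more than
#' one external name, are excluded and reported, so the returned mapping is
#' injective.
#'
#' @param proteins Protein tibble with `accession` and `gene_name`.
#' @param external_names Character vector of gene names from another
#'   resource.
#' @return Tibble with columns `gene_name` (folded), `accession`, `status`
#'   (`"mapped"`, `"ambiguous_name"`, or `"unmapped"`). The injective mapping
#'   is the `status == "mapped"` subset.
#' @export
map_gene_names <- function(proteins, external_names) {
  prot <- tibble(accession = proteins$accession,
                 gene_name = trim_fold(proteins$gene_name)) |>
    filter(!is.na(.data$gene_name), nzchar(.data$gene_name))
  ext <- unique(trim_fold(external_names))
  ext <- ext[!is.na(ext) & nzchar(ext)]

  name_counts <- prot |> count(.data$gene_name, name = "n_acc")
  cand <- prot |>
    inner_join(name_counts, by = "gene_name") |>
    filter(.data$gene_name %in% ext)
  ambiguous <- cand |> filter(.data$n_acc > 1)
  unique_map <- cand |> filter(.data$n_acc == 1)
  # An accession matched by several external names cannot happen after
  # folding (names are unique post-fold), but guard for duplicated
  # accessions in the input table.
  dup_acc <- unique_map$accession[duplicated(unique_map$accession)]
  amb2 <- unique_map |> filter(.data$accession %in% dup_acc)
  unique_map <- unique_map |> filter(!.data$accession %in% dup_acc)

  bind_rows(
    unique_map |> transmute(.data$gene_name, .data$accession, status = "mapped"),
    bind_rows(ambiguous, amb2) |>
      transmute(.data$gene_name, .data$accession, status = "ambiguous_name"),
    tibble(gene_name = setdiff(ext, cand$gene_name),
           accession = NA_character_, status = "unmapped")
  ) |> arrange(.data$status, .data$gene_name)
}
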