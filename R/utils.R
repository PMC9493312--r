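# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Binary entropy in bits, elementwise, with 0*log(0) := 0.
binary_entropy <- function(p) {
  h <- numeric(length(p))
  ok <- !is.na(p) & p > 0 & p < 1
  h[ok] <- -p[ok] * log2(p[ok]) - (1 - p[ok]) * log2(1 - p[ok])
  h[is.na(p)] <- NA_real_
  h
}

# Coerce a labels argument (tibble with gene_name/label, or named/plain
# vector) to a 0/1 integer vector aligned with `genes`.
align_labels <- function(labels, genes) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("gene_name", "label") %in% names(labels)))
    v <- labels$label[match(genes, labels$gene_name)]
  } else if (!is.null(names(labels))) {
    v <- labels[genes]
  } else {
    if (length(labels) != length(genes)) {
      stop("unnamed label vector must match the gene universe length",
           call. = FALSE)
    }
    v <- labels
  }
  if (anyNA(v)) stop("labels missing for some genes", call. = FALSE)
  v <- as.integer(v)
  if (!all(v %in% c(0L, 1L))) {
    stop("labels must be binary 0/1 at this stage", call. = FALSE)
  }
  unname(v)
}

# Stable sub-seed derivation: keeps everything below 2^31 for R's RNG.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  invisible(x)
}

trim_fold <- function(x) toupper(trimws(x))
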