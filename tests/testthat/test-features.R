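test_that("sequence features match direct counting on tiny proteins", {
  prot <- mini_proteome(2)
  prot$sequence <- c("MKK", "M")
  prot$length <- nchar(prot$sequence)
  prot$molecular_weight <- NA_real_
  f <- featurize_sequences(prot, k_range = c(1, 2))
  g1 <- f[f$gene_name == "G001", ]
  expect_equal(g1$value[g1$feature_id == "length"], 3)
  expect_equal(g1$value[g1$feature_id == "aa_frac:K"], 2 / 3)
  expect_equal(g1$value[g1$feature_id == "aa_frac:M"], 1 / 3)
  kmers1 <- g1$feature_id[g1$kind == "binary"]
  expect_setequal(kmers1, paste0("kmer:", c("M", "K", "MK", "KK")))
  g2 <- f[f$gene_name == "G002", ]
  expect_equal(g2$value[g2$feature_id == "aa_frac:M"], 1)
  expect_setequal(g2$feature_id[g2$kind == "binary"], "kmer:M")  # no 2-mers
  expect_error(featurize_sequences(dplyr::mutate(prot, sequence = "")), "empty sequence")
})

test_that("k-mer features equal brute-force enumeration on a random sequence", {
  set.seed(7)
  seq <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 100, TRUE),
               collapse = "")
  prot <- mini_proteome(1)
  prot$sequence <- seq
  f <- featurize_sequences(prot, k_range = c(2, 2))
  got <- sub("^kmer:", "", f$feature_id[f$kind == "binary"])
  brute <- unique(substring(seq, 1:99, 2:100))
  expect_setequal(got, brute)
  expect_lte(length(got), 400)
  # every emitted k-mer is verifiable by substring search
  expect_true(all(vapply(got, grepl, logical(1), x = seq, fixed = TRUE)))
})

test_that("composition fractions plus the ambiguity fraction sum to one", {
  set.seed(8)
  alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "B", "Z", "U")
  for (i in 1:5) {
    prot <- mini_proteome(1)
    prot$sequence <- paste(sample(alphabet, 80, TRUE), collapse = "")
    f <- featurize_sequences(prot, k_range = NULL)
    fr <- f$value[startsWith(f$feature_id, "aa_frac:")]
    amb <- 1 - sum(fr)
    n_amb <- sum(strsplit(prot$sequence, "")[[1]] %in% c("X", "B", "Z", "U"))
    expect_equal(sum(fr) + n_amb / 80, 1, tolerance = 1e-12)
    expect_gte(amb, -1e-12)
  }
})

test_that("annotation features cover keywords, pairs, flags and tissue text", {
  prot <- mini_proteome(2)
  prot$keywords <- list(c("Membrane", "Receptor"), character(0))
  prot$ptm_annotations <- list(character(0), "Modified residue")
  prot$tissue_specificity <- c("Expressed in brain and heart", NA)
  f <- featurize_annotations(prot, ngram_max = 2)
  g1 <- f$feature_id[f$gene_name == "G001"]
  expect_true(all(c("kw:Membrane", "kw:Receptor",
                    "kwpair:Membrane+Receptor") %in% g1))
  expect_true(all(c("tissue:brain", "tissue:heart") %in% g1))
  expect_false("tissue:testis" %in% g1)
  expect_false("nonEmpty(ptm)" %in% g1)
  expect_true("nonEmpty(ptm)" %in% f$feature_id[f$gene_name == "G002"])
  # counts come out numeric
  expect_equal(f$value[f$gene_name == "G001" & f$feature_id == "n_keywords"], 2)
  # pair features are marked as composite for the simplicity tie-break
  expect_true(all(f$complexity[f$generator_tag == "keyword_pair"] == 2L))
})

test_that("genomic features include UTR presence and exact n-gram sets", {
  gen <- tibble::tibble(
    gene_name = c("A", "B"),
    transcript_length = c(541L, 900L),
    cds_length = c(300L, 600L),
    utr5_length = c(41L, 100L),
    utr3_length = c(0L, 200L),
    n_splice_variants = c(1L, 3L),
    chromosome = c("chr1", "chr2"),
    start_pos = c(100L, 5000L), end_pos = c(10000L, 90000L),
    utr3_sequence = c("", "AUGAUG"))
  expect_warning(f <- featurize_genomic(gen, with_utr3_ngrams = TRUE,
                                        ngram_ranges = list(c(2, 3))),
                 "absent")
  expect_false("has_utr3" %in% f$feature_id[f$gene_name == "A"])
  expect_true("has_utr3" %in% f$feature_id[f$gene_name == "B"])
  expect_equal(f$value[f$gene_name == "A" & f$feature_id == "g:transcript_length"], 541)
  grams <- sub("^utr3gram:", "",
               grep("^utr3gram:", f$feature_id[f$gene_name == "B"], value = TRUE))
  expect_setequal(grams, c("AU", "UG", "GA", "AUG", "UGA", "GAU"))
})

test_that("assembly prunes low-support columns and flags missing numerics", {
  long <- dplyr::bind_rows(
    tibble::tibble(gene_name = "g1", feature_id = "rare", value = 1,
                   source = "annotation", kind = "binary",
                   generator_tag = "t", complexity = 1L),
    tibble::tibble(gene_name = c("g1", "g3"), feature_id = "ok", value = 1,
                   source = "annotation", kind = "binary",
                   generator_tag = "t", complexity = 1L),
    tibble::tibble(gene_name = c("g1", "g3"), feature_id = "num", value = c(5, 9),
                   source = "annotation", kind = "numeric",
                   generator_tag = "t", complexity = 1L))
  fm <- assemble_features(long, genes = c("g1", "g2", "g3"), min_support_count = 2)
  expect_false("rare" %in% colnames(fm$values))   # support 1 < 2: pruned
  expect_equal(unname(fm$values[, "ok"]), c(1, 0, 1))
  expect_equal(unname(fm$values[, "is_missing(num)"]), c(0, 1, 0))
  expect_true(is.na(fm$values["g2", "num"]))
  # binary columns contain only 0/1 and none is constant
  bin <- fm$values[, fm$descriptors$kind == "binary", drop = FALSE]
  expect_true(all(bin %in% c(0, 1)))
  expect_true(all(apply(fm$values, 2, function(c) length(unique(na.omit(c)))) > 1))
})

test_that("conflicting feature kinds are rejected", {
  long <- dplyr::bind_rows(
    tibble::tibble(gene_name = c("g1", "g2"), feature_id = "f", value = 1,
                   source = "a", kind = "binary", generator_tag = "t",
                   complexity = 1L),
    tibble::tibble(gene_name = "g3", feature_id = "f", value = 7,
                   source = "a", kind = "numeric", generator_tag = "t",
                   complexity = 1L))
  expect_error(assemble_features(long, genes = paste0("g", 1:3)), "conflicting kind")
})

test_that("assembled column count equals an independent recount", {
  cfg <- generator_config(n_genes = 500, n_noise_keywords = 300, seed = 21)
  sim <- generate_proteome(cfg)
  long <- featurize_annotations(sim$proteome, ngram_max = 1, fields = "keywords")
  fm <- assemble_features(long, genes = sim$proteome$gene_name,
                          min_support_count = 5)
  counts <- table(long$feature_id)
  expected <- sum(counts >= 5 & counts < 500)
  expect_equal(ncol(fm$values), expected)
})

test_that("feature generation is deterministic on identical records", {
  prot <- mini_proteome(4)
  prot$keywords <- list("A", c("A", "B"), "B", character(0))
  expect_identical(featurize_annotations(prot), featurize_annotations(prot))
  expect_identical(featurize_sequences(prot, c(1, 2)),
                   featurize_sequences(prot, c(1, 2)))
})
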