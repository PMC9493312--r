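# Entropy-based feature ranking: relative information gain (RIG), lift,
# support, chi-squared screening, label-aware binarization of numeric
# features, redundancy removal and top-K selection.

#' Shannon entropy of a binary label vector (bits)
#'
#' @param labels 0/1 vector.
#' @return Entropy in bits, with the convention 0*log2(0) = 0.
#' @export
entropy_bits <- function(labels) {
  if (length(labels) == 0L) stop("empty label vector", call. = FALSE)
  binary_entropy(mean(labels))
}

#' Relative information gain of a binary feature
#'
#' The information gain IG(T, a) = H(T) - H(T|a) of the label T under the
#' partition induced by binary feature a, normalized by the label entropy
#' H(T) so that scores lie in \[0, 1\] and are comparable across datasets
#' with different class priors. Undefined (error) when the labels are pure.
#'
#' @param feature 0/1 feature vector.
#' @param labels 0/1 label vector of the same length.
#' @return RIG in \[0, 1\].
#' @export
rig <- function(feature, labels) {
  if (length(feature) != length(labels)) stop("length mismatch", call. = FALSE)
  n <- length(labels)
  n1 <- sum(labels)
  h_t <- binary_entropy(n1 / n)
  if (h_t == 0) stop("labels are pure; RIG normalization undefined", call. = FALSE)
  nf <- sum(feature)
  n1f <- sum(labels[feature == 1])
  h_cond <- 0
  if (nf > 0) h_cond <- h_cond + (nf / n) * binary_entropy(n1f / nf)
  if (nf < n) h_cond <- h_cond + ((n - nf) / n) * binary_entropy((n1 - n1f) / (n - nf))
  max(0, (h_t - h_cond) / h_t)
}

#' Support and class lifts of a binary feature
#'
#' Support is the fraction of genes on which the feature is 1. The lift for
#' class c is P(label = c | feature = 1) / P(label = c): how much more
#' likely the class is, given the feature. Lifts are `NA` when the feature
#' covers no gene.
#'
#' @inheritParams rig
#' @return One-row tibble `support`, `lift_pos`, `lift_neg`.
#' @export
lift_and_support <- function(feature, labels) {
  if (length(feature) != length(labels)) stop("length mismatch", call. = FALSE)
  n <- length(labels)
  nf <- sum(feature)
  p1 <- mean(labels)
  if (nf == 0) return(tibble(support = 0, lift_pos = NA_real_, lift_neg = NA_real_))
  p1f <- mean(labels[feature == 1])
  tibble(support = nf / n,
         lift_pos = if (p1 > 0) p1f / p1 else NA_real_,
         lift_neg = if (p1 < 1) (1 - p1f) / (1 - p1) else NA_real_)
}

#' Pearson chi-squared screen of a binary feature against the labels
#'
#' 2x2 Pearson chi-squared test with 1 degree of freedom, no continuity
#' correction, returning the uncorrected p-value. A degenerate table (a zero
#' margin) yields p = 1 with a warning.
#'
#' @inheritParams rig
#' @return p-value in (0, 1\].
#' @export
chi2_screen <- function(feature, labels) {
  if (length(feature) != length(labels)) stop("length mismatch", call. = FALSE)
  n <- length(labels)
  a <- sum(feature == 1 & labels == 1)
  b <- sum(feature == 1 & labels == 0)
  c_ <- sum(feature == 0 & labels == 1)
  d <- n - a - b - c_
  stat <- chi2_stat_cells(a, b, c_, d)
  if (is.na(stat)) {
    warning("degenerate 2x2 table (zero margin); p = 1", call. = FALSE)
    return(1)
  }
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Vectorized Pearson statistic from 2x2 cell counts; NA on zero margins.
chi2_stat_cells <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  stat <- n * (a * d - b * c_)^2 / (r1 * r2 * c1 * c2)
  stat[r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0] <- NA_real_
  stat
}

#' Label-aware binarization threshold for a numeric feature
#'
#' Evaluates every split at the midpoints between consecutive distinct
#' sorted values and returns the one maximizing the RIG of the induced
#' binary feature; ties break toward the smaller threshold. The
#' feature-positive side (`direction`) is the minority side of the winning
#' split (`"below"` on a tie), mirroring how sparse indicator features are
#' reported.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @param labels 0/1 labels aligned with `x`.
#' @return List with `threshold`, `direction` (`"below"`/`"above"`),
#'   `binarized` (0/1 integer vector; `NA` inputs map to 0), and `rig`.
#' @export
best_threshold <- function(x, labels) {
  ok <- is.finite(x)
  v <- sort(unique(x[ok]))
  if (length(v) < 2) stop("need >= 2 distinct finite values", call. = FALSE)
  xo <- x[ok]; yo <- labels[ok]
  n <- length(xo); n1 <- sum(yo)
  h_t <- binary_entropy(n1 / n)
  if (h_t == 0) stop("labels are pure; RIG normalization undefined", call. = FALSE)

  ord <- order(xo)
  xs <- xo[ord]; ys <- yo[ord]
  # Counts below each candidate cut (between distinct values v[i], v[i+1]).
  last_idx <- cumsum(tabulate(match(xs, v), nbins = length(v)))
  n_below <- last_idx[-length(v)]
  pos_below <- cumsum(ys)[last_idx][-length(v)]
  cuts <- (v[-length(v)] + v[-1]) / 2

  h_b <- binary_entropy(pos_below / n_below)
  n_above <- n - n_below
  h_a <- binary_entropy((n1 - pos_below) / n_above)
  rigs <- (h_t - (n_below / n) * h_b - (n_above / n) * h_a) / h_t
  best <- which.max(rigs)  # first maximum = smallest threshold

  thr <- cuts[best]
  direction <- if (n_below[best] <= n - n_below[best]) "below" else "above"
  bin <- if (direction == "below") as.integer(!is.na(x) & x < thr)
         else as.integer(!is.na(x) & x > thr)
  list(threshold = thr, direction = direction, binarized = bin,
       rig = max(0, rigs[best]))
}

# Binarized 0/1 columns for a set of scored features, as a genes x features
# integer matrix. Numeric features use their stored threshold/direction.
binarized_columns <- function(fm, scores) {
  m <- fm$values[, scores$feature_id, drop = FALSE]
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    if (scores$kind[j] == "binary") {
      out[, j] <- as.integer(m[, j] == 1)
    } else if (!is.na(scores$threshold[j])) {
      out[, j] <- if (scores$direction[j] == "below") {
        as.integer(!is.na(m[, j]) & m[, j] < scores$threshold[j])
      } else {
        as.integer(!is.na(m[, j]) & m[, j] > scores$threshold[j])
      }
    }
  }
  out
}

#' Score every feature of a matrix against binary labels
#'
#' Computes, per feature: RIG (numeric features are first binarized at their
#' optimal threshold via [best_threshold()]), unnormalized information gain,
#' support, class lifts, the uncorrected Pearson chi-squared p-value, and
#' the dominant class (the class whose lift exceeds 1 on the
#' feature-positive side). The result is the machine-readable twin of a
#' ranked feature report.
#'
#' @param fm A `feature_matrix`.
#' @param labels Binary labels (tibble `gene_name`/`label`, named vector, or
#'   vector aligned with `fm$genes`).
#' @return Tibble of per-feature scores, sorted by decreasing RIG.
#' @export
score_features <- function(fm, labels) {
  y <- align_labels(labels, fm$genes)
  n <- length(y); n1 <- sum(y)
  h_t <- binary_entropy(n1 / n)
  if (h_t == 0) stop("labels are pure; RIG normalization undefined", call. = FALSE)

  desc <- fm$descriptors
  thr <- rep(NA_real_, nrow(desc))
  dir <- rep(NA_character_, nrow(desc))
  bin <- matrix(0L, n, nrow(desc))
  num_idx <- which(desc$kind == "numeric")
  bin_idx <- which(desc$kind == "binary")
  bin[, bin_idx] <- (fm$values[, bin_idx, drop = FALSE] == 1) * 1L
  for (j in num_idx) {
    x <- fm$values[, j]
    v <- unique(x[is.finite(x)])
    if (length(v) < 2) next  # constant after NA removal; stays all-zero
    bt <- best_threshold(x, y)
    thr[j] <- bt$threshold; dir[j] <- bt$direction; bin[, j] <- bt$binarized
  }

  nf <- colSums(bin)
  n1f <- as.vector(crossprod(bin, y))
  n0f <- nf - n1f
  # Conditional entropy over the induced partition.
  p_in <- ifelse(nf > 0, n1f / nf, 0)
  p_out <- ifelse(nf < n, (n1 - n1f) / (n - nf), 0)
  h_cond <- (nf / n) * binary_entropy(p_in) + ((n - nf) / n) * binary_entropy(p_out)
  ig <- pmax(0, h_t - h_cond)

  a <- n1f; b <- n0f; c_ <- n1 - n1f; d <- n - nf - c_
  stat <- chi2_stat_cells(a, b, c_, d)
  p <- ifelse(is.na(stat), 1, stats::pchisq(stat, df = 1, lower.tail = FALSE))

  p1 <- n1 / n
  lift_pos <- ifelse(nf > 0 & p1 > 0, (n1f / nf) / p1, NA_real_)
  lift_neg <- ifelse(nf > 0 & p1 < 1, (n0f / nf) / (1 - p1), NA_real_)
  dominant <- dplyr::case_when(
    is.na(lift_pos) | is.na(lift_neg) ~ NA_integer_,
    lift_pos > 1 ~ 1L,
    lift_neg > 1 ~ 0L,
    TRUE ~ NA_integer_
  )

  tibble(
    feature_id = desc$feature_id,
    source = desc$source,
    kind = desc$kind,
    complexity = desc$complexity,
    rig = ig / h_t,
    ig = ig,
    support = nf / n,
    lift_pos = lift_pos,
    lift_neg = lift_neg,
    chi2_p = p,
    dominant_class = dominant,
    threshold = thr,
    direction = dir
  ) |> arrange(desc(.data$rig), .data$feature_id)
}

#' Screen, de-duplicate and select the top-K features
#'
#' Three passes over scored features: (1) drop features whose uncorrected
#' chi-squared p exceeds `p_max`; (2) group features whose binarized columns
#' are identical or exact complements - such features carry the same
#' information - keeping the lexicographically smallest feature id of each
#' group and recording the rest as redundant with their retained proxy;
#' (3) greedy selection in descending RIG order (RIG ties within 1e-3 broken
#' toward lower complexity, then feature id), skipping any candidate whose
#' binarized column has absolute phi correlation above `redundancy_cap`
#' with an already selected column, stopping at `k_max`.
#'
#' @param scores Tibble from [score_features()].
#' @param fm The `feature_matrix` the scores were computed on.
#' @param k_max Maximum number of selected features (default 300).
#' @param p_max Chi-squared screening threshold (default 1e-4).
#' @param redundancy_cap Absolute phi correlation above which a candidate is
#'   considered redundant with a selected feature (default 0.95).
#' @return A `feature_selection` object: list with `selected` (scores of the
#'   selected features, in selection order), `redundant` (feature_id,
#'   proxy), `screened_out` count, and the parameters.
#' @export
dedupe_and_select <- function(scores, fm, k_max = 300L, p_max = 1e-4,
                              redundancy_cap = 0.95) {
  if (k_max <= 0) stop("k_max must be positive", call. = FALSE)
  surv <- scores[!is.na(scores$chi2_p) & scores$chi2_p <= p_max, , drop = FALSE]
  screened_out <- nrow(scores) - nrow(surv)
  if (nrow(surv) == 0L) {
    return(structure(list(selected = surv, redundant = tibble(feature_id = character(0),
                                                              proxy = character(0)),
                          screened_out = screened_out, k_max = k_max,
                          p_max = p_max, redundancy_cap = redundancy_cap),
                     class = "feature_selection"))
  }

  bin <- binarized_columns(fm, surv)
  # Canonical form identifies complements with each other: flip any column
  # whose first entry is 1, then hash.
  canon <- bin
  flip <- canon[1, ] == 1L
  canon[, flip] <- 1L - canon[, flip, drop = FALSE]
  key <- apply(canon, 2, paste, collapse = "")
  reps <- tapply(surv$feature_id, key, function(ids) min(ids))
  proxy <- as.character(reps[key])
  redundant <- tibble(feature_id = surv$feature_id, proxy = proxy) |>
    filter(.data$feature_id != .data$proxy)
  keep <- surv$feature_id == proxy
  surv <- surv[keep, , drop = FALSE]
  bin <- bin[, keep, drop = FALSE]

  # Banded RIG ordering implements the simpler-feature preference.
  ord <- order(-round(surv$rig / 1e-3), surv$complexity, surv$feature_id)
  surv <- surv[ord, , drop = FALSE]
  bin <- bin[, ord, drop = FALSE]

  sel_idx <- integer(0)
  for (j in seq_len(nrow(surv))) {
    if (length(sel_idx) >= k_max) break
    if (length(sel_idx)) {
      cors <- suppressWarnings(
        abs(stats::cor(bin[, j], bin[, sel_idx, drop = FALSE])))
      cors[is.na(cors)] <- 0
      if (any(cors > redundancy_cap)) next
    }
    sel_idx <- c(sel_idx, j)
  }

  structure(list(selected = surv[sel_idx, , drop = FALSE],
                 redundant = redundant,
                 screened_out = screened_out,
                 k_max = k_max, p_max = p_max, redundancy_cap = redundancy_cap),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %d selected (cap %d), %d redundant, %d screened out\n",
              nrow(x$selected), x$k_max, nrow(x$redundant), x$screened_out))
  invisible(x)
}

#' Write the ranked feature report
#'
#' @param selection A `feature_selection` (or a scores tibble).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_report <- function(selection, path) {
  tab <- if (inherits(selection, "feature_selection")) selection$selected else selection
  readr::write_tsv(
    tab[, c("feature_id", "rig", "support", "lift_pos", "lift_neg", "chi2_p",
            "dominant_class", "threshold")],
    path, na = "", progress = FALSE)
  invisible(path)
}
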