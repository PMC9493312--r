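# Independent oracles: deliberately naive implementations used to freeze
# expected values, kept free of any package internals.

oracle_entropy <- function(y) {
  p <- mean(y)
  terms <- c(p, 1 - p)
  terms <- terms[terms > 0]
  -sum(terms * log2(terms))
}

oracle_rig <- function(f, y) {
  h <- oracle_entropy(y)
  hc <- 0
  for (v in c(0, 1)) {
    idx <- f == v
    if (any(idx)) hc <- hc + mean(idx) * oracle_entropy(y[idx])
  }
  (h - hc) / h
}

# Pairwise rocAUC with ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Exact binomial tails by direct summation of dbinom terms.
oracle_binom_greater <- function(x, n, p) sum(stats::dbinom(x:n, n, p))
oracle_binom_two_sided <- function(x, n, p) {
  lower <- sum(stats::dbinom(0:x, n, p))
  upper <- sum(stats::dbinom(x:n, n, p))
  min(1, 2 * min(lower, upper))
}

# Exhaustive threshold search over all midpoints between distinct values.
oracle_best_threshold <- function(x, y) {
  v <- sort(unique(x))
  cuts <- (v[-length(v)] + v[-1]) / 2
  rigs <- vapply(cuts, function(t) oracle_rig(as.integer(x < t), y), numeric(1))
  list(threshold = cuts[which.max(rigs)], rig = max(rigs))
}
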