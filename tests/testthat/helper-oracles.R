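# Independent oracles used to verify the hand-implemented statistics.

# Brute-force AUC: explicit all-pairs concordance count, ties 1/2.
brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Leave-one-out jackknife variance of the AUC difference, built on the
# brute-force AUC (never on the package's ROC path).
jackknife_var_diff <- function(a, b, labels) {
  N <- length(labels)
  d <- vapply(seq_len(N), function(i) {
    brute_auc(a[-i], labels[-i]) - brute_auc(b[-i], labels[-i])
  }, numeric(1))
  (N - 1) / N * sum((d - mean(d))^2)
}

# Label-permutation p-value for the AUC difference, brute-force AUCs.
permutation_p_diff <- function(a, b, labels, B, seed) {
  set.seed(seed)
  obs <- abs(brute_auc(a, labels) - brute_auc(b, labels))
  hits <- 0L
  for (i in seq_len(B)) {
    l2 <- sample(labels)
    if (abs(brute_auc(a, l2) - brute_auc(b, l2)) >= obs - 1e-12) {
      hits <- hits + 1L
    }
  }
  hits / B
}

# Fixed 12-subject paired toy set (6 diseased, 6 non-diseased).
delong_toy <- function() {
  list(
    labels = rep(c(TRUE, FALSE), each = 6),
    a = c(1.515, 2.44, 1.137, 1.049, 2.336, 1.492,
          -0.17, -1.088, -3.011, -0.593, -0.76, 0.292),
    b = c(0.621, -1.094, 0.269, -0.613, 1.711, -0.072,
          1.558, -0.237, 1.283, -0.009, -0.4, 0.022)
  )
}

# Exhaustive signed-rank two-sided p over all sign assignments (no ties).
enumerate_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  vs <- vapply(seq_len(2^n) - 1L, function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  if (v_obs > mu) {
    min(1, 2 * mean(vs >= v_obs))
  } else if (v_obs < mu) {
    min(1, 2 * mean(vs <= v_obs))
  } else 1
}
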