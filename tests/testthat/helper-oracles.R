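# Independent oracles used across the suite. These re-derive expected
# values by brute force / direct arithmetic and must stay free of the
# package's own implementation paths.

# Confusion-matrix metrics via explicit per-class loops.
oracle_metrics <- function(tp, fp, tn, fn) {
  prec_pos <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec_pos <- if (tp + fn == 0) 0 else tp / (tp + fn)
  prec_neg <- if (tn + fn == 0) 0 else tn / (tn + fn)
  rec_neg <- if (tn + fp == 0) 0 else tn / (tn + fp)
  f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  f1_pos <- f1(prec_pos, rec_pos)
  f1_neg <- f1(prec_neg, rec_neg)
  n_pos <- tp + fn
  n_neg <- tn + fp
  list(
    sensitivity = rec_pos,
    specificity = rec_neg,
    accuracy = if (tp + fp + tn + fn == 0) 0 else
      (tp + tn) / (tp + fp + tn + fn),
    precision = prec_pos,
    macro_f1 = (f1_pos + f1_neg) / 2,
    weighted_f1 = if (n_pos + n_neg == 0) 0 else
      (n_pos * f1_pos + n_neg * f1_neg) / (n_pos + n_neg),
    weighted_f1_printed = (n_pos * f1_pos + n_neg * f1_neg) / 2)
}

# AUC by exhaustive pair counting, ties counted half.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Dense evaluation of the symmetric normalization.
oracle_normalize <- function(A) {
  At <- A + diag(nrow(A))
  D <- diag(1 / sqrt(rowSums(At)))
  D %*% At %*% D
}

# Brute-force threshold scan for the mean-degree rule.
oracle_select_threshold <- function(S, target) {
  n <- nrow(S)
  off <- S[row(S) != col(S)]
  cands <- sort(unique(off), decreasing = TRUE)
  for (tau in cands) {
    deg <- sum(off >= tau) / n
    if (deg >= target) return(tau)
  }
  min(off)
}

leaky_oracle <- function(Z, slope = 0.25) ifelse(Z < 0, slope * Z, Z)

# Plain MLP forward with a GCN module's weights (graph-free limit).
oracle_mlp_forward <- function(params, X) {
  H <- X
  L <- length(params$layers)
  for (i in seq_len(L)) {
    W <- params$layers[[i]]$W
    Z <- H %*% W
    if (!is.null(params$layers[[i]]$b)) {
      Z <- Z + matrix(params$layers[[i]]$b, nrow(Z), ncol(W), byrow = TRUE)
    }
    H <- if (i < L) leaky_oracle(Z, params$slope) else Z
  }
  unname(H)
}

oracle_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  se2 <- var(x) / n1 + var(y) / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((var(x) / n1)^2 / (n1 - 1) + (var(y) / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

random_confusion <- function() {
  as.list(setNames(sample(0:30, 4, replace = TRUE),
                   c("tp", "fp", "tn", "fn")))
}

# Small aligned two-block cohort for model-level tests.
tiny_cohort <- function(n = 24, seed = 7) {
  toy <- generate_separable_toy(n, seed = seed)
  align_cohort(list(toy$expression, toy$methylation), toy$labels,
               toy$variants)
}
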