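# Independent brute-force oracles.  These deliberately use scalar loops and
# explicit set operations so they share no code path with the package.

oracle_cosine <- function(x) {
  n <- nrow(x)
  s <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- sum(x[i, ] * x[j, ])
    den <- sqrt(sum(x[i, ]^2)) * sqrt(sum(x[j, ]^2))
    s[i, j] <- if (den > 0) num / den else 0
  }
  s
}

oracle_tanimoto <- function(x) {
  n <- nrow(x)
  s <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- which(x[i, ] == 1); b <- which(x[j, ] == 1)
    u <- length(union(a, b))
    s[i, j] <- if (u > 0) length(intersect(a, b)) / u else 0
  }
  s
}

# Self-inclusive top-k neighbor prediction over rows, ties broken by label.
oracle_predict_rows <- function(s_mat, sim, k) {
  n <- nrow(s_mat)
  labs <- rownames(sim)
  p <- s_mat * 0
  for (d in seq_len(n)) {
    others <- setdiff(seq_len(n), d)
    ord <- others[order(-sim[d, others], labs[others])]
    nn <- ord[seq_len(min(k, length(ord)))]
    for (e in seq_len(ncol(s_mat))) {
      num <- 1 * s_mat[d, e]
      den <- 1
      for (j in nn) {
        num <- num + sim[d, j] * s_mat[j, e]
        den <- den + sim[d, j]
      }
      p[d, e] <- num / den
    }
  }
  p
}

oracle_objective <- function(beta, assoc, preds) {
  total <- 0
  for (k in seq_along(preds)) {
    ck <- 0
    for (i in seq_along(assoc)) {
      if (assoc[i] == 1) ck <- ck + (1 - preds[[k]][i])^2
      if (assoc[i] == 0) ck <- ck - preds[[k]][i]^2
    }
    total <- total + beta[k]^2 * ck
  }
  total
}

oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth != 1]
  wins <- 0
  for (a in pos) for (b in neg)
    wins <- wins + (a > b) + 0.5 * (a == b)
  wins / (length(pos) * length(neg))
}

oracle_best_f <- function(scores, truth) {
  cand <- sort(unique(c(scores - 1e-9, scores + 1e-9, min(scores) - 1,
                        max(scores) + 1)))
  best <- -1
  for (t in cand) {
    tp <- sum(scores >= t & truth == 1)
    fp <- sum(scores >= t & truth != 1)
    fn <- sum(scores < t & truth == 1)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    best <- max(best, f)
  }
  best
}

# Exhaustive simplex grid search for K sources at the given step.
oracle_grid_weights <- function(cc, step = 0.01, epsilon = 1e-4) {
  k <- length(cc)
  stopifnot(k == 3L)
  best <- NULL; best_val <- Inf
  for (b1 in seq(step, 1 - 2 * step, by = step))
    for (b2 in seq(step, 1 - b1 - step, by = step)) {
      b <- c(b1, b2, 1 - b1 - b2)
      v <- sum(b^2 * cc)
      if (v < best_val) { best_val <- v; best <- b }
    }
  list(weights = best, value = best_val)
}
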