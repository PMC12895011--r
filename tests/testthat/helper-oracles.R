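# Independent brute-force oracles and small fixtures used across the suite.
# Oracles enumerate definitions directly and share no code with the package.

# AUC by explicit positive-negative pair enumeration
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# concordance by O(n^2) pair enumeration: comparable when one subject has an
# event strictly before the other's time
oracle_cindex <- function(time, event, pred) {
  n <- length(time)
  credit <- 0; comparable <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (event[i] == 1 && time[i] < time[j]) {
      comparable <- comparable + 1
      if (pred[i] > pred[j]) credit <- credit + 1
      else if (pred[i] == pred[j]) credit <- credit + 0.5
    }
  }
  credit / comparable
}

# Benjamini-Hochberg by the explicit step-up recursion
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, sorted[i] * n / i)
    adj[i] <- prev
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# Youden threshold by exhaustive scan over observed scores; the criterion is
# compared as exact integer counts (J scaled by n_pos * n_neg)
oracle_youden <- function(scores, labels) {
  cand <- sort(unique(scores))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  best_j <- -Inf; best_t <- NA
  for (t in cand) {
    tp <- 0; tn <- 0
    for (i in seq_along(scores)) {
      if (labels[i] == 1 && scores[i] >= t) tp <- tp + 1
      if (labels[i] == 0 && scores[i] < t) tn <- tn + 1
    }
    j <- tp * n_neg + tn * n_pos
    if (j > best_j) { best_j <- j; best_t <- t }
  }
  best_t
}

# two-group log-rank chi-square from the O/E table over event times
oracle_logrank_chisq <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1L
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n1 <- sum(at_risk & g); n0 <- sum(at_risk & !g)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g)
    n <- n1 + n0
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n0 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# minimal valid bag with arbitrary features
tiny_bag <- function(features, slide_id = "S1", mpp = 0.5, patch_um = 128) {
  features <- rbind(features)
  n <- nrow(features)
  side <- round(patch_um / mpp)
  per_row <- ceiling(sqrt(n))
  geom <- slide_geometry(per_row * side, ceiling(n / per_row) * side,
                         mpp, patch_um)
  grid <- compute_patch_grid(geom)
  embedding_bag(features, grid[seq_len(n), ], geom, slide_id)
}

# stub risk model: mean of the first feature column of a bag
stub_mean_model <- function(bag) mean(bag$features[, 1])

# small, fast training configuration used throughout the tests
quick_cfg <- function(...) {
  abmil_config(embed_dim = 32, attention_dim = 24, lr = 1e-3,
               max_epochs = 10, patience = 3, ...)
}

# training configuration for the planted-signal recovery checks
recovery_cfg <- function() {
  abmil_config(embed_dim = 64, attention_dim = 48, lr = 1e-3,
               max_epochs = 20, patience = 4)
}
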