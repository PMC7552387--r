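# Small reusable fixtures, all generated in code.

# a small two-group cohort quick enough for repeated training
small_cohort <- function(seed = 1, n1 = 120, n2 = 60, p = 30, n_de = 4,
                         beta_counts = c(10, 5, 5, 10)) {
  generate_cohort(synthetic_config(n1 = n1, n2 = n2, n_features = p,
                                   n_de = n_de, beta_counts = beta_counts,
                                   seed = seed))
}

# linearly separable toy data in 2 features
separable_toy <- function(n = 40, seed = 7) {
  set.seed(seed)
  y <- rep(c(-1, 1), each = n / 2)
  X <- cbind(rnorm(n, mean = ifelse(y == 1, 2, -2), sd = 0.3),
             rnorm(n, mean = ifelse(y == 1, -2, 2), sd = 0.3))
  list(X = scale(X), y = y)
}

# brute-force AUROC: explicit double loop over all positive-negative pairs
auroc_bruteforce <- function(scores, labels) {
  pos <- which(labels == 1)
  neg <- which(labels != 1)
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  total / (length(pos) * length(neg))
}

# brute-force CCSA pair losses: explicit double loop over cross-domain pairs
pair_losses_bruteforce <- function(Es, Et, ys, yt, m) {
  sa <- 0; s <- 0; n_sa <- 0; n_s <- 0
  for (i in seq_len(nrow(Es))) for (j in seq_len(nrow(Et))) {
    d <- sqrt(sum((Es[i, ] - Et[j, ])^2))
    if (ys[i] == yt[j]) {
      sa <- sa + 0.5 * d^2
      n_sa <- n_sa + 1
    } else {
      s <- s + 0.5 * max(0, m - d)^2
      n_s <- n_s + 1
    }
  }
  list(L_SA = if (n_sa > 0) sa / n_sa else 0,
       L_S = if (n_s > 0) s / n_s else 0)
}

# fast training configuration for toy-scale tests
quick_train <- function(seed = 1, ...) {
  train_config(max_iter = 30L, batch_size = 16L, seed = seed, ...)
}
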