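# Shared fixtures and independent oracles, all built in code at test time.

# A small random bag of model-ready tensors (size must be divisible by 8).
random_bag <- function(K, size = 16L, seed = 1L, label = "positive",
                       subject_id = paste0("rb", seed)) {
  set.seed(seed)
  tensors <- lapply(seq_len(K), function(i) array(rnorm(size * size * 3), c(size, size, 3L)))
  new_bag(subject_id, label, tensors)
}

# Compact model configuration used by most unit tests.
tiny_model_config <- function(dropout_rate = 0.5) {
  model_config(feature_dim = 8L, attention_dim = 4L, channels = c(2L, 3L, 4L),
               dropout_rate = dropout_rate)
}

# Scalar brute-force gated-attention oracle: plain loops, no linear algebra.
naive_gated_attention <- function(H, V, U, w, gate = "sigmoid") {
  K <- nrow(H); D <- nrow(V)
  logits <- numeric(K)
  for (k in seq_len(K)) {
    s <- 0
    for (d in seq_len(D)) {
      t_d <- 0; u_d <- 0
      for (l in seq_len(ncol(H))) {
        t_d <- t_d + V[d, l] * H[k, l]
        u_d <- u_d + U[d, l] * H[k, l]
      }
      g_d <- if (gate == "sigmoid") 1 / (1 + exp(-u_d)) else 1
      s <- s + w[d] * tanh(t_d) * g_d
    }
    logits[k] <- s
  }
  e <- exp(logits - max(logits))
  e / sum(e)
}

# Loop-based aggregation oracle.
naive_aggregate <- function(H, a) {
  z <- numeric(ncol(H))
  for (k in seq_len(nrow(H))) for (l in seq_len(ncol(H))) z[l] <- z[l] + a[k] * H[k, l]
  z
}

# Exhaustive pair-counting AUC oracle (ties get half credit).
naive_auc <- function(scores, labels) {
  pos <- scores[labels == "positive"]; neg <- scores[labels == "negative"]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Trapezoidal integral of an ROC polyline.
trapezoid_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Tiny on-disk cohort shared by synthetic/preprocessing tests (25 slices per
# bag at 32 px keeps generation under a second per subject).
tiny_cohort_config <- function(seed = 5L, n_positive = 2L, n_negative = 2L) {
  cohort_config(n_positive = n_positive, n_negative = n_negative,
                slices_min = 25L, slices_max = 25L, image_size = 32L,
                lesion_contrast = 80, noise_sd = 5, lesion_radius_px = 3,
                seed = seed)
}
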