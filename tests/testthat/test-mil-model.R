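# Gated-attention MIL network: feature extraction, attention pooling,
# aggregation, classification, and the slice-level baseline.

test_that("feature extraction yields one finite L-vector per slice, deterministically", {
  cfg <- tiny_model_config()
  m <- mil_model(cfg, seed = 2)
  bag <- random_bag(4, size = 16, seed = 1)
  H <- extract_features(bag, m)
  expect_equal(dim(H), c(4L, cfg$feature_dim))
  expect_true(all(is.finite(H)))

  # two identical slices give identical feature rows (pure function in eval mode)
  t1 <- bag$slices[, , , 2]
  twin <- new_bag("t", "negative", list(t1, t1))
  Ht <- extract_features(twin, m)
  expect_equal(Ht[1, ], Ht[2, ])

  # gradient flows back to the first conv layer on a 32x32 input (the head
  # must be off its zero initialization for upstream gradient to exist)
  m2 <- m
  set.seed(30)
  m2$params$head$W <- matrix(rnorm(16, sd = 0.5), 2, 8)
  bag32 <- random_bag(2, size = 32, seed = 3)
  lg <- milsij:::mil_loss_grads(m2, bag32, dropout_seed = 1)
  expect_gt(max(abs(lg$grads$backbone$conv1$W)), 0)

  # the pretrained-resnet backbone is not available in this implementation
  expect_error(model_config(backbone = "resnet18_pretrained"), "small_cnn")
})

test_that("gated attention matches a scalar brute-force oracle", {
  # the 2-D toy case: V = U = I, w = (1, 1)
  H <- rbind(c(1, 0), c(0, 1))
  params <- list(V = diag(2), U = diag(2), w = matrix(c(1, 1), 2, 1))
  logit <- tanh(1) * (1 / (1 + exp(-1))) + tanh(0) * 0.5   # identical for both rows
  expect_equal(gated_attention(H, params), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(gated_attention(H, params),
               naive_gated_attention(H, params$V, params$U, as.vector(params$w)),
               tolerance = 1e-12)

  # fuzzed feature matrices against the loop oracle
  set.seed(7)
  for (i in 1:20) {
    K <- sample(1:7, 1); L <- sample(2:5, 1); D <- sample(2:4, 1)
    Hf <- matrix(rnorm(K * L), K, L)
    pf <- list(V = matrix(rnorm(D * L), D, L), U = matrix(rnorm(D * L), D, L),
               w = matrix(rnorm(D), D, 1))
    a <- gated_attention(Hf, pf)
    expect_equal(a, naive_gated_attention(Hf, pf$V, pf$U, as.vector(pf$w)),
                 tolerance = 1e-6)
    expect_equal(sum(a), 1, tolerance = 1e-6)
    expect_true(all(a >= 0))
  }

  # K = 1 gives weight 1 regardless of parameters; equal rows give 1/K
  expect_equal(gated_attention(matrix(rnorm(3), 1, 3),
                               list(V = matrix(rnorm(6), 2, 3),
                                    U = matrix(rnorm(6), 2, 3),
                                    w = matrix(rnorm(2), 2, 1))), 1)
  Heq <- matrix(rep(rnorm(3), each = 5), 5, 3)
  expect_equal(gated_attention(Heq, list(V = matrix(rnorm(6), 2, 3),
                                         U = matrix(rnorm(6), 2, 3),
                                         w = matrix(rnorm(2), 2, 1))),
               rep(0.2, 5), tolerance = 1e-12)

  expect_error(gated_attention(matrix(c(1, NA), 1, 2), params), "finite")
})

test_that("forcing the gate to one reduces to plain tanh attention", {
  set.seed(8)
  H <- matrix(rnorm(12), 4, 3)
  pf <- list(V = matrix(rnorm(6), 2, 3), U = matrix(rnorm(6), 2, 3),
             w = matrix(rnorm(2), 2, 1))
  expect_equal(gated_attention(H, pf, gate = "ones"),
               naive_gated_attention(H, pf$V, pf$U, as.vector(pf$w), gate = "ones"),
               tolerance = 1e-12)
  # and differs from the gated form in general
  expect_gt(max(abs(gated_attention(H, pf) - gated_attention(H, pf, gate = "ones"))), 1e-6)
})

test_that("attention is monotone: raising one slice's logit raises only its weight", {
  set.seed(9)
  logits <- rnorm(6)
  a0 <- milsij:::softmax_vec(logits)
  for (j in 1:6) {
    bumped <- logits; bumped[j] <- bumped[j] + 0.3
    a1 <- milsij:::softmax_vec(bumped)
    expect_gt(a1[j], a0[j])
    expect_true(all(a1[-j] < a0[-j]))
  }
})

test_that("aggregation is the attention-weighted sum of instance features", {
  set.seed(10)
  H <- matrix(rnorm(20), 4, 5)
  onehot <- c(0, 0, 1, 0)
  expect_equal(aggregate_bag(H, onehot), H[3, ], ignore_attr = TRUE)
  expect_equal(aggregate_bag(H, rep(0.25, 4)), colMeans(H), ignore_attr = TRUE)
  a <- runif(4); a <- a / sum(a)
  expect_equal(aggregate_bag(H, a), naive_aggregate(H, a), tolerance = 1e-6)
  expect_error(aggregate_bag(H, c(0.5, 0.5)), "bag size")
  expect_error(aggregate_bag(H, c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
})

test_that("bag classification: closed forms, dropout only in training mode", {
  head <- list(W = matrix(0, 2, 4), b = c(0, 0))
  expect_equal(as.vector(classify_bag(rnorm(4), head)), c(0.5, 0.5))

  # logits (2, 0): probabilities (e^2, 1) / (e^2 + 1); positive is class 2
  head2 <- list(W = rbind(c(1, 0), c(0, 1)), b = c(0, 0))
  p <- classify_bag(c(0, 2), head2)
  expect_equal(unname(p["positive"]), exp(2) / (exp(2) + 1), tolerance = 1e-12)
  expect_equal(unname(p["negative"]), 1 / (exp(2) + 1), tolerance = 1e-12)

  # eval mode ignores the dropout RNG; train mode consumes it
  z <- rnorm(4)
  head3 <- list(W = matrix(rnorm(8), 2, 4), b = rnorm(2))
  expect_identical(classify_bag(z, head3, dropout_rate = 0.5, mode = "eval", seed = 1)[],
                   classify_bag(z, head3, dropout_rate = 0.5, mode = "eval", seed = 2)[])
  tr <- replicate(8, unname(classify_bag(z, head3, dropout_rate = 0.5,
                                         mode = "train", seed = sample.int(1e6, 1))["positive"]))
  expect_gt(stats::sd(tr), 0)
})

test_that("forward pass composes the stages and is permutation-equivariant", {
  m <- mil_model(tiny_model_config(), seed = 5)
  # zero-initialized head: untrained model sits exactly at chance
  bag <- random_bag(5, size = 16, seed = 6)
  p0 <- forward(m, bag)
  expect_equal(unname(p0$probs), c(0.5, 0.5))

  # give the head weights so probabilities depend on the bag
  m$params$head$W <- matrix(rnorm(2 * 8, sd = 0.5), 2, 8)
  m$params$head$b <- rnorm(2)
  p1 <- forward(m, bag)
  expect_equal(sum(p1$probs), 1, tolerance = 1e-6)
  expect_equal(sum(p1$attention$a), 1, tolerance = 1e-6)

  perm <- c(4, 1, 5, 3, 2)
  bagp <- new_bag(bag$subject_id, bag$label,
                  lapply(perm, function(k) bag$slices[, , , k]))
  p2 <- forward(m, bagp)
  expect_equal(p1$probs, p2$probs, tolerance = 1e-12)
  expect_equal(p1$attention$a[perm], p2$attention$a, tolerance = 1e-12)

  # K = 1: bag probability equals classifying the single instance feature
  one <- new_bag("k1", "positive", list(bag$slices[, , , 1]))
  H1 <- extract_features(one, m)
  expect_equal(unname(forward(m, one)$probs),
               as.vector(classify_bag(as.vector(H1), m$params$head)),
               tolerance = 1e-12)

  # bitwise-stable across repeated eval calls
  expect_identical(forward(m, bag)$probs, forward(m, bag)$probs)
})

test_that("training-mode gradients match finite differences", {
  cfg <- tiny_model_config(dropout_rate = 0.3)
  m <- mil_model(cfg, seed = 3)
  m$params$head$W <- matrix(rnorm(16, sd = 0.3), 2, 8)  # move off the zero init
  bag <- random_bag(3, size = 16, seed = 9)
  lg <- milsij:::mil_loss_grads(m, bag, dropout_seed = 77)
  eps <- 1e-5
  probe <- list(
    list(get = function(p) p$backbone$conv1$W[4, 1],
         set = function(p, v) { p$backbone$conv1$W[4, 1] <- v; p },
         g = lg$grads$backbone$conv1$W[4, 1]),
    list(get = function(p) p$backbone$conv3$gamma[2],
         set = function(p, v) { p$backbone$conv3$gamma[2] <- v; p },
         g = lg$grads$backbone$conv3$gamma[2]),
    list(get = function(p) p$attention$V[2, 3],
         set = function(p, v) { p$attention$V[2, 3] <- v; p },
         g = lg$grads$attention$V[2, 3]),
    list(get = function(p) p$head$W[1, 5],
         set = function(p, v) { p$head$W[1, 5] <- v; p },
         g = lg$grads$head$W[1, 5])
  )
  for (pr in probe) {
    f <- function(v) {
      m2 <- m; m2$params <- pr$set(m2$params, v)
      milsij:::mil_loss_grads(m2, bag, dropout_seed = 77)$loss
    }
    v0 <- pr$get(m$params)
    num <- (f(v0 + eps) - f(v0 - eps)) / (2 * eps)
    expect_equal(pr$g, num, tolerance = 1e-5)
  }
})

test_that("baseline predictor is the equal-weight mean of per-slice outputs", {
  cfg <- tiny_model_config()
  bm <- baseline_model(cfg, seed = 4)
  bm$params$head$W <- matrix(rnorm(16, sd = 0.5), 2, 8)
  bm$params$head$b <- rnorm(2)
  bag <- random_bag(4, size = 16, seed = 12)
  pred <- baseline_forward(bm, bag)
  expect_equal(sum(pred$probs), 1, tolerance = 1e-6)
  expect_equal(pred$attention$a, rep(0.25, 4))

  # independent oracle: per-slice forward passes via K = 1 bags, then the mean
  slice_probs <- t(vapply(1:4, function(k) {
    one <- new_bag("o", NA, list(bag$slices[, , , k]))
    as.vector(baseline_forward(bm, one)$probs)
  }, numeric(2)))
  expect_equal(unname(pred$probs), colMeans(slice_probs), tolerance = 1e-10)

  # constant slice probabilities pass through the mean unchanged
  twin <- new_bag("tw", NA, list(bag$slices[, , , 1], bag$slices[, , , 1]))
  one <- new_bag("o1", NA, list(bag$slices[, , , 1]))
  expect_equal(baseline_forward(bm, twin)$probs, baseline_forward(bm, one)$probs,
               tolerance = 1e-12)
})
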