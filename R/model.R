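# The gated-attention MIL network: instance feature extraction, gated
# attention pooling, bag embedding, bag-level classification -- plus the
# slice-level baseline classifier used for comparison.

#' Model configuration
#'
#' The published configuration pairs an ImageNet-pretrained ResNet-18 backbone
#' with attention dimensions L = 512, D = 128, K = 1 and dropout 0.5. This
#' package ships the compact `small_cnn` backbone (3 conv blocks, global
#' average pooling, linear projection to L) with correspondingly smaller
#' defaults; no deep-learning runtime or pretrained weight source is bundled,
#' so requesting `resnet18_pretrained` signals an error.
#'
#' @param backbone `"small_cnn"`.
#' @param feature_dim L, the instance feature dimension.
#' @param attention_dim D, the internal attention dimension.
#' @param attention_branches K_att, number of attention branches (the
#'   published path uses 1; larger values concatenate branch embeddings).
#' @param dropout_rate dropout applied to the bag embedding during training.
#' @param channels conv channel widths of the three backbone blocks.
#' @return a `model_config` object.
#' @export
model_config <- function(backbone = "small_cnn", feature_dim = 64L,
                         attention_dim = 32L, attention_branches = 1L,
                         dropout_rate = 0.5, channels = c(8L, 16L, 32L)) {
  backbone <- match.arg(backbone, c("small_cnn", "resnet18_pretrained"))
  if (backbone == "resnet18_pretrained")
    stopf(paste("the resnet18_pretrained backbone needs an external deep-learning",
                "runtime with ImageNet weights, which this package does not bundle;",
                "use backbone = 'small_cnn'"))
  cfg <- list(backbone = backbone,
              feature_dim = assert_count(feature_dim, "feature_dim"),
              attention_dim = assert_count(attention_dim, "attention_dim"),
              attention_branches = assert_count(attention_branches, "attention_branches"),
              n_classes = 2L,
              dropout_rate = assert_number(dropout_rate, "dropout_rate", 0, 1 - 1e-12),
              channels = as.integer(channels))
  if (length(cfg$channels) != 3L || any(cfg$channels < 1L))
    stopf("channels must be three positive conv widths")
  class(cfg) <- "model_config"
  cfg
}

#' Initialize a gated-attention MIL model
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization (He for convolutions,
#'   Xavier elsewhere; biases zero).
#' @return a `mil_model` object holding `config` and `params`
#'   (`backbone`, `attention` with `V`, `U`, `w`, and the linear `head`).
#' @export
mil_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  L <- config$feature_dim; D <- config$attention_dim; Ka <- config$attention_branches
  params <- with_seed(seed, list(
    backbone = backbone_init(config$channels, L),
    attention = list(V = xavier_matrix(D, L, L),
                     U = xavier_matrix(D, L, L),
                     w = xavier_matrix(D, Ka, D)),
    # zero-initialized head: untrained models start at chance (loss ln 2)
    head = list(W = matrix(0, 2L, L * Ka), b = rep(0, 2L))
  ))
  structure(list(config = config, params = params), class = "mil_model")
}

#' Initialize the slice-level baseline classifier
#'
#' The equal-weight comparator: the same backbone with its own 2-class head
#' classifies every slice independently; the patient-level probability is the
#' unweighted mean of the slice probabilities.
#'
#' @inheritParams mil_model
#' @return a `mil_baseline` object.
#' @export
baseline_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  L <- config$feature_dim
  params <- with_seed(seed, list(
    backbone = backbone_init(config$channels, L),
    head = list(W = matrix(0, 2L, L), b = rep(0, 2L))
  ))
  structure(list(config = config, params = params), class = "mil_baseline")
}

#' Extract per-slice instance features
#'
#' Runs the backbone (truncated before any classification head, global-average
#' pooled) over every slice of the bag.
#'
#' @param bag a `mil_bag`.
#' @param model a `mil_model` or `mil_baseline`.
#' @return K x L feature matrix H, one row per slice.
#' @export
extract_features <- function(bag, model) {
  stopifnot(inherits(bag, "mil_bag"))
  H <- backbone_forward(model$params$backbone, bag$slices)$H
  if (!all(is.finite(H))) stopf("non-finite instance features")
  H
}

#' Gated attention weights over a bag's instances
#'
#' Computes, per slice k, the logit `w' (tanh(V h_k) * sigmoid(U h_k))`
#' (elementwise product of the tanh branch and the sigmoid gate) and returns
#' the softmax over slices, with max-subtraction for numerical stability.
#'
#' @param H K x L instance feature matrix.
#' @param params list with `V` (D x L), `U` (D x L), `w` (D x K_att).
#' @param gate `"sigmoid"` for the gated form; `"ones"` forces the gate to a
#'   constant one, reducing to plain tanh attention (used for ablation).
#' @return numeric vector of K attention weights summing to 1 (a K x K_att
#'   matrix when `K_att > 1`).
#' @export
gated_attention <- function(H, params, gate = c("sigmoid", "ones")) {
  gate <- match.arg(gate)
  if (!is.matrix(H) || !all(is.finite(H))) stopf("H must be a finite numeric matrix")
  fw <- gated_attention_forward(H, params, gate = gate)
  if (ncol(fw$A) == 1L) as.vector(fw$A) else fw$A
}

gated_attention_forward <- function(H, params, gate = "sigmoid") {
  Tm <- tanh(H %*% t(params$V))                       # K x D
  Sm <- if (gate == "sigmoid") 1 / (1 + exp(-(H %*% t(params$U)))) else
    matrix(1, nrow(H), nrow(params$U))
  G <- Tm * Sm
  logits <- G %*% params$w                            # K x K_att
  A <- apply(logits, 2L, function(l) softmax_vec(l))
  A <- matrix(A, nrow = nrow(H))
  list(A = A, T = Tm, S = Sm, G = G, logits = logits, gate = gate)
}

# Backward through attention + aggregation. dZ: K_att x L gradient w.r.t. the
# per-branch embeddings. Returns dH plus parameter gradients.
gated_attention_backward <- function(H, params, fw, dZ) {
  A <- fw$A
  dH <- A %*% dZ                                      # via z_b = sum_k A[k,b] H[k,]
  dA <- H %*% t(dZ)                                   # K x K_att
  dlogits <- A * (dA - matrix(colSums(A * dA), nrow(A), ncol(A), byrow = TRUE))
  dG <- dlogits %*% t(params$w)                       # K x D
  dw <- crossprod(fw$G, dlogits)                      # D x K_att
  dT <- dG * fw$S
  dpreV <- dT * (1 - fw$T^2)
  dV <- crossprod(dpreV, H)                           # D x L
  dH <- dH + dpreV %*% params$V
  if (fw$gate == "sigmoid") {
    dS <- dG * fw$T
    dpreU <- dS * fw$S * (1 - fw$S)
    dU <- crossprod(dpreU, H)
    dH <- dH + dpreU %*% params$U
  } else {
    dU <- params$U * 0
  }
  list(dH = dH, dV = dV, dU = dU, dw = dw)
}

#' Attention-weighted bag embedding
#'
#' @param H K x L instance feature matrix.
#' @param a attention weights: K-vector summing to 1 (or K x K_att matrix).
#' @return the bag embedding `z = sum_k a_k h_k` (length L, or `L * K_att`
#'   with branch embeddings concatenated).
#' @export
aggregate_bag <- function(H, a) {
  A <- if (is.matrix(a)) a else matrix(a, ncol = 1L)
  if (nrow(A) != nrow(H)) stopf("length of attention weights (%d) must equal bag size (%d)",
                                nrow(A), nrow(H))
  if (any(abs(colSums(A) - 1) > 1e-6)) stopf("attention weights must sum to 1")
  as.vector(t(t(A) %*% H))                            # branch-major concatenation
}

#' Classify a bag embedding
#'
#' Single affine layer to 2 classes followed by softmax. Dropout is applied to
#' the embedding in training mode only.
#'
#' @param z bag embedding vector.
#' @param head list with `W` (2 x length(z)) and `b` (length 2).
#' @param dropout_rate dropout probability on `z`.
#' @param mode `"eval"` or `"train"`.
#' @param seed RNG seed for the dropout mask (train mode).
#' @return named probability vector `c(negative = ..., positive = ...)`.
#' @export
classify_bag <- function(z, head, dropout_rate = 0, mode = c("eval", "train"), seed = 1L) {
  mode <- match.arg(mode)
  mask <- rep(1, length(z))
  if (mode == "train" && dropout_rate > 0) {
    mask <- with_seed(seed, stats::rbinom(length(z), 1L, 1 - dropout_rate)) / (1 - dropout_rate)
  }
  zd <- z * mask
  logits <- as.vector(head$W %*% zd + head$b)
  probs <- softmax_vec(logits)
  names(probs) <- CLASS_NAMES
  attr(probs, "logits") <- logits
  attr(probs, "dropout_mask") <- mask
  probs
}

# Full cached forward pass used by training, Grad-CAM and the public forward.
mil_forward_cached <- function(model, bag, mode = "eval", dropout_seed = 1L,
                               gate = "sigmoid", force_uniform_attention = FALSE,
                               keep_backbone_cache = FALSE) {
  bb <- backbone_forward(model$params$backbone, bag$slices,
                         keep_cache = keep_backbone_cache)
  H <- bb$H
  K <- nrow(H)
  att <- gated_attention_forward(H, model$params$attention, gate = gate)
  if (force_uniform_attention) att$A <- matrix(1 / K, K, ncol(att$A))
  Z <- t(att$A) %*% H                                 # K_att x L
  z <- as.vector(t(Z))
  probs <- classify_bag(z, model$params$head,
                        dropout_rate = model$config$dropout_rate,
                        mode = mode, seed = dropout_seed)
  list(H = H, att = att, z = z, probs = probs, bb_cache = bb$cache,
       force_uniform = force_uniform_attention)
}

#' Forward pass of the gated-attention MIL model on one bag
#'
#' Composition: instance features -> gated attention -> attention-weighted
#' aggregation -> bag classification.
#'
#' @param model a `mil_model`.
#' @param bag a `mil_bag`.
#' @param mode `"eval"` (deterministic) or `"train"` (dropout active).
#' @param dropout_seed seed for the train-mode dropout mask.
#' @return A `bag_prediction`: list with `subject_id`, named `probs`,
#'   `predicted_label`, and `attention` (list with weights `a` summing to 1
#'   and embedding `z`).
#' @export
forward <- function(model, bag, mode = c("eval", "train"), dropout_seed = 1L) {
  stopifnot(inherits(model, "mil_model"), inherits(bag, "mil_bag"))
  mode <- match.arg(mode)
  fw <- mil_forward_cached(model, bag, mode = mode, dropout_seed = dropout_seed)
  a <- if (ncol(fw$att$A) == 1L) as.vector(fw$att$A) else fw$att$A
  structure(list(
    subject_id = bag$subject_id,
    probs = stats::setNames(as.numeric(fw$probs), CLASS_NAMES),
    logits = stats::setNames(attr(fw$probs, "logits"), CLASS_NAMES),
    predicted_label = CLASS_NAMES[which.max(fw$probs)],
    attention = list(a = a, z = fw$z)
  ), class = "bag_prediction")
}

#' @export
print.bag_prediction <- function(x, ...) {
  cat(sprintf("<bag_prediction> %s: P(positive) = %.4f -> %s\n",
              x$subject_id, x$probs["positive"], x$predicted_label))
  invisible(x)
}

#' Forward pass of the slice-level baseline on one bag
#'
#' Every slice is classified independently by the shared backbone + 2-class
#' head; the patient-level prediction combines the slices with equal weight.
#' `combine = "probability"` averages slice softmax probabilities (the default
#' equal-weight comparator); `combine = "logit"` averages slice logits before
#' the softmax, which is algebraically identical to a uniform-attention MIL
#' pass through the same affine head.
#'
#' @param model a `mil_baseline`.
#' @param bag a `mil_bag`.
#' @param combine `"probability"` or `"logit"`.
#' @return a `bag_prediction`; the attention field reports the uniform weights
#'   `1/K`.
#' @export
baseline_forward <- function(model, bag, combine = c("probability", "logit")) {
  stopifnot(inherits(model, "mil_baseline"), inherits(bag, "mil_bag"))
  combine <- match.arg(combine)
  H <- backbone_forward(model$params$backbone, bag$slices)$H
  logits <- H %*% t(model$params$head$W)
  logits <- sweep(logits, 2L, model$params$head$b, `+`)   # K x 2 slice logits
  probs_slice <- softmax_rows(logits)
  probs <- if (combine == "probability") colMeans(probs_slice) else
    softmax_vec(colMeans(logits))
  probs <- stats::setNames(as.numeric(probs), CLASS_NAMES)
  K <- nrow(H)
  structure(list(
    subject_id = bag$subject_id,
    probs = probs,
    logits = stats::setNames(colMeans(logits), CLASS_NAMES),
    predicted_label = CLASS_NAMES[which.max(probs)],
    attention = list(a = rep(1 / K, K), z = colMeans(H)),
    slice_probs = probs_slice
  ), class = "bag_prediction")
}
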