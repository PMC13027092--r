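# Training: Adam with gradient accumulation over patient-level bags,
# cross-entropy bag loss, and checkpoint selection by best validation F1.

#' Training configuration
#'
#' Defaults follow the published protocol: Adam, learning rate 1e-4, weight
#' decay 1e-3, a batch of 4 patient-level bags, 20 epochs, cross-entropy loss,
#' model selection by the highest validation F1 (earliest epoch on ties).
#' Bags have variable sizes, so a "batch" is realized as gradient accumulation
#' over `batch_bags` bags processed one at a time -- mathematically a batch of
#' 4 bags without padding.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty folded into the gradient.
#' @param batch_bags bags per optimizer step.
#' @param epochs training epochs.
#' @param seed master seed: drives bag order shuffling, dropout masks and
#'   augmentation draws.
#' @param augment optional [augment_policy()] applied independently per slice
#'   during training (`NULL` disables augmentation).
#' @return a `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-3,
                         batch_bags = 4L, epochs = 20L, seed = 1L,
                         augment = NULL) {
  if (!is.null(augment)) stopifnot(inherits(augment, "augment_policy"))
  cfg <- list(learning_rate = assert_number(learning_rate, "learning_rate", 0),
              weight_decay = assert_number(weight_decay, "weight_decay", 0),
              batch_bags = assert_count(batch_bags, "batch_bags"),
              epochs = assert_count(epochs, "epochs"),
              loss = "cross_entropy", selection_metric = "validation_f1",
              seed = assert_count(seed, "seed", min = 0L),
              augment = augment)
  class(cfg) <- "train_config"
  cfg
}

#' Bag-level cross-entropy loss
#'
#' Negative log probability of the true class; the probability is clamped at
#' 1e-12 so a degenerate zero never produces an infinite loss.
#'
#' @param probs probability vector over `c(negative, positive)`.
#' @param label true label.
#' @return scalar loss.
#' @export
bag_loss <- function(probs, label) {
  y <- label_to_index(label)
  if (abs(sum(probs) - 1) > 1e-6 || any(probs < -1e-12))
    stopf("probs must be a valid probability vector")
  -log(max(probs[y], 1e-12))
}

# Loss + full parameter gradients for one bag (gated-attention MIL model).
mil_loss_grads <- function(model, bag, dropout_seed) {
  y <- label_to_index(bag$label)
  fw <- mil_forward_cached(model, bag, mode = "train", dropout_seed = dropout_seed,
                           keep_backbone_cache = TRUE)
  probs <- fw$probs
  loss <- -log(max(probs[y], 1e-12))
  dlogits <- as.vector(probs); dlogits[y] <- dlogits[y] - 1
  mask <- attr(probs, "dropout_mask")
  zd <- fw$z * mask
  head_g <- list(W = outer(dlogits, zd), b = dlogits)
  dz <- as.vector(t(model$params$head$W) %*% dlogits) * mask
  dZ <- matrix(dz, nrow = ncol(fw$att$A), byrow = TRUE)   # K_att x L
  ab <- gated_attention_backward(fw$H, model$params$attention, fw$att, dZ)
  bb <- backbone_backward(model$params$backbone, fw$bb_cache, ab$dH)
  list(loss = loss,
       grads = list(backbone = bb$grads,
                    attention = list(V = ab$dV, U = ab$dU, w = ab$dw),
                    head = head_g))
}

# Loss + gradients for the slice-level baseline: per-slice cross-entropy
# against the broadcast bag label, averaged over slices.
baseline_loss_grads <- function(model, bag, dropout_seed = NULL) {
  y <- label_to_index(bag$label)
  bb <- backbone_forward(model$params$backbone, bag$slices, keep_cache = TRUE)
  H <- bb$H; K <- nrow(H)
  logits <- sweep(H %*% t(model$params$head$W), 2L, model$params$head$b, `+`)
  P <- softmax_rows(logits)
  loss <- mean(-log(pmax(P[, y], 1e-12)))
  dlog <- P; dlog[, y] <- dlog[, y] - 1; dlog <- dlog / K
  head_g <- list(W = crossprod(dlog, H), b = colSums(dlog))
  dH <- dlog %*% model$params$head$W
  bk <- backbone_backward(model$params$backbone, bb$cache, dH)
  list(loss = loss, grads = list(backbone = bk$grads, head = head_g))
}

positive_probability <- function(model, bag) {
  if (inherits(model, "mil_baseline")) {
    unname(baseline_forward(model, bag)$probs["positive"])
  } else {
    unname(forward(model, bag)$probs["positive"])
  }
}

# Validation F1 (positive class) at threshold 0.5, plus accuracy. An undefined
# F1 (no predicted or no true positives) counts as 0 for model selection.
validation_scores <- function(model, bags, threshold = 0.5) {
  p <- vapply(bags, function(b) positive_probability(model, b), numeric(1))
  truth <- vapply(bags, function(b) b$label, character(1))
  pred <- ifelse(p >= threshold, "positive", "negative")
  cm <- confusion_matrix(tp = sum(pred == "positive" & truth == "positive"),
                         fn = sum(pred == "negative" & truth == "positive"),
                         tn = sum(pred == "negative" & truth == "negative"),
                         fp = sum(pred == "positive" & truth == "negative"))
  m <- metrics_from_cm(cm)
  list(f1 = if (is.na(m$f1)) 0 else m$f1, accuracy = m$accuracy)
}

augment_bag <- function(bag, policy) {
  K <- bag_size(bag)
  seeds <- sample.int(.Machine$integer.max - 1L, K)
  tensors <- lapply(seq_len(K), function(k)
    augment_train(bag$slices[, , , k], policy, seed = seeds[k]))
  new_bag(bag$subject_id, bag$label, tensors)
}

#' Train a MIL (or baseline) model
#'
#' Iterates epochs over the training bags in seeded shuffled order, one
#' optimizer step per `batch_bags` bags (gradients averaged), evaluates the
#' validation F1 after every epoch (threshold 0.5, no test-time augmentation),
#' and returns the parameters from the epoch with the highest validation F1
#' (ties broken to the earliest epoch). Training and validation sets must be
#' patient-disjoint; any shared subject id aborts with a leakage error. Fully
#' deterministic given `config$seed`.
#'
#' @param model a `mil_model` or `mil_baseline` (initial weights).
#' @param train_bags,val_bags lists of labeled `mil_bag` objects.
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return A `train_result`: list with `model` (best state), `history`
#'   (data.frame epoch/train_loss/val_f1/val_acc), `best_epoch`, and `config`.
#' @export
train_mil <- function(model, train_bags, val_bags, config = train_config(),
                      verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (length(train_bags) == 0L || length(val_bags) == 0L)
    stopf("train and validation sets must be nonempty")
  train_ids <- vapply(train_bags, function(b) b$subject_id, character(1))
  val_ids <- vapply(val_bags, function(b) b$subject_id, character(1))
  overlap <- intersect(train_ids, val_ids)
  if (length(overlap) > 0L)
    stopf("patient-level leakage: subject(s) %s appear in both train and validation",
          paste(overlap, collapse = ", "))
  labs <- vapply(train_bags, function(b) b$label, character(1))
  if (any(is.na(labs)) || any(is.na(vapply(val_bags, function(b) b$label, character(1)))))
    stopf("all training and validation bags must be labeled")

  loss_grads <- if (inherits(model, "mil_baseline")) baseline_loss_grads else mil_loss_grads

  with_seed(config$seed, {
    opt <- adam_init(model$params)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_f1 = numeric(0), val_acc = numeric(0))
    best <- list(f1 = -Inf, epoch = NA_integer_, params = model$params)
    n <- length(train_bags)
    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample.int(n)
      losses <- numeric(0)
      i <- 1L
      while (i <= n) {
        batch <- order_idx[i:min(i + config$batch_bags - 1L, n)]
        acc_grads <- NULL
        for (j in batch) {
          bag <- train_bags[[j]]
          if (!is.null(config$augment)) bag <- augment_bag(bag, config$augment)
          ds <- sample.int(.Machine$integer.max - 1L, 1L)
          lg <- loss_grads(model, bag, ds)
          losses <- c(losses, lg$loss)
          acc_grads <- if (is.null(acc_grads)) lg$grads else
            nmap2(`+`, acc_grads, lg$grads)
        }
        acc_grads <- nmap(function(g) g / length(batch), acc_grads)
        if (config$learning_rate > 0) {
          step <- adam_step(model$params, acc_grads, opt,
                            lr = config$learning_rate,
                            weight_decay = config$weight_decay)
          model$params <- step$params
          opt <- step$state
        }
        i <- i + config$batch_bags
      }
      vs <- validation_scores(model, val_bags)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = mean(losses),
                                           val_f1 = vs$f1, val_acc = vs$accuracy))
      if (vs$f1 > best$f1) best <- list(f1 = vs$f1, epoch = epoch, params = model$params)
      if (verbose)
        message(sprintf("epoch %2d  loss %.4f  val F1 %.4f  val acc %.4f",
                        epoch, mean(losses), vs$f1, vs$accuracy))
    }
    model$params <- best$params
    structure(list(model = model, history = history, best_epoch = best$epoch,
                   best_val_f1 = best$f1, config = config),
              class = "train_result")
  })
}

#' Select the best epoch from a validation-F1 sequence
#'
#' Argmax with ties broken to the earliest epoch (1-based).
#' @param val_f1 numeric vector of per-epoch validation F1 scores.
#' @return integer epoch index.
#' @export
select_best_epoch <- function(val_f1) {
  if (length(val_f1) == 0L) stopf("empty F1 sequence")
  which.max(val_f1)
}

#' Per-split class balance report
#'
#' Reports positive:negative subject counts and their ratio per split, with a
#' warning (not an error) when a ratio leaves \[0.8, 1.25\] -- the regime in
#' which training proceeds without any explicit class-balancing strategy.
#'
#' @param manifest cohort manifest data.frame.
#' @return data.frame with columns split, n_positive, n_negative, ratio.
#' @export
class_balance_report <- function(manifest) {
  if (nrow(manifest) == 0L) stopf("empty manifest")
  labels <- normalize_label(manifest$label)
  splits <- unique(manifest$split)
  out <- do.call(rbind, lapply(splits, function(s) {
    sel <- manifest$split == s
    np <- sum(labels[sel] == "positive"); nn <- sum(labels[sel] == "negative")
    data.frame(split = s, n_positive = np, n_negative = nn,
               ratio = if (nn > 0) np / nn else NA_real_)
  }))
  bad <- !is.na(out$ratio) & (out$ratio < 0.8 | out$ratio > 1.25)
  if (any(bad))
    warning(sprintf("class imbalance in split(s) %s (ratio outside [0.8, 1.25])",
                    paste(out$split[bad], collapse = ", ")), call. = FALSE)
  out
}

#' Save a model (or training result) as a JSON checkpoint
#'
#' Text-only serialization: configuration, parameters, and, for a training
#' result, the history and best epoch.
#' @param x a `mil_model`, `mil_baseline`, or `train_result`.
#' @param path output file.
#' @export
save_checkpoint <- function(x, path) {
  if (inherits(x, "train_result")) {
    obj <- list(kind = class(x$model)[1], config = unclass(x$model$config),
                params = x$model$params, history = x$history,
                best_epoch = x$best_epoch)
  } else {
    obj <- list(kind = class(x)[1], config = unclass(x$config), params = x$params)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a JSON checkpoint saved by [save_checkpoint()]
#' @param path checkpoint file.
#' @return a `mil_model` or `mil_baseline`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  cfg <- obj$config
  config <- model_config(backbone = cfg$backbone, feature_dim = cfg$feature_dim,
                         attention_dim = cfg$attention_dim,
                         attention_branches = cfg$attention_branches,
                         dropout_rate = cfg$dropout_rate, channels = cfg$channels)
  fix <- function(p) if (is.list(p)) lapply(p, fix) else if (is.matrix(p)) p else as.numeric(p)
  params <- fix(obj$params)
  # vectors serialized as length-1-dim arrays come back as plain vectors; matrices survive
  structure(list(config = config, params = params),
            class = if (identical(obj$kind, "mil_baseline")) "mil_baseline" else "mil_model")
}
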