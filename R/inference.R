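# Inference: deterministic test-time augmentation (identity + horizontal
# flip, probability averaging) and cohort-level prediction tables.

#' Test-time augmentation configuration
#'
#' @param views ordered character vector of deterministic views; supported:
#'   `"identity"`, `"hflip"`. The identity view must always be included.
#' @param combine `"probability"` (average softmax outputs across views; the
#'   default reading of output averaging) or `"logit"`.
#' @param threshold decision cut on the positive-class probability.
#' @return a `tta_config` object.
#' @export
tta_config <- function(views = c("identity", "hflip"),
                       combine = c("probability", "logit"),
                       threshold = 0.5) {
  combine <- match.arg(combine)
  if (length(views) == 0L) stopf("TTA needs at least one view")
  views <- match.arg(views, c("identity", "hflip"), several.ok = TRUE)
  if (!"identity" %in% views) stopf("the identity view must be part of the TTA views")
  threshold <- assert_number(threshold, "threshold", 0, 1)
  if (threshold <= 0 || threshold >= 1) stopf("threshold must lie strictly in (0, 1)")
  structure(list(views = views, combine = combine, threshold = threshold),
            class = "tta_config")
}

apply_view <- function(bag, view) {
  if (view == "identity") return(bag)
  slices <- bag$slices[, rev(seq_len(dim(bag$slices)[2])), , , drop = FALSE]
  structure(list(subject_id = bag$subject_id, label = bag$label, slices = slices),
            class = "mil_bag")
}

model_predict <- function(model, bag) {
  if (inherits(model, "mil_baseline")) baseline_forward(model, bag)
  else forward(model, bag)
}

#' Predict one bag with test-time augmentation
#'
#' Each slice is presented in every configured deterministic view (original
#' and horizontally flipped by default), one full forward pass is run per
#' view, and the class outputs are averaged. Attention weights are reported
#' from the identity view. No randomness is consumed at inference.
#'
#' @param model a trained `mil_model` or `mil_baseline`.
#' @param bag a `mil_bag`.
#' @param config a [tta_config()].
#' @return a `bag_prediction` with averaged probabilities; the predicted label
#'   is positive iff the averaged positive probability reaches the threshold.
#' @export
predict_tta <- function(model, bag, config = tta_config()) {
  stopifnot(inherits(config, "tta_config"), inherits(bag, "mil_bag"))
  per_view <- lapply(config$views, function(v) model_predict(model, apply_view(bag, v)))
  probs <- if (config$combine == "probability") {
    Reduce(`+`, lapply(per_view, function(p) as.numeric(p$probs))) / length(per_view)
  } else {
    softmax_vec(Reduce(`+`, lapply(per_view, function(p) as.numeric(p$logits))) /
                  length(per_view))
  }
  names(probs) <- CLASS_NAMES
  identity_pred <- per_view[[match("identity", config$views)]]
  structure(list(
    subject_id = bag$subject_id,
    probs = probs,
    predicted_label = if (probs["positive"] >= config$threshold) "positive" else "negative",
    attention = identity_pred$attention
  ), class = "bag_prediction")
}

#' Predict a whole cohort
#'
#' One row per subject, sorted by subject id for reproducible output.
#'
#' @param model trained model.
#' @param bags list of `mil_bag` objects (duplicate subject ids are an error;
#'   unlabeled bags are allowed and yield `NA` labels).
#' @param config a [tta_config()]; pass `tta_config(views = "identity")` to
#'   disable augmentation.
#' @return data.frame with columns subject_id, label, p_positive, pred.
#' @export
predict_cohort <- function(model, bags, config = tta_config()) {
  if (length(bags) == 0L) stopf("no bags to predict")
  ids <- vapply(bags, function(b) b$subject_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate subject ids: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- lapply(bags, function(b) {
    pr <- predict_tta(model, b, config)
    data.frame(subject_id = b$subject_id,
               label = if (is.na(b$label)) NA_character_ else b$label,
               p_positive = unname(pr$probs["positive"]),
               pred = pr$predicted_label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
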