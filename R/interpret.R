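# Interpretability: slice-level attention ranking, Grad-CAM saliency on the
# backbone's last convolutional maps, and the attention-vs-planted-lesion
# overlap score that makes interpretability testable on synthetic cohorts.

#' Rank a bag's slices by attention weight
#'
#' Deterministic descending sort, ties broken by the lower slice index.
#'
#' @param attention attention weights: the `attention` list of a
#'   `bag_prediction`, or a bare numeric vector of weights.
#' @param k number of top/bottom slices to select (at most the bag size).
#' @return A `slice_ranking`: list with `ranking` (data.frame slice_index
#'   (0-based) / weight, sorted descending), `top_k`, `bottom_k`.
#' @export
rank_slices <- function(attention, k = 5L) {
  a <- if (is.list(attention)) attention$a else attention
  if (is.matrix(a)) a <- a[, 1L]                      # branch 1 of a multi-branch model
  K <- length(a)
  k <- assert_count(k, "k")
  if (k > K) stopf("k = %d exceeds bag size %d", k, K)
  ord <- order(-a, seq_len(K))
  ranking <- data.frame(slice_index = ord - 1L, weight = a[ord])
  structure(list(ranking = ranking,
                 top_k = ranking[seq_len(k), , drop = FALSE],
                 bottom_k = ranking[seq.int(K - k + 1L, K), , drop = FALSE]),
            class = "slice_ranking")
}

#' Grad-CAM saliency map for one slice of a bag
#'
#' Gradients of the target-class *bag logit* with respect to the backbone's
#' last convolutional feature maps of the chosen slice are channel-averaged
#' into weights; the weighted feature-map sum is rectified, upsampled
#' bilinearly to the input size, and min-max normalized to \[0, 1\]. The bag
#' logit is back-propagated through the attention-weighted path, so both the
#' direct feature contribution and the slice's influence on the attention
#' distribution are captured. Raw logits are used (not softmax), so the map
#' is invariant to adding a constant to all logits.
#'
#' @param model a `mil_model`.
#' @param bag a `mil_bag`.
#' @param slice_index 0-based slice index within the bag.
#' @param target_class `"positive"`, `"negative"`, or `NULL` for the
#'   predicted class.
#' @return A `grad_cam_map`: list with `heatmap` (matrix in \[0, 1\], input
#'   spatial size; all zeros for a constant map), `target_class`,
#'   `slice_index`.
#' @export
grad_cam <- function(model, bag, slice_index, target_class = NULL) {
  stopifnot(inherits(model, "mil_model"), inherits(bag, "mil_bag"))
  K <- bag_size(bag)
  slice_index <- assert_count(slice_index, "slice_index", min = 0L)
  if (slice_index >= K) stopf("slice_index %d out of range for bag of size %d", slice_index, K)
  fw <- mil_forward_cached(model, bag, mode = "eval", keep_backbone_cache = TRUE)
  if (is.null(target_class)) target_class <- CLASS_NAMES[which.max(fw$probs)]
  cls <- match.arg(target_class, CLASS_NAMES)
  c_idx <- match(cls, CLASS_NAMES)

  # d(logit_c)/dz, then through attention + aggregation to the per-slice
  # features, then to the last conv maps via the projection and GAP.
  dz <- as.numeric(model$params$head$W[c_idx, ])
  dZ <- matrix(dz, nrow = ncol(fw$att$A), byrow = TRUE)
  ab <- gated_attention_backward(fw$H, model$params$attention, fw$att, dZ)
  dH_j <- ab$dH[slice_index + 1L, , drop = FALSE]      # 1 x L
  dgap <- dH_j %*% t(model$params$backbone$proj$W)     # 1 x C3 channel gradients

  maps <- fw$bb_cache$last_maps[, , , slice_index + 1L, drop = FALSE]  # h x w x C3 x 1
  d <- dim(maps)
  # Channel-averaging the spatial gradient of the pooled feature gives
  # dgap / (h*w) whatever the global pooling routes it through; the positive
  # scale cancels in the final normalization.
  alpha <- as.numeric(dgap)
  cam <- matrix(0, d[1], d[2])
  for (c in seq_len(d[3])) cam <- cam + alpha[c] * maps[, , c, 1L]
  cam <- pmax(cam, 0)
  up <- EBImage::resize(cam, w = dim(bag$slices)[1], h = dim(bag$slices)[2],
                        filter = "bilinear")
  up <- matrix(as.numeric(up), dim(bag$slices)[1], dim(bag$slices)[2])
  rng <- range(up)
  heat <- if (rng[2] > rng[1]) (up - rng[1]) / (rng[2] - rng[1]) else up * 0
  structure(list(heatmap = heat, target_class = cls,
                 slice_index = as.integer(slice_index)),
            class = "grad_cam_map")
}

#' Attention mass on planted lesion slices
#'
#' Quantifies how much of the attention distribution a positive bag's
#' planted-lesion slices receive: (i) the attention mass on lesion slices,
#' (ii) precision-at-k (fraction of the top-k attended slices that are lesion
#' slices), and (iii) the uniform baseline `|lesion| / K` for comparison.
#'
#' @param attention attention weights (vector or the `attention` list of a
#'   `bag_prediction`).
#' @param ground_truth one subject's entry of the synthetic ground truth
#'   (list with `label` and 0-based `lesion_slice_indices`).
#' @param k top-k for the precision term.
#' @return list with `lesion_mass`, `precision_at_k`, `uniform_mass`.
#' @export
attention_lesion_overlap <- function(attention, ground_truth, k = 5L) {
  a <- if (is.list(attention)) attention$a else attention
  if (is.matrix(a)) a <- a[, 1L]
  if (!identical(normalize_label(ground_truth$label), "positive") ||
      length(ground_truth$lesion_slice_indices) == 0L)
    stopf("attention_lesion_overlap needs a positive bag with planted lesions")
  K <- length(a)
  lesions <- as.integer(ground_truth$lesion_slice_indices)
  if (any(lesions < 0L | lesions >= K)) stopf("lesion slice index out of range")
  k <- min(assert_count(k, "k"), K)
  top <- rank_slices(a, k = k)$top_k$slice_index
  list(lesion_mass = sum(a[lesions + 1L]),
       precision_at_k = length(intersect(top, lesions)) / k,
       uniform_mass = length(lesions) / K)
}

#' Write attention ranking and Grad-CAM overlays for one subject
#'
#' Emits `attention_ranking.csv` and, for the `top_k` highest-attended
#' slices, alpha-blended overlay PNGs (grayscale slice + hot-colored
#' Grad-CAM heat).
#'
#' @param model a trained `mil_model`.
#' @param bag the subject's `mil_bag`.
#' @param out_dir output directory.
#' @param top_k number of slices to explain.
#' @param alpha blend weight of the heatmap.
#' @return invisibly, the ranking data.frame.
#' @export
explain_subject <- function(model, bag, out_dir, top_k = 5L, alpha = 0.45) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pred <- forward(model, bag)
  top_k <- min(assert_count(top_k, "top_k"), bag_size(bag))
  rk <- rank_slices(pred$attention, k = top_k)
  utils::write.csv(rk$ranking, file.path(out_dir, "attention_ranking.csv"),
                   row.names = FALSE)
  ramp <- grDevices::colorRamp(c("black", "red", "yellow"))
  for (i in seq_len(top_k)) {
    si <- rk$top_k$slice_index[i]
    cam <- grad_cam(model, bag, si)
    gray <- from_model_tensor(bag$slices[, , , si + 1L, drop = TRUE])
    heat <- ramp(as.vector(cam$heatmap)) / 255
    rgb <- array(0, dim = c(dim(gray), 3L))
    for (c in 1:3) {
      hc <- matrix(heat[, c], nrow(gray), ncol(gray))
      rgb[, , c] <- pmin(pmax((1 - alpha) * gray + alpha * hc, 0), 1)
    }
    png::writePNG(rgb, file.path(out_dir, sprintf("slice_%03d_gradcam.png", si)))
  }
  invisible(rk$ranking)
}
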