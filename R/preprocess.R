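# Slice preprocessing: resize -> 0-255 min-max rescale -> global histogram
# equalization, then ImageNet-style tensorization and train-time augmentation.

IMAGENET_MEAN <- c(0.485, 0.456, 0.406)
IMAGENET_SD   <- c(0.229, 0.224, 0.225)

#' Standardize a raw grayscale slice
#'
#' Resizes (bilinear) to `image_size` x `image_size`, min-max rescales to
#' \[0, 255\] (a constant image is left unchanged), and applies global 256-bin
#' histogram equalization via the cumulative-distribution mapping
#' `floor(255 * cdf(v))`. A single-valued image passes through equalization
#' unchanged, so degenerate dynamic range never divides by zero.
#'
#' @param raw numeric matrix of intensities (any range; 8-bit expected).
#' @param image_size output side length in pixels.
#' @param subject_id,slice_index identification carried along (slice_index is
#'   0-based).
#' @return A `slice_image`: list with integer `pixels` in \[0, 255\],
#'   `subject_id`, `slice_index`.
#' @export
standardize_slice <- function(raw, image_size = 224L, subject_id = NA_character_,
                              slice_index = NA_integer_) {
  if (!is.matrix(raw) || any(dim(raw) == 0L)) stopf("raw slice must be a nonempty 2-D matrix")
  image_size <- assert_count(image_size, "image_size", min = 1L)
  x <- raw * 1.0
  if (!all(dim(x) == c(image_size, image_size))) {
    x <- EBImage::resize(x, w = image_size, h = image_size, filter = "bilinear")
    x <- matrix(as.numeric(x), image_size, image_size)
  }
  rng <- range(x)
  if (rng[2] > rng[1]) x <- (x - rng[1]) / (rng[2] - rng[1]) * 255
  v <- matrix(as.integer(pmin(pmax(round(x), 0), 255)), image_size, image_size)
  lv <- sort(unique(as.vector(v)))
  if (length(lv) > 1L) {
    counts <- tabulate(as.vector(v) + 1L, nbins = 256L)
    cdf <- cumsum(counts) / length(v)
    map <- as.integer(floor(255 * cdf))      # 256-bin CDF mapping
    v <- matrix(map[v + 1L], image_size, image_size)
  }
  structure(list(pixels = v, subject_id = subject_id,
                 slice_index = as.integer(slice_index)),
            class = "slice_image")
}

#' Convert a standardized slice to a model-ready tensor
#'
#' Replicates the grayscale channel to 3 channels, scales to \[0, 1\], and
#' normalizes per channel with the ImageNet statistics (means 0.485/0.456/0.406,
#' sds 0.229/0.224/0.225) expected by ImageNet-pretrained backbones.
#'
#' @param slice a `slice_image` from [standardize_slice()], or a matrix of
#'   8-bit intensities.
#' @return numeric array of dim `c(H, W, 3)`.
#' @export
to_model_tensor <- function(slice) {
  px <- if (inherits(slice, "slice_image")) slice$pixels else slice
  if (!is.matrix(px)) stopf("slice must be a slice_image or a matrix")
  x <- px / 255
  out <- array(0, dim = c(nrow(px), ncol(px), 3L))
  for (c in 1:3) out[, , c] <- (x - IMAGENET_MEAN[c]) / IMAGENET_SD[c]
  out
}

#' Invert ImageNet normalization back to the \[0, 1\] grayscale
#' @param tensor array `c(H, W, 3)` as produced by [to_model_tensor()].
#' @return numeric matrix in \[0, 1\] (channel 1; channels are replicas).
#' @export
from_model_tensor <- function(tensor) {
  tensor[, , 1L] * IMAGENET_SD[1L] + IMAGENET_MEAN[1L]
}

#' Train-time augmentation policy
#'
#' @param p_hflip,p_vflip probabilities of horizontal / vertical mirroring.
#' @param brightness_jitter,contrast_jitter maximal relative perturbation `b`;
#'   factors are drawn uniformly from `[1 - b, 1 + b]`.
#' @return An `augment_policy` object.
#' @export
augment_policy <- function(p_hflip = 0.5, p_vflip = 0.5,
                           brightness_jitter = 0.2, contrast_jitter = 0.2) {
  pol <- list(p_hflip = assert_number(p_hflip, "p_hflip", 0, 1),
              p_vflip = assert_number(p_vflip, "p_vflip", 0, 1),
              brightness_jitter = assert_number(brightness_jitter, "brightness_jitter", 0),
              contrast_jitter = assert_number(contrast_jitter, "contrast_jitter", 0))
  class(pol) <- "augment_policy"
  pol
}

flip_h <- function(tensor) tensor[, rev(seq_len(dim(tensor)[2])), , drop = FALSE]
flip_v <- function(tensor) tensor[rev(seq_len(dim(tensor)[1])), , , drop = FALSE]

#' Apply stochastic train-time augmentation to one slice tensor
#'
#' With probability `p_hflip` mirrors left-right and independently with
#' `p_vflip` top-bottom; then scales brightness and contrast by factors drawn
#' uniformly from the jitter intervals (applied on the \[0, 1\] grayscale
#' scale, i.e. the tensor is de-normalized, perturbed with clipping to
#' \[0, 1\], and re-normalized). Deterministic given `seed`.
#'
#' @param tensor model-ready array `c(H, W, 3)`.
#' @param policy an [augment_policy()].
#' @param seed integer seed for the draw.
#' @return augmented tensor, same shape.
#' @export
augment_train <- function(tensor, policy, seed) {
  stopifnot(inherits(policy, "augment_policy"))
  draws <- with_seed(seed, list(
    hflip = stats::runif(1) < policy$p_hflip,
    vflip = stats::runif(1) < policy$p_vflip,
    fb = stats::runif(1, 1 - policy$brightness_jitter, 1 + policy$brightness_jitter),
    fc = stats::runif(1, 1 - policy$contrast_jitter, 1 + policy$contrast_jitter)
  ))
  if (!draws$hflip && !draws$vflip && draws$fb == 1 && draws$fc == 1) return(tensor)
  if (draws$hflip) tensor <- flip_h(tensor)
  if (draws$vflip) tensor <- flip_v(tensor)
  if (draws$fb != 1 || draws$fc != 1) {
    g <- from_model_tensor(tensor)
    g <- pmin(pmax(g * draws$fb, 0), 1)                     # brightness
    g <- pmin(pmax((g - mean(g)) * draws$fc + mean(g), 0), 1)  # contrast
    out <- array(0, dim = dim(tensor))
    for (c in 1:3) out[, , c] <- (g - IMAGENET_MEAN[c]) / IMAGENET_SD[c]
    tensor <- out
  }
  tensor
}

#' Assemble a bag from a subject's slice folder
#'
#' Loads every PNG in explicit lexicographic filename order (zero-padded
#' indices make this the stack order), standardizes, tensorizes, and stacks
#' them into the bag array.
#'
#' @param folder directory of 8-bit grayscale PNG slices.
#' @param subject_id subject identifier (defaults to the folder name).
#' @param label `"positive"`, `"negative"`, or `NA` for unlabeled bags.
#' @param image_size standardization size.
#' @return A `mil_bag`: list with `subject_id`, `label`, and `slices`, an
#'   array of dim `c(H, W, 3, K)` in slice order.
#' @export
assemble_bag <- function(folder, subject_id = basename(folder), label = NA,
                         image_size = 224L) {
  if (!dir.exists(folder)) stopf("subject folder does not exist: '%s'", folder)
  files <- sort(list.files(folder, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stopf("empty bag: no PNG slices in '%s'", folder)
  label <- normalize_label(label, allow_na = TRUE)
  tensors <- vector("list", length(files))
  for (i in seq_along(files)) {
    px <- tryCatch(png::readPNG(files[i]), error = function(e)
      stopf("cannot read slice file '%s': %s", files[i], conditionMessage(e)))
    if (length(dim(px)) == 3L) px <- px[, , 1L]  # tolerate RGB(A) input
    sl <- standardize_slice(px * 255, image_size = image_size,
                            subject_id = subject_id, slice_index = i - 1L)
    tensors[[i]] <- to_model_tensor(sl)
  }
  new_bag(subject_id, label, tensors)
}

#' Construct a bag from in-memory slice tensors
#' @param subject_id subject identifier.
#' @param label `"positive"`, `"negative"`, or `NA`.
#' @param tensors list of arrays `c(H, W, 3)`, in slice order.
#' @return a `mil_bag`.
#' @export
new_bag <- function(subject_id, label, tensors) {
  if (length(tensors) == 0L) stopf("a bag must contain at least one slice")
  dims <- dim(tensors[[1]])
  if (length(dims) != 3L || dims[3] != 3L) stopf("slice tensors must have dim c(H, W, 3)")
  for (t in tensors) if (!identical(dim(t), dims)) stopf("all slices in a bag must share shape")
  slices <- array(unlist(tensors, use.names = FALSE), dim = c(dims, length(tensors)))
  structure(list(subject_id = as.character(subject_id),
                 label = normalize_label(label, allow_na = TRUE),
                 slices = slices),
            class = "mil_bag")
}

#' @export
print.mil_bag <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("<mil_bag> subject %s, label %s, %d slices of %dx%d\n",
              x$subject_id, x$label, d[4], d[1], d[2]))
  invisible(x)
}

#' Number of slices in a bag
#' @param bag a `mil_bag`.
#' @return integer slice count K.
#' @export
bag_size <- function(bag) dim(bag$slices)[4]

#' Load every bag listed in a manifest (optionally one split)
#' @param manifest manifest data.frame.
#' @param split if given, restrict to that split.
#' @param image_size standardization size.
#' @return named list of `mil_bag` objects.
#' @export
load_bags <- function(manifest, split = NULL, image_size = 224L) {
  if (!is.null(split)) manifest <- manifest[manifest$split == split, , drop = FALSE]
  if (nrow(manifest) == 0L) stopf("no subjects to load")
  bags <- lapply(seq_len(nrow(manifest)), function(i)
    assemble_bag(manifest$path[i], subject_id = manifest$subject_id[i],
                 label = manifest$label[i], image_size = image_size))
  names(bags) <- manifest$subject_id
  bags
}
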