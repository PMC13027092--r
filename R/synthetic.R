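# Synthetic cohort generator: seeded slice-stack phantoms with planted focal
# lesions, written in the on-disk layout the pipeline consumes (one PNG folder
# per subject + CSV manifest + JSON ground truth).

#' Configuration for a synthetic MRI cohort
#'
#' Describes a cohort of slice-stack "bags": per-subject axial stacks of 8-bit
#' grayscale slices over a procedural pelvic background (two symmetric
#' elliptical joint regions on a smooth gradient plus Gaussian noise).
#' Positive subjects carry a contiguous run of lesion-bearing slices with a
#' bright focal blob planted inside one joint region, emulating the sparse,
#' patchy distribution of bone marrow edema; negative subjects have no
#' lesions.
#'
#' @param n_positive,n_negative subject counts per class (positive = inflamed).
#' @param slices_min,slices_max bounds on slices per bag; at least 25, matching
#'   the minimum stack size the pipeline assumes.
#' @param image_size pixels per side of each square slice.
#' @param lesion_fraction_range closed interval in (0, 1]: the fraction of a
#'   positive bag's slices that carry lesions is drawn uniformly from it.
#' @param lesion_contrast mean intensity elevation (8-bit units) of the lesion
#'   disc over the same location on a lesion-free slice.
#' @param lesion_radius_px radius (pixels) of the lesion's flat core; the blob
#'   falls off with a Gaussian skirt (sigma = radius / 2) beyond the core.
#' @param noise_sd standard deviation of additive Gaussian noise (8-bit units).
#' @param seed integer seed; the cohort is a pure function of the config.
#' @return An object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_positive = 2, n_negative = 2, image_size = 32,
#'                      lesion_radius_px = 3)
cohort_config <- function(n_positive, n_negative,
                          slices_min = 25L, slices_max = 60L,
                          image_size = 224L,
                          lesion_fraction_range = c(0.10, 0.30),
                          lesion_contrast = 80,
                          lesion_radius_px = 12,
                          noise_sd = 10,
                          seed = 1L) {
  cfg <- list(
    n_positive = assert_count(n_positive, "n_positive"),
    n_negative = assert_count(n_negative, "n_negative"),
    slices_min = assert_count(slices_min, "slices_min", min = 25L),
    slices_max = assert_count(slices_max, "slices_max", min = 25L),
    image_size = assert_count(image_size, "image_size", min = 8L),
    lesion_fraction_range = as.numeric(lesion_fraction_range),
    lesion_contrast = assert_number(lesion_contrast, "lesion_contrast", min = 0, strict_min = TRUE),
    lesion_radius_px = assert_number(lesion_radius_px, "lesion_radius_px", min = 1),
    noise_sd = assert_number(noise_sd, "noise_sd", min = 0),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (cfg$slices_min > cfg$slices_max)
    stopf("slices_min (%d) must not exceed slices_max (%d)", cfg$slices_min, cfg$slices_max)
  fr <- cfg$lesion_fraction_range
  if (length(fr) != 2L || any(!is.finite(fr)) || fr[1] <= 0 || fr[2] > 1 || fr[1] > fr[2])
    stopf("lesion_fraction_range must be an interval within (0, 1]")
  class(cfg) <- "cohort_config"
  cfg
}

# Fixed joint-region geometry, relative to image size. Two symmetric ellipses
# stand in for the sacroiliac joints; lesions are planted inside one of them.
joint_geometry <- function(image_size) {
  s <- image_size
  list(
    centers = rbind(left  = c(row = 0.52 * s, col = 0.30 * s),
                    right = c(row = 0.52 * s, col = 0.70 * s)),
    semi_axes = c(row = 0.16 * s, col = 0.09 * s)
  )
}

# Procedural anatomical background: a wide smooth intensity ramp plus
# brighter elliptical joint regions. The ramp deliberately populates the
# whole 8-bit histogram: global histogram equalization (the prescribed
# preprocessing) preserves local lesion contrast only where intermediate
# intensities carry mass, as they do on real fat-suppressed T2 slices.
# Deterministic (noise is added by the caller).
synthetic_background <- function(image_size) {
  s <- image_size
  rows <- matrix(seq_len(s), s, s)
  cols <- matrix(seq_len(s), s, s, byrow = TRUE)
  bg <- 25 + 160 * (rows / s)
  geo <- joint_geometry(s)
  for (side in seq_len(nrow(geo$centers))) {
    ctr <- geo$centers[side, ]
    d2 <- ((rows - ctr["row"]) / geo$semi_axes["row"])^2 +
          ((cols - ctr["col"]) / geo$semi_axes["col"])^2
    bg <- bg + 30 * (d2 <= 1)
  }
  bg
}

# Lesion intensity profile: flat core of the configured radius with a Gaussian
# skirt, so the mean elevation inside the nominal lesion disc equals
# lesion_contrast exactly (before clipping).
lesion_profile <- function(image_size, center, radius) {
  s <- image_size
  rows <- matrix(seq_len(s), s, s)
  cols <- matrix(seq_len(s), s, s, byrow = TRUE)
  r <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  sigma <- radius / 2
  prof <- exp(-pmax(r - radius, 0)^2 / (2 * sigma^2))
  prof[r <= radius] <- 1
  prof
}

#' Generate one synthetic slice-stack bag
#'
#' Builds a single subject's stack of 8-bit slices: procedural background plus
#' Gaussian noise; for a positive label, a contiguous run of
#' `ceiling(f * n_slices)` slices (f drawn from `lesion_fraction_range`)
#' receives a bright focal blob centered inside one joint region.
#'
#' @param label `"positive"` or `"negative"`.
#' @param n_slices number of slices; must lie in `[slices_min, slices_max]`.
#' @param config a [cohort_config()].
#' @param seed integer seed for this bag's random stream.
#' @return A list with `slices` (list of `image_size x image_size` integer
#'   matrices in \[0, 255\]) and `ground_truth` (subject-level truth: `label`,
#'   0-based `lesion_slice_indices`, and per-lesion-slice `lesion_centers`
#'   as (row, col) pixel coordinates).
#' @export
generate_bag <- function(label, n_slices, config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  label <- normalize_label(label)
  n_slices <- assert_count(n_slices, "n_slices")
  if (n_slices < config$slices_min || n_slices > config$slices_max)
    stopf("n_slices = %d outside configured bounds [%d, %d]",
          n_slices, config$slices_min, config$slices_max)

  s <- config$image_size
  with_seed(seed, {
    lesion_idx <- integer(0)
    centers <- NULL
    if (label == "positive") {
      f <- stats::runif(1, config$lesion_fraction_range[1], config$lesion_fraction_range[2])
      n_les <- min(n_slices, max(1L, as.integer(ceiling(f * n_slices))))
      start <- sample.int(n_slices - n_les + 1L, 1L)
      lesion_idx <- seq.int(start, length.out = n_les)  # 1-based internally
      geo <- joint_geometry(s)
      side <- sample.int(2L, 1L)
      base_ctr <- geo$centers[side, ]
      jit <- stats::runif(2, -0.03 * s, 0.03 * s)
      base_ctr <- base_ctr + jit
      centers <- t(vapply(lesion_idx, function(i) {
        base_ctr + stats::runif(2, -0.01 * s, 0.01 * s)
      }, numeric(2)))
      colnames(centers) <- c("row", "col")
    }
    bg <- synthetic_background(s)
    slices <- vector("list", n_slices)
    for (i in seq_len(n_slices)) {
      img <- bg + stats::rnorm(s * s, sd = config$noise_sd)
      li <- match(i, lesion_idx)
      if (!is.na(li)) {
        img <- img + config$lesion_contrast *
          lesion_profile(s, centers[li, ], config$lesion_radius_px)
      }
      slices[[i]] <- matrix(as.integer(round(pmin(pmax(img, 0), 255))), s, s)
    }
    list(
      slices = slices,
      ground_truth = list(
        label = label,
        lesion_slice_indices = as.integer(lesion_idx - 1L),  # 0-based on disk
        lesion_centers = centers
      )
    )
  })
}

#' Generate a synthetic cohort on disk
#'
#' Writes one folder of zero-padded 8-bit grayscale PNG slices per subject
#' (lexicographic filename order equals stack order), a cohort manifest CSV
#' (`subject_id,label,split,n_slices,path`), and a ground-truth JSON mapping
#' subject id to planted-lesion slice indices and centers. Fully determined by
#' `config$seed`: each subject draws from a derived stream `seed + index`, so
#' enlarging a cohort never reshuffles existing subjects.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if missing).
#' @param write_images if `FALSE`, only the manifest and ground truth are
#'   written (useful for split planning at full cohort scale without image I/O).
#' @return The manifest as a data.frame (invisibly also written to
#'   `manifest.csv`; ground truth to `ground_truth.json`). The `split` column
#'   is `"unassigned"` until [split_patients()] fills it.
#' @export
generate_cohort <- function(config, out_dir, write_images = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  assert_flag(write_images, "write_images")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stopf("cannot create output directory '%s'", out_dir)
  }
  n_total <- config$n_positive + config$n_negative
  labels <- rep(c("positive", "negative"), c(config$n_positive, config$n_negative))
  ids <- sprintf("%s%03d", ifelse(labels == "positive", "pos", "neg"),
                 c(seq_len(config$n_positive), seq_len(config$n_negative)))

  manifest <- data.frame(subject_id = ids, label = labels, split = "unassigned",
                         n_slices = NA_integer_, path = NA_character_,
                         stringsAsFactors = FALSE)
  truth <- vector("list", n_total)
  names(truth) <- ids
  for (i in seq_len(n_total)) {
    subj_seed <- config$seed + i
    n_slices <- with_seed(subj_seed * 2L + 1L,
                          sample.int(config$slices_max - config$slices_min + 1L, 1L) +
                            config$slices_min - 1L)
    folder <- file.path(out_dir, ids[i])
    manifest$n_slices[i] <- n_slices
    manifest$path[i] <- folder
    if (write_images) {
      bag <- generate_bag(labels[i], n_slices, config, seed = subj_seed)
      dir.create(folder, showWarnings = FALSE)
      for (k in seq_len(n_slices)) {
        png::writePNG(bag$slices[[k]] / 255,
                      file.path(folder, sprintf("slice_%03d.png", k - 1L)))
      }
      gt <- bag$ground_truth
    } else {
      # draw ground truth through the same stream without synthesizing pixels
      gt <- with_seed(subj_seed, {
        lesion_idx <- integer(0)
        if (labels[i] == "positive") {
          f <- stats::runif(1, config$lesion_fraction_range[1], config$lesion_fraction_range[2])
          n_les <- min(n_slices, max(1L, as.integer(ceiling(f * n_slices))))
          start <- sample.int(n_slices - n_les + 1L, 1L)
          lesion_idx <- seq.int(start, length.out = n_les)
        }
        list(label = labels[i], lesion_slice_indices = as.integer(lesion_idx - 1L),
             lesion_centers = NULL)
      })
    }
    truth[[i]] <- list(
      label = gt$label,
      lesion_slice_indices = gt$lesion_slice_indices,
      lesion_centers = if (is.null(gt$lesion_centers)) list() else
        apply(gt$lesion_centers, 1L, function(r) as.numeric(r), simplify = FALSE)
    )
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Read a cohort manifest CSV
#' @param path path to `manifest.csv` (or a cohort directory containing it).
#' @return manifest data.frame.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  if (!file.exists(path)) stopf("manifest not found: '%s'", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "split", "n_slices", "path")
  if (!all(need %in% names(m))) stopf("manifest lacks columns: %s",
                                      paste(setdiff(need, names(m)), collapse = ", "))
  m
}

#' Read the planted-lesion ground truth of a synthetic cohort
#' @param path path to `ground_truth.json` (or the cohort directory).
#' @return named list: per subject, `label`, integer `lesion_slice_indices`
#'   (0-based) and `lesion_centers`.
#' @export
read_ground_truth <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "ground_truth.json")
  gt <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(gt, function(g) list(
    label = g$label,
    lesion_slice_indices = as.integer(unlist(g$lesion_slice_indices)),
    lesion_centers = lapply(g$lesion_centers, function(ctr) as.numeric(unlist(ctr)))
  ))
}

#' Patient-wise train/validation/test split
#'
#' Assigns each subject to exactly one split, with requested per-class counts,
#' shuffled deterministically by `seed`. Splitting is at the patient level:
#' a subject id can never appear in two splits, which is the leakage guard the
#' whole evaluation rests on.
#'
#' @param manifest cohort manifest data.frame.
#' @param split_counts named list `list(train = c(pos, neg), val = c(pos, neg),
#'   test = c(pos, neg))`; per-class counts must sum to the class totals.
#' @param seed integer seed for the shuffle.
#' @return The manifest with its `split` column filled.
#' @export
#' @examples
#' m <- data.frame(subject_id = c("p1", "p2", "n1", "n2"),
#'                 label = c("positive", "positive", "negative", "negative"),
#'                 split = "unassigned", n_slices = 25L, path = ".")
#' split_patients(m, list(train = c(1, 1), val = c(0, 0), test = c(1, 1)), seed = 7)
split_patients <- function(manifest, split_counts, seed = 1L) {
  need <- c("train", "val", "test")
  if (!is.list(split_counts) || !setequal(names(split_counts), need))
    stopf("split_counts must be a named list with entries train, val, test")
  counts <- lapply(split_counts[need], function(x) {
    if (length(x) != 2L || any(x < 0) || any(x != as.integer(x)))
      stopf("each split_counts entry must be two nonnegative integers c(pos, neg)")
    as.integer(x)
  })
  if (anyDuplicated(manifest$subject_id))
    stopf("duplicate subject_id in manifest")
  labels <- normalize_label(manifest$label)
  n_pos <- sum(labels == "positive"); n_neg <- sum(labels == "negative")
  req_pos <- sum(vapply(counts, `[`, integer(1), 1L))
  req_neg <- sum(vapply(counts, `[`, integer(1), 2L))
  if (req_pos != n_pos || req_neg != n_neg)
    stopf("requested counts (pos %d, neg %d) do not match cohort totals (pos %d, neg %d)",
          req_pos, req_neg, n_pos, n_neg)

  manifest$split <- NA_character_
  for (cls in c("positive", "negative")) {
    j <- if (cls == "positive") 1L else 2L
    idx <- which(labels == cls)
    perm <- with_seed(seed + j, sample(idx))
    sizes <- vapply(counts, `[`, integer(1), j)
    assign_split <- rep(need, sizes)
    manifest$split[perm] <- assign_split
  }
  manifest
}
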