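# YAML pipeline configuration: one file describing the synthetic cohort, the
# preprocessing, the model, the training protocol and TTA, consumed by the
# command-line entry point (inst/cli/milsij.R) and by scripted experiments.

#' Read a pipeline configuration YAML
#'
#' Recognized top-level keys (all optional; defaults are the package
#' defaults): `cohort` (arguments of [cohort_config()]), `split` (named lists
#' `train`/`val`/`test` of `c(pos, neg)` counts), `preprocess`
#' (`image_size`), `model` ([model_config()] arguments), `train`
#' ([train_config()] arguments, plus `augment: true` to enable the default
#' augmentation policy), `tta` ([tta_config()] arguments).
#'
#' @param path YAML file.
#' @return list with elements `cohort`, `split_counts`, `image_size`,
#'   `model`, `train`, `tta`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: '%s'", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  cohort <- if (!is.null(y$cohort)) do.call(cohort_config, y$cohort) else NULL
  split_counts <- if (!is.null(y$split))
    lapply(y$split, function(x) as.integer(unlist(x))) else NULL
  image_size <- if (!is.null(y$preprocess$image_size))
    as.integer(y$preprocess$image_size)
  else if (!is.null(cohort)) cohort$image_size else 224L
  model <- do.call(model_config, if (is.null(y$model)) list() else y$model)
  train_args <- if (is.null(y$train)) list() else y$train
  if (isTRUE(train_args$augment)) train_args$augment <- augment_policy()
  if (isFALSE(train_args$augment)) train_args$augment <- NULL
  train <- do.call(train_config, train_args)
  tta <- do.call(tta_config, if (is.null(y$tta)) list() else y$tta)
  list(cohort = cohort, split_counts = split_counts, image_size = image_size,
       model = model, train = train, tta = tta)
}
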