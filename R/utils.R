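# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state on exit, so library functions never perturb the
#' user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  seed <- as.integer(seed)  # force now: the promise may itself consume RNG
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) stopf("`%s` must be TRUE or FALSE", name)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != as.integer(x))
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

assert_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_min) x > min else x >= min) && x <= max
  if (!ok) stopf("`%s` must be a single number in [%s, %s]", name,
                 format(min), format(max))
  as.numeric(x)
}

#' Normalized label vocabulary: "positive" (inflamed) / "negative" (healthy)
#' @noRd
normalize_label <- function(label, allow_na = FALSE) {
  if (allow_na && (is.null(label) || length(label) == 0L || is.na(label))) return(NA_character_)
  lab <- tolower(as.character(label))
  map <- c(positive = "positive", pos = "positive", inflamed = "positive", "1" = "positive",
           negative = "negative", neg = "negative", healthy = "negative", "0" = "negative")
  out <- unname(map[lab])
  if (any(is.na(out))) stopf("unrecognized label: %s", paste(lab[is.na(out)], collapse = ", "))
  out
}

# class index convention used throughout: 1 = negative (healthy), 2 = positive
label_to_index <- function(label) ifelse(normalize_label(label) == "positive", 2L, 1L)

CLASS_NAMES <- c("negative", "positive")
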