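#' Default added-contrast set of the two-interval discrimination design
#'
#' The four contrast increments added to the baseline Gabor contrast in the
#' study design this package models. All model functions take an explicit
#' `contrasts` argument that defaults to this set.
#'
#' @return A sorted numeric vector of length four.
#' @export
#' @examples
#' default_contrasts()
default_contrasts <- function() c(0.015, 0.035, 0.07, 0.15)

# Deterministic 32-bit substream seed derived from a root seed and a label
# path, so that every random step of a pipeline is independently replayable.
substream_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- abs(as.numeric(seed)) %% 2147483647
  label <- paste(c(...), collapse = "/")
  if (nzchar(label)) {
    for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Run `code` under a derived substream seed without touching the caller's RNG
# state. With seed = NULL the code runs on the ambient RNG stream.
with_substream <- function(seed, ..., code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(substream_seed(seed, ...), code)
}

# round-half-up, used for all sample-count targets so the R and C++ paths
# place thresholds identically (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

log_sum_exp <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Enumerate the stimulus conditions of a design
#'
#' Crosses the two target intervals with the contrast set, in a fixed order
#' (interval 1 then 2, contrasts ascending) used consistently by the sample
#' pools, cell tables and the Monte-Carlo likelihood kernel.
#'
#' @param contrasts Numeric vector of added-contrast values.
#' @return A tibble with columns `interval` and `contrast`, one row per
#'   condition.
#' @export
condition_grid <- function(contrasts = default_contrasts()) {
  check_contrast_set(contrasts)
  tidyr::expand_grid(interval = c(1L, 2L), contrast = sort(contrasts))
}

condition_index <- function(interval, contrast, contrasts) {
  contrasts <- sort(contrasts)
  k <- match(contrast, contrasts)
  if (anyNA(k)) {
    abort("contrast value not in the configured contrast set",
          class = "confbms_error_invalid_input")
  }
  (as.integer(interval) - 1L) * length(contrasts) + k
}

check_contrast_set <- function(contrasts) {
  if (length(contrasts) == 0L || !is.numeric(contrasts) ||
      anyNA(contrasts) || any(contrasts <= 0)) {
    abort("`contrasts` must be a nonempty set of positive reals",
          class = "confbms_error_invalid_parameter")
  }
  invisible(contrasts)
}

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    abort("`sigma` must be a single positive number",
          class = "confbms_error_invalid_parameter")
  }
  invisible(sigma)
}

check_model <- function(model) {
  if (length(model) != 1L || !model %in% c("difference", "max", "bayes")) {
    abort('`model` must be one of "difference", "max", "bayes"',
          class = "confbms_error_invalid_parameter")
  }
  model
}

model_code <- function(model) {
  match(check_model(model), c("difference", "max", "bayes")) - 1L
}

check_decision <- function(decision) {
  if (anyNA(decision) || !all(decision %in% c(1, 2))) {
    abort("decisions must be 1 or 2", class = "confbms_error_invalid_parameter")
  }
  as.integer(decision)
}

# flatten a 2x6 (decision x confidence) cell matrix row-major:
# (d=1,c=1..6), (d=2,c=1..6) -- the canonical cell order everywhere
flatten_cells <- function(m) as.vector(t(m))
unflatten_cells <- function(v) matrix(v, nrow = 2L, ncol = 6L, byrow = TRUE,
                                      dimnames = list(decision = c("1", "2"),
                                                      confidence = as.character(1:6)))
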