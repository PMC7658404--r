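# Condition classes: the pipeline wrapper maps these onto process exit codes
# (config/usage -> 2, data validation -> 3, internal invariant breach -> 4).

abort_config <- function(message, ...) {
  rlang::abort(message, class = "reopairs_config_error", ...)
}

abort_data <- function(message, ...) {
  rlang::abort(message, class = "reopairs_data_error", ...)
}

abort_internal <- function(message, ...) {
  rlang::abort(message, class = "reopairs_internal_error", ...)
}

# "a, b, c, ... (12 total)" -- for error messages that name offenders
fmt_ids <- function(x, max_show = 5L) {
  shown <- paste(utils::head(x, max_show), collapse = ", ")
  if (length(x) > max_show) {
    shown <- sprintf("%s, ... (%d total)", shown, length(x))
  }
  shown
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# All package randomness flows through this: one integer seed, Mersenne-Twister,
# restoring the caller's RNG state afterwards.
with_rng <- function(seed, code) {
  if (!is_count(seed) || seed >= 2^31) {
    abort_config("`seed` must be a single non-negative integer below 2^31.")
  }
  withr::with_seed(
    as.integer(seed), code,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}
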