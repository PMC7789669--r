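# Internal validation helpers. All user-facing configuration errors are
# classed conditions so callers (and tests) can match on class rather than
# message wording.

stop_config <- function(field, msg) {
  abort(sprintf("invalid configuration: field '%s' %s", field, msg),
        class = "anaerodesign_config_error", field = field)
}

check_count <- function(x, field, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    stop_config(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(x)
}

check_rate <- function(x, field) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop_config(field, "must be a single probability in [0, 1]")
  }
  as.numeric(x)
}

check_fraction <- function(x, field, lo = 0, hi = 1, lo_open = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && x <= hi
  if (!ok) {
    stop_config(field, sprintf("must be a single value in %s%g, %g]",
                               if (lo_open) "(" else "[", lo, hi))
  }
  as.numeric(x)
}

check_flag <- function(x, field) {
  if (length(x) != 1L || !is.logical(x) || is.na(x)) {
    stop_config(field, "must be TRUE or FALSE")
  }
  x
}

check_string <- function(x, field) {
  if (length(x) != 1L || !is.character(x) || is.na(x) || !nzchar(x)) {
    stop_config(field, "must be a single non-empty string")
  }
  x
}

# Seeds handed to set.seed() must stay inside the 32-bit integer range.
check_seed <- function(x, field = "seed") {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x)) {
    stop_config(field, "must be a single integer")
  }
  as.integer(x %% .Machine$integer.max)
}

# Derive a reproducible child seed from a base seed and an index without
# touching the global RNG more than once.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 1103) %%
               .Machine$integer.max)
}
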