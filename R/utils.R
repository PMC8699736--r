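# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Ordered harm categories used throughout the error-grid module.
harm_levels <- function() c("none", "mild", "moderate", "severe")

# Deterministic per-device seed so that adding or removing a device from a
# simulation never perturbs the random stream of the other devices.
device_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) * 131
  as.integer((as.numeric(seed) + h) %% (.Machine$integer.max - 1))
}

strand_seed <- function(seed, strand) {
  device_seed(seed, paste0("strand:", strand))
}

stop_if_not_number <- function(x, what, lo = -Inf, strict_lo = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", what), call. = FALSE)
  }
  if (strict_lo && x <= lo) {
    stop(sprintf("`%s` must be > %s", what, lo), call. = FALSE)
  }
  if (!strict_lo && x < lo) {
    stop(sprintf("`%s` must be >= %s", what, lo), call. = FALSE)
  }
  invisible(x)
}
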