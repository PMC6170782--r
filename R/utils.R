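# Shared helpers.

# Expand a single global seed deterministically into per-component streams
# so modules can be tested in isolation.  Result stays below 2^31.
derive_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

gaussian_kernel <- function(sigma, half = max(1L, ceiling(3 * sigma))) {
  xs <- -half:half
  k <- exp(-xs^2 / (2 * sigma^2))
  k / sum(k)
}

log_msg <- function(level, ...) {
  msg <- sprintf("[%s] %s %s", level, format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(..., collapse = ""))
  message(msg)
  invisible(msg)
}
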