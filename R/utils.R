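# Internal helpers shared across modules.

# Classed error so callers can distinguish failure modes with
# tryCatch()/expect_error(class = ...). `class` is one of the
# module-level error classes, e.g. "acdosim_invalid_input".
abort_acdosim <- function(message, class) {
  stop(errorCondition(message, class = c(class, "acdosim_error")))
}

stopifnot_scalar_positive <- function(x, name, class = "acdosim_invalid_input") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_acdosim(sprintf("`%s` must be a single positive finite number", name), class)
  }
  invisible(x)
}

# Population (divide-by-n) standard deviation; cohort summaries use this
# convention rather than the n-1 sample estimator.
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  sqrt(mean((x - mean(x))^2))
}

# Derive a component sub-seed from a master seed, staying within 32-bit
# integer range so set.seed() accepts it.
derive_seed <- function(master, component) {
  stopifnot(is.numeric(master), length(master) == 1L)
  offsets <- c(image = 11L, tac = 23L, urine = 37L, calibration = 53L, cohort = 71L)
  off <- if (component %in% names(offsets)) offsets[[component]] else abs(sum(utf8ToInt(component)))
  as.integer((abs(master) * 7919 + off) %% 2147483647)
}
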