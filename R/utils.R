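# internal helpers shared across modules

# classed error helpers so callers can distinguish failure modes
stop_parameter <- function(msg, ...) {
  abort(msg, class = "motorpool_error_parameter", ...)
}
stop_geometry <- function(msg, ...) {
  abort(msg, class = "motorpool_error_geometry", ...)
}
stop_insufficient <- function(msg, ...) {
  abort(msg, class = "motorpool_error_insufficient_data", ...)
}
stop_format <- function(msg, ...) {
  abort(msg, class = "motorpool_error_format", ...)
}

# run code under a seed without disturbing the caller's RNG state;
# seed = NULL leaves the RNG stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# deterministic child seeds (kept within 32-bit integer range)
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %%
               2147483629)
}

# 2x2 rotation matrix
rotation2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

check_xy <- function(data, what = "points") {
  if (!is.data.frame(data) || !all(c("x", "y") %in% names(data))) {
    stop_parameter(sprintf("`%s` must be a data frame with columns `x` and `y`.", what))
  }
  if (!all(is.finite(data$x)) || !all(is.finite(data$y))) {
    stop_parameter(sprintf("`%s` contains non-finite coordinates.", what))
  }
  invisible(data)
}

sem <- function(x) sd(x) / sqrt(length(x))
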