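#' Derive a stage seed from a master seed
#'
#' All pipeline stages draw their randomness from seeds derived
#' deterministically from one master seed and the stage name, so stages are
#' reproducible in isolation while remaining statistically independent.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps seeds valid R integers
  h <- as.double(master %% m)
  for (ch in utf8ToInt(stage)) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field, open_right = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && x >= 0 && (if (open_right) x < 1 else x <= 1)
  if (!ok) stop_config(field, if (open_right) "must lie in [0, 1)" else "must lie in [0, 1]")
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && x == as.integer(x) && x >= min
  if (!ok) stop_config(field, sprintf("must be an integer >= %d", min))
  invisible(as.integer(x))
}

# row-binding for lists of equal-length numeric vectors without dependencies
rbind_list <- function(lst) do.call(rbind, lst)
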