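# Internal helpers shared across modules.

# Stage-tagged, timestamped log line on stderr.
ec_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s | %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage,
                  sprintf(fmt, ...)))
}

ec_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ec_stop("'%s' must be a single finite number", name)
  if (x < min || x > max)
    ec_stop("'%s' must be in [%s, %s], got %s", name, min, max, x)
  invisible(as.numeric(x))
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != trunc(x))
    ec_stop("'%s' must be a single non-negative integer", name)
  if (x < min) ec_stop("'%s' must be >= %d", name, min)
  invisible(as.integer(x))
}
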