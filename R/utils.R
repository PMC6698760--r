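# Internal helpers: classed conditions, scoped RNG, quadrature.

kb_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("kbdvh_", class), "kbdvh_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

kb_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(paste0("kbdvh_", class), "kbdvh_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Counted events (clamps, subsamples, out-of-extent voxels) surfaced at INFO
# level; never alter results silently.
kb_log <- function(msg, ...) {
  if (isTRUE(getOption("kbdvh.verbose", TRUE))) message("[kbdvh] ", sprintf(msg, ...))
  invisible(NULL)
}

# Run code under a fixed seed without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Trapezoid integral of y over x (uniform or not).
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Cumulative trapezoid integral, same length as x, starting at 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) * diff(x) / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
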