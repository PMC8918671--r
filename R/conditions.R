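# Classed error helpers so callers (and the CLI) can distinguish
# I/O problems, malformed files, and invalid arguments.

stop_io <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("spottype_io_error", "spottype_error")))
}

stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("spottype_format_error", "spottype_error")))
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("spottype_validation_error", "spottype_error")))
}

# Round half away from zero. base::round() rounds half to even, which
# would map a molecule at exactly x.5 pixels inconsistently with the
# "closest output pixel" convention used throughout.
round_half_away <- function(z) sign(z) * floor(abs(z) + 0.5)
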