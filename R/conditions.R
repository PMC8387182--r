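# Classed conditions so callers (and the CLI) can map failures to exit codes.

config_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("echoasd_config_error", "echoasd_error")))
}

format_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("echoasd_format_error", "echoasd_error")))
}

geometry_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("echoasd_geometry_error", "echoasd_error")))
}

numeric_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("echoasd_numeric_error", "echoasd_error")))
}
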