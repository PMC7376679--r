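# Classed error conditions. Every domain error subclasses "seedtrace_error" so
# callers (CLI, import loop) can trap the package's own failures without
# swallowing programming errors.

st_abort <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "seedtrace_error")))
}

st_duplicate   <- function(msg, ...) st_abort("seedtrace_duplicate_key", msg, ...)
st_validation  <- function(msg, ...) st_abort("seedtrace_validation", msg, ...)
st_multiplicity<- function(msg, ...) st_abort("seedtrace_multiplicity", msg, ...)
st_cycle       <- function(msg, ...) st_abort("seedtrace_cycle", msg, ...)
st_unknown     <- function(msg, ...) st_abort("seedtrace_unknown", msg, ...)
st_downstream  <- function(msg, ...) st_abort("seedtrace_downstream_exists", msg, ...)
st_format      <- function(msg, ...) st_abort("seedtrace_format", msg, ...)
st_date        <- function(msg, ...) st_abort("seedtrace_date_parse", msg, ...)
st_incompatible<- function(msg, ...) st_abort("seedtrace_incompatible_selection", msg, ...)
st_usage       <- function(msg, ...) st_abort("seedtrace_usage", msg, ...)
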