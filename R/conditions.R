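# Classed conditions so callers (and the CLI) can map failures to exit codes.

msersStop <- function(subclass, message, call = sys.call(-1)) {
  stop(structure(
    class = c(subclass, "msersError", "error", "condition"),
    list(message = message, call = call)
  ))
}

stopArgument  <- function(message) msersStop("msersArgumentError", message)
stopConfig    <- function(message) msersStop("msersConfigError", message)
stopData      <- function(message) msersStop("msersDataError", message)
stopNumerical <- function(message) msersStop("msersNumericalError", message)
stopCapacity  <- function(message) msersStop("msersCapacityError", message)
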