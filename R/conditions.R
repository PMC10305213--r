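# Classed conditions: validation errors (bad user input / malformed files)
# vs computation errors (valid input the method cannot reduce). The CLI maps
# these to exit codes 2 and 3.

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("aeroperf_validation_error", "aeroperf_error")))
}

stop_compute <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("aeroperf_computation_error", "aeroperf_error")))
}

warn_flag <- function(..., class = "aeroperf_warning") {
  warning(warningCondition(paste0(...), class = class))
}
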