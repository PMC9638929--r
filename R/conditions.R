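# Classed error conditions so callers (and the CLI) can map failure modes
# to exit codes without string-matching messages.

pp_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "polyprof_error", "error")))
}

pp_stop_invalid <- function(msg) pp_stop(msg, "polyprof_invalid_input")
pp_stop_insufficient <- function(msg) pp_stop(msg, "polyprof_insufficient_data")
pp_stop_degenerate <- function(msg) pp_stop(msg, "polyprof_degenerate")
pp_stop_domain <- function(msg) pp_stop(msg, "polyprof_domain_error")
pp_stop_fit <- function(msg) pp_stop(msg, "polyprof_fit_failure")
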