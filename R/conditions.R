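#' @keywords internal
#' @noRd
hs_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "heartsnap_error"), call = call))
}

# exit-code contract used by the CLI: 2 validation, 3 insufficient data,
# 4 configuration
hs_invalid_input <- function(msg) hs_stop(msg, "hs_invalid_input")
hs_insufficient_data <- function(msg) hs_stop(msg, "hs_insufficient_data")
hs_config_error <- function(msg) hs_stop(msg, "hs_config_error")
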