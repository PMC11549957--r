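#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can distinguish bad
# configuration from bad data from a missing runtime.
psefit_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "psefit_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

config_error <- function(message) psefit_error(message, "psefit_config_error")
input_error <- function(message) psefit_error(message, "psefit_input_error")
environment_error <- function(message) psefit_error(message, "psefit_environment_error")
size_error <- function(message) psefit_error(message, "psefit_size_error")
scoring_error <- function(message) psefit_error(message, "psefit_scoring_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# collapse/squish whitespace, used by the segmentation round-trip contract
squish <- function(x) {
  gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", x))
}
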