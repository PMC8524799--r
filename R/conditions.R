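#' Classed error helpers
#'
#' All user-facing failures raised by the package carry one of four condition
#' classes below `kanonet_error`, so that callers (and the command-line
#' wrapper) can map them to distinct exit codes:
#' \describe{
#'   \item{`kanonet_input_error`}{malformed or inconsistent input data
#'     (unknown ids, unparseable values, missing columns).}
#'   \item{`kanonet_parameter_error`}{an invalid tuning parameter
#'     (k out of range, bad weight, bad grid).}
#'   \item{`kanonet_precondition_error`}{a call that violates a documented
#'     precondition (e.g. asking for the distance from a node to a cluster
#'     containing it).}
#'   \item{`kanonet_validation_error`}{an inconsistent derived object
#'     (a partition that does not cover the node set, overlapping clusters).}
#' }
#' @name kanonet-conditions
#' @keywords internal
NULL

stop_input <- function(msg, ...) {
  stop(structure(
    class = c("kanonet_input_error", "kanonet_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_parameter <- function(msg, ...) {
  stop(structure(
    class = c("kanonet_parameter_error", "kanonet_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_precondition <- function(msg, ...) {
  stop(structure(
    class = c("kanonet_precondition_error", "kanonet_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_validation <- function(msg, ...) {
  stop(structure(
    class = c("kanonet_validation_error", "kanonet_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
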