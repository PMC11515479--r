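# Classed conditions so callers and tests can discriminate failure modes.

paco2_stop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "paco2_error"), call = call))
}

stop_invalid_config <- function(msg) paco2_stop("paco2_invalid_config", msg)
stop_domain <- function(msg) paco2_stop("paco2_domain_error", msg)
stop_singular <- function(msg) paco2_stop("paco2_singular_design", msg)
stop_degenerate_scale <- function(msg) paco2_stop("paco2_degenerate_scale", msg)
stop_build <- function(msg) paco2_stop("paco2_build_error", msg)
stop_parse <- function(msg) paco2_stop("paco2_parse_error", msg)
stop_unit <- function(msg) paco2_stop("paco2_unit_error", msg)
stop_schema <- function(msg) paco2_stop("paco2_schema_error", msg)
stop_insufficient <- function(msg) paco2_stop("paco2_insufficient_data", msg)
stop_missing_parameters <- function(msg) paco2_stop("paco2_missing_parameters", msg)
stop_consistency <- function(msg) paco2_stop("paco2_consistency_error", msg)
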