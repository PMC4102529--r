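# Classed error helpers. Every user-facing failure mode gets a stable
# condition class so callers (and the CLI wrapper) can branch on it.

fq_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "fretquant_error"), call = call))
}

fq_validation_error <- function(msg) fq_stop(msg, "fq_validation_error")
fq_format_error     <- function(msg) fq_stop(msg, "fq_format_error")
fq_consistency_error<- function(msg) fq_stop(msg, "fq_consistency_error")
fq_range_error      <- function(msg) fq_stop(msg, "fq_range_error")
fq_degenerate_error <- function(msg) fq_stop(msg, "fq_degenerate_error")
fq_config_error     <- function(msg) fq_stop(msg, "fq_config_error")
fq_fit_error <- function(msg, best = NULL) {
  stop(errorCondition(msg, best = best,
                      class = c("fq_fit_error", "fretquant_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
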