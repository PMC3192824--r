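# Shared internal helpers: constants, condition constructors, formatting.

.kB <- 0.0019872041 # kcal/(mol K)

#' Boltzmann constant in kcal/(mol K)
#'
#' @return The Boltzmann constant used throughout the package,
#'   0.0019872041 kcal/(mol K).
#' @export
boltzmann_kcal <- function() .kB

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed error so callers/tests can discriminate failure modes:
# actipath_input_error, actipath_geometry_error, actipath_selection_error,
# actipath_parse_error, actipath_config_error, actipath_validation_error,
# actipath_integration_error.
abort_ap <- function(msg, class = "actipath_input_error") {
  stop(errorCondition(msg, class = c(class, "actipath_error")))
}

check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    abort_ap(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}

fmt_g <- function(x) sprintf("%.9g", x)

# log(sum(exp(a))) without overflow/underflow; returns -Inf for empty input
logsumexp <- function(a) {
  m <- max(a)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(a - m)))
}
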