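# Classed error conditions shared across the package. Every user-facing
# validation failure carries a condition class so callers (and tests) can
# distinguish bad measurements from bad configuration without parsing text.

cc_stop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "cellcarbon_error", "error"),
                      call = call))
}

stop_invalid_measurement <- function(msg) cc_stop("invalid_measurement_error", msg)
stop_configuration <- function(msg) cc_stop("configuration_error", msg)
stop_degenerate_sample <- function(msg) cc_stop("degenerate_sample_error", msg)
stop_invalid_design <- function(msg) cc_stop("invalid_design_error", msg)
stop_invalid_fractions <- function(msg) cc_stop("invalid_fractions_error", msg)
stop_invalid_composition <- function(msg) cc_stop("invalid_composition_error", msg)
stop_schema <- function(msg) cc_stop("schema_error", msg)

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
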