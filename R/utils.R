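#' Round half away from zero
#'
#' Report-style rounding: .05 at one decimal always rounds up, matching how
#' clinical tables are typically printed (base [round()] rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a child seed from a global seed
#'
#' Deterministic splitting so each pipeline stage can be re-run in isolation
#' with its own reproducible stream. The child is `(seed * 48271 + index)`
#' reduced modulo a Mersenne prime, kept within the 32-bit integer range.
#'
#' @param seed integer global seed.
#' @param index integer stage index (>= 1).
#' @return integer child seed.
#' @export
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + index) %% 2147483647)
}

# internal: evaluate expr under a temporary seed, restoring the RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# internal: stop with a classed validation error
validation_error <- function(msg, field = NULL) {
  stop(structure(
    class = c("glycostrat_validation_error", "error", "condition"),
    list(message = if (is.null(field)) msg else sprintf("%s [field: %s]", msg, field),
         call = sys.call(-1))
  ))
}
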