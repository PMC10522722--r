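#' Round half away from zero
#'
#' Fixed-point rounding with halves going up, matching how accuracy tables
#' are conventionally printed (base `round()` rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop unless all coordinates land on the grid
assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (x < min) abort(sprintf("`%s` must be >= %s.", name, min))
  invisible(x)
}

# derive a reproducible child seed (keeps within 32-bit integer range)
derive_seed <- function(seed, k) {
  (as.integer(seed) + 104729L * as.integer(k)) %% .Machine$integer.max
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# structured logging to stderr; level gate settable via option
.log_levels <- c(debug = 10, info = 20, warning = 30, error = 40)

log_msg <- function(level, ...) {
  gate <- getOption("phenomaize.log_level", "info")
  if (.log_levels[[level]] < .log_levels[[gate]]) return(invisible())
  message(sprintf("[%s] %s %s", toupper(level),
                  format(Sys.time(), "%H:%M:%S"), paste0(...)))
}
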