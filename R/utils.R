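# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
abort_sb <- function(message, class) {
  stop(structure(
    class = c(class, "specbind_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' @keywords internal
#' @noRd
warn_sb <- function(message, class) {
  warning(structure(
    class = c(class, "specbind_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG
# state. All stochastic simulators route through this; there is no other
# use of the global random stream inside the package.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @keywords internal
#' @noRd
is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Thermochemical calorie; standard in the binding literature.
#' Convert between J/mol and kcal/mol
#'
#' Uses the thermochemical calorie, 1 kcal = 4184 J.
#'
#' @param x energy value(s).
#' @return converted energy value(s).
#' @examples
#' joules_to_kcal(4184)
#' @export
joules_to_kcal <- function(x) x / 4184

#' @rdname joules_to_kcal
#' @export
kcal_to_joules <- function(x) x * 4184
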