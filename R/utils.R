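`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` under set.seed(seed) without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

#' Format a fraction as a percentage string
#'
#' Helper used by the report writers: per-speaker accuracies are printed with
#' two decimals (`"88.33%"`), overall method averages with one (`"71.1%"`).
#'
#' @param x numeric vector of fractions in `[0, 1]`.
#' @param digits decimal places.
#' @return character vector.
#' @export
format_pct <- function(x, digits = 2) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f%%"), 100 * x))
}
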