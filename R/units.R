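#' Unit helpers
#'
#' Internal convention: volumes are microliters (uL) and lengths millimeters
#' everywhere inside the package; nanoliters are accepted at user-facing
#' interfaces and converted on entry. These helpers also parse quantity
#' strings such as `"500 nL"` or `"3.5 uL"` found in method files.
#'
#' @param x numeric volume, or a character scalar with a unit suffix
#'   (`nL`, `uL`/`µL`, `mL`; case-insensitive). Bare numerics are taken
#'   to already be in the target unit.
#' @return numeric volume in microliters (`as_microliters()`) or nanoliters
#'   (`as_nanoliters()`).
#' @examples
#' as_microliters("500 nL")
#' as_nanoliters(0.5)   # 0.5 uL -> 500 nL
#' @export
as_microliters <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  if (!is.character(x)) {
    stop_nanosampler("volume must be numeric (uL) or a unit string", "unit_error")
  }
  vapply(x, parse_volume_ul, numeric(1), USE.NAMES = FALSE)
}

#' @rdname as_microliters
#' @export
as_nanoliters <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x) * 1000)
  }
  as_microliters(x) * 1000
}

parse_volume_ul <- function(s) {
  m <- regmatches(s, regexec(
    "^\\s*([-+0-9.eE]+)\\s*(n[lL]|[uµ][lL]|m[lL])\\s*$", s
  ))[[1]]
  if (length(m) != 3) {
    stop_nanosampler(
      sprintf("cannot parse volume %s (expected e.g. '500 nL' or '3.5 uL')", dQuote(s)),
      "unit_error"
    )
  }
  value <- as.numeric(m[2])
  unit <- tolower(substr(m[3], 1, 1))
  value * switch(unit, n = 1e-3, u = 1, "µ" = 1, m = 1e3)
}

# classed conditions, so callers can test for specific failure modes
stop_nanosampler <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("nanosampler_", class), "nanosampler_error"), ...)
}

warn_nanosampler <- function(message, class) {
  rlang::warn(message, class = c(paste0("nanosampler_", class), "nanosampler_warning"))
}
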