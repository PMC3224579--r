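#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes in the fixed order used
#' throughout the package for every probability vector and PWM row.
#' Ambiguity codes (B, Z, X, U, O) are rejected at parse time because the
#' information-theoretic machinery assumes a 20-letter alphabet.
#'
#' @format A character vector of length 20.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP <- "-"

#' @keywords internal
is_aa <- function(x) x %in% AA20

stop_sdr <- function(fmt, ..., class = "sdrcov_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "sdrcov_error")))
}
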