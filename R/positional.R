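#' @include AllClasses.R
NULL

#' Sinusoidal positional code
#'
#' Fixed periodic positional embedding: for position p and dimension pair i,
#' `sin(p / 10000^(2i/d))` and `cos(p / 10000^(2i/d))`. Deterministic, no
#' learned parameters; added elementwise to the token embeddings.
#'
#' @param positions integer vector of positions (0-based).
#' @param d embedding width (even).
#' @return `length(positions) x d` matrix of codes.
#' @examples
#' positionalEncoding(0, 8)  # even columns 0 (sin 0), odd columns 1 (cos 0)
#' @export
positionalEncoding <- function(positions, d) {
  if (d %% 2 != 0) stop("embedding width must be even")
  i <- seq_len(d / 2) - 1
  freq <- 1 / 10000^(2 * i / d)
  ang <- outer(positions, freq)
  out <- matrix(0, length(positions), d)
  out[, 2 * i + 1] <- sin(ang)
  out[, 2 * i + 2] <- cos(ang)
  out
}
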