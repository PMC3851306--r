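#' Haldane map function
#'
#' Converts a sex-averaged genetic distance in centimorgans to a
#' recombination fraction, \eqn{\theta = (1 - e^{-2d/100})/2}.
#'
#' @param cM Non-negative genetic distance(s) in centimorgans.
#' @return Recombination fraction(s) in [0, 0.5).
#' @export
#' @examples
#' haldane_theta(c(0, 10, 50, Inf))
haldane_theta <- function(cM) {
  stopifnot(all(cM >= 0))
  (1 - exp(-2 * cM / 100)) / 2
}

#' Inverse Haldane map function
#'
#' @param theta Recombination fraction(s) in [0, 0.5).
#' @return Genetic distance(s) in centimorgans.
#' @export
haldane_cM <- function(theta) {
  stopifnot(all(theta >= 0), all(theta < 0.5))
  -50 * log(1 - 2 * theta)
}

## log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log(mean(exp(x)))
logmeanexp <- function(x) logsumexp(x) - log(length(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
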