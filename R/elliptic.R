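#' Complete elliptic integrals of the first and second kind
#'
#' Evaluates
#' \deqn{K(k^2) = \int_0^{\pi/2} \frac{d\theta}{\sqrt{1 - k^2 \sin^2\theta}},
#'   \qquad
#'   E(k^2) = \int_0^{\pi/2} \sqrt{1 - k^2 \sin^2\theta}\, d\theta}
#' via the arithmetic-geometric mean ([pracma::ellipke()]), accurate to machine
#' precision. These parameterize the exact off-axis field of a circular loop.
#'
#' The argument is the *parameter* \eqn{m = k^2}, as is conventional for the
#' loop-field kernel. `K` diverges as \eqn{m \to 1}; `m = 1` corresponds to
#' evaluation on the loop filament itself and raises a domain error.
#'
#' @param k_squared vector of parameters in `[0, 1)`.
#' @return a list with components `K` and `E` (same length as `k_squared`).
#' @examples
#' elliptic_ke(0)     # both pi/2
#' elliptic_ke(0.5)   # K = 1.8540747, E = 1.3506439
#' @export
elliptic_ke <- function(k_squared) {
  if (!is.numeric(k_squared) || length(k_squared) < 1 || any(!is.finite(k_squared)))
    stop_domain("k_squared must be finite numeric")
  if (any(k_squared < 0) || any(k_squared >= 1))
    stop_domain("k_squared must lie in [0, 1): K diverges at 1 ",
                "(evaluation point on the loop filament)")
  ke <- pracma::ellipke(k_squared)
  list(K = ke$k, E = ke$e)
}
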