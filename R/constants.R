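#' Physical constants used throughout the package
#'
#' Vacuum permeability `mu0` (H/m), vacuum permittivity `eps0` (F/m), and
#' the CGS conversion `oersted` (1 Oe in A/m, `1e3 / (4 pi)`).
#'
#' @return Named list with elements `mu0`, `eps0`, `oersted`.
#' @examples
#' physical_constants()$mu0
#' @export
physical_constants <- function() {
  list(mu0 = 4 * pi * 1e-7,
       eps0 = 8.8541878128e-12,
       oersted = 1e3 / (4 * pi))
}

.mu0 <- 4 * pi * 1e-7
.eps0 <- 8.8541878128e-12
.oersted <- 1e3 / (4 * pi)
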