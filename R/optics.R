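#' Background optical properties of a diffusive phantom
#'
#' Bundles the absorption and reduced scattering coefficients at the
#' excitation (Cherenkov) and emission (fluorescence) wavelengths together
#' with the fluorophore absorption \code{mu_af} and quantum efficiency
#' \code{eta}.  Diffusion coefficients follow the standard diffusion
#' approximation \eqn{D = 1/(3(\mu_a + \mu_s'))}.
#'
#' Defaults are the background properties of a 1% Intralipid-like tissue
#' phantom: \code{mu_ax = 0.009}, \code{mu_am = 0.006},
#' \code{mu_sx = 1.314}, \code{mu_sm = 1.273}, \code{mu_af = 0.008}
#' (all mm^-1).
#'
#' @param mu_ax absorption at the excitation wavelength (mm^-1)
#' @param mu_am absorption at the emission wavelength (mm^-1)
#' @param mu_sx reduced scattering at the excitation wavelength (mm^-1)
#' @param mu_sm reduced scattering at the emission wavelength (mm^-1)
#' @param mu_af fluorophore absorption at the excitation wavelength (mm^-1)
#' @param eta fluorophore quantum efficiency in (0, 1]
#' @return an object of class \code{optical_properties}: a list with the six
#'   coefficients plus derived diffusion coefficients \code{Dx}, \code{Dm}
#'   and the background fluorescence yield \code{eta * mu_af}.
#' @export
#' @examples
#' op <- optical_properties()
#' op$Dx   # ~0.25 mm
optical_properties <- function(mu_ax = 0.009, mu_am = 0.006,
                               mu_sx = 1.314, mu_sm = 1.273,
                               mu_af = 0.008, eta = 1.0) {
  co <- c(mu_ax = mu_ax, mu_am = mu_am, mu_sx = mu_sx,
          mu_sm = mu_sm, mu_af = mu_af)
  if (any(!is.finite(co)) || any(co <= 0))
    stop("all optical coefficients must be positive and finite")
  if (!is.finite(eta) || eta <= 0 || eta > 1)
    stop("eta must lie in (0, 1]")
  obj <- list(mu_ax = mu_ax, mu_am = mu_am, mu_sx = mu_sx, mu_sm = mu_sm,
              mu_af = mu_af, eta = eta,
              Dx = 1 / (3 * (mu_ax + mu_sx)),
              Dm = 1 / (3 * (mu_am + mu_sm)),
              yield = eta * mu_af)
  stopifnot(is.finite(obj$Dx), obj$Dx > 0, is.finite(obj$Dm), obj$Dm > 0)
  class(obj) <- "optical_properties"
  obj
}

#' @export
print.optical_properties <- function(x, ...) {
  cat("Optical properties (mm^-1):\n")
  cat(sprintf("  mu_ax=%.4g mu_am=%.4g mu_sx'=%.4g mu_sm'=%.4g\n",
              x$mu_ax, x$mu_am, x$mu_sx, x$mu_sm))
  cat(sprintf("  mu_af=%.4g eta=%.3g -> yield eta*mu_af=%.4g\n",
              x$mu_af, x$eta, x$yield))
  cat(sprintf("  Dx=%.4g Dm=%.4g (diffusion approximation)\n", x$Dx, x$Dm))
  invisible(x)
}
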