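#' Optical properties of a tissue or medium
#'
#' Bundles the absorption coefficient, reduced scattering coefficient,
#' scattering anisotropy and refractive index of a homogeneous medium at one
#' wavelength. The reduced scattering coefficient is stored as primary and the
#' full scattering coefficient \eqn{\mu_s = \mu_s' / (1 - g)} is derived on
#' demand (see [scattering_from_reduced()]).
#'
#' @param mu_a absorption coefficient, cm^-1 (>= 0)
#' @param mu_s_prime reduced scattering coefficient, cm^-1 (>= 0)
#' @param g scattering anisotropy factor, in [0, 1)
#' @param n refractive index (>= 1)
#' @param wavelength wavelength in nm (informational)
#' @param label optional free-text label
#' @return an object of class `optical_properties`
#' @examples
#' optical_properties(1.23, 8.26, g = 0.93, n = 1.33, wavelength = 650)
#' @export
optical_properties <- function(mu_a, mu_s_prime, g = 0.9, n = 1.33,
                               wavelength = NA_real_, label = NULL) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1L,
            is.numeric(mu_s_prime), length(mu_s_prime) == 1L,
            is.numeric(g), length(g) == 1L,
            is.numeric(n), length(n) == 1L)
  if (mu_a < 0) stop("mu_a must be >= 0")
  if (mu_s_prime < 0) stop("mu_s_prime must be >= 0")
  if (g < 0 || g >= 1) stop("g must lie in [0, 1)")
  if (n < 1) stop("refractive index n must be >= 1")
  structure(
    list(mu_a = as.numeric(mu_a), mu_s_prime = as.numeric(mu_s_prime),
         g = as.numeric(g), n = as.numeric(n),
         wavelength = as.numeric(wavelength), label = label),
    class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "<optical_properties%s> mu_a=%.4g cm^-1, mu_s'=%.4g cm^-1 (mu_s=%.4g), g=%.3g, n=%.3g, lambda=%s nm\n",
    if (!is.null(x$label)) paste0(" ", x$label) else "",
    x$mu_a, x$mu_s_prime, scattering_from_reduced(x$mu_s_prime, x$g),
    x$g, x$n, format(x$wavelength)))
  invisible(x)
}

#' Scattering coefficient from the reduced scattering coefficient
#'
#' Inverts the similarity relation \eqn{\mu_s' = \mu_s (1 - g)}:
#' \eqn{\mu_s = \mu_s' / (1 - g)}.
#'
#' @param mu_s_prime reduced scattering coefficient, cm^-1 (>= 0)
#' @param g anisotropy factor, in [0, 1)
#' @return scattering coefficient \eqn{\mu_s}, cm^-1
#' @examples
#' scattering_from_reduced(18.341, 0.90) # 183.41
#' @export
scattering_from_reduced <- function(mu_s_prime, g) {
  if (any(!is.finite(mu_s_prime)) || any(mu_s_prime < 0))
    stop("mu_s_prime must be finite and >= 0")
  if (any(!is.finite(g)) || any(g < 0) || any(g >= 1))
    stop("g must lie in [0, 1)")
  mu_s_prime / (1 - g)
}

#' Effective attenuation coefficient (diffusion approximation)
#'
#' \eqn{\mu_{eff} = \sqrt{3 \mu_a (\mu_a + \mu_s')}}. Used as an analytic
#' cross-check of deep-fluence decay; the diffusion limit is undefined for a
#' non-absorbing medium, in which case 0 is returned with a warning.
#'
#' @param props an [optical_properties()] object
#' @return effective attenuation coefficient, cm^-1
#' @export
effective_attenuation <- function(props) {
  stopifnot(inherits(props, "optical_properties"))
  if (props$mu_a == 0) {
    warning("mu_a = 0: diffusion limit undefined, returning 0")
    return(0)
  }
  sqrt(3 * props$mu_a * (props$mu_a + props$mu_s_prime))
}

# Tabulated liver properties used throughout: absorption and reduced
# scattering of native and thermally ablated (70 C) liver at the three
# simulated wavelengths; anisotropy 0.93 (native) / 0.90 (ablated), n = 1.33
# for both states.
.liver_table <- data.frame(
  tissue_state = rep(c("native", "ablated_70C"), each = 3L),
  wavelength = rep(c(650, 900, 1050), 2L),
  mu_a = c(1.23, 0.73, 0.60, 0.70, 0.23, 0.24),
  mu_s_prime = c(8.26, 5.04, 3.85, 31.48, 24.90, 18.341),
  mu_s_printed = c(118.01, 72.03, 55.02, 314.79, 248.98, 183.41),
  g = c(rep(0.93, 3L), rep(0.90, 3L)),
  n = 1.33,
  stringsAsFactors = FALSE)

#' Liver optical-property presets
#'
#' Tabulated optical properties of native and thermally ablated (70 C)
#' liver tissue at 650, 900 and 1050 nm. Only the tabulated combinations are
#' available; there is no spectral interpolation.
#'
#' @param tissue_state `"native"` or `"ablated_70C"`
#' @param wavelength one of 650, 900, 1050 (nm)
#' @return an [optical_properties()] object
#' @examples
#' liver_optical_properties("native", 650)
#' @export
liver_optical_properties <- function(tissue_state = c("native", "ablated_70C"),
                                     wavelength) {
  tissue_state <- match.arg(tissue_state)
  row <- .liver_table[.liver_table$tissue_state == tissue_state &
                        .liver_table$wavelength == wavelength, ]
  if (nrow(row) != 1L)
    stop(sprintf("no tabulated properties for %s liver at %s nm",
                 tissue_state, format(wavelength)))
  optical_properties(row$mu_a, row$mu_s_prime, g = row$g, n = row$n,
                     wavelength = row$wavelength,
                     label = sprintf("%s liver %g nm", tissue_state,
                                     row$wavelength))
}

#' Full liver optical-property table
#'
#' @return a data frame with one row per (tissue state, wavelength)
#'   combination, including the printed scattering coefficient `mu_s_printed`
#'   alongside the value derived from `mu_s_prime` and `g`.
#' @export
liver_optics_table <- function() {
  out <- .liver_table
  out$mu_s <- scattering_from_reduced(out$mu_s_prime, out$g)
  out
}

#' Read region optical properties from a YAML configuration
#'
#' The file maps region names to `{mu_a, mu_s_prime, g, n, wavelength}`,
#' or to `{preset: liver, tissue_state, wavelength}` to pull a tabulated
#' liver preset.
#'
#' @param path path to a YAML file
#' @return named list of [optical_properties()] objects
#' @export
read_region_properties <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    x <- cfg[[nm]]
    if (!is.null(x$preset) && identical(x$preset, "liver")) {
      liver_optical_properties(x$tissue_state, x$wavelength)
    } else {
      optical_properties(x$mu_a, x$mu_s_prime,
                         g = if (is.null(x$g)) 0.9 else x$g,
                         n = if (is.null(x$n)) 1.33 else x$n,
                         wavelength = if (is.null(x$wavelength)) NA_real_
                                      else x$wavelength,
                         label = nm)
    }
  })
  names(out) <- names(cfg)
  out
}
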