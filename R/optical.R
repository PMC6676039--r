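# Container for co-registered per-pixel light-scattering parameter maps.

#' Construct an optical property map
#'
#' Per-pixel light-scattering parameters from structured-illumination
#' reflectance imaging: the reduced scattering coefficient mu_s' (mm^-1), the
#' phase-function parameter gamma (dimensionless, forward-vs-backward scatter),
#' and the scatter power B (dimensionless exponent of the wavelength dependence
#' `mu_s'(lambda) = A (lambda / 800 nm)^-B`).
#'
#' @param mus_prime,gamma,b_power Numeric matrices of equal dimension.
#' @param pixel_size Pixel side in mm (> 0).
#' @param valid_mask Logical matrix of valid pixels; default all valid.
#' @param amplitude_a Optional matrix of the amplitude A (mm^-1).
#' @param specimen_id Identifier string.
#' @return An `optical_property_map` object.
#' @export
optical_property_map <- function(mus_prime, gamma, b_power, pixel_size,
                                 valid_mask = NULL, amplitude_a = NULL,
                                 specimen_id = "unknown") {
  mus_prime <- as.matrix(mus_prime)
  gamma <- as.matrix(gamma)
  b_power <- as.matrix(b_power)
  d <- dim(mus_prime)
  if (!all(dim(gamma) == d) || !all(dim(b_power) == d))
    stop("property maps must share one grid")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be positive (mm)")
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, d[1], d[2])
  valid_mask <- as.matrix(valid_mask)
  storage.mode(valid_mask) <- "logical"
  if (!all(dim(valid_mask) == d)) stop("valid_mask not aligned")
  if (any(mus_prime[valid_mask] <= 0))
    stop("mus_prime must be positive where valid")
  structure(
    list(mus_prime = mus_prime, gamma = gamma, b_power = b_power,
         amplitude_a = amplitude_a, pixel_size = pixel_size,
         valid_mask = valid_mask, specimen_id = as.character(specimen_id)),
    class = "optical_property_map")
}

#' @export
print.optical_property_map <- function(x, ...) {
  d <- dim(x$mus_prime)
  cat(sprintf(
    "optical_property_map '%s': %d x %d px (%g mm/px), %d valid\n",
    x$specimen_id, d[1], d[2], x$pixel_size, sum(x$valid_mask)))
  invisible(x)
}
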