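# Spectral forward model: skin chromophore absorption, band-pass filter
# transmission, two-pass diffuse reflectance, and camera RGB rendering.
# This module models the physics of the acquisition chain; the cohort
# renderer is purely phenomenological and the two deliberately disagree on
# the sign of the blue-channel/bilirubin relationship (see the vignette).

#' Spectral curve on a wavelength grid
#'
#' @param wavelengths strictly increasing grid, nm, within [380, 780].
#' @param values nonnegative per-wavelength magnitudes (extinction,
#'   transmittance or sensitivity), same length as `wavelengths`.
#' @return object of class `spectral_curve` (list with `wavelengths`,
#'   `values`).
#' @export
spectral_curve <- function(wavelengths, values) {
  if (length(wavelengths) != length(values))
    stopf("spectral_curve: wavelength and value arrays differ in length")
  if (any(diff(wavelengths) <= 0))
    stopf("spectral_curve: wavelengths must be strictly increasing")
  if (min(wavelengths) < 380 || max(wavelengths) > 780)
    stopf("spectral_curve: wavelengths must lie within [380, 780] nm")
  if (any(values < 0)) stopf("spectral_curve: values must be nonnegative")
  structure(list(wavelengths = as.numeric(wavelengths),
                 values = as.numeric(values)),
            class = "spectral_curve")
}

#' Default visible-range wavelength grid (380-780 nm at 1 nm)
#' @export
default_grid <- function() 380:780

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Bilirubin extinction spectrum
#'
#' Bilirubin is a yellow chromophore with broad absorption in the blue, peaking
#' around 460 nm. Modelled as a Gaussian band with configurable full width at
#' half maximum, peak normalised to 1 at 460 nm.
#'
#' @param grid wavelength grid, nm, within the visible range.
#' @param fwhm full width at half maximum, nm (default 100).
#' @return a [spectral_curve()].
#' @export
bilirubin_extinction <- function(grid = default_grid(), fwhm = 100) {
  if (min(grid) < 380 || max(grid) > 780)
    stopf("bilirubin_extinction: grid outside the visible range")
  s <- fwhm / (2 * sqrt(2 * log(2)))
  spectral_curve(grid, exp(-(grid - 460)^2 / (2 * s^2)))
}

#' Haemoglobin extinction spectrum (parametric stand-in)
#'
#' Double-peaked absorption near 540 and 576 nm (the oxyhaemoglobin alpha and
#' beta bands), as a sum of two Gaussians normalised to peak 1. A schematic
#' shape, adequate for exploring filter effects, not a measured spectrum.
#'
#' @param grid wavelength grid, nm.
#' @return a [spectral_curve()].
#' @export
haemoglobin_extinction <- function(grid = default_grid()) {
  v <- exp(-(grid - 540)^2 / (2 * 12^2)) + 0.85 * exp(-(grid - 576)^2 / (2 * 12^2))
  spectral_curve(grid, v / max(v))
}

#' Melanin extinction spectrum (parametric stand-in)
#'
#' Monotone decreasing with wavelength, normalised to 1 at 380 nm.
#'
#' @param grid wavelength grid, nm.
#' @return a [spectral_curve()].
#' @export
melanin_extinction <- function(grid = default_grid()) {
  spectral_curve(grid, exp(-(grid - 380) / 150))
}

#' Wratten No. 11 band-pass transmission
#'
#' Yellow-green gelatine filter with half-maximum (cut-on/cut-off) points at
#' 483 and 589 nm and unit peak transmission at 516 nm. Modelled as an
#' asymmetric generalised Gaussian (order 4) on each side of the peak, which
#' meets the three printed points exactly and is near-zero outside roughly
#' [430, 650] nm.
#'
#' @param grid wavelength grid, nm.
#' @return a [spectral_curve()].
#' @export
wratten11_transmission <- function(grid = default_grid()) {
  hw <- ifelse(grid < 516, 516 - 483, 589 - 516)  # half-widths at half maximum
  spectral_curve(grid, exp(-log(2) * ((grid - 516) / hw)^4))
}

#' Skin composition
#'
#' Relative chromophore concentrations and an effective optical path length
#' for the two-pass reflectance model.
#'
#' @param bilirubin,haemoglobin,melanin relative concentrations (>= 0).
#' @param effective_path relative path length (> 0, default 1).
#' @return object of class `skin_composition`.
#' @export
skin_composition <- function(bilirubin = 0, haemoglobin = 0, melanin = 0,
                             effective_path = 1) {
  if (bilirubin < 0 || haemoglobin < 0 || melanin < 0)
    stopf("skin_composition: concentrations must be nonnegative")
  if (effective_path <= 0)
    stopf("skin_composition: effective_path must be > 0")
  structure(list(bilirubin = bilirubin, haemoglobin = haemoglobin,
                 melanin = melanin, effective_path = effective_path),
            class = "skin_composition")
}

#' Two-pass Beer-Lambert diffuse reflectance
#'
#' `R(lambda) = exp(-2 * L * sum_i c_i * eps_i(lambda))`: light traverses the
#' absorbing layer down and back (factor 2) with effective path `L`; no
#' scattering model. Values lie in (0, 1].
#'
#' @param composition a [skin_composition()].
#' @param curves named list of extinction [spectral_curve()]s on a common
#'   grid, with elements `bilirubin`, `haemoglobin`, `melanin`. Defaults to
#'   the built-in stand-ins on [default_grid()].
#' @return a [spectral_curve()] of reflectance.
#' @export
diffuse_reflectance <- function(composition, curves = NULL) {
  stopifnot(inherits(composition, "skin_composition"))
  if (is.null(curves))
    curves <- list(bilirubin = bilirubin_extinction(),
                   haemoglobin = haemoglobin_extinction(),
                   melanin = melanin_extinction())
  grid <- curves$bilirubin$wavelengths
  for (nm in names(curves))
    if (!identical(curves[[nm]]$wavelengths, grid))
      stopf("diffuse_reflectance: extinction curves are on mismatched grids")
  absorb <- composition$bilirubin * curves$bilirubin$values +
    composition$haemoglobin * curves$haemoglobin$values +
    composition$melanin * curves$melanin$values
  spectral_curve(grid, exp(-2 * composition$effective_path * absorb))
}

#' Gaussian camera channel sensitivities
#'
#' Three Gaussian bands centred at 600 (red), 530 (green) and 460 (blue) nm
#' with 70 nm full width at half maximum -- schematic consumer-sensor curves
#' (actual smartphone sensor responses are unpublished).
#'
#' @param grid wavelength grid, nm.
#' @return named list of three [spectral_curve()]s (`red`, `green`, `blue`).
#' @export
camera_sensitivities <- function(grid = default_grid()) {
  s <- 70 / (2 * sqrt(2 * log(2)))
  centres <- c(red = 600, green = 530, blue = 460)
  lapply(centres, function(mu) spectral_curve(grid, exp(-(grid - mu)^2 / (2 * s^2))))
}

#' Render RGB channel values from a reflectance spectrum
#'
#' Channel value `= round(255 * int R*I*S_c*T dlambda / int I*S_c dlambda)`,
#' clipped to [0, 255], by trapezoidal integration on the common grid. The
#' normalisation excludes the filter, so inserting a filter (T <= 1) can only
#' lower channel values; a perfect reflector without a filter renders as
#' (255, 255, 255).
#'
#' @param reflectance a [spectral_curve()].
#' @param illuminant optional illuminant [spectral_curve()]; `NULL` means a
#'   flat equal-energy spectrum.
#' @param sensitivities named list of three channel [spectral_curve()]s
#'   (default [camera_sensitivities()] on the reflectance grid).
#' @param filter optional transmission [spectral_curve()] (e.g.
#'   [wratten11_transmission()]); `NULL` means no filter.
#' @return named integer vector `c(red=, green=, blue=)` in [0, 255].
#' @export
render_rgb <- function(reflectance, illuminant = NULL, sensitivities = NULL,
                       filter = NULL) {
  stopifnot(inherits(reflectance, "spectral_curve"))
  grid <- reflectance$wavelengths
  if (is.null(sensitivities)) sensitivities <- camera_sensitivities(grid)
  ivals <- if (is.null(illuminant)) rep(1, length(grid)) else {
    if (!identical(illuminant$wavelengths, grid))
      stopf("render_rgb: illuminant grid does not match reflectance grid")
    illuminant$values
  }
  tvals <- if (is.null(filter)) rep(1, length(grid)) else {
    if (!identical(filter$wavelengths, grid))
      stopf("render_rgb: filter grid does not match reflectance grid")
    filter$values
  }
  out <- vapply(c("red", "green", "blue"), function(ch) {
    s <- sensitivities[[ch]]
    if (!identical(s$wavelengths, grid))
      stopf("render_rgb: sensitivity grid does not match reflectance grid")
    num <- trapz(grid, reflectance$values * ivals * s$values * tvals)
    den <- trapz(grid, ivals * s$values)
    clip8(round_half_away(255 * num / den))
  }, numeric(1))
  out
}

#' Read / write a spectral curve as two-column CSV
#' @param curve a [spectral_curve()].
#' @param path CSV path (columns `wavelength_nm`, `value`).
#' @rdname spectral_io
#' @export
write_spectral_curve <- function(curve, path) {
  utils::write.csv(data.frame(wavelength_nm = curve$wavelengths,
                              value = curve$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname spectral_io
#' @export
read_spectral_curve <- function(path) {
  d <- utils::read.csv(path)
  spectral_curve(d$wavelength_nm, d$value)
}
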