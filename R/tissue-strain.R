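#' Convert CT Hounsfield units to Young's modulus
#'
#' Maps Hounsfield units to an equivalent bone density through the linear
#' phantom calibration `rho = intercept + slope * HU` and then to Young's
#' modulus through the power law `E = coefficient * rho^exponent`. Densities
#' that map non-positive are clamped at `density_floor` with a warning
#' (air-filled or artefactual voxels). Default constants are the widely used
#' density-modulus relation `E [MPa] = 10500 * rho_ash^2.29` with an ash
#' density calibration on a g/cm^3 scale; all four constants are exposed
#' because scanner calibrations differ.
#'
#' @param hu Numeric vector of Hounsfield units.
#' @param slope,intercept Linear HU-to-density calibration (g/cm^3 per HU and
#'   g/cm^3).
#' @param coefficient,exponent Density-to-modulus power law (MPa at
#'   rho = 1 g/cm^3, and the dimensionless exponent).
#' @param density_floor Lower clamp for the mapped density, g/cm^3 (> 0).
#' @return Numeric vector of Young's moduli in MPa.
#' @export
#' @examples
#' hu_to_modulus(c(200, 800, 1400))
hu_to_modulus <- function(hu, slope = 0.0007, intercept = 0.0526,
                          coefficient = 10500, exponent = 2.29,
                          density_floor = 0.005) {
  stopifnot(density_floor > 0)
  rho <- intercept + slope * hu
  if (any(rho <= 0)) {
    warn(sprintf("%d non-positive mapped densities clamped at the floor",
                 sum(rho <= 0)))
    rho <- pmax(rho, density_floor)
  }
  coefficient * rho^exponent
}

#' Classify finite-element tissue from Young's modulus
#'
#' Applies the modulus thresholds used for CT-derived tibial meshes:
#' intramedullary tissue for `E < 6` MPa, trabecular bone for
#' `6 MPa <= E < 8 GPa`, cortical bone for `E >= 8 GPa`. Poisson's ratio is
#' 0.325 for trabecular and cortical bone and 0.167 for intramedullary
#' tissue.
#'
#' @param moduli Numeric vector of Young's moduli in MPa.
#' @return A tibble with columns `youngs_modulus_mpa`, `tissue` (factor:
#'   intramedullary, trabecular, cortical) and `poisson`.
#' @export
classify_tissue <- function(moduli) {
  stopifnot(all(moduli > 0))
  tissue <- cut(moduli, breaks = c(0, 6, 8000, Inf),
                labels = c("intramedullary", "trabecular", "cortical"),
                right = FALSE)
  tibble(
    youngs_modulus_mpa = moduli,
    tissue = tissue,
    poisson = ifelse(tissue == "intramedullary", 0.167, 0.325)
  )
}

#' 90th-percentile cortical von Mises strain
#'
#' Summarises an element table to the 90th percentile of the von Mises
#' strain over cortical-bone elements only, using the linear-interpolation
#' quantile convention (`stats::quantile` type 7 by default).
#'
#' @param element_table A tibble with columns `tissue` and
#'   `von_mises_strain_ue` (e.g. from [generate_element_table()]).
#' @param probs Percentile to report as a fraction (default 0.9).
#' @param type Quantile algorithm passed to [stats::quantile()].
#' @return A one-row tibble: `participant_id`, `condition` (taken from the
#'   table attributes when present, else `NA`), `n_cortical`, `strain_p90_ue`.
#' @export
cortical_strain_p90 <- function(element_table, probs = 0.9, type = 7) {
  ct <- element_table$von_mises_strain_ue[element_table$tissue == "cortical"]
  if (length(ct) == 0) {
    abort("element table contains no cortical elements",
          class = "tibfrax_input_error")
  }
  tibble(
    participant_id = attr(element_table, "participant_id") %||% NA_character_,
    condition = attr(element_table, "condition") %||% NA_character_,
    n_cortical = length(ct),
    strain_p90_ue = quantile(ct, probs, type = type, names = FALSE)
  )
}

#' Normalise kinetics by body size
#'
#' Forces (ground-reaction and joint reaction forces, N) are expressed in
#' body weights, `force / (mass * g)` with `g = 9.81` m/s^2; joint moments
#' (N m) are expressed per kilogram of body mass, `moment / mass`.
#'
#' @param x Numeric vector of forces in newtons or moments in newton-metres.
#' @param mass_kg Body mass in kilograms (> 0).
#' @param quantity `"force"` or `"moment"`.
#' @return Numeric vector in BW (forces) or N m/kg (moments).
#' @export
#' @examples
#' normalize_kinetics(1471.5, 50)           # 3 BW
#' normalize_kinetics(120, 60, "moment")    # 2 Nm/kg
normalize_kinetics <- function(x, mass_kg, quantity = c("force", "moment")) {
  quantity <- match.arg(quantity)
  if (!is.numeric(mass_kg) || any(mass_kg <= 0)) {
    abort("mass must be positive", class = "tibfrax_input_error")
  }
  if (quantity == "force") x / (mass_kg * GRAVITY) else x / mass_kg
}
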