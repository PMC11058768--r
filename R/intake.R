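#' Herbivore parameters
#'
#' Body-mass range and intake/allometry constants for the model herbivore.
#' Defaults describe an adult male woolly mammoth of the North Siberian
#' form: body mass 3,900-5,200 kg (reference mean 4,550 kg), a 2% of body
#' mass daily dry-matter-intake rule, and the Damuth's-law coefficients
#' (slope -0.75, intercept 4.23 on the log10 scale, mass in grams).
#'
#' Note the bound convention: the HIGH body mass eats more and therefore
#' yields the LOWER population-density bound, and vice versa. Summary
#' tables label bounds by body mass to keep this explicit.
#'
#' @param body_mass_low_kg,body_mass_high_kg,body_mass_ref_kg Body-mass
#'   range endpoints and reference mean, kg.
#' @param dmi_rate Daily dry-matter intake as a fraction of body mass.
#' @param damuth_slope,damuth_intercept Damuth's-law coefficients.
#' @return An object of class `herbivore_params`.
#' @export
herbivore_params <- function(body_mass_low_kg = 3900, body_mass_high_kg = 5200,
                             body_mass_ref_kg = 4550, dmi_rate = 0.02,
                             damuth_slope = -0.75, damuth_intercept = 4.23) {
  if (!(body_mass_low_kg > 0 && body_mass_low_kg <= body_mass_ref_kg &&
        body_mass_ref_kg <= body_mass_high_kg)) {
    stop("need 0 < body_mass_low_kg <= body_mass_ref_kg <= body_mass_high_kg",
         call. = FALSE)
  }
  if (!(dmi_rate > 0 && dmi_rate < 1)) {
    stop("`dmi_rate` must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(body_mass_low_kg = body_mass_low_kg,
         body_mass_high_kg = body_mass_high_kg,
         body_mass_ref_kg = body_mass_ref_kg, dmi_rate = dmi_rate,
         damuth_slope = damuth_slope, damuth_intercept = damuth_intercept),
    class = "herbivore_params"
  )
}

#' @export
print.herbivore_params <- function(x, ...) {
  cat(sprintf("<herbivore_params> mass %g-%g kg (ref %g), DMI %g%% of mass/day\n",
              x$body_mass_low_kg, x$body_mass_high_kg, x$body_mass_ref_kg,
              100 * x$dmi_rate))
  cat(sprintf("  Damuth: log10 D = %g log10 W + %g\n", x$damuth_slope,
              x$damuth_intercept))
  invisible(x)
}

#' Daily dry-forage intake from body mass
#'
#' The 2% body-mass rule: a large herbivore's daily dry-matter need is a
#' fixed fraction of its body mass. With the default rate, the 3,900 and
#' 5,200 kg mass bounds give 78 and 104 kg of dry forage per day.
#'
#' @param body_mass_kg Body mass, kg (vectorised).
#' @param dmi_rate Intake fraction of body mass per day, in (0, 1).
#' @return Dry forage need, kg per day.
#' @export
daily_intake <- function(body_mass_kg, dmi_rate = 0.02) {
  if (any(body_mass_kg < 0)) stop("body mass must be >= 0", call. = FALSE)
  if (!(all(dmi_rate > 0) && all(dmi_rate < 1))) {
    stop("`dmi_rate` must be in (0, 1)", call. = FALSE)
  }
  body_mass_kg * dmi_rate
}

#' Annual dry-forage intake in tonnes
#'
#' Converts a daily need (kg/day) to tonnes per 365-day year, unrounded;
#' downstream capacity calculations always use the unrounded value.
#' [round_tonnes()] is the presentation helper (78 kg/day -> 28 t/yr,
#' 104 kg/day -> 38 t/yr).
#'
#' @param daily_kg Daily need, kg (vectorised).
#' @return Tonnes of dry forage per year.
#' @export
annual_intake_tonnes <- function(daily_kg) {
  if (any(daily_kg < 0)) stop("daily intake must be >= 0", call. = FALSE)
  daily_kg * 365 / 1000
}

#' @rdname annual_intake_tonnes
#' @param tonnes Annual tonnage to round for display.
#' @export
round_tonnes <- function(tonnes) round_half_up(tonnes, 0)

#' Annual needs at both body-mass bounds
#'
#' @param params A [herbivore_params()].
#' @return Named numeric: `low_mass` and `high_mass` annual needs in tonnes
#'   (unrounded). The low-mass animal needs less, so it supports the higher
#'   density bound.
#' @export
annual_needs <- function(params = herbivore_params()) {
  stopifnot(inherits(params, "herbivore_params"))
  c(low_mass = annual_intake_tonnes(daily_intake(params$body_mass_low_kg,
                                                 params$dmi_rate)),
    high_mass = annual_intake_tonnes(daily_intake(params$body_mass_high_kg,
                                                  params$dmi_rate)))
}

#' Half-up rounding at a fixed number of decimals
#'
#' For comparison with conventionally printed values; base `round()` is
#' half-to-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return `x` rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
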