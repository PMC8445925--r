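#' Allometric parameters for shoulder height and body mass
#'
#' Bundles the sex-specific linear regressions of shoulder height (cm) on
#' foot length (cm) derived from extant savanna elephants, and the
#' species-specific power law relating body mass (kg) to shoulder height:
#'
#' \deqn{ESH_{male} = 10.22 + 5.816 \times FL}
#' \deqn{ESH_{female} = 3.044 + 5.466 \times FL}
#' \deqn{EBM = 3.63 \times 10^{-4} \times ESH^{2.903}}
#'
#' The male intercept deserves a note: the source prints it with a negative
#' sign, but the published per-track estimates are consistent with the
#' positive form, which is therefore the default; set
#' `male_intercept_cm = -10.22` to use the printed form.
#'
#' @param male_intercept_cm,male_slope_cm_per_cm male regression coefficients
#'   (defaults 10.22, 5.816).
#' @param female_intercept_cm,female_slope_cm_per_cm female regression
#'   coefficients (defaults 3.044, 5.466).
#' @param mass_coeff,mass_exponent power-law coefficients (defaults
#'   `3.63e-4` kg cm^-2.903 and 2.903).
#' @param rounding `"nearest_integer"` (reporting convention of the source
#'   table: derived values rounded to the nearest integer, ties away from
#'   zero, and body mass chained from the rounded height) or `"none"` (full
#'   precision end to end).
#' @param female_max_fl_cm foot length (cm) above which only the male
#'   hypothesis is reported (default 38; the source table stops printing
#'   female estimates near that size).
#' @return An object of class `allometry_params`.
#' @seealso [shoulder_height()], [body_mass()], [estimate_tracks()]
#' @export
allometry_params <- function(male_intercept_cm = 10.22,
                             male_slope_cm_per_cm = 5.816,
                             female_intercept_cm = 3.044,
                             female_slope_cm_per_cm = 5.466,
                             mass_coeff = 3.63e-4,
                             mass_exponent = 2.903,
                             rounding = c("nearest_integer", "none"),
                             female_max_fl_cm = 38) {
  rounding <- match.arg(rounding)
  stopifnot(male_slope_cm_per_cm > 0, female_slope_cm_per_cm > 0,
            mass_coeff > 0, mass_exponent > 1, female_max_fl_cm > 0)
  structure(list(male_intercept_cm = male_intercept_cm,
                 male_slope_cm_per_cm = male_slope_cm_per_cm,
                 female_intercept_cm = female_intercept_cm,
                 female_slope_cm_per_cm = female_slope_cm_per_cm,
                 mass_coeff = mass_coeff, mass_exponent = mass_exponent,
                 rounding = rounding, female_max_fl_cm = female_max_fl_cm),
            class = "allometry_params")
}

#' @export
print.allometry_params <- function(x, ...) {
  cat("Allometric parameters\n")
  cat(sprintf("  ESH(male)   = %g + %g x FL\n",
              x$male_intercept_cm, x$male_slope_cm_per_cm))
  cat(sprintf("  ESH(female) = %g + %g x FL\n",
              x$female_intercept_cm, x$female_slope_cm_per_cm))
  cat(sprintf("  EBM = %g x ESH^%g\n", x$mass_coeff, x$mass_exponent))
  cat(sprintf("  rounding: %s; female hypothesis reported below FL %g cm\n",
              x$rounding, x$female_max_fl_cm))
  invisible(x)
}

.coef_for_sex <- function(sex, params) {
  sex <- match.arg(sex, c("male", "female"))
  if (sex == "male") {
    c(intercept = params$male_intercept_cm, slope = params$male_slope_cm_per_cm)
  } else {
    c(intercept = params$female_intercept_cm,
      slope = params$female_slope_cm_per_cm)
  }
}

.apply_rounding <- function(x, params) {
  if (params$rounding == "nearest_integer") round_half_away(x) else x
}

#' Shoulder height from foot length
#'
#' Evaluates the sex-specific linear regression of shoulder height on foot
#' length. Computed at full precision; rounded to the nearest integer for
#' reporting when the parameter set says so.
#'
#' @param foot_length_cm positive foot (print) axial length, cm (vectorised).
#' @param sex `"male"` or `"female"`.
#' @param params an [allometry_params()] object.
#' @return Estimated shoulder height, cm.
#' @export
#' @examples
#' shoulder_height(9.6, "female")  # 56
shoulder_height <- function(foot_length_cm, sex,
                            params = allometry_params()) {
  if (any(!is.finite(foot_length_cm) | foot_length_cm <= 0)) {
    stop("foot_length_cm must be positive", call. = FALSE)
  }
  cf <- .coef_for_sex(sex, params)
  h <- cf["intercept"] + cf["slope"] * foot_length_cm
  if (any(h <= 0)) {
    stop("foot length below the validity range of the ", sex,
         " regression (non-positive height)", call. = FALSE)
  }
  unname(.apply_rounding(h, params))
}

#' Body mass from shoulder height
#'
#' Evaluates the species power law `mass = coeff * height^exponent`.
#'
#' @param shoulder_height_cm positive shoulder height, cm (vectorised).
#' @param params an [allometry_params()] object.
#' @return Estimated body mass, kg.
#' @export
#' @examples
#' body_mass(325)  # 7111
body_mass <- function(shoulder_height_cm, params = allometry_params()) {
  if (any(!is.finite(shoulder_height_cm) | shoulder_height_cm <= 0)) {
    stop("shoulder_height_cm must be positive", call. = FALSE)
  }
  m <- params$mass_coeff * shoulder_height_cm ^ params$mass_exponent
  unname(.apply_rounding(m, params))
}

#' Foot length from shoulder height (inverse regression)
#'
#' Exact inverse of the linear shoulder-height regression, used by the herd
#' simulator to lay down allometrically consistent prints:
#' `shoulder_height(foot_length_from_height(h, s), s)` equals `h` to
#' numerical precision (with rounding `"none"`).
#'
#' @param shoulder_height_cm shoulder height, cm; must exceed the
#'   sex-specific intercept.
#' @param sex `"male"` or `"female"`.
#' @param params an [allometry_params()] object.
#' @return Foot length, cm (never rounded: this is a simulation primitive).
#' @export
foot_length_from_height <- function(shoulder_height_cm, sex,
                                    params = allometry_params()) {
  cf <- .coef_for_sex(sex, params)
  if (any(!is.finite(shoulder_height_cm) |
            shoulder_height_cm <= cf["intercept"])) {
    stop("shoulder height must exceed the ", sex, " intercept (",
         cf["intercept"], " cm)", call. = FALSE)
  }
  unname((shoulder_height_cm - cf["intercept"]) / cf["slope"])
}

#' Per-track size, mass and age estimates under both sex hypotheses
#'
#' Applies the shoulder-height regression, the mass power law and the
#' growth-curve inversion to every record of a track table. The print's
#' axial length is used as foot length regardless of limb (forefoot lengths
#' carry the same regression in the source methodology). Both sex hypotheses
#' are always computed; the `reported_sexes` column marks which the reporting
#' convention would print (`"mf"` below `female_max_fl_cm`, `"m"` above).
#'
#' With `params$rounding == "nearest_integer"` the body mass is chained from
#' the rounded height, reproducing the published table's convention.
#'
#' @param tracks a track table (see [read_track_table()]).
#' @param params an [allometry_params()] object.
#' @param growth a [growth_params()] object, or `NULL` to skip age columns.
#' @param plateau_fraction,max_age_years passed to [age_at_height()].
#' @return A data frame, one row per record: identifiers, `fl_cm`, estimated
#'   height/mass per sex (`esh_m_cm`, `ebm_m_kg`, `esh_f_cm`, `ebm_f_kg`),
#'   age estimates and censoring qualifiers per sex (`age_m_yr`, `qual_m`,
#'   `age_f_yr`, `qual_f`) when `growth` is supplied, and `reported_sexes`.
#' @export
estimate_tracks <- function(tracks, params = allometry_params(),
                            growth = growth_params(),
                            plateau_fraction = 0.95, max_age_years = Inf) {
  fl <- tracks$length_cm
  est <- data.frame(record_id = tracks$record_id, sector = tracks$sector,
                    letter = tracks$letter, limb = tracks$limb, fl_cm = fl,
                    stringsAsFactors = FALSE)
  est$esh_m_cm <- shoulder_height(fl, "male", params)
  est$ebm_m_kg <- body_mass(est$esh_m_cm, params)
  est$esh_f_cm <- shoulder_height(fl, "female", params)
  est$ebm_f_kg <- body_mass(est$esh_f_cm, params)
  if (!is.null(growth)) {
    am <- age_at_height(est$esh_m_cm, "male", growth,
                        plateau_fraction = plateau_fraction,
                        max_age_years = max_age_years)
    af <- age_at_height(est$esh_f_cm, "female", growth,
                        plateau_fraction = plateau_fraction,
                        max_age_years = max_age_years)
    est$age_m_yr <- am$age_years
    est$qual_m <- am$qualifier
    est$age_f_yr <- af$age_years
    est$qual_f <- af$qualifier
  }
  est$reported_sexes <- ifelse(fl < params$female_max_fl_cm, "mf", "m")
  est
}
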