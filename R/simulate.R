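#' Configuration of a simulated herd
#'
#' Describes the herd whose trackway assemblage [simulate_herd()] lays down:
#' the age-class mixture, the within-class age ranges (uniform), a sex rule
#' per class, the growth and allometry parameters that turn age into height
#' and height into foot length, multiplicative lognormal noise on
#' height-about-curve (biological scatter) and on each measured foot length
#' (measurement scatter), a track count distribution per individual, and a
#' minimal gait model (pace as a fraction of shoulder height, random bearing,
#' an overstepping probability for adults).
#'
#' The default composition mirrors a matriarchal family unit watering with
#' its young: mostly calves and juveniles, few adults, old bulls rare. The
#' default sex rule makes the young classes and adults female and old bulls
#' male, matching the sex hypothesis the downstream reading policy assigns by
#' track size, so that parameter recovery measures estimator error rather
#' than sexual-dimorphism mismatch; set a class to `"mixed"` to quantify that
#' mismatch instead.
#'
#' @param n_individuals number of simulated animals.
#' @param mix named non-negative mixture weights over
#'   `calf, juvenile, adolescent, adult_female, old_bull`; must sum to 1.
#' @param sex_rule named character vector per class: `"female"`, `"male"` or
#'   `"mixed"` (50/50).
#' @param age_ranges named list of `c(min, max)` ages per class, years.
#' @param noise_height_sd,noise_fl_sd lognormal sigma of the multiplicative
#'   noise on height and on each measured foot length (default 0.03 each).
#' @param tracks_per_individual integer vector sampled uniformly for the
#'   number of tracks each individual leaves (default `1:4`).
#' @param pes_wl,manus_wl width/length ratio bands per limb (defaults
#'   `c(0.70, 0.96)` and `c(1.00, 1.15)`).
#' @param pace_fraction pace length as a fraction of shoulder height
#'   (default 0.6).
#' @param overstep_prob probability that the manus of an adult manus-pes
#'   couple is overstepped (default 0.2).
#' @param bull_threshold_cm old-bull track-length threshold, cm (default 50).
#' @param growth a [growth_params()] object.
#' @param allometry an [allometry_params()] object (its rounding mode is
#'   irrelevant here: simulation uses full precision).
#' @return An object of class `herd_config`.
#' @export
herd_config <- function(n_individuals = 500,
                        mix = c(calf = 0.45, juvenile = 0.25,
                                adolescent = 0.15, adult_female = 0.13,
                                old_bull = 0.02),
                        sex_rule = c(calf = "female", juvenile = "female",
                                     adolescent = "female",
                                     adult_female = "female",
                                     old_bull = "male"),
                        age_ranges = list(calf = c(0, 2),
                                          juvenile = c(2, 8),
                                          adolescent = c(8, 15),
                                          adult_female = c(15, 60),
                                          old_bull = c(38, 60)),
                        noise_height_sd = 0.03, noise_fl_sd = 0.03,
                        tracks_per_individual = 1:4,
                        pes_wl = c(0.70, 0.96), manus_wl = c(1.00, 1.15),
                        pace_fraction = 0.6, overstep_prob = 0.2,
                        bull_threshold_cm = 50,
                        growth = growth_params(),
                        allometry = allometry_params(rounding = "none")) {
  classes <- c("calf", "juvenile", "adolescent", "adult_female", "old_bull")
  stopifnot(n_individuals >= 0,
            setequal(names(mix), classes), all(mix >= 0),
            abs(sum(mix) - 1) < 1e-8,
            all(sex_rule[classes] %in% c("female", "male", "mixed")),
            noise_height_sd >= 0, noise_fl_sd >= 0,
            all(tracks_per_individual >= 1),
            pace_fraction > 0, overstep_prob >= 0, overstep_prob <= 1)
  # an old-bull class only makes sense if the male curve can produce tracks
  # past the bull threshold
  if (mix[["old_bull"]] > 0) {
    max_fl <- foot_length_from_height(
      0.999 * growth$male[["h_inf"]], "male", allometry)
    if (max_fl <= bull_threshold_cm) {
      stop("configured male growth curve cannot produce foot lengths above ",
           "the old-bull threshold (", bull_threshold_cm, " cm)",
           call. = FALSE)
    }
  }
  structure(list(n_individuals = n_individuals, mix = mix[classes],
                 sex_rule = sex_rule[classes], age_ranges = age_ranges,
                 noise_height_sd = noise_height_sd, noise_fl_sd = noise_fl_sd,
                 tracks_per_individual = tracks_per_individual,
                 pes_wl = pes_wl, manus_wl = manus_wl,
                 pace_fraction = pace_fraction,
                 overstep_prob = overstep_prob,
                 bull_threshold_cm = bull_threshold_cm,
                 growth = growth, allometry = allometry),
            class = "herd_config")
}

#' Simulate a herd's track assemblage
#'
#' Forward model: for each individual, draw an age class from the mixture, a
#' sex from the class rule, an age uniformly within the class range; height
#' is the growth curve at that age times lognormal noise; foot length is the
#' inverse allometry of that height times per-track measurement noise; track
#' width is drawn in the limb's width/length band; tracks are laid on a line
#' with pace proportional to shoulder height, alternating pes and manus.
#' All draws come from one seeded generator in a fixed order, so identical
#' `(config, seed)` give bit-identical output.
#'
#' @param config a [herd_config()].
#' @param seed integer seed.
#' @return A list of class `herd_sim`: `tracks` (a standard track table the
#'   estimation pipeline consumes directly), `truth` (one row per individual:
#'   key, class, sex, age, true height and mass) and `run_id`.
#' @export
simulate_herd <- function(config, seed = 1) {
  stopifnot(inherits(config, "herd_config"))
  set.seed(seed, kind = "Mersenne-Twister")
  run_id <- sprintf("herd-%d-n%d", as.integer(seed), config$n_individuals)
  classes <- names(config$mix)
  n <- config$n_individuals
  empty_tracks <- as_track_table(
    data.frame(record_id = character(0), limb = character(0),
               length_cm = numeric(0), width_cm = numeric(0)))
  truth_cols <- data.frame(individual = character(0), age_class = character(0),
                           sex = character(0), age_years = numeric(0),
                           height_cm = numeric(0), mass_kg = numeric(0),
                           stringsAsFactors = FALSE)
  if (n == 0L) {
    return(structure(list(tracks = empty_tracks, truth = truth_cols,
                          config = config, run_id = run_id),
                     class = "herd_sim"))
  }
  full <- allometry_params(
    male_intercept_cm = config$allometry$male_intercept_cm,
    male_slope_cm_per_cm = config$allometry$male_slope_cm_per_cm,
    female_intercept_cm = config$allometry$female_intercept_cm,
    female_slope_cm_per_cm = config$allometry$female_slope_cm_per_cm,
    mass_coeff = config$allometry$mass_coeff,
    mass_exponent = config$allometry$mass_exponent,
    rounding = "none")
  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- sample(classes, 1L, prob = config$mix)
    rule <- config$sex_rule[[cls]]
    sex <- switch(rule, mixed = if (stats::runif(1) < 0.5) "female" else "male",
                  rule)
    rng <- config$age_ranges[[cls]]
    age <- stats::runif(1, rng[1], rng[2])
    height <- height_at_age(age, sex, config$growth) *
      exp(stats::rnorm(1, 0, config$noise_height_sd))
    fl <- foot_length_from_height(height, sex, full)
    mass <- body_mass(height, full)
    n_tracks <- config$tracks_per_individual[
      sample.int(length(config$tracks_per_individual), 1L)]
    bearing <- stats::runif(1, 0, 2 * pi)
    origin <- stats::runif(2, 0, 100)
    pace_m <- config$pace_fraction * height / 100
    limb <- rep(c("pes", "manus"), length.out = n_tracks)
    fl_meas <- fl * exp(stats::rnorm(n_tracks, 0, config$noise_fl_sd))
    wl <- ifelse(limb == "pes",
                 stats::runif(n_tracks, config$pes_wl[1], config$pes_wl[2]),
                 stats::runif(n_tracks, config$manus_wl[1],
                              config$manus_wl[2]))
    over <- limb == "manus" & cls %in% c("adult_female", "old_bull") &
      stats::runif(n_tracks) < config$overstep_prob
    step <- (seq_len(n_tracks) - 1L) * pace_m
    rows[[i]] <- data.frame(
      record_id = sprintf("SIM/%04d", i),
      limb = limb,
      length_cm = fl_meas,
      width_cm = fl_meas * wl,
      toe_impressions = "",
      trackway_id = sprintf("TW%04d", i),
      overstepped = over,
      x_m = origin[1] + step * cos(bearing),
      y_m = origin[2] + step * sin(bearing),
      notes = "",
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      individual = sprintf("%04d.", i), age_class = cls, sex = sex,
      age_years = age, height_cm = height, mass_kg = mass,
      stringsAsFactors = FALSE)
  }
  tracks <- as_track_table(do.call(rbind, rows))
  structure(list(tracks = tracks, truth = do.call(rbind, truth),
                 config = config, run_id = run_id),
            class = "herd_sim")
}

#' @export
print.herd_sim <- function(x, ...) {
  cat("Simulated herd:", nrow(x$truth), "individuals,",
      nrow(x$tracks), "tracks (", x$run_id, ")\n")
  print(table(factor(x$truth$age_class, levels = names(x$config$mix))))
  invisible(x)
}

#' Gait summary of an ordered trackway
#'
#' Standard ichnological measures from the planar coordinates of tracks in
#' footfall order: pace lengths (consecutive-point distances), stride lengths
#' (alternate-point distances, i.e. successive prints of the same foot) and
#' the mean bearing. For collinear, equally spaced prints the stride is twice
#' the pace.
#'
#' @param x_m,y_m coordinates (m) of at least two tracks, in order.
#' @return A list with `pace_m`, `stride_m` (length 0 when fewer than 3
#'   points) and `bearing_deg` (circular-mean direction of travel, degrees
#'   counterclockwise from +x).
#' @export
#' @examples
#' trackway_geometry(0:3, rep(0, 4))
trackway_geometry <- function(x_m, y_m) {
  stopifnot(length(x_m) == length(y_m))
  if (length(x_m) < 2L) {
    stop("a trackway needs at least 2 positioned tracks", call. = FALSE)
  }
  dx <- diff(x_m); dy <- diff(y_m)
  pace <- sqrt(dx^2 + dy^2)
  n <- length(x_m)
  stride <- if (n >= 3L) {
    sqrt((x_m[-(1:2)] - x_m[seq_len(n - 2)])^2 +
           (y_m[-(1:2)] - y_m[seq_len(n - 2)])^2)
  } else numeric(0)
  bearing <- atan2(mean(dy), mean(dx)) * 180 / pi
  list(pace_m = pace, stride_m = stride, bearing_deg = bearing)
}

#' Parameter-recovery report for a simulated run
#'
#' Closes the validation loop: runs the estimation pipeline on the simulated
#' track table and compares it with the generating truth. Height and mass
#' recovery are evaluated per individual under the individual's TRUE sex
#' hypothesis (isolating the numerical pipeline from the sex-reading policy),
#' on the representative track; class-frequency recovery uses the actual
#' reading policy via [demographic_frequency()], i.e. what an analyst without
#' the truth would report.
#'
#' @param sim a [simulate_herd()] result.
#' @param estimates optional [estimate_tracks()] output for `sim$tracks`
#'   computed with full precision; recomputed if missing. Must carry
#'   attribute `run_id` equal to `sim$run_id` if supplied.
#' @param sex_policy,bull_threshold_cm passed to [demographic_frequency()].
#' @return A list of class `recovery_report`: `freq_error_pp` (per-class
#'   estimated minus true frequency, percentage points), `height_bias`,
#'   `height_rmse_rel`, `mass_bias`, `mass_rmse_rel` (relative to truth),
#'   `n`, `demography` and `truth_counts`.
#' @export
recovery_report <- function(sim, estimates = NULL, sex_policy = 38,
                            bull_threshold_cm = NULL) {
  stopifnot(inherits(sim, "herd_sim"))
  if (is.null(bull_threshold_cm)) {
    bull_threshold_cm <- sim$config$bull_threshold_cm
  }
  full <- sim$config$allometry
  if (!is.null(estimates)) {
    rid <- attr(estimates, "run_id")
    if (!is.null(rid) && !identical(rid, sim$run_id)) {
      stop("estimates come from a different run than the simulation",
           call. = FALSE)
    }
    stopifnot(nrow(estimates) == nrow(sim$tracks))
  } else {
    estimates <- estimate_tracks(sim$tracks, full, sim$config$growth)
  }
  n <- nrow(sim$truth)
  if (n == 0L) {
    return(structure(list(freq_error_pp = NULL, height_bias = NA_real_,
                          height_rmse_rel = NA_real_, mass_bias = NA_real_,
                          mass_rmse_rel = NA_real_, n = 0L,
                          demography = NULL, truth_counts = NULL),
                     class = "recovery_report"))
  }
  rep_idx <- .representative(sim$tracks)
  key <- names(rep_idx)
  truth <- sim$truth[match(key, sim$truth$individual), ]
  est_h <- ifelse(truth$sex == "female",
                  estimates$esh_f_cm[rep_idx], estimates$esh_m_cm[rep_idx])
  est_m <- ifelse(truth$sex == "female",
                  estimates$ebm_f_kg[rep_idx], estimates$ebm_m_kg[rep_idx])
  rel_h <- (est_h - truth$height_cm) / truth$height_cm
  rel_m <- (est_m - truth$mass_kg) / truth$mass_kg
  demog <- demographic_frequency(sim$tracks, estimates,
                                 sex_policy = sex_policy,
                                 bull_threshold_cm = bull_threshold_cm)
  truth_cls <- ifelse(sim$truth$age_class == "adult_female", "adult",
                      sim$truth$age_class)
  truth_counts <- table(factor(truth_cls, levels = age_class_levels()))
  freq_err <- 100 * (demog$counts / demog$total -
                       as.integer(truth_counts) / n)
  structure(list(freq_error_pp = stats::setNames(as.numeric(freq_err),
                                                 age_class_levels()),
                 height_bias = mean(rel_h),
                 height_rmse_rel = sqrt(mean(rel_h^2)),
                 mass_bias = mean(rel_m),
                 mass_rmse_rel = sqrt(mean(rel_m^2)),
                 n = n, demography = demog, truth_counts = truth_counts),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery over", x$n, "individuals\n")
  if (x$n == 0L) return(invisible(x))
  cat(sprintf("  height bias %+.3g%%, rel. RMSE %.3g%%\n",
              100 * x$height_bias, 100 * x$height_rmse_rel))
  cat(sprintf("  mass   bias %+.3g%%, rel. RMSE %.3g%%\n",
              100 * x$mass_bias, 100 * x$mass_rmse_rel))
  cat("  class frequency error (pp):\n")
  print(round(x$freq_error_pp, 2))
  invisible(x)
}
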