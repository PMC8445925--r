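#' Age classes of a proboscidean assemblage
#'
#' Five classes partition the age axis, with a track-size promotion for the
#' largest animals: calves `[0, 2)`, juveniles `[2, 8)` (up to female
#' puberty), adolescents `[8, 15]` (up to male puberty), adults `(15, Inf)`,
#' and old bulls -- adults whose track length exceeds the bull threshold
#' (default 50 cm), a size no female reaches.
#'
#' The source prose brackets juveniles as "2 to 7" while its table prints
#' "8-15" for the next class; the half-open convention used here
#' (`[2, 8)` / `[8, 15]`) makes the classes a true partition, and the
#' ambiguity only touches ages in `[7, 8)`.
#'
#' @return Character vector of the class labels, in order.
#' @export
age_class_levels <- function() {
  c("calf", "juvenile", "adolescent", "adult", "old_bull")
}

#' Assign an age estimate to an age class
#'
#' Classifies by the age value (minimum-qualified ages classify by their
#' floor value: an animal at least 17 years old is at least an adult;
#' maximum-qualified ages by the cap, which for newborn clamps is 0), then
#' promotes adults whose track length exceeds the bull threshold to
#' `old_bull`.
#'
#' @param age_years age estimate(s), years (vectorised).
#' @param track_length_cm the track's axial length, cm.
#' @param bull_threshold_cm track length above which an adult is an old bull
#'   (default 50).
#' @param qualifier censoring qualifier(s) from [age_at_height()]; only used
#'   for documentation of intent -- classification uses the value itself.
#' @return Factor with levels [age_class_levels()].
#' @export
#' @examples
#' assign_age_class(0.5, 12)    # calf
#' assign_age_class(60, 51)     # old_bull
assign_age_class <- function(age_years, track_length_cm,
                             bull_threshold_cm = 50, qualifier = "point") {
  stopifnot(all(age_years >= 0), all(track_length_cm > 0))
  cls <- ifelse(age_years < 2, "calf",
         ifelse(age_years < 8, "juvenile",
         ifelse(age_years <= 15, "adolescent", "adult")))
  cls <- ifelse(cls == "adult" & track_length_cm > bull_threshold_cm,
                "old_bull", cls)
  factor(cls, levels = age_class_levels())
}

# Pick each individual's representative record index: the longest pes if any
# pes exists, else the longest manus/unknown. Order-independent.
.representative <- function(tracks) {
  split_idx <- split(seq_len(nrow(tracks)),
                     paste(tracks$sector, tracks$letter, sep = "."))
  vapply(split_idx, function(i) {
    pes <- i[tracks$limb[i] == "pes"]
    pool <- if (length(pes)) pes else i
    pool[which.max(tracks$length_cm[pool])]
  }, integer(1))
}

#' Demographic frequency table of a track assemblage
#'
#' Collapses track records to individuals (keyed by sector and letter), picks
#' one representative track per individual (the pes when present, else the
#' manus -- hindfoot measurements are preferred), chooses the sex hypothesis
#' by a size policy, and tabulates individuals per age class.
#'
#' @param tracks a track table.
#' @param estimates the output of [estimate_tracks()] for the same records
#'   (computed if missing).
#' @param sex_policy foot length (cm) below which the female-hypothesis age
#'   drives classification and above which the male one does (default 38).
#'   Post-puberty sex cannot be read from a track; this policy mirrors the
#'   reporting convention of the source table.
#' @param bull_threshold_cm old-bull track-length threshold (default 50 cm).
#' @param params,growth parameter objects used if `estimates` is missing.
#' @return An object of class `demography_table`: a list with `counts`
#'   (named integer vector over [age_class_levels()]), `total`, `fl_range`
#'   (per-class min/max representative foot length), `individuals` (per
#'   individual: key, representative record, sex hypothesis, age, class) and
#'   `conflicts` (individuals whose records disagree on class, resolved by
#'   the representative track).
#' @export
demographic_frequency <- function(tracks, estimates = NULL, sex_policy = 38,
                                  bull_threshold_cm = 50,
                                  params = allometry_params(),
                                  growth = growth_params()) {
  if (is.null(estimates)) {
    estimates <- estimate_tracks(tracks, params, growth)
  }
  stopifnot(nrow(estimates) == nrow(tracks))
  classify_row <- function(i) {
    female <- estimates$fl_cm[i] < sex_policy
    age <- if (female) estimates$age_f_yr[i] else estimates$age_m_yr[i]
    qual <- if (female) estimates$qual_f[i] else estimates$qual_m[i]
    list(sex = if (female) "female" else "male", age = age, qual = qual,
         class = as.character(assign_age_class(age, tracks$length_cm[i],
                                               bull_threshold_cm, qual)))
  }
  n <- nrow(tracks)
  if (n == 0L) {
    counts <- stats::setNames(integer(5), age_class_levels())
    return(structure(list(counts = counts, total = 0L,
                          fl_range = NULL, individuals = NULL,
                          conflicts = character(0)),
                     class = "demography_table"))
  }
  per_row <- lapply(seq_len(n), classify_row)
  rep_idx <- .representative(tracks)
  keys <- names(rep_idx)
  ind <- data.frame(
    individual = keys,
    record_id = tracks$record_id[rep_idx],
    limb = tracks$limb[rep_idx],
    fl_cm = tracks$length_cm[rep_idx],
    sex_hypothesis = vapply(rep_idx, function(i) per_row[[i]]$sex, ""),
    age_years = vapply(rep_idx, function(i) per_row[[i]]$age, 0),
    qualifier = vapply(rep_idx, function(i) per_row[[i]]$qual, ""),
    age_class = vapply(rep_idx, function(i) per_row[[i]]$class, ""),
    stringsAsFactors = FALSE)
  ind <- ind[order(ind$individual), ]
  rownames(ind) <- NULL
  # individuals whose non-representative records would classify differently
  all_classes <- vapply(per_row, `[[`, "", "class")
  key_of_row <- paste(tracks$sector, tracks$letter, sep = ".")
  conflicts <- names(Filter(function(k) k > 1,
    lapply(split(all_classes, key_of_row), function(cl) length(unique(cl)))))
  counts <- table(factor(ind$age_class, levels = age_class_levels()))
  counts <- stats::setNames(as.integer(counts), age_class_levels())
  fl_range <- do.call(rbind, lapply(age_class_levels(), function(cl) {
    x <- ind$fl_cm[ind$age_class == cl]
    data.frame(age_class = cl,
               fl_min_cm = if (length(x)) min(x) else NA_real_,
               fl_max_cm = if (length(x)) max(x) else NA_real_)
  }))
  structure(list(counts = counts, total = nrow(ind), fl_range = fl_range,
                 individuals = ind, conflicts = unlist(conflicts)),
            class = "demography_table")
}

#' @export
print.demography_table <- function(x, ...) {
  cat("Demographic frequency (", x$total, "individuals )\n")
  for (cl in age_class_levels()) {
    bar <- paste(rep("#", x$counts[[cl]]), collapse = "")
    cat(sprintf("  %-10s %3d %s\n", cl, x$counts[[cl]], bar))
  }
  if (length(x$conflicts)) {
    cat("  class conflicts resolved by representative track:",
        paste(x$conflicts, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.demography_table <- function(x, ...) {
  data.frame(age_class = age_class_levels(),
             n = unname(x$counts[age_class_levels()]),
             stringsAsFactors = FALSE)
}

#' @rdname demographic_frequency
#' @param x a `demography_table`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.demography_table <- function(x, ...) {
  graphics::barplot(x$counts, names.arg = age_class_levels(),
                    ylab = "projected number of individuals (N)",
                    xlab = "age class", ...)
  invisible(x)
}

#' Write a demographic frequency table to CSV
#'
#' @param x a `demography_table`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_demography <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}

#' Summary statistics of a track assemblage
#'
#' Exact order statistics of the measurement columns: per-limb counts and
#' length range/median, the overall range, and the number of labelled
#' trackways.
#'
#' @param tracks a track table.
#' @return A list with `n_records`, `per_limb` (data frame: limb, n, min,
#'   median, max length), `length_range_cm`, `n_trackways`,
#'   `n_individuals`; or an empty-summary sentinel (`n_records = 0`) for an
#'   empty table.
#' @export
assemblage_summary <- function(tracks) {
  if (nrow(tracks) == 0L) {
    return(list(n_records = 0L, per_limb = NULL,
                length_range_cm = c(NA_real_, NA_real_),
                n_trackways = 0L, n_individuals = 0L))
  }
  per_limb <- do.call(rbind, lapply(c("manus", "pes", "unknown"),
    function(l) {
      x <- tracks$length_cm[tracks$limb == l]
      if (!length(x)) return(NULL)
      data.frame(limb = l, n = length(x), min_cm = min(x),
                 median_cm = stats::median(x), max_cm = max(x),
                 stringsAsFactors = FALSE)
    }))
  list(n_records = nrow(tracks),
       per_limb = per_limb,
       length_range_cm = range(tracks$length_cm),
       n_trackways = length(unique(tracks$trackway_id[
         !is.na(tracks$trackway_id) & tracks$trackway_id != ""])),
       n_individuals = length(count_individuals(tracks)))
}
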