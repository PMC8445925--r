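#' @keywords internal
"_PACKAGE"

# Canonical columns of a track table; the first four are mandatory on read.
.track_columns <- c("record_id", "limb", "length_cm", "width_cm",
                    "toe_impressions", "trackway_id", "overstepped",
                    "x_m", "y_m", "notes")

#' Round half away from zero
#'
#' Reporting convention for derived columns: nearest integer with ties
#' rounded away from zero (225.51 -> 226, 66.5 -> 67), unlike [base::round()]
#' which rounds half to even.
#'
#' @param x numeric vector.
#' @return `x` rounded to the nearest integer, ties away from zero.
#' @export
#' @examples
#' round_half_away(c(66.5, -66.5, 225.51))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Parse structured track identifiers
#'
#' Track identifiers follow the grammar `<site>/<sector><letter?>`, e.g.
#' `"PAT/MTS/003a"`: a site prefix, a numeric sector, and an optional single
#' lowercase suffix letter distinguishing individuals within the sector
#' (`x` is an ordinary individual letter).
#'
#' @param record_id character vector of identifiers.
#' @return A data frame with columns `site`, `sector`, `letter` (empty string
#'   when absent) and `individual` (the `"sector.letter"` key used to count
#'   individuals).
#' @export
#' @examples
#' parse_track_id(c("PAT/MTS/003a", "PAT/MTS/016"))
parse_track_id <- function(record_id) {
  record_id <- as.character(record_id)
  bad <- !grepl("^.*[0-9]+[a-z]?$", record_id)
  if (any(bad)) {
    stop("unparseable record_id: ", paste(record_id[bad], collapse = ", "),
         call. = FALSE)
  }
  # suffix letter = whatever follows the trailing digit run (possibly empty)
  letter <- sub("^.*[0-9]", "", record_id)
  base <- substr(record_id, 1L, nchar(record_id) - nchar(letter))
  sector <- regmatches(base, regexpr("[0-9]+$", base))
  site <- sub("/?[0-9]+$", "", base)
  data.frame(site = site, sector = sector, letter = letter,
             individual = paste(sector, letter, sep = "."),
             stringsAsFactors = FALSE)
}

# Parse toe impression strings ("3", "2-3", "") into (min, max) integer pairs.
# Unparseable strings yield NA pairs and are reported via attribute "unparsed".
.parse_toes <- function(x) {
  x <- trimws(gsub("–", "-", as.character(x)))
  lo <- rep(NA_integer_, length(x))
  hi <- rep(NA_integer_, length(x))
  single <- grepl("^[0-9]+$", x)
  lo[single] <- hi[single] <- as.integer(x[single])
  rng <- grepl("^[0-9]+-[0-9]+$", x)
  lo[rng] <- as.integer(sub("-.*$", "", x[rng]))
  hi[rng] <- as.integer(sub("^.*-", "", x[rng]))
  unparsed <- !single & !rng & !is.na(x) & x != ""
  structure(list(min = lo, max = hi), unparsed = unparsed)
}

.validate_tracks <- function(tracks) {
  for (col in c("record_id", "limb", "length_cm", "width_cm")) {
    if (!col %in% names(tracks)) {
      stop("track table is missing mandatory column '", col, "'",
           call. = FALSE)
    }
  }
  bad <- which(!is.finite(tracks$length_cm) | tracks$length_cm <= 0 |
                 !is.finite(tracks$width_cm) | tracks$width_cm <= 0)
  if (length(bad)) {
    stop("non-positive or missing dimensions in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(tracks$limb %in% c("manus", "pes", "unknown"))) {
    stop("limb must be one of 'manus', 'pes', 'unknown' (or M/P on read)",
         call. = FALSE)
  }
  ids <- parse_track_id(tracks$record_id)
  if (any(nchar(ids$letter) > 1L)) {
    stop("individual letter must be a single lowercase letter", call. = FALSE)
  }
  toe_ok <- is.na(tracks$toe_min) |
    (tracks$toe_min >= 1L & tracks$toe_max <= 5L & tracks$toe_min <= tracks$toe_max)
  if (!all(toe_ok)) {
    stop("toe counts must lie in 1..5 (rows ",
         paste(which(!toe_ok), collapse = ", "), ")", call. = FALSE)
  }
  invisible(tracks)
}

#' Read a track measurement table
#'
#' Reads a delimited text table of footprint measurements, one row per track.
#' The canonical dialect is comma-separated, UTF-8, decimal point, header
#' mandatory. Mandatory columns: `record_id`, `limb` (`M`/`P`/`manus`/`pes`,
#' empty for unknown), `length_cm`, `width_cm`. Optional columns
#' `toe_impressions` (a count or a range such as `"2-3"`), `trackway_id`,
#' `overstepped`, `x_m`, `y_m`, `notes` are carried through; missing ones are
#' filled with defaults. Extra columns are ignored. Unparseable toe strings
#' are retained in `notes` rather than dropped.
#'
#' @param file path to a CSV file, or a connection.
#' @param sep field separator (default `","`).
#' @return A data frame of validated track records with columns
#'   `record_id`, `site`, `sector`, `letter`, `limb`, `length_cm`, `width_cm`,
#'   `toe_impressions`, `toe_min`, `toe_max`, `trackway_id`, `overstepped`,
#'   `x_m`, `y_m`, `notes`.
#' @seealso [write_track_table()], [mts_table1()]
#' @export
read_track_table <- function(file, sep = ",") {
  raw <- utils::read.csv(file, sep = sep, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE,
                         fileEncoding = "UTF-8")
  for (col in c("record_id", "limb", "length_cm", "width_cm")) {
    if (!col %in% names(raw)) {
      stop("track table is missing mandatory column '", col, "'",
           call. = FALSE)
    }
  }
  if (nrow(raw) == 0L) {
    return(as_track_table(data.frame(record_id = character(0),
                                     limb = character(0),
                                     length_cm = numeric(0),
                                     width_cm = numeric(0))))
  }
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(is.na(raw[[col]]) | raw[[col]] == ""))
    if (length(bad)) {
      stop("column '", col, "' not parseable as a decimal in row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    v
  }
  opt <- function(col, default) if (col %in% names(raw)) raw[[col]] else
    rep(default, nrow(raw))
  limb <- c(M = "manus", P = "pes", manus = "manus", pes = "pes",
            unknown = "unknown")[trimws(raw$limb)]
  limb[is.na(limb)] <- "unknown"
  tracks <- data.frame(
    record_id = trimws(raw$record_id),
    limb = unname(limb),
    length_cm = num("length_cm"),
    width_cm = num("width_cm"),
    toe_impressions = trimws(opt("toe_impressions", "")),
    trackway_id = trimws(opt("trackway_id", "")),
    overstepped = tolower(trimws(opt("overstepped", "FALSE"))) %in%
      c("true", "t", "1", "yes"),
    x_m = suppressWarnings(as.numeric(opt("x_m", NA))),
    y_m = suppressWarnings(as.numeric(opt("y_m", NA))),
    notes = opt("notes", ""),
    stringsAsFactors = FALSE
  )
  as_track_table(tracks)
}

#' Build a validated track table from a data frame
#'
#' Normalises, parses identifiers and toe counts, and validates the record
#' invariants (positive dimensions, single-letter individual suffix, toe
#' counts in 1..5).
#'
#' @param tracks data frame with at least `record_id`, `limb`, `length_cm`,
#'   `width_cm`.
#' @return The validated track table (see [read_track_table()]).
#' @export
as_track_table <- function(tracks) {
  tracks <- as.data.frame(tracks, stringsAsFactors = FALSE)
  for (col in .track_columns) {
    if (!col %in% names(tracks)) {
      fill <- switch(col,
        toe_impressions = "", trackway_id = "", notes = "",
        overstepped = FALSE, x_m = NA_real_, y_m = NA_real_,
        stop("track table is missing mandatory column '", col, "'",
             call. = FALSE))
      tracks[[col]] <- rep(fill, nrow(tracks))
    }
  }
  toes <- .parse_toes(tracks$toe_impressions)
  tracks$toe_min <- toes$min
  tracks$toe_max <- toes$max
  unp <- attr(toes, "unparsed")
  if (any(unp)) {
    tracks$notes[unp] <- trimws(paste(tracks$notes[unp], "unparsed toe count:",
                                      tracks$toe_impressions[unp]))
  }
  ids <- parse_track_id(tracks$record_id)
  tracks$site <- ids$site
  tracks$sector <- ids$sector
  tracks$letter <- ids$letter
  tracks <- tracks[, c("record_id", "site", "sector", "letter", "limb",
                       "length_cm", "width_cm", "toe_impressions",
                       "toe_min", "toe_max", "trackway_id", "overstepped",
                       "x_m", "y_m", "notes")]
  if (nrow(tracks)) .validate_tracks(tracks)
  rownames(tracks) <- NULL
  tracks
}

#' Write a track table to CSV
#'
#' Writes the canonical track-table columns so that
#' `read_track_table(write_track_table(x, f))` round-trips all fields.
#'
#' @param tracks a track table (see [read_track_table()]).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_track_table <- function(tracks, file) {
  out <- tracks[, intersect(.track_columns, names(tracks))]
  utils::write.csv(out, file, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' Classify a footprint as forefoot or hindfoot from its outline
#'
#' Elephant hindfeet (pes) leave elliptical to sub-rounded prints with the
#' length axis exceeding the width; forefeet (manus) are circular or
#' elliptical with width exceeding length. Prints whose relative
#' length-width difference falls within a circularity tolerance are
#' subcircular and classified `unknown`.
#'
#' @param length_cm,width_cm positive print dimensions (vectorised).
#' @param toe_impressions optional toe counts; currently annotational only
#'   (toe counts of 3-5 occur on both feet).
#' @param circularity_tol relative tolerance `|L - W| / max(L, W)` below which
#'   the print is called subcircular (default 0.05).
#' @return A character vector in `c("manus", "pes", "unknown")` with a
#'   `confidence` attribute holding the relative asymmetry of each print.
#' @export
#' @examples
#' classify_limb(17.7, 10.5)  # pes
#' classify_limb(15, 17)      # manus
classify_limb <- function(length_cm, width_cm, toe_impressions = NULL,
                          circularity_tol = 0.05) {
  if (any(!is.finite(length_cm) | length_cm <= 0 |
            !is.finite(width_cm) | width_cm <= 0)) {
    stop("length_cm and width_cm must be positive", call. = FALSE)
  }
  asym <- abs(length_cm - width_cm) / pmax(length_cm, width_cm)
  out <- ifelse(asym <= circularity_tol, "unknown",
                ifelse(length_cm > width_cm, "pes", "manus"))
  attr(out, "confidence") <- asym
  out
}

#' Screening configuration for track records
#'
#' Encodes the record-level screening applied before estimation: prints whose
#' width/length ratio falls outside a band are treated as slippage, and the
#' overstepped member of a manus-pes couple is unreliable. The direction of
#' the published slippage rule is ambiguous, so the default mode is
#' `"report_only"`: records are flagged but kept. `"exclude"` moves flagged
#' records out of the analysis set.
#'
#' @param wl_ratio_min,wl_ratio_max width/length ratio band (defaults 0.80,
#'   0.96).
#' @param mode `"report_only"` (default) or `"exclude"`.
#' @param exclude_overstepped flag overstepped records (default `TRUE`).
#' @return An object of class `screening_config`.
#' @export
screening_config <- function(wl_ratio_min = 0.80, wl_ratio_max = 0.96,
                             mode = c("report_only", "exclude"),
                             exclude_overstepped = TRUE) {
  mode <- match.arg(mode)
  stopifnot(wl_ratio_min > 0, wl_ratio_min <= wl_ratio_max)
  structure(list(wl_ratio_min = wl_ratio_min, wl_ratio_max = wl_ratio_max,
                 mode = mode, exclude_overstepped = exclude_overstepped),
            class = "screening_config")
}

#' Screen track records for slippage and overstepping
#'
#' Partitions a track table into kept and flagged records. Measurements are
#' never altered; every input row lands in exactly one partition (in
#' `report_only` mode all rows are kept and flag reasons are attached).
#'
#' @param tracks a track table.
#' @param config a [screening_config()].
#' @return A list with elements `kept` and `flagged` (both track tables; the
#'   flagged table gains a `flag_reason` column) plus `reasons`, a character
#'   vector parallel to the input rows ("" where clean).
#' @export
screen_records <- function(tracks, config = screening_config()) {
  stopifnot(inherits(config, "screening_config"))
  wl <- tracks$width_cm / tracks$length_cm
  reasons <- rep("", nrow(tracks))
  out_of_band <- wl < config$wl_ratio_min | wl > config$wl_ratio_max
  reasons[out_of_band] <- sprintf("W/L ratio %.3f outside [%.2f, %.2f]",
                                  wl[out_of_band], config$wl_ratio_min,
                                  config$wl_ratio_max)
  if (config$exclude_overstepped && any(tracks$overstepped)) {
    i <- which(tracks$overstepped)
    reasons[i] <- trimws(paste(reasons[i], "overstepped"))
  }
  flagged_idx <- which(reasons != "")
  if (config$mode == "exclude") {
    kept <- tracks[setdiff(seq_len(nrow(tracks)), flagged_idx), , drop = FALSE]
    flagged <- tracks[flagged_idx, , drop = FALSE]
  } else {
    kept <- tracks
    flagged <- tracks[integer(0), , drop = FALSE]
  }
  if (nrow(flagged)) flagged$flag_reason <- reasons[flagged_idx]
  else flagged$flag_reason <- character(0)
  rownames(kept) <- rownames(flagged) <- NULL
  list(kept = kept, flagged = flagged, reasons = reasons)
}

#' Count distinct individuals in a track table
#'
#' Individuals are keyed by (sector, letter): tracks sharing a sector number
#' and suffix letter (for example the manus and pes of one trackway) are the
#' same animal.
#'
#' @param tracks a track table.
#' @return Character vector of unique individual keys (`"sector.letter"`);
#'   its length is the individual count.
#' @export
count_individuals <- function(tracks) {
  if (nrow(tracks) == 0L) return(character(0))
  unique(paste(tracks$sector, tracks$letter, sep = "."))
}

#' The Matalascanas Trampled Surface track table
#'
#' The packaged measurement table of the 34 proboscidean tracks of the
#' Matalascanas Trampled Surface (Huelva, SW Spain), ordered smallest to
#' largest, together with the published derived columns: estimated shoulder
#' height (`esh_*_cm`), body mass (`ebm_*_kg`) and age (`ea_*_yr`, possibly
#' censored strings such as `"<1"`) under the male (`_m_`) and female (`_f_`)
#' hypotheses, and the published age-class block (`age_class_block`).
#'
#' @param golden if `TRUE` (default) attach the published derived columns;
#'   if `FALSE` return only the measurement columns as a plain track table.
#' @return A validated track table, with the published columns appended when
#'   `golden = TRUE`.
#' @export
#' @examples
#' nrow(mts_table1(golden = FALSE))  # 34
mts_table1 <- function(golden = TRUE) {
  path <- system.file("extdata", "mts_table1.csv", package = "proboscipeda",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  tracks <- read_track_table(path)
  if (!golden) return(tracks)
  for (col in c("esh_m_cm", "ebm_m_kg", "esh_f_cm", "ebm_f_kg")) {
    tracks[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  tracks$ea_m_yr <- raw$ea_m_yr
  tracks$ea_f_yr <- raw$ea_f_yr
  tracks$age_class_block <- raw$age_class_block
  tracks
}
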