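test_that("track identifiers parse into site, sector and individual letter", {
  p <- parse_track_id(c("PAT/MTS/003a", "PAT/MTS/012x", "PAT/MTS/016",
                        "SIM/0042"))
  expect_equal(p$sector, c("003", "012", "016", "0042"))
  expect_equal(p$letter, c("a", "x", "", ""))
  expect_equal(p$site, c("PAT/MTS", "PAT/MTS", "PAT/MTS", "SIM"))
  expect_error(parse_track_id("no-digits"), "unparseable")
})

test_that("reading a track table parses rows, IDs and toe ranges", {
  csv <- "record_id,limb,length_cm,width_cm,toe_impressions\nPAT/MTS/005,P,9.6,7.3,\nPAT/MTS/012a,P,14.1,10.8,2-3\n"
  tr <- read_track_table(textConnection(csv))
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$limb, c("pes", "pes"))
  expect_equal(tr$length_cm, c(9.6, 14.1))
  expect_equal(tr$toe_min, c(NA_integer_, 2L))
  expect_equal(tr$toe_max, c(NA_integer_, 3L))

  empty <- read_track_table(textConnection(
    "record_id,limb,length_cm,width_cm\n"))
  expect_equal(nrow(empty), 0L)
})

test_that("read errors name the offending column or row", {
  expect_error(read_track_table(textConnection(
    "record_id,limb,length_cm\nPAT/MTS/005,P,9.6\n")), "width_cm")
  expect_error(read_track_table(textConnection(
    "record_id,limb,length_cm,width_cm\nPAT/MTS/005,P,-9.6,7.3\n")),
    "row\\(s\\) 1")
  expect_error(read_track_table(textConnection(
    "record_id,limb,length_cm,width_cm,toe_impressions\nPAT/MTS/005,P,9.6,7.3,7\n")),
    "toe")
})

test_that("the packaged table has 34 rows, 15 in the calf block", {
  tab <- mts_table1()
  expect_equal(nrow(tab), 34L)
  expect_equal(sum(tab$age_class_block == "calf"), 15L)
  expect_equal(length(count_individuals(tab)), 33L)  # PAT/MTS/005 repeats
})

test_that("write/read round-trips every field bit-identically", {
  tab <- mts_table1(golden = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_track_table(tab, f)
  back <- read_track_table(f)
  expect_identical(back, tab)
})

test_that("limb classification follows outline elongation", {
  expect_equal(as.character(classify_limb(17.7, 10.5)), "pes")
  expect_equal(as.character(classify_limb(15, 17)), "manus")
  expect_equal(as.character(classify_limb(10, 10)), "unknown")
  expect_error(classify_limb(0, 5), "positive")
})

test_that("limb classification is antisymmetric away from circularity", {
  set.seed(11)
  l <- runif(200, 5, 60)
  w <- l * runif(200, 0.5, 2)
  asym <- abs(l - w) / pmax(l, w)
  keep <- asym > 0.06
  a <- classify_limb(l[keep], w[keep])
  b <- classify_limb(w[keep], l[keep])
  expect_true(all((a == "pes") == (b == "manus")))
  expect_false(any(a == "unknown"))
})

test_that("screening partitions records completely and never mutates them", {
  tab <- mts_table1(golden = FALSE)
  tab$overstepped[3] <- TRUE
  for (mode in c("report_only", "exclude")) {
    for (band in list(c(0.80, 0.96), c(0.5, 0.9), c(0.95, 0.96))) {
      cfg <- screening_config(band[1], band[2], mode = mode)
      s <- screen_records(tab, cfg)
      expect_equal(nrow(s$kept) + nrow(s$flagged), nrow(tab))
      key <- function(x) sort(paste(x$record_id, x$limb, x$length_cm))
      expect_equal(sort(c(key(s$kept), key(s$flagged))), key(tab))
    }
  }
})

test_that("default screening reports rather than excludes; the W/L band flags the elongate pes", {
  tab <- mts_table1(golden = FALSE)
  s <- screen_records(tab, screening_config())
  expect_equal(nrow(s$kept), 34L)
  n_low <- sum(tab$limb == "pes" & tab$width_cm / tab$length_cm < 0.80)
  expect_equal(n_low, 16L)  # counted from the packaged table
  flagged_pes <- grepl("W/L", s$reasons) & tab$limb == "pes"
  expect_gte(sum(flagged_pes), n_low)

  sx <- screen_records(tab, screening_config(mode = "exclude"))
  expect_equal(nrow(sx$kept) + nrow(sx$flagged), 34L)
  expect_true(all(grepl("W/L|overstepped", sx$flagged$flag_reason)))
})

test_that("overstepped records are flagged with the reason", {
  tr <- as_track_table(data.frame(
    record_id = c("X/1", "X/2"), limb = c("pes", "manus"),
    length_cm = c(30, 28), width_cm = c(27, 30),
    overstepped = c(FALSE, TRUE)))
  s <- screen_records(tr, screening_config(mode = "exclude"))
  expect_equal(s$flagged$record_id, "X/2")
  expect_match(s$flagged$flag_reason, "overstepped")
})

test_that("individuals are keyed by (sector, letter), not per record", {
  tr <- as_track_table(data.frame(
    record_id = c("PAT/MTS/003a", "PAT/MTS/003b", "PAT/MTS/003a"),
    limb = c("pes", "pes", "manus"),
    length_cm = c(20, 25, 19), width_cm = c(15, 20, 21)))
  expect_equal(length(count_individuals(tr)), 2L)
  expect_equal(length(count_individuals(tr[0, ])), 0L)
})
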