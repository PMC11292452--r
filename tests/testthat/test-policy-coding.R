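# day-count oracle: count in-force days by enumerating the calendar
oracle_exposure <- function(eff, rep_, year) {
  days <- seq(as.Date(sprintf("%d-01-01", year)),
              as.Date(sprintf("%d-12-31", year)), by = "day")
  in_force <- days >= as.Date(eff)
  if (!is.null(rep_)) in_force <- in_force & days < as.Date(rep_)
  sum(in_force) / length(days)
}

test_that("exposure_fraction matches the calendar day-count oracle", {
  expect_equal(exposure_fraction("1995-01-01", NULL, 1995), 1.0)
  expect_equal(exposure_fraction("1995-03-01", NULL, 1994), 0.0)
  expect_equal(exposure_fraction("1995-07-02", NULL, 1995), 183 / 365)
  cases <- list(
    list("1995-07-02", NULL, 1995),
    list("1996-02-29", NULL, 1996),     # leap year, 366-day denominator
    list("1999-12-31", NULL, 1999),
    list("1990-06-15", "1992-03-01", 1992),  # repeal mid-year
    list("1990-06-15", "1992-03-01", 1993),  # fully repealed
    list("2000-01-01", "2000-07-01", 2000)
  )
  for (cs in cases) {
    expect_equal(exposure_fraction(cs[[1]], cs[[2]], cs[[3]]),
                 oracle_exposure(cs[[1]], cs[[2]], cs[[3]]),
                 info = paste(unlist(cs), collapse = " "))
  }
})

test_that("exposure_fraction rejects invalid dates", {
  expect_error(exposure_fraction("not-a-date", NULL, 1995), "unparseable")
  expect_error(exposure_fraction("1995-01-01", "1994-12-31", 1995),
               "strictly after")
})

test_that("phase_in is the clipped linear ramp", {
  expect_equal(phase_in(0), 0)
  expect_equal(phase_in(5), 1)
  expect_equal(phase_in(2.5), 0.5)
  expect_equal(phase_in(-3), 0)
  expect_equal(phase_in(12), 1)
  expect_equal(phase_in(1, horizon = 2), 0.5)
  expect_error(phase_in(1, horizon = 0), "positive")
})

test_that("law_records validates fields and fixes direction by policy", {
  lr <- law_records("CA", "stand_your_ground", "2005-10-01")
  expect_s3_class(lr, "law_records")
  expect_equal(lr$direction, "permissive")
  expect_error(law_records("CA", "not_a_policy", "2005-10-01"), "unknown")
  expect_error(law_records("Cal", "bc_dealer", "2005-10-01"), "2-letter")
  expect_error(law_records("CA", "bc_dealer", "2005-10-01", "2004-01-01"),
               "strictly after")
})

test_that("build_policy_panel covers the grid with correct e and f", {
  years <- 1995:2010
  empty <- law_records(character(), character(), as.Date(character()))
  p0 <- build_policy_panel(empty, c("AA", "BB"), years)
  expect_equal(nrow(p0), 2 * length(years) * 10)
  expect_true(all(p0$exposure == 0) && all(p0$phase == 0))

  old <- law_records("AA", "bc_dealer", "1900-01-01")
  p1 <- build_policy_panel(old, "AA", years)
  sub <- p1[p1$policy_id == "bc_dealer", ]
  expect_true(all(sub$exposure == 1) && all(sub$phase == 1))

  rec <- law_records("AA", "bc_dealer", "2000-01-01")
  p2 <- build_policy_panel(rec, "AA", years)
  sub <- p2[p2$policy_id == "bc_dealer", ]
  expect_equal(sub$exposure, ifelse(years >= 2000, 1, 0))
  expect_equal(sub$phase[sub$year == 2000], 0.1, tolerance = 0.005)
  expect_true(all(sub$phase[sub$year >= 2005] == 1))
  expect_true(all(sub$phase[sub$year < 2000] == 0))
  expect_true(all(diff(sub$phase) >= 0))
})

test_that("panel bounds and year-shift equivariance hold", {
  years <- 1995:2012
  for (eff in c("2001-03-15", "1997-11-30")) {
    r1 <- law_records("AA", "cap_storage", eff)
    eff2 <- as.Date(eff) + 365  # same calendar date next (non-leap) year
    r2 <- law_records("AA", "cap_storage", eff2)
    p1 <- build_policy_panel(r1, "AA", years)
    p2 <- build_policy_panel(r2, "AA", years)
    s1 <- p1[p1$policy_id == "cap_storage", ]
    s2 <- p2[p2$policy_id == "cap_storage", ]
    expect_true(all(s1$exposure >= 0 & s1$exposure <= 1))
    expect_true(all(s1$phase >= 0 & s1$phase <= 1))
    shift_years <- years[-length(years)]
    expect_equal(s2$exposure[match(shift_years + 1, s2$year)],
                 s1$exposure[match(shift_years, s1$year)], tolerance = 1e-9)
    # phase uses real calendars; a leap day inside the phase-in window can
    # shift years_since by 1/365.25
    expect_equal(s2$phase[match(shift_years + 1, s2$year)],
                 s1$phase[match(shift_years, s1$year)], tolerance = 0.002)
  }
})

test_that("repeal returns exposure and phase to zero", {
  rec <- law_records("AA", "wait_24h", "2000-07-01", "2004-03-01")
  p <- build_policy_panel(rec, "AA", 1998:2008)
  sub <- p[p$policy_id == "wait_24h", ]
  expect_equal(sub$exposure[sub$year == 2004], oracle_exposure(
    "2000-07-01", "2004-03-01", 2004))
  expect_true(all(sub$exposure[sub$year > 2004] == 0))
  expect_true(all(sub$phase[sub$year >= 2004] == 0))  # repealed pre-midpoint
  expect_true(all(sub$phase[sub$year %in% 2001:2003] > 0))
})

test_that("overlapping records for one state-policy are rejected", {
  recs <- law_records(c("AA", "AA"), c("bc_dealer", "bc_dealer"),
                      c("2000-01-01", "2003-01-01"))
  expect_error(build_policy_panel(recs, "AA", 1998:2008), "overlapping")
  # non-overlapping re-enactment is fine
  recs2 <- law_records(c("AA", "AA"), c("bc_dealer", "bc_dealer"),
                       c("2000-01-01", "2005-01-01"),
                       c("2002-06-30", NA))
  expect_silent(build_policy_panel(recs2, "AA", 1998:2008))
})

test_that("class map matches the checked-in fixture and 4+2 structure", {
  pol <- firearm_policies()
  fix <- read.csv(system.file("extdata", "policy_classes.csv",
                              package = "gunpolicy"),
                  stringsAsFactors = FALSE)
  expect_equal(pol[, c("policy_id", "class", "direction", "combination")],
               fix)
  expect_equal(anyDuplicated(pol$policy_id), 0L)
  byclass <- unique(pol[, c("class", "direction")])
  expect_equal(sum(byclass$direction == "restrictive"), 4L)
  expect_equal(sum(byclass$direction == "permissive"), 2L)
  expect_equal(sum(pol$direction == "restrictive"), 7L)
  # every policy in exactly one class and one combination
  expect_true(all(table(pol$policy_id) == 1))
})

test_that("laws CSV round-trips through read_laws", {
  df <- data.frame(state = c("AA", "BB"), policy_id = c("bc_dealer",
                   "permitless_carry"),
                   effective_date = c("1994-02-28", "2010-07-01"),
                   repeal_date = c("", "2015-01-01"))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  lr <- read_laws(path)
  expect_equal(lr$state, c("AA", "BB"))
  expect_equal(lr$repeal_date, as.Date(c(NA, "2015-01-01")))
  expect_equal(lr$direction, c("restrictive", "permissive"))
})
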