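#' The ten modeled state firearm policies
#'
#' Returns the enumeration of the ten state firearm policies the model
#' estimates jointly, their conceptual policy class, their direction
#' (restrictive laws limit firearm purchase, possession, storage or use;
#' permissive laws expand carry or use), and the broader combination
#' (purchase-and-possession vs use-and-storage) each class belongs to.
#'
#' Four classes are restrictive (background checks, minimum age, waiting
#' periods, child access prevention) and two are permissive (concealed carry
#' deregulation, stand-your-ground).
#'
#' @return A data.frame with columns `policy_id`, `label`, `class`,
#'   `direction` (`"restrictive"` or `"permissive"`) and `combination`
#'   (`"purchase_possession"` or `"use_storage"`), one row per policy.
#' @export
firearm_policies <- function() {
  data.frame(
    policy_id = c(
      "bc_dealer", "bc_private",
      "possess_under18", "purchase_under20",
      "wait_24h", "wait_7day",
      "cap_storage",
      "shall_issue", "permitless_carry",
      "stand_your_ground"
    ),
    label = c(
      "Background checks for dealer sales",
      "Background checks for private sales",
      "Possession prohibited under age 18",
      "Purchase prohibited under age 20",
      "24-hour waiting period",
      "7-day waiting period",
      "Child-access-prevention storage requirement",
      "Shall-issue concealed carry (no discretion)",
      "Permitless concealed carry",
      "Stand-your-ground"
    ),
    class = c(
      "background_checks", "background_checks",
      "minimum_age", "minimum_age",
      "waiting_period", "waiting_period",
      "child_access",
      "concealed_carry", "concealed_carry",
      "stand_your_ground"
    ),
    direction = c(rep("restrictive", 7L), rep("permissive", 3L)),
    combination = c(rep("purchase_possession", 6L), rep("use_storage", 4L)),
    stringsAsFactors = FALSE
  )
}

policy_ids <- function() firearm_policies()$policy_id

parse_date <- function(x) {
  tryCatch(as.Date(x), error = function(e) as.Date(NA))
}

#' Construct a validated set of law records
#'
#' A law record is one policy enactment: the state, which of the ten policies
#' it is, the date it took effect and (optionally) the date it was repealed.
#' Direction is fixed by the policy identifier and is attached automatically.
#'
#' @param state Character vector of 2-letter state codes.
#' @param policy_id Character vector; each element one of
#'   `firearm_policies()$policy_id`.
#' @param effective_date Dates (or ISO-8601 strings) on which each law took
#'   effect (first day in force).
#' @param repeal_date Optional dates on which each law ceased to be in force
#'   (the repeal day itself is no longer in force); `NA` for laws never
#'   repealed.
#' @return A data.frame of class `"law_records"` with columns `state`,
#'   `policy_id`, `effective_date`, `repeal_date`, `direction`.
#' @export
law_records <- function(state, policy_id, effective_date,
                        repeal_date = as.Date(NA)) {
  effective_date <- as.Date(effective_date)
  repeal_date <- as.Date(repeal_date)
  n <- length(state)
  if (length(policy_id) != n || length(effective_date) != n)
    stop("state, policy_id and effective_date must have equal length")
  repeal_date <- rep_len(repeal_date, n)
  if (!all(grepl("^[A-Z]{2}$", state)))
    stop("state must be 2-letter uppercase codes")
  pol <- firearm_policies()
  bad <- setdiff(unique(policy_id), pol$policy_id)
  if (length(bad))
    stop("unknown policy_id: ", paste(bad, collapse = ", "))
  if (anyNA(effective_date))
    stop("effective_date contains missing or unparseable dates")
  rev <- !is.na(repeal_date) & repeal_date <= effective_date
  if (any(rev))
    stop("repeal_date must be strictly after effective_date (rows ",
         paste(which(rev), collapse = ", "), ")")
  out <- data.frame(
    state = state, policy_id = policy_id,
    effective_date = effective_date, repeal_date = repeal_date,
    direction = pol$direction[match(policy_id, pol$policy_id)],
    stringsAsFactors = FALSE
  )
  class(out) <- c("law_records", "data.frame")
  out
}

#' Read law records from CSV
#'
#' Expects columns `state`, `policy_id`, `effective_date` (ISO 8601) and
#' optionally `repeal_date`.
#'
#' @param path Path to a CSV file.
#' @return A `"law_records"` data.frame (see [law_records()]).
#' @export
read_laws <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("state", "policy_id", "effective_date")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("laws file missing columns: ", paste(miss, collapse = ", "))
  rep_d <- if ("repeal_date" %in% names(df)) df$repeal_date else NA
  if (is.character(rep_d)) rep_d[!nzchar(rep_d)] <- NA
  law_records(df$state, df$policy_id, df$effective_date, rep_d)
}

#' Fraction of a calendar year a law is in force
#'
#' The exposure covariate e for a state-year is the number of days of the
#' year on which the law was in force divided by the number of days in the
#' year (366 in leap years). A law is in force on day d when
#' `effective_date <= d` and, if repealed, `d < repeal_date`.
#'
#' @param effective_date Date the law took effect.
#' @param repeal_date Optional repeal date (`NULL` or `NA` if never repealed).
#' @param year Calendar year (integer, possibly vector).
#' @return Exposure in `[0, 1]`, vectorized over `year`.
#' @export
exposure_fraction <- function(effective_date, repeal_date = NULL, year) {
  effective_date <- parse_date(effective_date)
  if (is.na(effective_date)) stop("effective_date is missing/unparseable")
  if (is.null(repeal_date) || all(is.na(repeal_date))) {
    repeal_date <- as.Date(NA)
  } else {
    repeal_date <- as.Date(repeal_date)
    if (repeal_date <= effective_date)
      stop("repeal_date must be strictly after effective_date")
  }
  year <- as.integer(year)
  start <- as.Date(sprintf("%d-01-01", year))
  end <- as.Date(sprintf("%d-12-31", year))
  ndays <- as.numeric(end - start) + 1
  last_in_force <- if (is.na(repeal_date)) end else pmin(end, repeal_date - 1)
  first_in_force <- pmax(start, effective_date)
  in_force <- pmax(0, as.numeric(last_in_force - first_in_force) + 1)
  in_force / ndays
}

#' Linear phase-in covariate
#'
#' Policy effects ramp in linearly over a fixed horizon (default 5 years)
#' after implementation: f = 0 at implementation, 1 at and beyond the
#' horizon, and `years_since / horizon` in between. Negative `years_since`
#' (law not yet in force) clips to 0.
#'
#' @param years_since Signed years since the effective date (any real).
#' @param horizon Phase-in horizon in years (> 0), default 5.
#' @return Phase value in `[0, 1]`, vectorized.
#' @export
phase_in <- function(years_since, horizon = 5) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("horizon must be a single positive number")
  pmin(pmax(years_since / horizon, 0), 1)
}

# days per year used to convert date differences to years_since
DAYS_PER_YEAR <- 365.25

#' Build the state-year-policy exposure panel
#'
#' Expands law records onto the full state x year x policy grid, computing for
#' every cell the exposure fraction e, the phase-in covariate f, and
#' `years_since`, the signed years between the observation year's midpoint
#' (July 1) and the effective date. Annual outcomes carry no sub-annual
#' timing, so phase-in is evaluated at mid-year. The phase covariate is 0
#' whenever no law is in force at the year midpoint (including after repeal).
#'
#' @param records A `"law_records"` data.frame (possibly zero rows).
#' @param states Character vector of state codes defining the grid.
#' @param years Contiguous integer years defining the grid.
#' @param horizon Phase-in horizon in years, default 5.
#' @return A data.frame of class `"policy_panel"` with columns `state`,
#'   `year`, `policy_id`, `exposure`, `phase`, `years_since` covering the
#'   full grid, plus attributes `states`, `years`, `horizon`.
#' @export
build_policy_panel <- function(records, states, years, horizon = 5) {
  if (!inherits(records, "law_records"))
    records <- law_records(records$state, records$policy_id,
                           records$effective_date,
                           if ("repeal_date" %in% names(records))
                             records$repeal_date else as.Date(NA))
  years <- as.integer(years)
  if (length(years) && !identical(years, seq(min(years), max(years))))
    stop("years must be contiguous")
  pols <- policy_ids()

  # reject overlapping records for the same (state, policy)
  key <- paste(records$state, records$policy_id)
  for (k in unique(key[duplicated(key)])) {
    r <- records[key == k, ]
    r <- r[order(r$effective_date), ]
    for (i in seq_len(nrow(r) - 1L)) {
      if (is.na(r$repeal_date[i]) || r$repeal_date[i] > r$effective_date[i + 1L])
        stop("overlapping law records for ", k)
    }
  }

  grid <- expand.grid(policy_id = pols, year = years, state = states,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("state", "year", "policy_id")]
  grid$exposure <- 0
  grid$phase <- 0
  grid$years_since <- NA_real_
  midpoints <- as.Date(sprintf("%d-07-01", years))

  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    rows <- which(grid$state == rec$state & grid$policy_id == rec$policy_id)
    e <- exposure_fraction(rec$effective_date, rec$repeal_date, years)
    ys <- as.numeric(midpoints - rec$effective_date) / DAYS_PER_YEAR
    active_mid <- rec$effective_date <= midpoints &
      (is.na(rec$repeal_date) | midpoints < rec$repeal_date)
    f <- ifelse(active_mid, phase_in(ys, horizon), 0)
    grid$exposure[rows] <- pmin(1, grid$exposure[rows] + e)
    # the record governing years_since/phase: active at midpoint wins; else
    # keep whichever record is closest in time (re-enactments are rare)
    take <- active_mid | is.na(grid$years_since[rows]) |
      abs(ys) < abs(grid$years_since[rows])
    grid$years_since[rows][take] <- ys[take]
    grid$phase[rows] <- pmax(grid$phase[rows], f)
  }
  structure(grid, states = states, years = years, horizon = horizon,
            class = c("policy_panel", "data.frame"))
}

#' Reshape a policy panel into exposure and phase matrices
#'
#' @param policy_panel A `"policy_panel"` data.frame.
#' @return A list with matrices `E` and `F` (rows = state-years ordered by
#'   state then year, columns = the ten policies) and the row keys.
#' @keywords internal
policy_matrices <- function(policy_panel) {
  pols <- policy_ids()
  states <- attr(policy_panel, "states")
  years <- attr(policy_panel, "years")
  keys <- expand.grid(year = years, state = states,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keys <- keys[, c("state", "year")]
  idx <- match(
    paste(rep(keys$state, each = length(pols)),
          rep(keys$year, each = length(pols)),
          rep(pols, times = nrow(keys))),
    paste(policy_panel$state, policy_panel$year, policy_panel$policy_id)
  )
  E <- matrix(policy_panel$exposure[idx], ncol = length(pols), byrow = TRUE,
              dimnames = list(NULL, pols))
  F_ <- matrix(policy_panel$phase[idx], ncol = length(pols), byrow = TRUE,
               dimnames = list(NULL, pols))
  list(E = E, F = F_, keys = keys)
}
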