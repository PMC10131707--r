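# Contract rules -> per-day availability calendars.
#
# Availability is preprocessing, not an ILP constraint: an unavailable
# staff-day simply generates no decision variables. The working pattern
# encoded here: full-time staff work 5 days a week (part-time 2-4), every
# practitioner works 2 weekends per 4-week block (both days, so demand can
# be met 7 days a week), and leave is taken within the block (3 days for
# full-time, 1-2 for part-time) on otherwise-available weekdays.

#' Contract rules for availability generation
#'
#' @param weekends_per_block weekends worked per 4-week block (both days
#'   each); scaled proportionally for shorter blocks.
#' @param leave_days named vector of leave days per 4-week block by
#'   contract type.
#' @param weekend_mode `"both_days"` (a worked weekend makes Saturday and
#'   Sunday available) or `"either_day"` (one of the two, chosen at
#'   random).
#' @return an object of class `contract_rules`.
#' @export
contract_rules <- function(weekends_per_block = 2L,
                           leave_days = c(full_time = 3L, part_time_2 = 1L,
                                          part_time_3 = 1L, part_time_4 = 2L),
                           weekend_mode = c("both_days", "either_day")) {
  weekend_mode <- match.arg(weekend_mode)
  stopifnot(weekends_per_block >= 0, all(leave_days >= 0),
            all(CONTRACT_TYPES %in% names(leave_days)))
  structure(list(weekends_per_block = as.integer(weekends_per_block),
                 leave_days = leave_days, weekend_mode = weekend_mode),
            class = "contract_rules")
}

#' Generate an availability calendar from contract rules
#'
#' For each staff member and each 4-week block: 2 worked weekends are
#' drawn at random (both days available, other weekend days off), weekday
#' availability is drawn so each week holds exactly the contracted number
#' of available days, and leave days are drawn from otherwise-available
#' weekdays. Horizons that are not whole weeks are padded to the next
#' multiple of 7, generated, and truncated (with a warning); blocks
#' shorter than 4 weeks scale the weekend and leave counts
#' proportionally.
#'
#' @param staff staff table.
#' @param horizon `Date` vector of consecutive dates.
#' @param rules a [contract_rules()] object.
#' @param seed integer; the calendar is deterministic given the seed.
#' @return character matrix (staff by date) with entries `"available"`,
#'   `"off_contract"`, `"on_leave"`.
#' @export
build_availability <- function(staff, horizon, rules = contract_rules(), seed) {
  horizon <- check_horizon(horizon)
  n0 <- length(horizon)
  pad <- (7L - n0 %% 7L) %% 7L
  if (pad > 0L) {
    warning("horizon length ", n0, " is not a whole number of weeks; ",
            "padding by ", pad, " day(s) and truncating")
    horizon <- c(horizon, horizon[n0] + seq_len(pad))
  }
  n <- length(horizon)
  n_weeks <- n %/% 7L
  wd <- weekday_of(horizon)
  week_of <- rep(seq_len(n_weeks), each = 7L)
  block_of_week <- (seq_len(n_weeks) - 1L) %/% 4L + 1L
  n_blocks <- max(block_of_week)
  if (any(tabulate(block_of_week) < 4L) && rules$weekends_per_block > 0L)
    warning("horizon holds a block shorter than 4 weeks; ",
            "weekend and leave counts scale proportionally")
  # full weekends: Saturday immediately followed by its Sunday
  sat_idx <- which(wd == "Sat" & c(wd[-1], "") == "Sun")
  cal <- matrix("off_contract", nrow = nrow(staff), ncol = n,
                dimnames = list(staff$id, date_key(horizon)))
  with_seed(seed, {
    for (i in seq_len(nrow(staff))) {
      cdays <- contract_days(staff$contract[i])
      lv_per_block <- rules$leave_days[[staff$contract[i]]]
      for (b in seq_len(n_blocks)) {
        weeks_b <- which(block_of_week == b)
        w_b <- length(weeks_b)
        days_b <- which(week_of %in% weeks_b)
        # worked weekends: pairs whose Saturday lies in this block
        pairs_b <- sat_idx[week_of[sat_idx] %in% weeks_b]
        target_ww <- min(length(pairs_b),
                         round_half_up(rules$weekends_per_block * w_b / 4))
        worked_sat <- if (target_ww > 0)
          sort(resample(pairs_b, target_ww)) else integer()
        for (s in worked_sat) {
          if (rules$weekend_mode == "both_days") cal[i, c(s, s + 1L)] <- "available"
          else cal[i, resample(c(s, s + 1L), 1L)] <- "available"
        }
        # weekday availability per week: top up to the contracted count
        for (wk in weeks_b) {
          days_w <- which(week_of == wk)
          wknd_avail <- sum(cal[i, days_w] == "available")
          mon_fri <- days_w[!(wd[days_w] %in% c("Sat", "Sun"))]
          need <- max(0L, min(length(mon_fri), cdays - wknd_avail))
          if (need > 0) {
            pick <- sort(resample(mon_fri, need))
            cal[i, pick] <- "available"
          }
        }
        # leave on otherwise-available weekdays
        target_lv <- round_half_up(lv_per_block * w_b / 4)
        cand <- days_b[cal[i, days_b] == "available" &
                       !(wd[days_b] %in% c("Sat", "Sun"))]
        target_lv <- min(target_lv, length(cand))
        if (target_lv > 0) {
          pick <- sort(resample(cand, target_lv))
          cal[i, pick] <- "on_leave"
        }
      }
    }
  })
  cal[, seq_len(n0), drop = FALSE]
}

#' Audit an availability calendar against contract rules
#'
#' Checks a generated or user-supplied calendar: complete coverage of the
#' staff-by-date grid, valid states, no week with more available days
#' than the contract allows, and (under the both-days weekend rule)
#' Saturday/Sunday availability moving as a pair.
#'
#' @param calendar character matrix (staff by ISO date).
#' @param staff staff table.
#' @param rules a [contract_rules()] object.
#' @return a `validation_report` data frame; zero rows means compliant.
#' @export
audit_availability <- function(calendar, staff, rules = contract_rules()) {
  rep <- new_report()
  missing_staff <- setdiff(staff$id, rownames(calendar))
  for (s in missing_staff)
    rep <- add_violation(rep, "coverage", s, "no calendar rows for staff member")
  if (anyNA(calendar))
    rep <- add_violation(rep, "coverage", "calendar", "missing staff-day entries")
  bad <- !(calendar %in% c(AVAILABILITY_STATES, NA))
  if (any(bad, na.rm = TRUE))
    rep <- add_violation(rep, "state", "calendar",
                         paste("invalid state(s):",
                               paste(unique(calendar[bad]), collapse = ", ")))
  dates <- as_iso_date(colnames(calendar))
  wd <- weekday_of(dates)
  n_weeks <- length(dates) %/% 7L
  for (s in intersect(staff$id, rownames(calendar))) {
    cdays <- contract_days(staff$contract[match(s, staff$id)])
    for (wk in seq_len(n_weeks)) {
      days_w <- (wk - 1L) * 7L + 1:7
      n_avail <- sum(calendar[s, days_w] == "available", na.rm = TRUE)
      if (n_avail > cdays)
        rep <- add_violation(rep, "week_overload", paste(s, "week", wk),
                             sprintf("%d available days exceed contracted %d",
                                     n_avail, cdays))
    }
    if (rules$weekend_mode == "both_days") {
      sat_idx <- which(wd == "Sat" & c(wd[-1], "") == "Sun")
      for (si in sat_idx) {
        a <- calendar[s, si] == "available"
        b <- calendar[s, si + 1L] == "available"
        if (isTRUE(a) != isTRUE(b))
          rep <- add_violation(rep, "weekend_pair",
                               paste(s, colnames(calendar)[si]),
                               "worked weekends must include both days")
      }
    }
  }
  rep
}
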