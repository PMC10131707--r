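# The shipped CAMHS case-study instance and randomized instance /
# history generators, so every stage is testable without external data.

# --- the case-study week -------------------------------------------------

cwtch_staff_names <- c("Kelly", "James", "Olivia", "Amelia",
                       "Joseph", "Emily", "Matthew", "Laura")

# round-trip miles to the three hospital sites, one row per practitioner
cwtch_distances_raw <- matrix(c(
   0, 20, 30,
  44, 25,  0,
  20,  0, 30,
  28, 17,  0,
   0, 21, 38,
  32,  0, 18,
  29,  0, 35,
   0, 24, 36), nrow = 8, byrow = TRUE,
  dimnames = list(tolower(cwtch_staff_names),
                  c("hospital_1", "hospital_2", "hospital_3")))

# the published minimum-staffing rota for the week of 2019-10-14
# (cells: h1/h2/h3 = hospital sites, aa = telehealth hub, off = day off)
cwtch_rota_cells <- matrix(c(
  "h1",  "h3",  "aa",  "off", "off", "h1",  "h2",
  "off", "h2",  "off", "h2",  "aa",  "aa",  "off",
  "h3",  "off", "off", "off", "h2",  "h3",  "h1",
  "h2",  "aa",  "aa",  "off", "off", "off", "off",
  "off", "h1",  "h3",  "aa",  "aa",  "off", "off",
  "aa",  "off", "h1",  "h3",  "h1",  "off", "off",
  "off", "off", "h2",  "h1",  "h3",  "h2",  "h3",
  "off", "off", "off", "aa",  "off", "off", "aa"),
  nrow = 8, byrow = TRUE)

# the published mileage grid of the pure travel-minimization run
cwtch_mileage_obj2_raw <- matrix(0, nrow = 8, ncol = 7,
                                 dimnames = list(tolower(cwtch_staff_names),
                                                 NULL))
cwtch_mileage_obj2_raw["olivia", 7] <- 30
cwtch_mileage_obj2_raw["amelia", 2] <- 17

cwtch_locations <- function() {
  location_table(id = c("hospital_1", "hospital_2", "hospital_3", "aa"),
                 name = c("Hospital 1", "Hospital 2", "Hospital 3", "AA"),
                 kind = c("hospital", "hospital", "hospital", "telehealth_hub"))
}

cwtch_horizon <- function() planning_horizon("2019-10-14", 7L)

#' The shipped CAMHS case-study instance
#'
#' An 8-practitioner, 3-hospital + telehealth-hub, one-week instance of
#' the published hybrid CAMHS rostering case study: the distance matrix
#' is reproduced verbatim, every capacity is 1 patient/day, all staff are
#' available all week, and the expected demand per location-day is
#' reconstructed by counting the assignments in the published
#' minimum-staffing rota (the only demand information the case study
#' discloses; under unit capacity any demand with these per-cell counts
#' reproduces the published optimum).
#'
#' @return a [schedule_instance()].
#' @seealso [cwtch_rota()] for the published rota itself,
#'   [cwtch_mileage_objective2()] for the published travel-minimal
#'   mileage grid.
#' @export
#' @examples
#' inst <- cwtch_instance()
#' sum(inst$demand)  # 31 staff-days of demand
cwtch_instance <- function() {
  staff <- staff_table(id = tolower(cwtch_staff_names),
                       name = cwtch_staff_names,
                       contract = "full_time",
                       capacity = 1L,
                       home_base = colnames(cwtch_distances_raw)[
                         apply(cwtch_distances_raw, 1, which.min)])
  locations <- cwtch_locations()
  horizon <- cwtch_horizon()
  pub <- cwtch_rota()
  demand <- matrix(0L, nrow = nrow(locations), ncol = length(horizon),
                   dimnames = list(locations$id, date_key(horizon)))
  tab <- table(pub$assignments$location, date_key(pub$assignments$date))
  demand[rownames(tab), colnames(tab)] <- as.integer(tab)
  schedule_instance(staff, locations, horizon, demand,
                    distances = cwtch_distances_raw)
}

#' The published minimum-staffing rota of the case study
#'
#' @return a [rota()] with 31 assignments over the week of 2019-10-14.
#' @export
cwtch_rota <- function() {
  horizon <- cwtch_horizon()
  ids <- tolower(cwtch_staff_names)
  loc_of <- c(h1 = "hospital_1", h2 = "hospital_2", h3 = "hospital_3",
              aa = "aa")
  rows <- which(cwtch_rota_cells != "off", arr.ind = TRUE)
  asg <- data.frame(staff = ids[rows[, 1]],
                    date = horizon[rows[, 2]],
                    location = unname(loc_of[cwtch_rota_cells[rows]]),
                    stringsAsFactors = FALSE)
  asg <- asg[order(asg$date, asg$staff), ]
  rownames(asg) <- NULL
  rota(asg, ids, horizon, objective_value = nrow(asg),
       objective_mode = "min_staffing", solver_status = "published")
}

#' The published travel-minimal mileage grid of the case study
#'
#' The case study publishes the mileage grid (not the rota) of its pure
#' travel-minimization run; only two cells are nonzero.
#'
#' @return a `mileage_table` whose grid can be re-totalled.
#' @export
cwtch_mileage_objective2 <- function() {
  m <- cwtch_mileage_obj2_raw
  colnames(m) <- date_key(cwtch_horizon())
  as_mileage_table(m)
}

# --- randomized generators ----------------------------------------------

#' Configuration for the synthetic instance generator
#'
#' The weekday demand means and ranges default to the observed
#' weekday-dependent distribution of the case-study service (service-wide
#' daily referral totals, Monday through Sunday).
#'
#' @param n_staff,n_hospitals,horizon_days instance dimensions (one
#'   telehealth hub is always added).
#' @param weekday_means mean daily demand per weekday, Mon..Sun.
#' @param weekday_min,weekday_max clipping range for sampled daily
#'   totals, Mon..Sun.
#' @param bank_holiday_effect additive shift of the daily mean on bank
#'   holidays (negative: holidays behave like weekends).
#' @param distance_range round-trip miles drawn uniformly in this range
#'   for non-home hospitals.
#' @param contract_mix sampling weights per contract type.
#' @param capacity patients treatable per worked day (every staff member).
#' @param start first horizon date.
#' @param seed mandatory integer seed.
#' @param allow_infeasible if `FALSE` (default) daily demand is capped at
#'   the total capacity of the staff available that day, so generated
#'   instances are feasible by construction.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_staff = 8L, n_hospitals = 3L,
                             horizon_days = 28L,
                             weekday_means = c(Mon = 2.42, Tue = 2.65,
                                               Wed = 2.23, Thu = 2.16,
                                               Fri = 2.20, Sat = 1.29,
                                               Sun = 1.43),
                             weekday_min = c(Mon = 0, Tue = 0, Wed = 0,
                                             Thu = 1, Fri = 1, Sat = 0,
                                             Sun = 0),
                             weekday_max = c(Mon = 8, Tue = 7, Wed = 6,
                                             Thu = 5, Fri = 5, Sat = 3,
                                             Sun = 3),
                             bank_holiday_effect = -1,
                             distance_range = c(15, 45),
                             contract_mix = c(full_time = 0.6,
                                              part_time_4 = 0.2,
                                              part_time_3 = 0.1,
                                              part_time_2 = 0.1),
                             capacity = 1L,
                             start = "2023-01-02",
                             seed,
                             allow_infeasible = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_staff >= 1, n_hospitals >= 1, horizon_days >= 1,
            all(weekday_means >= 0), all(weekday_max >= weekday_min),
            capacity >= 1, all(contract_mix >= 0), sum(contract_mix) > 0)
  cfg <- list(n_staff = as.integer(n_staff),
              n_hospitals = as.integer(n_hospitals),
              horizon_days = as.integer(horizon_days),
              weekday_means = weekday_means, weekday_min = weekday_min,
              weekday_max = weekday_max,
              bank_holiday_effect = bank_holiday_effect,
              distance_range = distance_range,
              contract_mix = contract_mix, capacity = as.integer(capacity),
              start = as_iso_date(start), seed = as.integer(seed),
              allow_infeasible = isTRUE(allow_infeasible))
  class(cfg) <- "generator_config"
  cfg
}

sample_daily_total <- function(dates, cfg, bank_holidays = as.Date(character())) {
  wd <- match(weekday_of(dates), WEEKDAYS)
  mu <- cfg$weekday_means[wd]
  mu <- pmax(0, mu + ifelse(as.Date(dates) %in% as.Date(bank_holidays),
                            cfg$bank_holiday_effect, 0))
  tot <- rpois(length(dates), mu)
  pmin(pmax(tot, cfg$weekday_min[wd]), cfg$weekday_max[wd])
}

#' Generate a random schedule instance
#'
#' Distances are drawn uniformly in the configured range with exactly one
#' zero (the home base) per staff member; hub distances are zero. Daily
#' demand totals are Poisson with the configured weekday mean, clipped to
#' the weekday's range, split across locations uniformly at random, and
#' capped at the capacity available that day (availability itself comes
#' from [build_availability()] under the same seed).
#'
#' @param config a [generator_config()].
#' @param bank_holidays optional `Date` vector.
#' @param rules contract rules for the availability stage.
#' @return a [schedule_instance()]; deterministic given the config seed.
#' @export
generate_instance <- function(config, bank_holidays = as.Date(character()),
                              rules = contract_rules()) {
  stopifnot(inherits(config, "generator_config"))
  hosp_ids <- sprintf("hospital_%d", seq_len(config$n_hospitals))
  locations <- location_table(
    id = c(hosp_ids, "aa"),
    name = c(sprintf("Hospital %d", seq_len(config$n_hospitals)), "AA"),
    kind = c(rep("hospital", config$n_hospitals), "telehealth_hub"))
  horizon <- planning_horizon(config$start, config$horizon_days)
  ids <- sprintf("staff_%02d", seq_len(config$n_staff))
  inst <- with_seed(config$seed, {
    contracts <- resample(rep(names(config$contract_mix),
                              times = round(config$contract_mix * 1000)),
                          config$n_staff)
    home <- hosp_ids[sample.int(config$n_hospitals, config$n_staff,
                                replace = TRUE)]
    dm <- matrix(0, nrow = config$n_staff, ncol = config$n_hospitals,
                 dimnames = list(ids, hosp_ids))
    for (i in seq_len(config$n_staff)) {
      away <- setdiff(hosp_ids, home[i])
      dm[i, away] <- round(runif(length(away), config$distance_range[1],
                                 config$distance_range[2]))
    }
    staff <- staff_table(ids, name = sprintf("Staff %02d",
                                             seq_len(config$n_staff)),
                         contract = contracts, capacity = config$capacity,
                         home_base = home)
    avail <- build_availability(staff, horizon, rules,
                                seed = child_seed(config$seed, 1L))
    totals <- sample_daily_total(horizon, config, bank_holidays)
    demand <- matrix(0L, nrow = nrow(locations), ncol = length(horizon),
                     dimnames = list(locations$id, date_key(horizon)))
    for (t in seq_along(horizon)) {
      tot <- totals[t]
      if (!config$allow_infeasible) {
        cap <- sum(staff$capacity[avail[, t] == "available"])
        tot <- min(tot, cap)
      }
      if (tot > 0) {
        picks <- sample.int(nrow(locations), tot, replace = TRUE)
        demand[, t] <- tabulate(picks, nbins = nrow(locations))
      }
    }
    schedule_instance(staff, locations, horizon, demand, dm, avail)
  })
  inst
}

#' Generate a synthetic demand history
#'
#' Daily counts per location are `round(max(0, lp + noise))` where the
#' linear predictor `lp` is built from caller-specified weekday, month
#' and bank-holiday coefficients (reference Sunday / January /
#' non-holiday) and the noise is Gaussian. Fuel for exercising
#' [fit_demand_model()]: with zero noise and integer-valued predictors
#' the regression recovers the coefficients exactly.
#'
#' @param config a [generator_config()] (supplies locations, start date
#'   and seed).
#' @param n_days series length in days (at least 56, two rota blocks).
#' @param coefficients list with `intercept` (number), `weekday` (named
#'   vector, subset of Mon..Sat), `month` (named vector, subset of
#'   Feb..Dec), `holiday` (number).
#' @param noise_sd Gaussian noise standard deviation.
#' @param bank_holidays `Date` vector of holidays inside the series.
#' @return a [demand_history()] with one record per location-day.
#' @export
generate_demand_history <- function(config, n_days = 728L,
                                    coefficients = list(intercept = 2,
                                                        weekday = NULL,
                                                        month = NULL,
                                                        holiday = 0),
                                    noise_sd = 0.3,
                                    bank_holidays = as.Date(character())) {
  stopifnot(inherits(config, "generator_config"))
  if (n_days < 56L) stop("n_days must be at least 56")
  dates <- planning_horizon(config$start, n_days)
  loc_ids <- c(sprintf("hospital_%d", seq_len(config$n_hospitals)), "aa")
  wd_coef <- setNames(rep(0, 6), WEEKDAYS_SUN_FIRST[-1])
  if (!is.null(coefficients$weekday)) {
    bad <- setdiff(names(coefficients$weekday), names(wd_coef))
    if (length(bad)) stop("weekday coefficients must be among Mon..Sat")
    wd_coef[names(coefficients$weekday)] <- coefficients$weekday
  }
  mo_coef <- setNames(rep(0, 11), MONTHS[-1])
  if (!is.null(coefficients$month)) {
    bad <- setdiff(names(coefficients$month), names(mo_coef))
    if (length(bad)) stop("month coefficients must be among Feb..Dec")
    mo_coef[names(coefficients$month)] <- coefficients$month
  }
  wd <- weekday_of(dates); mo <- month_of(dates)
  lp <- (coefficients$intercept %||% 0) +
    ifelse(wd == "Sun", 0, wd_coef[wd]) +
    ifelse(mo == "Jan", 0, mo_coef[mo]) +
    (coefficients$holiday %||% 0) * (dates %in% as.Date(bank_holidays))
  with_seed(config$seed, {
    recs <- lapply(loc_ids, function(l) {
      noise <- if (noise_sd > 0) rnorm(n_days, 0, noise_sd) else 0
      data.frame(date = dates, location = l,
                 count = as.integer(round_half_up(pmax(0, lp + noise))),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, recs)
    demand_history(df$date, df$location, df$count)
  })
}
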