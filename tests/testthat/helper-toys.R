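# Small random instances for oracle sweeps, plus calendar helpers.

wday_label <- function(dates) {
  c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")[as.POSIXlt(dates)$wday + 1]
}

month_label <- function(dates) {
  c("Jan", "Feb", "Mar", "Apr", "May", "Jun", "Jul", "Aug", "Sep", "Oct",
    "Nov", "Dec")[as.POSIXlt(dates)$mon + 1]
}

# A toy instance small enough for exhaustive enumeration (<= 12 binary
# variables): 2-3 staff, 1-2 locations, 1-2 days, mixed capacities,
# random availability, demand that may or may not be coverable.
random_toy_instance <- function(seed) {
  set.seed(seed)
  n_staff <- sample(2:3, 1)
  n_loc <- sample(1:2, 1)
  n_days <- sample(1:2, 1)
  ids <- paste0("s", seq_len(n_staff))
  locs <- paste0("hospital_", seq_len(n_loc))
  staff <- staff_table(ids, contract = "full_time",
                       capacity = sample(1:2, n_staff, replace = TRUE),
                       home_base = locs[1])
  lt <- location_table(locs)
  h <- planning_horizon("2023-01-02", n_days)
  dm <- matrix(sample(c(0, 0, 10, 20, 35), n_staff * n_loc, replace = TRUE),
               n_staff, n_loc, dimnames = list(ids, locs))
  dm[, locs[1]] <- 0
  dd <- matrix(sample(0:3, n_loc * n_days, replace = TRUE),
               n_loc, n_days, dimnames = list(locs, format(h)))
  av <- matrix(sample(c("available", "off_contract"), n_staff * n_days,
                      replace = TRUE, prob = c(0.8, 0.2)),
               n_staff, n_days, dimnames = list(ids, format(h)))
  suppressWarnings(schedule_instance(staff, lt, h, dd, dm, av))
}

# The 8-staff, 3-hospital + hub case-study shape with random demand,
# used where a desk-scale (non-enumerable) instance is wanted.
desk_instance <- function(seed, horizon_days = 7) {
  suppressWarnings(
    generate_instance(generator_config(seed = seed,
                                       horizon_days = horizon_days)))
}
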