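# Domain types for the rostering model.
#
# The mathematical objects are: the planning horizon T (consecutive
# calendar dates), the staff set I with per-day treatment capacities w_i,
# the location set L (hospital sites plus telehealth hub), the expected
# demand d_{l,t}, the round-trip distance matrix m_{i,l}, and a staff-day
# availability calendar that fixes x_{i,l,t} = 0 outside contracted days.
# All of them are plain data frames / matrices wrapped in light S3
# classes so they can be read from and written to CSV unchanged.

CONTRACT_TYPES <- c("full_time", "part_time_2", "part_time_3", "part_time_4")
AVAILABILITY_STATES <- c("available", "off_contract", "on_leave")
LOCATION_KINDS <- c("hospital", "telehealth_hub")

#' Contracted working days per week for a contract type
#'
#' Full-time staff work 5 days a week; part-time contracts work the
#' number of days encoded in the contract label (2 to 4).
#'
#' @param contract character vector of contract types
#'   (`"full_time"`, `"part_time_2"`, `"part_time_3"`, `"part_time_4"`).
#' @return integer vector of working days per week.
#' @export
#' @examples
#' contract_days(c("full_time", "part_time_3"))
contract_days <- function(contract) {
  days <- c(full_time = 5L, part_time_2 = 2L, part_time_3 = 3L, part_time_4 = 4L)
  bad <- setdiff(unique(contract), names(days))
  if (length(bad))
    stop("unknown contract type(s): ", paste(bad, collapse = ", "))
  unname(days[contract])
}

#' Build a staff roster table
#'
#' @param id unique staff identifiers (tokens).
#' @param name display names; defaults to `id`.
#' @param contract contract type per staff member (see [contract_days()]).
#' @param capacity patients treatable per worked day (`w_i`), positive
#'   integers. Defaults to 1.
#' @param home_base location id whose round-trip distance is zero for this
#'   staff member.
#' @return a `data.frame` with one row per staff member.
#' @export
staff_table <- function(id, name = id, contract = "full_time",
                        capacity = 1L, home_base) {
  df <- data.frame(id = as.character(id), name = as.character(name),
                   contract = as.character(contract),
                   capacity = as.integer(capacity),
                   home_base = as.character(home_base),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("staff ids must be unique")
  contract_days(df$contract)  # validates
  df
}

#' Build a location table
#'
#' @param id unique location identifiers.
#' @param name display names (e.g. `"Hospital 1"`, `"AA"`).
#' @param kind `"hospital"` or `"telehealth_hub"`.
#' @return a `data.frame` with one row per location.
#' @export
location_table <- function(id, name = id, kind = "hospital") {
  df <- data.frame(id = as.character(id), name = as.character(name),
                   kind = as.character(kind), stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("location ids must be unique")
  bad <- setdiff(unique(df$kind), LOCATION_KINDS)
  if (length(bad)) stop("unknown location kind(s): ", paste(bad, collapse = ", "))
  df
}

#' Construct a planning horizon of consecutive dates
#'
#' @param start first date of the horizon (ISO string or `Date`).
#' @param n_days horizon length in days; the deployed default is a
#'   4-week (28-day) rolling window.
#' @return a `Date` vector of consecutive dates.
#' @export
#' @examples
#' planning_horizon("2019-10-14", 7)
planning_horizon <- function(start, n_days = 28L) {
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 1L) stop("n_days must be >= 1")
  as_iso_date(start) + seq_len(n_days) - 1L
}

check_horizon <- function(dates) {
  dates <- as.Date(dates)
  if (length(dates) < 1L) stop("horizon must contain at least one date")
  if (length(dates) > 1L && any(diff(dates) != 1))
    stop("horizon dates must be consecutive and strictly increasing")
  dates
}

#' Build a location-by-day demand matrix
#'
#' Accepts either a numeric matrix (rows = locations, columns = horizon
#' dates) or a long data frame with columns `location`, `date`, `demand`.
#' Cells absent from a long input default to zero with a warning, since
#' sparse demand files routinely omit zero-demand weekend cells.
#'
#' @param x matrix or long data frame of expected demand `d_{l,t}`.
#' @param locations location table (see [location_table()]).
#' @param horizon `Date` vector from [planning_horizon()].
#' @return an integer matrix with `rownames` = location ids and
#'   `colnames` = ISO dates.
#' @export
demand_matrix <- function(x, locations, horizon) {
  horizon <- check_horizon(horizon)
  keys <- date_key(horizon)
  m <- matrix(0L, nrow = nrow(locations), ncol = length(horizon),
              dimnames = list(locations$id, keys))
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x)))
      stop("demand matrix needs location ids as rownames and ISO dates as colnames")
    miss_r <- setdiff(rownames(x), locations$id)
    if (length(miss_r)) stop("unknown demand location(s): ",
                             paste(miss_r, collapse = ", "))
    miss_c <- setdiff(colnames(x), keys)
    if (length(miss_c)) stop("demand date(s) outside horizon: ",
                             paste(miss_c, collapse = ", "))
    m[rownames(x), colnames(x)] <- x
    if (length(x) < length(m))
      warning("missing demand cells default to 0")
  } else {
    df <- as.data.frame(x)
    need <- c("location", "date", "demand")
    if (!all(need %in% names(df)))
      stop("long demand input needs columns: ", paste(need, collapse = ", "))
    df$date <- date_key(as_iso_date(df$date))
    miss_r <- setdiff(unique(df$location), locations$id)
    if (length(miss_r)) stop("unknown demand location(s): ",
                             paste(miss_r, collapse = ", "))
    df <- df[df$date %in% keys, , drop = FALSE]
    if (anyDuplicated(df[c("location", "date")]))
      stop("duplicate (location, date) demand rows")
    m[cbind(df$location, df$date)] <- df$demand
    if (nrow(df) < length(m))
      warning("missing demand cells default to 0")
  }
  storage.mode(m) <- "integer"
  m
}

#' Build a staff-by-location round-trip distance matrix
#'
#' Distances to any telehealth hub are forced to zero (remote work incurs
#' no travel), as is each staff member's home base.
#'
#' @param x numeric matrix with staff ids as rownames and location ids as
#'   colnames; hub columns may be omitted. `NULL` means no travel matters:
#'   all distances are zero.
#' @param staff staff table.
#' @param locations location table.
#' @return numeric matrix of miles `m_{i,l}`, staff by location.
#' @export
distance_matrix <- function(x, staff, locations) {
  m <- matrix(if (is.null(x)) 0 else NA_real_,
              nrow = nrow(staff), ncol = nrow(locations),
              dimnames = list(staff$id, locations$id))
  hubs <- locations$id[locations$kind == "telehealth_hub"]
  m[, hubs] <- 0
  if (!is.null(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x)))
      stop("distance matrix needs staff ids as rownames and location ids as colnames")
    keep <- intersect(colnames(x), locations$id)
    miss <- setdiff(rownames(x), staff$id)
    if (length(miss)) stop("unknown staff in distances: ",
                           paste(miss, collapse = ", "))
    m[rownames(x), keep] <- as.numeric(x[, keep])
    m[, hubs] <- 0  # hub travel is always free, whatever the file says
  }
  hosp <- setdiff(locations$id, hubs)
  if (anyNA(m[, hosp]))
    stop("every (staff, hospital) pair needs a distance entry")
  m
}

#' Fully-available calendar for a staff set and horizon
#'
#' @param staff staff table.
#' @param horizon `Date` vector.
#' @return character matrix (staff by date) of availability states.
#' @export
full_availability <- function(staff, horizon) {
  horizon <- check_horizon(horizon)
  matrix("available", nrow = nrow(staff), ncol = length(horizon),
         dimnames = list(staff$id, date_key(horizon)))
}

#' Assemble a schedule instance
#'
#' Bundles staff, locations, horizon, demand, distances and availability
#' into the full problem object consumed by [build_model()] and
#' [solve_rota()]. Structural errors (unknown ids, wrong shapes) raise
#' immediately; rule violations are reported by [validate_instance()].
#'
#' @param staff staff table ([staff_table()]).
#' @param locations location table ([location_table()]).
#' @param horizon `Date` vector ([planning_horizon()]).
#' @param demand demand matrix or long data frame ([demand_matrix()]).
#' @param distances distance matrix ([distance_matrix()]).
#' @param availability character matrix of availability states; defaults
#'   to every staff member available every day.
#' @return an object of class `schedule_instance`.
#' @export
schedule_instance <- function(staff, locations, horizon, demand,
                              distances = NULL, availability = NULL) {
  horizon <- check_horizon(horizon)
  demand <- demand_matrix(demand, locations, horizon)
  distances <- distance_matrix(distances, staff, locations)
  if (is.null(availability)) availability <- full_availability(staff, horizon)
  keys <- date_key(horizon)
  if (!is.matrix(availability) ||
      !identical(sort(rownames(availability)), sort(staff$id)) ||
      !identical(colnames(availability), keys))
    stop("availability must be a staff x horizon-date matrix")
  availability <- availability[staff$id, , drop = FALSE]
  structure(list(staff = staff, locations = locations, horizon = horizon,
                 demand = demand, distances = distances,
                 availability = availability),
            class = "schedule_instance")
}

#' @export
print.schedule_instance <- function(x, ...) {
  cat("Schedule instance:", nrow(x$staff), "staff,",
      nrow(x$locations), "locations,",
      length(x$horizon), "days (",
      date_key(x$horizon[1]), "to",
      date_key(x$horizon[length(x$horizon)]), ")\n")
  cat("  total demand:", sum(x$demand),
      "| total capacity if all available:",
      sum(x$staff$capacity) * length(x$horizon), "\n")
  invisible(x)
}

new_report <- function(check = character(), subject = character(),
                       message = character()) {
  structure(data.frame(check = check, subject = subject, message = message,
                       stringsAsFactors = FALSE),
            class = c("validation_report", "data.frame"))
}

add_violation <- function(report, check, subject, message) {
  rbind(report, new_report(check, subject, message))
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) cat("No violations.\n")
  else {
    cat(nrow(x), "violation(s):\n")
    for (i in seq_len(nrow(x)))
      cat(sprintf("  [%s] %s: %s\n", x$check[i], x$subject[i], x$message[i]))
  }
  invisible(x)
}

#' Validate a schedule instance
#'
#' Checks every type invariant of the model plus a guaranteed-infeasibility
#' certificate: a (location, date) whose demand exceeds the total capacity
#' of all staff available that day can never be covered, whatever the
#' solver does. Violations are returned as data, not raised.
#'
#' @param instance a [schedule_instance()].
#' @return a `validation_report` data frame; zero rows means valid.
#' @export
validate_instance <- function(instance) {
  stopifnot(inherits(instance, "schedule_instance"))
  rep <- new_report()
  st <- instance$staff; loc <- instance$locations
  if (any(st$capacity < 1L))
    for (i in which(st$capacity < 1L))
      rep <- add_violation(rep, "capacity", st$id[i], "capacity must be >= 1")
  bad_base <- !(st$home_base %in% loc$id)
  for (i in which(bad_base))
    rep <- add_violation(rep, "home_base", st$id[i],
                         paste0("unknown home base '", st$home_base[i], "'"))
  # distances
  neg <- which(instance$distances < 0, arr.ind = TRUE)
  for (i in seq_len(nrow(neg)))
    rep <- add_violation(rep, "distance",
                         paste(rownames(instance$distances)[neg[i, 1]],
                               colnames(instance$distances)[neg[i, 2]], sep = "/"),
                         "distance must be >= 0")
  hubs <- loc$id[loc$kind == "telehealth_hub"]
  if (length(hubs) && any(instance$distances[, hubs, drop = FALSE] != 0))
    rep <- add_violation(rep, "distance", "telehealth_hub",
                         "hub distances must be 0")
  for (i in seq_len(nrow(st))) {
    hb <- st$home_base[i]
    if (hb %in% colnames(instance$distances) && !bad_base[i] &&
        instance$distances[st$id[i], hb] != 0)
      rep <- add_violation(rep, "distance", st$id[i],
                           "home-base distance must be 0")
  }
  # demand
  if (any(instance$demand < 0))
    rep <- add_violation(rep, "demand", "matrix", "demand must be >= 0")
  # availability states
  bad_state <- !(instance$availability %in% AVAILABILITY_STATES)
  if (any(bad_state))
    rep <- add_violation(rep, "availability", "calendar",
                         paste("invalid availability state(s):",
                               paste(unique(instance$availability[bad_state]),
                                     collapse = ", ")))
  # infeasibility certificate: day capacity of available staff vs demand
  keys <- date_key(instance$horizon)
  for (t in seq_along(keys)) {
    avail <- instance$availability[, t] == "available"
    cap <- sum(st$capacity[avail])
    tot <- sum(instance$demand[, t])
    if (tot > cap)
      rep <- add_violation(rep, "infeasible_day", keys[t],
                           sprintf("total demand %d exceeds available capacity %d",
                                   tot, cap))
  }
  rep
}
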