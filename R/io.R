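# CSV interfaces for instances, histories and calendars.
#
# An "instance directory" holds staff.csv, locations.csv, distances.csv,
# demand.csv and optionally availability.csv; each stage of the pipeline
# reads and writes these files so stages can be rerun independently.

#' Read a staff roster CSV
#'
#' Columns: `id,name,contract,capacity,home_base`.
#'
#' @param path file path.
#' @return staff table (see [staff_table()]).
#' @export
read_staff_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "contract", "capacity", "home_base")
  if (!all(need %in% names(df)))
    stop("staff CSV needs columns: ", paste(need, collapse = ", "))
  staff_table(df$id, df$name, df$contract, df$capacity, df$home_base)
}

#' Read a location table CSV
#'
#' Columns: `id,name,kind` with kind `hospital` or `telehealth_hub`.
#'
#' @param path file path.
#' @return location table.
#' @export
read_locations_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  location_table(df$id, df$name, df$kind)
}

#' Read a distance CSV in roster layout
#'
#' First column is the staff display name; one column per hospital
#' (matched against location ids or display names). A telehealth-hub
#' column, if present, is ignored: hub distances are always zero.
#'
#' @param path file path.
#' @param staff staff table.
#' @param locations location table.
#' @return numeric distance matrix (staff id by location id).
#' @export
read_distance_csv <- function(path, staff, locations) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "name"
  unknown <- setdiff(df$name, staff$name)
  if (length(unknown)) stop("unknown staff name(s) in distance CSV: ",
                            paste(unknown, collapse = ", "))
  hosp <- locations[locations$kind == "hospital", ]
  col_ids <- character(0)
  col_map <- list()
  for (cn in setdiff(names(df), "name")) {
    id <- if (cn %in% hosp$id) cn
          else if (cn %in% hosp$name) hosp$id[match(cn, hosp$name)]
          else NA_character_
    if (!is.na(id)) col_map[[cn]] <- id
  }
  missing <- setdiff(hosp$id, unlist(col_map))
  if (length(missing)) stop("distance CSV lacks hospital column(s): ",
                            paste(missing, collapse = ", "))
  m <- matrix(NA_real_, nrow = nrow(staff), ncol = length(col_map),
              dimnames = list(staff$id, unlist(col_map)))
  for (cn in names(col_map))
    m[staff$id[match(df$name, staff$name)], col_map[[cn]]] <- df[[cn]]
  distance_matrix(m, staff, locations)
}

#' Read a long demand CSV
#'
#' Columns: `location,date,demand` (ISO-8601 dates). Cells absent for a
#' (location, date) in the horizon default to zero with a warning.
#'
#' @param path file path.
#' @param locations location table.
#' @param horizon `Date` vector.
#' @return integer demand matrix.
#' @export
read_demand_csv <- function(path, locations, horizon) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  demand_matrix(df, locations, horizon)
}

#' Read a long availability CSV
#'
#' Columns: `staff,date,status`.
#'
#' @param path file path.
#' @param staff staff table.
#' @param horizon `Date` vector.
#' @return character availability matrix (staff by date); cells absent
#'   from the file are `NA` and will be flagged by [audit_availability()].
#' @export
read_availability_csv <- function(path, staff, horizon) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("staff", "date", "status")
  if (!all(need %in% names(df)))
    stop("availability CSV needs columns: ", paste(need, collapse = ", "))
  horizon <- check_horizon(horizon)
  keys <- date_key(horizon)
  m <- matrix(NA_character_, nrow = nrow(staff), ncol = length(keys),
              dimnames = list(staff$id, keys))
  df$date <- date_key(as_iso_date(df$date))
  df <- df[df$staff %in% staff$id & df$date %in% keys, , drop = FALSE]
  m[cbind(df$staff, df$date)] <- df$status
  m
}

#' Read a bank-holiday file (one ISO date per line)
#'
#' @param path file path.
#' @return `Date` vector.
#' @export
read_bank_holidays <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  as_iso_date(lines[nzchar(lines)])
}

#' Read a demand-history CSV
#'
#' Columns: `date,location,count`.
#'
#' @param path file path.
#' @return a [demand_history()].
#' @export
read_demand_history_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "location", "count")
  if (!all(need %in% names(df)))
    stop("demand history CSV needs columns: ", paste(need, collapse = ", "))
  demand_history(df$date, df$location, df$count)
}

#' Write a schedule instance to a directory of CSVs
#'
#' @param instance a [schedule_instance()].
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_instance_dir <- function(instance, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(instance$staff, file.path(dir, "staff.csv"), row.names = FALSE)
  write.csv(instance$locations, file.path(dir, "locations.csv"),
            row.names = FALSE)
  hosp <- instance$locations[instance$locations$kind == "hospital", ]
  dm <- instance$distances[, hosp$id, drop = FALSE]
  ddf <- data.frame(name = instance$staff$name, dm, check.names = FALSE)
  colnames(ddf) <- c("name", hosp$id)
  write.csv(ddf, file.path(dir, "distances.csv"), row.names = FALSE)
  keys <- date_key(instance$horizon)
  dl <- expand.grid(location = rownames(instance$demand), date = keys,
                    stringsAsFactors = FALSE)
  dl$demand <- as.vector(instance$demand)
  write.csv(dl, file.path(dir, "demand.csv"), row.names = FALSE)
  al <- expand.grid(staff = rownames(instance$availability), date = keys,
                    stringsAsFactors = FALSE)
  al$status <- as.vector(instance$availability)
  write.csv(al, file.path(dir, "availability.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a schedule instance from a directory of CSVs
#'
#' Expects `staff.csv`, `locations.csv`, `distances.csv`, `demand.csv`
#' and optionally `availability.csv` (absent: all staff available on all
#' days). The horizon is taken from the demand file unless given.
#'
#' @param dir instance directory.
#' @param horizon optional `Date` vector; default: the full date range of
#'   `demand.csv`.
#' @return a [schedule_instance()].
#' @export
read_instance_dir <- function(dir, horizon = NULL) {
  staff <- read_staff_csv(file.path(dir, "staff.csv"))
  locations <- read_locations_csv(file.path(dir, "locations.csv"))
  if (is.null(horizon)) {
    dd <- read.csv(file.path(dir, "demand.csv"), stringsAsFactors = FALSE)
    dates <- as_iso_date(dd$date)
    horizon <- planning_horizon(min(dates),
                                as.integer(max(dates) - min(dates)) + 1L)
  }
  demand <- read_demand_csv(file.path(dir, "demand.csv"), locations, horizon)
  distances <- read_distance_csv(file.path(dir, "distances.csv"),
                                 staff, locations)
  av_path <- file.path(dir, "availability.csv")
  availability <- if (file.exists(av_path))
    read_availability_csv(av_path, staff, horizon) else NULL
  schedule_instance(staff, locations, horizon, demand, distances, availability)
}
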