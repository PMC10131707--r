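# Presentation layer: rota and mileage grids plus headline totals.
# CSV is the canonical output format; print methods give an aligned
# text table for terminals. Cells use the location display name (the
# hub's display name is "AA" in the shipped case study) and the fixed
# label "OFF" for off days.

OFF_LABEL <- "OFF"

#' Render a rota as a staff-by-date grid
#'
#' @param rota a [rota()].
#' @param instance the matching [schedule_instance()]; supplies staff and
#'   location display names and the row order.
#' @return character matrix (class `rota_table`) with staff display names
#'   as rownames, ISO dates as colnames, and location display names or
#'   `"OFF"` as cells.
#' @export
render_rota <- function(rota, instance) {
  stopifnot(inherits(rota, "rota"))
  asg <- rota$assignments
  bad_staff <- setdiff(asg$staff, instance$staff$id)
  bad_loc <- setdiff(asg$location, instance$locations$id)
  if (length(bad_staff) || length(bad_loc))
    stop("rota references unknown ids: ",
         paste(c(bad_staff, bad_loc), collapse = ", "))
  keys <- date_key(rota$dates)
  grid <- matrix(OFF_LABEL, nrow = nrow(instance$staff), ncol = length(keys),
                 dimnames = list(instance$staff$name, keys))
  if (nrow(asg)) {
    loc_name <- setNames(instance$locations$name, instance$locations$id)
    staff_name <- setNames(instance$staff$name, instance$staff$id)
    grid[cbind(staff_name[asg$staff], date_key(asg$date))] <- loc_name[asg$location]
  }
  structure(grid, class = c("rota_table", "matrix", "array"))
}

#' @export
print.rota_table <- function(x, ...) {
  print(unclass(x), quote = FALSE, ...)
  invisible(x)
}

#' Render the mileage grid for a rota
#'
#' Each cell holds the round-trip miles `m_{i,l}` of the assigned
#' location; OFF days and telehealth-hub days are 0. Row, column and
#' grand totals are computed.
#'
#' @param rota a [rota()].
#' @param distances staff-by-location distance matrix (hub columns zero).
#' @return an object of class `mileage_table`: `miles` (staff-by-date
#'   matrix), `row_totals`, `col_totals`, `grand_total`.
#' @export
render_mileage <- function(rota, distances) {
  stopifnot(inherits(rota, "rota"))
  asg <- rota$assignments
  bad <- setdiff(asg$staff, rownames(distances))
  bad <- c(bad, setdiff(asg$location, colnames(distances)))
  if (length(bad)) stop("rota references ids missing from the distance matrix: ",
                        paste(bad, collapse = ", "))
  keys <- date_key(rota$dates)
  m <- matrix(0, nrow = length(rota$staff_ids), ncol = length(keys),
              dimnames = list(rota$staff_ids, keys))
  if (nrow(asg))
    m[cbind(asg$staff, date_key(asg$date))] <-
      distances[cbind(asg$staff, asg$location)]
  as_mileage_table(m)
}

#' Wrap a mileage grid, computing its totals
#'
#' @param m numeric staff-by-date matrix of miles.
#' @return a `mileage_table`.
#' @export
as_mileage_table <- function(m) {
  structure(list(miles = m,
                 row_totals = rowSums(m),
                 col_totals = colSums(m),
                 grand_total = sum(m)),
            class = "mileage_table")
}

#' @export
print.mileage_table <- function(x, ...) {
  out <- rbind(cbind(x$miles, Total = x$row_totals),
               Total = c(x$col_totals, x$grand_total))
  print(out, ...)
  invisible(x)
}

#' Headline totals comparing the two objectives
#'
#' @param result_staffing `solve_result` under the staffing objective
#'   (or lexicographic).
#' @param result_miles `solve_result` under the miles objective.
#' @return list with `assignments_staffing`, `assignments_miles`,
#'   `miles_1`, `miles_2`, `miles_saved` (= `miles_1 - miles_2`).
#' @export
headline_summary <- function(result_staffing, result_miles) {
  stopifnot(inherits(result_staffing, "solve_result"),
            inherits(result_miles, "solve_result"))
  if (!identical(result_staffing$signature, result_miles$signature))
    stop("results come from different instances")
  a1 <- nrow(result_staffing$rota$assignments)
  a2 <- nrow(result_miles$rota$assignments)
  m1 <- if (result_staffing$mode == "min_miles")
    result_staffing$objective_value else result_staffing$secondary_value
  m2 <- if (result_miles$mode == "min_miles")
    result_miles$objective_value else result_miles$secondary_value
  saved <- m1 - m2
  if (saved < 0)
    warning("the mileage-focused solve travelled further than the ",
            "staffing-focused one (saving is negative)")
  list(assignments_staffing = a1, assignments_miles = a2,
       miles_1 = m1, miles_2 = m2, miles_saved = saved)
}

#' Write / read a rota grid as CSV
#'
#' The CSV mirrors the rendered grid: first column `name`, one column per
#' date. `read_rota_csv()` maps display names back to ids via the
#' instance, reconstructing an identical [rota()].
#'
#' @param rota a [rota()] (for writing).
#' @param instance the matching [schedule_instance()].
#' @param path file path.
#' @return `read_rota_csv` returns a [rota()].
#' @export
write_rota_csv <- function(rota, instance, path) {
  grid <- render_rota(rota, instance)
  df <- data.frame(name = rownames(grid), unclass(grid), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rota_csv
#' @export
read_rota_csv <- function(path, instance) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  keys <- setdiff(names(df), "name")
  staff_id <- setNames(instance$staff$id, instance$staff$name)
  loc_id <- setNames(instance$locations$id, instance$locations$name)
  unknown <- setdiff(df$name, names(staff_id))
  if (length(unknown)) stop("unknown staff name(s) in rota CSV: ",
                            paste(unknown, collapse = ", "))
  rows <- list()
  for (j in keys) for (i in seq_len(nrow(df))) {
    cell <- df[[j]][i]
    if (is.na(cell) || cell == OFF_LABEL) next
    if (!cell %in% names(loc_id))
      stop("unknown location name '", cell, "' in rota CSV")
    rows[[length(rows) + 1L]] <- data.frame(
      staff = staff_id[[df$name[i]]], date = as.Date(j),
      location = loc_id[[cell]], stringsAsFactors = FALSE)
  }
  asg <- if (length(rows)) do.call(rbind, rows)
         else data.frame(staff = character(), date = as.Date(character()),
                         location = character())
  rota(asg, instance$staff$id, as.Date(keys),
       objective_mode = NA_character_, solver_status = "loaded")
}

#' Write a mileage table as CSV (with totals row and column)
#'
#' @param mileage a `mileage_table`.
#' @param path file path.
#' @export
write_mileage_csv <- function(mileage, path) {
  out <- rbind(cbind(mileage$miles, Total = mileage$row_totals),
               Total = c(mileage$col_totals, mileage$grand_total))
  df <- data.frame(name = rownames(out), out, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a mileage grid CSV back into a mileage table
#'
#' Accepts grids written by [write_mileage_csv()] (totals are recomputed,
#' not trusted) or plain staff-by-date grids.
#'
#' @param path file path.
#' @return a `mileage_table`.
#' @export
read_mileage_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  keep_r <- rn != "Total"
  keep_c <- colnames(m) != "Total"
  m <- m[keep_r, keep_c, drop = FALSE]
  rownames(m) <- rn[keep_r]
  storage.mode(m) <- "double"
  as_mileage_table(m)
}
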