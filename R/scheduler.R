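# The binary integer program and its exact solution.
#
# Decision variables x_{i,l,t} = 1 iff staff member i works location l on
# day t. Objectives: (1) minimize total assignments sum x, (2) minimize
# total miles sum m_{i,l} x. Constraints: coverage
# sum_i w_i x_{i,l,t} >= d_{l,t} per location-day, one location per
# staff-day sum_l x_{i,l,t} <= 1, x binary. Unavailable staff-days
# contribute no variables (availability is preprocessing, not a
# constraint). No constraint couples two dates, so the program is solved
# exactly day by day by a specialised branch-and-bound (src/day_solver.cpp)
# and, for verification on small instances, by exhaustive enumeration in
# pure R.

OBJECTIVE_MODES <- c("lexicographic", "min_staffing", "min_miles")

#' Construct a rota object
#'
#' A rota realizes the decision variables as at most one assignment per
#' staff member per day; staff-days without an assignment row are OFF.
#'
#' @param assignments data frame with columns `staff`, `date`, `location`
#'   (one row per worked staff-day; OFF days are absent).
#' @param staff_ids all staff ids of the instance (kept so all-OFF staff
#'   still appear when the rota is rendered).
#' @param dates horizon dates.
#' @param objective_value,objective_mode,solver_status solve metadata.
#' @return an object of class `rota`.
#' @export
rota <- function(assignments, staff_ids, dates,
                 objective_value = NA_real_,
                 objective_mode = NA_character_,
                 solver_status = NA_character_) {
  assignments <- as.data.frame(assignments)
  if (nrow(assignments) == 0)
    assignments <- data.frame(staff = character(), date = as.Date(character()),
                              location = character(), stringsAsFactors = FALSE)
  stopifnot(all(c("staff", "date", "location") %in% names(assignments)))
  assignments$date <- as.Date(assignments$date)
  structure(list(assignments = assignments,
                 staff_ids = as.character(staff_ids),
                 dates = as.Date(dates),
                 objective_value = objective_value,
                 objective_mode = objective_mode,
                 solver_status = solver_status),
            class = "rota")
}

#' @export
print.rota <- function(x, ...) {
  cat("Rota:", nrow(x$assignments), "assignments over",
      length(x$staff_ids), "staff x", length(x$dates), "days",
      sprintf("[%s, status %s]\n", x$objective_mode, x$solver_status))
  invisible(x)
}

instance_signature <- function(instance) {
  list(staff = instance$staff$id, locations = instance$locations$id,
       dates = date_key(instance$horizon),
       demand_total = sum(instance$demand),
       distance_sum = sum(instance$distances))
}

#' Build the binary program for an instance
#'
#' Produces the abstract model: the variable index (one binary per
#' available staff-day and location), the per-variable objective
#' coefficients for both objectives, and constraint counts. The exact
#' solver does not consume this structure (it works day by day); the
#' model description documents exactly which program is being solved and
#' feeds the model statistics reported with every solve.
#'
#' @param instance a valid [schedule_instance()].
#' @param mode one of `"lexicographic"`, `"min_staffing"`, `"min_miles"`.
#' @return an object of class `rota_model` with elements `variables`
#'   (data frame `staff`, `location`, `date`), `cost_staffing`,
#'   `cost_miles`, `n_variables`, `n_coverage_constraints`,
#'   `n_assignment_constraints`, `mode`.
#' @export
build_model <- function(instance, mode = "lexicographic") {
  mode <- match.arg(mode, OBJECTIVE_MODES)
  report <- validate_instance(instance)
  # days whose demand provably exceeds capacity are solver business (the
  # solve reports them as infeasible with a shortfall diagnostic), not a
  # structural defect of the instance
  report <- report[report$check != "infeasible_day", , drop = FALSE]
  if (nrow(report) > 0) {
    err <- structure(class = c("telerota_invalid_instance", "error", "condition"),
                     list(message = paste0("instance fails validation (",
                                           nrow(report), " violation(s))"),
                          call = sys.call(-1), report = report))
    stop(err)
  }
  keys <- date_key(instance$horizon)
  avail <- instance$availability == "available"
  idx <- which(avail, arr.ind = TRUE)
  staff_day <- data.frame(staff = rownames(avail)[idx[, 1]],
                          date = keys[idx[, 2]], stringsAsFactors = FALSE)
  locs <- instance$locations$id
  vars <- staff_day[rep(seq_len(nrow(staff_day)), each = length(locs)), ]
  vars$location <- rep(locs, times = nrow(staff_day))
  rownames(vars) <- NULL
  vars <- vars[, c("staff", "location", "date")]
  cost_miles <- instance$distances[cbind(vars$staff, vars$location)]
  structure(list(variables = vars,
                 cost_staffing = rep(1, nrow(vars)),
                 cost_miles = cost_miles,
                 n_variables = nrow(vars),
                 n_coverage_constraints = length(locs) * length(keys),
                 n_assignment_constraints = nrow(staff_day),
                 mode = mode),
            class = "rota_model")
}

#' @export
print.rota_model <- function(x, ...) {
  cat("Binary rostering program [", x$mode, "]: ", x$n_variables,
      " variables, ", x$n_coverage_constraints, " coverage + ",
      x$n_assignment_constraints, " assignment constraints\n", sep = "")
  invisible(x)
}

solve_one_day <- function(instance, t, staff_order, mode, node_limit) {
  keys <- date_key(instance$horizon)
  avail_ids <- staff_order[instance$availability[staff_order, t] == "available"]
  d <- instance$demand[, t]
  if (length(avail_ids) == 0 && sum(d) > 0)
    return(list(feasible = FALSE, avail_ids = avail_ids))
  w <- instance$staff$capacity[match(avail_ids, instance$staff$id)]
  cost <- instance$distances[avail_ids, , drop = FALSE]
  run <- function(objective, count_eq = -1L)
    .solve_day_cpp(as.integer(w), cost, as.integer(d),
                   as.integer(objective), as.integer(count_eq), node_limit)
  res <- switch(mode,
    min_staffing = run(0L),
    min_miles = run(1L),
    lexicographic = {
      s1 <- run(0L)
      if (!s1$feasible || s1$aborted) s1
      else {
        s2 <- run(1L, count_eq = as.integer(s1$value))
        s2$stage1 <- s1$value
        s2
      }
    })
  res$avail_ids <- avail_ids
  res
}

#' Solve the rostering program exactly
#'
#' Solves the binary program day by day with an exact branch-and-bound.
#' In `"lexicographic"` mode the staffing objective is minimized first,
#' then miles are minimized subject to the staffing optimum being kept
#' (the stage-1 objective value is imposed as an equality in stage 2).
#' On infeasible instances a shortfall diagnostic is computed per
#' location-day from a max-coverage relaxation, and no rota is returned.
#'
#' @param instance a valid [schedule_instance()].
#' @param mode objective mode; see [build_model()].
#' @param time_limit soft wall-clock budget in seconds, translated into a
#'   search-node budget; desk-scale instances solve in milliseconds.
#' @param tie_break_seed optional integer; permutes the staff branching
#'   order so that alternate optima can be explored reproducibly. The
#'   objective value never depends on it.
#' @return an object of class `solve_result`: `rota`, `objective_value`,
#'   `secondary_value` (the other objective evaluated on the same rota),
#'   `status` (`"optimal"`, `"infeasible"`, `"time_limit"`), `wall_time`,
#'   `model_stats`, and (when infeasible) `shortfall`.
#' @export
solve_rota <- function(instance, mode = "lexicographic", time_limit = 60,
                       tie_break_seed = NULL) {
  mode <- match.arg(mode, OBJECTIVE_MODES)
  t0 <- proc.time()[["elapsed"]]
  model <- build_model(instance, mode)  # validates; supplies statistics
  # ~2e6 nodes/s for the C++ search; a generous per-day budget
  node_limit <- max(1e6, time_limit * 2e6 / length(instance$horizon))
  staff_order <- instance$staff$id
  if (!is.null(tie_break_seed))
    staff_order <- with_seed(tie_break_seed, sample(staff_order))
  keys <- date_key(instance$horizon)
  locs <- instance$locations$id
  assignments <- list()
  infeasible_days <- character()
  aborted <- FALSE
  for (t in seq_along(keys)) {
    res <- solve_one_day(instance, t, staff_order, mode, node_limit)
    if (isTRUE(res$aborted)) { aborted <- TRUE; break }
    if (!isTRUE(res$feasible)) { infeasible_days <- c(infeasible_days, keys[t]); next }
    on_duty <- which(res$assign > 0)
    if (length(on_duty))
      assignments[[keys[t]]] <- data.frame(
        staff = res$avail_ids[on_duty], date = as.Date(keys[t]),
        location = locs[res$assign[on_duty]], stringsAsFactors = FALSE)
  }
  wall <- proc.time()[["elapsed"]] - t0
  if (aborted || length(infeasible_days)) {
    status <- if (aborted) "time_limit" else "infeasible"
    shortfall <- if (length(infeasible_days))
      shortfall_diagnostic(instance, infeasible_days, staff_order, node_limit)
    else NULL
    return(structure(list(rota = NULL, objective_value = NA_real_,
                          secondary_value = NA_real_, status = status,
                          wall_time = wall, model_stats = model_stats(model),
                          mode = mode, shortfall = shortfall,
                          signature = instance_signature(instance)),
                     class = "solve_result"))
  }
  asg <- if (length(assignments)) do.call(rbind, assignments)
         else data.frame(staff = character(), date = as.Date(character()),
                         location = character())
  rownames(asg) <- NULL
  n_assign <- nrow(asg)
  miles <- if (n_assign) sum(instance$distances[cbind(asg$staff, asg$location)]) else 0
  primary <- switch(mode, min_miles = miles, n_assign)
  secondary <- switch(mode, min_miles = n_assign, miles)
  r <- rota(asg, instance$staff$id, instance$horizon,
            objective_value = primary, objective_mode = mode,
            solver_status = "optimal")
  structure(list(rota = r, objective_value = primary,
                 secondary_value = secondary, status = "optimal",
                 wall_time = wall, model_stats = model_stats(model),
                 mode = mode, shortfall = NULL,
                 signature = instance_signature(instance)),
            class = "solve_result")
}

model_stats <- function(model) {
  list(n_variables = model$n_variables,
       n_coverage_constraints = model$n_coverage_constraints,
       n_assignment_constraints = model$n_assignment_constraints)
}

# Per location-day unmet demand under the best achievable coverage
# (minimize total slack in sum w x + slack >= d). Diagnostic only.
shortfall_diagnostic <- function(instance, day_keys, staff_order, node_limit) {
  keys <- date_key(instance$horizon)
  out <- list()
  for (key in day_keys) {
    t <- match(key, keys)
    avail_ids <- staff_order[instance$availability[staff_order, t] == "available"]
    d <- instance$demand[, t]
    w <- instance$staff$capacity[match(avail_ids, instance$staff$id)]
    cost <- instance$distances[avail_ids, , drop = FALSE]
    res <- .solve_day_cpp(as.integer(w), cost, as.integer(d), 2L, -1L, node_limit)
    covered <- integer(length(d))
    on_duty <- which(res$assign > 0)
    for (k in on_duty) {
      l <- res$assign[k]
      covered[l] <- covered[l] + w[k]
    }
    short <- pmax(d - covered, 0L)
    hit <- which(short > 0)
    out[[key]] <- data.frame(location = instance$locations$id[hit],
                             date = as.Date(key), shortfall = short[hit],
                             stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' @export
print.solve_result <- function(x, ...) {
  cat("Solve [", x$mode, "]: status ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", objective ", x$objective_value,
        ", secondary ", x$secondary_value, sep = "")
  cat(sprintf(" (%.3fs, %d vars)\n", x$wall_time, x$model_stats$n_variables))
  if (!is.null(x$shortfall)) {
    cat("Unmet demand:\n"); print(x$shortfall)
  }
  invisible(x)
}

#' Exhaustive-enumeration oracle for small instances
#'
#' Enumerates every 0/1 assignment of the binary variables (at most 20 of
#' them), filters by the coverage and one-location constraints, and
#' returns the true optimum. Entirely independent of the branch-and-bound
#' path: constraints are rebuilt from the instance by plain loops and the
#' search is a vectorised scan. Intended for verification in tests.
#'
#' @inheritParams solve_rota
#' @param max_vars safety bound on enumerable binary variables.
#' @return a `solve_result` (without timing-oriented fields).
#' @export
brute_force_solve <- function(instance, mode = "lexicographic", max_vars = 20L) {
  mode <- match.arg(mode, OBJECTIVE_MODES)
  keys <- date_key(instance$horizon)
  locs <- instance$locations$id
  avail <- instance$availability == "available"
  vars <- list()
  for (i in seq_along(instance$staff$id))
    for (t in seq_along(keys))
      if (avail[i, t])
        for (l in seq_along(locs))
          vars[[length(vars) + 1L]] <- c(i, l, t)
  n <- length(vars)
  if (n > max_vars)
    stop("instance too large for exhaustive enumeration: ", n,
         " binary variables (bound ", max_vars, ")")
  if (n == 0) {
    feasible <- sum(instance$demand) == 0
    r <- if (feasible)
      rota(data.frame(), instance$staff$id, instance$horizon,
           objective_value = 0, objective_mode = mode,
           solver_status = "optimal")
    else NULL
    return(structure(list(rota = r, objective_value = if (feasible) 0 else NA_real_,
                          secondary_value = if (feasible) 0 else NA_real_,
                          status = if (feasible) "optimal" else "infeasible",
                          mode = mode, shortfall = NULL,
                          signature = instance_signature(instance)),
                     class = "solve_result"))
  }
  vm <- do.call(rbind, vars)  # columns: staff, location, day
  w <- instance$staff$capacity
  cost <- instance$distances[cbind(instance$staff$id[vm[, 1]], locs[vm[, 2]])]
  staff_day <- paste(vm[, 1], vm[, 3])
  loc_day <- paste(vm[, 2], vm[, 3])
  d_needed <- instance$demand
  best <- NULL
  total_d <- sum(d_needed)
  eval_chunk <- function(codes) {
    bits <- matrix(0L, nrow = length(codes), ncol = max(n, 1L))
    for (j in seq_len(n)) bits[, j] <- (codes %/% (2^(j - 1))) %% 2
    ok <- rep(TRUE, length(codes))
    for (sd in unique(staff_day)) {
      cols <- which(staff_day == sd)
      ok <- ok & rowSums(bits[, cols, drop = FALSE]) <= 1
    }
    for (l in seq_along(locs)) for (t in seq_along(keys)) {
      dlt <- d_needed[l, t]
      if (dlt == 0) next
      cols <- which(vm[, 2] == l & vm[, 3] == t)
      cover <- if (length(cols))
        as.vector(bits[, cols, drop = FALSE] %*% w[vm[cols, 1]])
      else 0
      ok <- ok & cover >= dlt
    }
    if (!any(ok)) return(NULL)
    bits <- bits[ok, , drop = FALSE]
    count <- rowSums(bits)
    miles <- as.vector(bits %*% cost)
    data.frame(count = count, miles = miles,
               code = codes[ok], stringsAsFactors = FALSE)
  }
  feas <- list()
  chunk <- 2^16
  codes_all <- 0:(2^n - 1)
  for (start in seq(1, length(codes_all), by = chunk)) {
    res <- eval_chunk(codes_all[start:min(start + chunk - 1, length(codes_all))])
    if (!is.null(res)) feas[[length(feas) + 1L]] <- res
  }
  if (!length(feas))
    return(structure(list(rota = NULL, objective_value = NA_real_,
                          secondary_value = NA_real_, status = "infeasible",
                          mode = mode, shortfall = NULL,
                          signature = instance_signature(instance)),
                     class = "solve_result"))
  feas <- do.call(rbind, feas)
  ord <- switch(mode,
    min_staffing = order(feas$count, feas$code),
    min_miles = order(feas$miles, feas$code),
    lexicographic = order(feas$count, feas$miles, feas$code))
  pick <- feas[ord[1], ]
  on <- which((pick$code %/% 2^(seq_len(n) - 1)) %% 2 == 1)
  asg <- data.frame(staff = instance$staff$id[vm[on, 1]],
                    date = as.Date(keys[vm[on, 3]]),
                    location = locs[vm[on, 2]], stringsAsFactors = FALSE)
  primary <- switch(mode, min_miles = pick$miles, pick$count)
  secondary <- switch(mode, min_miles = pick$count, pick$miles)
  r <- rota(asg, instance$staff$id, instance$horizon,
            objective_value = primary, objective_mode = mode,
            solver_status = "optimal")
  structure(list(rota = r, objective_value = primary,
                 secondary_value = secondary, status = "optimal",
                 mode = mode, shortfall = NULL,
                 signature = instance_signature(instance)),
            class = "solve_result")
}

#' Verify a rota against an instance
#'
#' Recomputes feasibility from first principles: coverage at every
#' location-day, at most one location per staff-day, and no assignment on
#' an unavailable staff-day. Also recomputes the two objective totals
#' from scratch.
#'
#' @param rota a [rota()] (e.g. from [solve_rota()] or [read_rota_csv()]).
#' @param instance the [schedule_instance()] it should satisfy.
#' @return an object of class `rota_audit`: `violations` (a
#'   `validation_report`), `total_assignments`, `total_miles`, `feasible`.
#' @export
verify_rota <- function(rota, instance) {
  stopifnot(inherits(rota, "rota"), inherits(instance, "schedule_instance"))
  rep <- new_report()
  asg <- rota$assignments
  keys <- date_key(instance$horizon)
  bad_staff <- setdiff(asg$staff, instance$staff$id)
  for (s in bad_staff) rep <- add_violation(rep, "unknown_staff", s, "not in instance")
  bad_loc <- setdiff(asg$location, instance$locations$id)
  for (l in bad_loc) rep <- add_violation(rep, "unknown_location", l, "not in instance")
  bad_date <- setdiff(date_key(asg$date), keys)
  for (d in bad_date) rep <- add_violation(rep, "unknown_date", d, "outside horizon")
  asg_ok <- asg[asg$staff %in% instance$staff$id &
                asg$location %in% instance$locations$id &
                date_key(asg$date) %in% keys, , drop = FALSE]
  # one location per staff-day
  key_sd <- paste(asg_ok$staff, date_key(asg_ok$date))
  dup <- unique(key_sd[duplicated(key_sd)])
  for (k in dup)
    rep <- add_violation(rep, "multiple_locations", k,
                         "staff member assigned to more than one location that day")
  # availability compliance
  av <- instance$availability[cbind(asg_ok$staff, date_key(asg_ok$date))]
  for (i in which(av != "available"))
    rep <- add_violation(rep, "unavailable",
                         paste(asg_ok$staff[i], date_key(asg_ok$date[i])),
                         paste("assignment on a", av[i], "day"))
  # coverage
  w <- setNames(instance$staff$capacity, instance$staff$id)
  for (t in seq_along(keys)) for (l in instance$locations$id) {
    dlt <- instance$demand[l, t]
    if (dlt == 0) next
    rows <- asg_ok$location == l & date_key(asg_ok$date) == keys[t]
    cover <- sum(w[asg_ok$staff[rows]])
    if (cover < dlt)
      rep <- add_violation(rep, "coverage", paste(l, keys[t]),
                           sprintf("capacity %d < demand %d", cover, dlt))
  }
  miles <- if (nrow(asg_ok))
    sum(instance$distances[cbind(asg_ok$staff, asg_ok$location)]) else 0
  structure(list(violations = rep,
                 total_assignments = nrow(asg),
                 total_miles = miles,
                 feasible = nrow(rep) == 0),
            class = "rota_audit")
}

#' @export
print.rota_audit <- function(x, ...) {
  cat("Rota audit:", if (x$feasible) "feasible" else "INFEASIBLE",
      "|", x$total_assignments, "assignments,", x$total_miles, "miles\n")
  if (!x$feasible) print(x$violations)
  invisible(x)
}
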