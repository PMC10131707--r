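# Demand analysis: weekday summary statistics and a calendar-covariate
# regression used to forecast daily referral counts per site.
#
# The forecasting model is an ordinary least-squares regression of the
# daily count on indicator covariates: day of week (reference Sunday),
# month (reference January) and a bank-holiday flag. Each location is
# fitted separately by default (the weaker assumption for site-dependent
# demand); a pooled fit with location dummies is available as a flag.

#' Construct a demand history
#'
#' @param date observation dates.
#' @param location location ids.
#' @param count observed daily referral counts (nonnegative integers).
#' @return a `demand_history` data frame.
#' @export
demand_history <- function(date, location, count) {
  df <- data.frame(date = as_iso_date(date), location = as.character(location),
                   count = as.integer(count), stringsAsFactors = FALSE)
  if (any(df$count < 0)) stop("counts must be nonnegative")
  if (anyDuplicated(df[c("date", "location")]))
    stop("duplicate (date, location) records")
  class(df) <- c("demand_history", "data.frame")
  df
}

stat_mode <- function(x) {
  # smallest most-frequent value on ties
  tab <- table(x)
  as.numeric(min(as.numeric(names(tab)[tab == max(tab)])))
}

WEEKDAY_SUMMARY_STATS <- c("Mean", "Median", "Mode", "Minimum", "Maximum",
                           "Range", "Total")

#' Weekday-dependent demand summary
#'
#' Computes, per weekday, the mean, median, mode (smallest most-frequent
#' value on ties), minimum, maximum, range and total of the observed
#' counts — the summary used to inspect how demand drops at weekends.
#'
#' @param history a [demand_history()].
#' @param location optional location id filter; by default all records
#'   are pooled.
#' @return a numeric matrix, statistics by weekday (Mon..Sun), of class
#'   `weekday_summary`.
#' @export
summarize_weekday_demand <- function(history, location = NULL) {
  if (!is.null(location))
    history <- history[history$location %in% location, , drop = FALSE]
  if (nrow(history) == 0) stop("empty demand history")
  wd <- factor(weekday_of(history$date), levels = WEEKDAYS)
  m <- matrix(NA_real_, nrow = length(WEEKDAY_SUMMARY_STATS),
              ncol = length(WEEKDAYS),
              dimnames = list(WEEKDAY_SUMMARY_STATS, WEEKDAYS))
  for (d in WEEKDAYS) {
    x <- history$count[wd == d]
    if (length(x) == 0) next
    m[, d] <- c(mean(x), median(x), stat_mode(x), min(x), max(x),
                max(x) - min(x), sum(x))
  }
  structure(m, class = c("weekday_summary", class(m)))
}

#' @export
print.weekday_summary <- function(x, digits = 3, ...) {
  print(round(unclass(x), digits), ...)
  invisible(x)
}

covariate_frame <- function(dates, bank_holidays) {
  data.frame(
    wday = factor(weekday_of(dates), levels = WEEKDAYS_SUN_FIRST),
    month = factor(month_of(dates), levels = MONTHS),
    holiday = as.integer(as.Date(dates) %in% as.Date(bank_holidays)))
}

# OLS on an explicitly built design matrix. lm() on the factor formula
# would silently drop unused weekday/month levels (e.g. for a history
# shorter than a year), losing the fixed 19-column coefficient layout,
# so the indicator matrix is expanded first and aliased columns are
# reported and zeroed.
fit_design <- function(X, y, label) {
  fit <- lm(y ~ X - 1)
  cf <- coef(fit)
  names(cf) <- colnames(X)
  dropped <- names(cf)[is.na(cf)]
  if (length(dropped))
    warning(label, ": aliased covariate column(s) dropped: ",
            paste(dropped, collapse = ", "))
  cf[is.na(cf)] <- 0
  sm <- suppressWarnings(summary(fit))
  se <- rep(NA_real_, length(cf))
  names(se) <- names(cf)
  est <- rownames(sm$coefficients)
  se[sub("^X", "", est)] <- sm$coefficients[, "Std. Error"]
  # centred R^2 (summary.lm would use the uncentred form for a
  # no-intercept call even though X carries an explicit intercept)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  list(coefficients = cf, se = se, dropped = dropped,
       r_squared = r2, sigma = sm$sigma, n = length(y))
}

fit_one_location <- function(df, bank_holidays, loc) {
  X <- model.matrix(~ wday + month + holiday,
                    covariate_frame(df$date, bank_holidays))
  fit_design(X, df$count, paste("location", loc))
}

#' Fit the calendar-covariate demand regression
#'
#' Ordinary least squares of the daily count on day-of-week, month and
#' bank-holiday indicators (19 coefficients per location: intercept, 6
#' weekday, 11 month, 1 holiday). Reference levels are Sunday, January
#' and non-holiday. Aliased (rank-deficient) columns are dropped to zero
#' with a warning.
#'
#' @param history a [demand_history()].
#' @param bank_holidays vector of bank-holiday dates.
#' @param pooled if `TRUE`, fit one model across locations with location
#'   dummies instead of separate per-location fits.
#' @param min_records minimum records per location for a fit.
#' @return an object of class `demand_model`.
#' @export
fit_demand_model <- function(history, bank_holidays = as.Date(character()),
                             pooled = FALSE, min_records = 20L) {
  stopifnot(inherits(history, "data.frame"), nrow(history) > 0)
  locs <- sort(unique(history$location))
  small <- locs[table(factor(history$location, levels = locs)) < min_records]
  if (length(small))
    stop("too few records (< ", min_records, ") for location(s): ",
         paste(small, collapse = ", "))
  fits <- if (pooled) {
    dat <- cbind(covariate_frame(history$date, bank_holidays),
                 location = factor(history$location, levels = locs))
    X <- model.matrix(~ location + wday + month + holiday, dat)
    pooled_fit <- fit_design(X, history$count, "pooled model")
    cf <- pooled_fit$coefficients
    base <- cf[!grepl("^location", names(cf))]
    lapply(setNames(locs, locs), function(l) {
      shift <- if (l == locs[1]) 0 else cf[[paste0("location", l)]]
      co <- base
      co[["(Intercept)"]] <- co[["(Intercept)"]] + shift
      list(coefficients = co, se = NULL, dropped = pooled_fit$dropped,
           r_squared = pooled_fit$r_squared, sigma = pooled_fit$sigma,
           n = sum(history$location == l))
    })
  } else {
    lapply(setNames(locs, locs), function(l)
      fit_one_location(history[history$location == l, , drop = FALSE],
                       bank_holidays, l))
  }
  structure(list(locations = fits, pooled = pooled,
                 reference = list(weekday = "Sun", month = "Jan",
                                  holiday = "none")),
            class = "demand_model")
}

#' @export
print.demand_model <- function(x, ...) {
  cat("Calendar-covariate demand model (",
      if (x$pooled) "pooled" else "per-location", "):\n", sep = "")
  for (l in names(x$locations)) {
    f <- x$locations[[l]]
    cat(sprintf("  %s: n = %d, R^2 = %.3f, residual SD = %.3f\n",
                l, f$n, f$r_squared, f$sigma))
  }
  invisible(x)
}

linear_predictor <- function(coefficients, dates, bank_holidays) {
  X <- model.matrix(~ wday + month + holiday,
                    covariate_frame(dates, bank_holidays))
  stopifnot(identical(colnames(X), names(coefficients)))
  as.vector(X %*% coefficients)
}

#' Predict an integer demand matrix from a fitted model
#'
#' Evaluates the linear predictor for every location and horizon date,
#' clamps negative raw predictions to zero, and rounds to an integer —
#' by default to the nearest integer (half away from zero), or with
#' `"ceiling"` for a conservative staffing plan.
#'
#' @param model a [fit_demand_model()] result.
#' @param horizon `Date` vector of forecast dates.
#' @param bank_holidays vector of bank-holiday dates.
#' @param rounding `"nearest"` or `"ceiling"`.
#' @param locations location ids to predict; defaults to the model's.
#' @return integer demand matrix (location by date).
#' @export
predict_demand <- function(model, horizon,
                           bank_holidays = as.Date(character()),
                           rounding = c("nearest", "ceiling"),
                           locations = NULL) {
  rounding <- match.arg(rounding)
  horizon <- check_horizon(horizon)
  locations <- locations %||% names(model$locations)
  unknown <- setdiff(locations, names(model$locations))
  if (length(unknown))
    stop("model has no fit for location(s): ", paste(unknown, collapse = ", "))
  m <- matrix(0L, nrow = length(locations), ncol = length(horizon),
              dimnames = list(locations, date_key(horizon)))
  for (l in locations) {
    raw <- linear_predictor(model$locations[[l]]$coefficients, horizon,
                            bank_holidays)
    raw <- pmax(raw, 0)
    m[l, ] <- as.integer(if (rounding == "nearest") round_half_up(raw)
                         else ceiling(raw))
  }
  m
}

#' Write / read a weekday summary as CSV
#'
#' The CSV layout has one row per statistic (Mean, Median, Mode, Minimum,
#' Maximum, Range, Total) and one column per weekday, so a written
#' summary re-reads to identical statistics.
#'
#' @param summary a [summarize_weekday_demand()] result.
#' @param path file path.
#' @return `read_weekday_summary_csv` returns a `weekday_summary` matrix.
#' @export
write_weekday_summary_csv <- function(summary, path) {
  df <- data.frame(statistic = rownames(summary), unclass(summary),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weekday_summary_csv
#' @export
read_weekday_summary_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, WEEKDAYS])
  rownames(m) <- df$statistic
  structure(m[WEEKDAY_SUMMARY_STATS, WEEKDAYS],
            class = c("weekday_summary", "matrix", "array"))
}
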