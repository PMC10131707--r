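# Shared helpers: calendar arithmetic, rounding, seeded RNG scopes.

# Weekday labels, Monday-first for presentation (rota weeks run Mon..Sun).
WEEKDAYS <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
# Sunday-first ordering used as the regression reference coding.
WEEKDAYS_SUN_FIRST <- c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")
MONTHS <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
            "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

# Locale-independent weekday label (as.POSIXlt wday: 0 = Sunday).
weekday_of <- function(dates) {
  WEEKDAYS_SUN_FIRST[as.POSIXlt(dates)$wday + 1L]
}

month_of <- function(dates) {
  MONTHS[as.POSIXlt(dates)$mon + 1L]
}

is_weekend <- function(dates) {
  weekday_of(dates) %in% c("Sat", "Sun")
}

# Round half away from zero (base round() rounds half to even).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

date_key <- function(dates) format(dates, "%Y-%m-%d")

as_iso_date <- function(x) {
  d <- as.Date(x, format = "%Y-%m-%d")
  if (anyNA(d)) stop("dates must be ISO-8601 (YYYY-MM-DD); got: ",
                     paste(utils::head(x[is.na(d)], 3L), collapse = ", "))
  d
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a bounded child seed so independent stages get distinct streams.
child_seed <- function(seed, offset) {
  (as.integer(seed) * 1000L + as.integer(offset)) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() without the scalar-x pitfall (sample(5, 1) draws from 1:5)
resample <- function(x, k) x[sample.int(length(x), k)]
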