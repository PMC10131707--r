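test_that("weekday summary statistics match hand arithmetic", {
  # three Mondays with counts 2, 2, 4 (2023-01-02/09/16 are Mondays)
  hist <- demand_history(c("2023-01-02", "2023-01-09", "2023-01-16"),
                         rep("hospital_1", 3), c(2, 2, 4))
  s <- summarize_weekday_demand(hist)
  expect_equal(unname(s[, "Mon"]),
               c(8 / 3, 2, 2, 2, 4, 2, 8))
  expect_true(all(is.na(s[, "Tue"])))
})

test_that("a single record degenerates to mean = median = mode = min = max", {
  hist <- demand_history("2023-01-04", "aa", 5)
  s <- summarize_weekday_demand(hist)
  expect_equal(unname(s[, "Wed"]), c(5, 5, 5, 5, 5, 0, 5))
})

test_that("mode breaks ties toward the smallest value", {
  hist <- demand_history(sprintf("2023-01-%02d", c(2, 9, 16, 23)),
                         rep("aa", 4), c(3, 1, 3, 1))
  expect_equal(summarize_weekday_demand(hist)["Mode", "Mon"], 1)
})

test_that("summary equals an independent recount of generated records", {
  cfg <- generator_config(seed = 5, n_hospitals = 2)
  hist <- generate_demand_history(cfg, n_days = 112,
                                  coefficients = list(intercept = 2,
                                                      weekday = c(Mon = 1)),
                                  noise_sd = 0.5)
  s <- summarize_weekday_demand(hist, location = "hospital_1")
  sub <- hist[hist$location == "hospital_1", ]
  wd <- wday_label(sub$date)
  for (d in c("Mon", "Wed", "Sun")) {
    x <- sub$count[wd == d]
    expect_equal(s["Mean", d], mean(x))
    expect_equal(s["Median", d], median(x))
    expect_equal(s["Minimum", d], min(x))
    expect_equal(s["Maximum", d], max(x))
    expect_equal(s["Range", d], max(x) - min(x))
    expect_equal(s["Total", d], sum(x))
    tab <- table(x)
    expect_equal(s["Mode", d], min(as.numeric(names(tab)[tab == max(tab)])))
  }
})

test_that("summary CSV layout round-trips to identical statistics", {
  cfg <- generator_config(seed = 9, n_hospitals = 1)
  hist <- generate_demand_history(cfg, n_days = 70)
  s <- summarize_weekday_demand(hist)
  path <- withr::local_tempfile(fileext = ".csv")
  write_weekday_summary_csv(s, path)
  s2 <- read_weekday_summary_csv(path)
  expect_equal(unclass(s2), unclass(s), ignore_attr = TRUE)
  expect_equal(rownames(s2), c("Mean", "Median", "Mode", "Minimum",
                               "Maximum", "Range", "Total"))
})

test_that("empty histories are rejected explicitly", {
  hist <- demand_history("2023-01-02", "aa", 1)
  expect_error(summarize_weekday_demand(hist, location = "not_there"),
               "empty")
})

test_that("a constant response fits to intercept-only with zero residual SD", {
  dates <- seq(as.Date("2022-01-01"), by = 1, length.out = 400)
  hist <- demand_history(dates, rep("aa", 400), rep(3L, 400))
  m <- suppressWarnings(fit_demand_model(hist))
  f <- m$locations[["aa"]]
  expect_equal(unname(f$coefficients["(Intercept)"]), 3)
  expect_equal(unname(f$coefficients[-1]), rep(0, 18))
  expect_equal(f$sigma, 0, tolerance = 1e-10)
  expect_equal(length(f$coefficients), 1 + 6 + 11 + 1)
})

test_that("coefficients match the closed-form normal-equations solution", {
  # one month of data: month and holiday columns are aliased and dropped,
  # leaving intercept + 6 weekday indicators, solved by hand
  dates <- planning_horizon("2023-01-02", 28)
  counts <- c(3, 2, 2, 2, 2, 1, 1)[match(wday_label(dates),
                                         c("Mon", "Tue", "Wed", "Thu",
                                           "Fri", "Sat", "Sun"))]
  counts <- counts + rep(c(0, 1, 0, 1), each = 7)  # deterministic wobble
  hist <- demand_history(dates, rep("hospital_1", 28), counts)
  expect_warning(m <- fit_demand_model(hist), "aliased")
  f <- m$locations[["hospital_1"]]
  X <- cbind(1, sapply(c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat"),
                       function(d) as.integer(wday_label(dates) == d)))
  beta <- solve(crossprod(X), crossprod(X, counts))
  got <- f$coefficients[c("(Intercept)", "wdayMon", "wdayTue", "wdayWed",
                          "wdayThu", "wdayFri", "wdaySat")]
  expect_equal(unname(got), as.vector(beta), tolerance = 1e-10)
  expect_true(all(c("wdaySun", "holiday") %in% f$dropped == c(FALSE, TRUE)))
})

test_that("weekday effects are recovered within 3 standard errors", {
  cfg <- generator_config(seed = 21, n_hospitals = 1)
  hist <- generate_demand_history(cfg, n_days = 364,
                                  coefficients = list(intercept = 2,
                                                      weekday = c(Mon = 1)),
                                  noise_sd = 0.3)
  hist <- hist[hist$location == "hospital_1", ]
  m <- suppressWarnings(fit_demand_model(hist))  # no holidays: column aliased
  f <- m$locations[["hospital_1"]]
  expect_lt(abs(f$coefficients[["wdayMon"]] - 1), 3 * f$se[["wdayMon"]])
})

test_that("too few records raise an error naming the location", {
  hist <- demand_history(sprintf("2023-01-%02d", 1:9), rep("tiny", 9), 1:9)
  expect_error(fit_demand_model(hist), "tiny")
})

test_that("predictions clamp, round and stay deterministic", {
  dates <- seq(as.Date("2022-01-01"), by = 1, length.out = 400)
  hist3 <- demand_history(dates, rep("aa", 400), rep(3L, 400))
  m3 <- suppressWarnings(fit_demand_model(hist3))
  h <- planning_horizon("2024-05-06", 7)
  expect_equal(unname(predict_demand(m3, h)["aa", ]), rep(3L, 7))

  hist0 <- demand_history(dates, rep("aa", 400), rep(0L, 400))
  m0 <- suppressWarnings(fit_demand_model(hist0))
  m0$locations$aa$coefficients["(Intercept)"] <- 0.2
  expect_equal(unname(predict_demand(m0, h)["aa", ]), rep(0L, 7))
  expect_equal(unname(predict_demand(m0, h, rounding = "ceiling")["aa", ]),
               rep(1L, 7))
  # determinism
  expect_identical(predict_demand(m3, h), predict_demand(m3, h))
})

test_that("the demand matrix equals a cell-by-cell evaluation of the predictor", {
  cfg <- generator_config(seed = 33, n_hospitals = 2)
  hol <- as.Date(c("2023-04-07", "2023-05-01"))
  hist <- generate_demand_history(cfg, n_days = 364,
                                  coefficients = list(intercept = 2,
                                                      weekday = c(Mon = 1, Sat = -1),
                                                      month = c(Jul = 1),
                                                      holiday = -1),
                                  noise_sd = 0.3, bank_holidays = hol)
  m <- fit_demand_model(hist, hol)
  h <- planning_horizon("2023-04-03", 14)
  dm <- predict_demand(m, h, hol)
  for (l in rownames(dm)) {
    cf <- m$locations[[l]]$coefficients
    for (j in seq_along(h)) {
      d <- h[j]
      wd <- wday_label(d)
      mo <- month_label(d)
      lp <- cf[["(Intercept)"]] +
        (if (wd != "Sun") cf[[paste0("wday", wd)]] else 0) +
        (if (mo != "Jan") cf[[paste0("month", mo)]] else 0) +
        cf[["holiday"]] * (d %in% hol)
      expect_equal(dm[l, j], as.integer(floor(max(lp, 0) + 0.5)))
    }
  }
})

test_that("noise-free histories reproduce integer coefficients exactly", {
  cfg <- generator_config(seed = 2, n_hospitals = 1)
  hol <- as.Date(c("2023-05-01", "2023-12-25", "2024-01-01"))
  truth <- list(intercept = 2, weekday = c(Mon = 1, Tue = 1, Sat = -1),
                month = c(Jun = 1), holiday = -1)
  hist <- generate_demand_history(cfg, n_days = 728, coefficients = truth,
                                  noise_sd = 0, bank_holidays = hol)
  m <- fit_demand_model(hist, hol)
  f <- m$locations[["hospital_1"]]
  expect_equal(f$coefficients[["(Intercept)"]], 2, tolerance = 1e-8)
  expect_equal(f$coefficients[["wdayMon"]], 1, tolerance = 1e-8)
  expect_equal(f$coefficients[["wdaySat"]], -1, tolerance = 1e-8)
  expect_equal(f$coefficients[["monthJun"]], 1, tolerance = 1e-8)
  expect_equal(f$coefficients[["holiday"]], -1, tolerance = 1e-8)
  expect_equal(f$sigma, 0, tolerance = 1e-8)
})

test_that("pooled mode shifts intercepts by location dummies", {
  cfg <- generator_config(seed = 8, n_hospitals = 2)
  hist <- generate_demand_history(cfg, n_days = 112,
                                  coefficients = list(intercept = 2),
                                  noise_sd = 0.2)
  m <- suppressWarnings(fit_demand_model(hist, pooled = TRUE))
  expect_length(m$locations, 3)
  for (f in m$locations)
    expect_equal(length(f$coefficients), 19)
})
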