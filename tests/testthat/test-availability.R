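ft_staff <- staff_table("ft", "FT", "full_time", 1, "hospital_1")

test_that("a full-time 28-day calendar has 17 available days, 4 on 2 weekends", {
  h <- planning_horizon("2023-01-02", 28)
  cal <- build_availability(ft_staff, h, contract_rules(), seed = 7)
  wd <- wday_label(as.Date(colnames(cal)))
  expect_equal(sum(cal == "available"), 17)
  wknd_avail <- cal["ft", wd %in% c("Sat", "Sun")] == "available"
  expect_equal(sum(wknd_avail), 4)
  # the 4 weekend days form exactly 2 Sat+Sun pairs
  sat <- which(wd == "Sat")
  pairs_worked <- sum(cal["ft", sat] == "available" &
                      cal["ft", sat + 1] == "available")
  expect_equal(pairs_worked, 2)
  expect_equal(sum(cal == "on_leave"), 3)
})

test_that("a part-time-2 staff member gets 2 available days in a single week", {
  pt <- staff_table("pt", "PT", "part_time_2", 1, "hospital_1")
  h <- planning_horizon("2023-01-02", 7)
  cal <- suppressWarnings(build_availability(pt, h, seed = 3))
  expect_equal(sum(cal == "available"), 2)
})

test_that("calendars are deterministic per seed and vary across seeds only in placement", {
  h <- planning_horizon("2023-01-02", 28)
  a <- build_availability(ft_staff, h, seed = 11)
  b <- build_availability(ft_staff, h, seed = 11)
  expect_identical(a, b)
  c2 <- build_availability(ft_staff, h, seed = 12)
  expect_equal(sum(a == "available"), sum(c2 == "available"))
})

test_that("weekly available-day counts never exceed the contract", {
  h <- planning_horizon("2023-01-02", 56)
  staff <- staff_table(paste0("s", 1:4),
                       contract = c("full_time", "part_time_2",
                                    "part_time_3", "part_time_4"),
                       capacity = 1, home_base = "hospital_1")
  for (seed in c(1, 2, 3)) {
    cal <- build_availability(staff, h, seed = seed)
    expect_equal(nrow(audit_availability(cal, staff)), 0)
    for (i in seq_len(4)) {
      cdays <- contract_days(staff$contract[i])
      weekly <- colSums(matrix(cal[i, ] == "available", nrow = 7))
      expect_true(all(weekly <= cdays))
      # equality whenever no leave fell in the week
      leave_wk <- colSums(matrix(cal[i, ] == "on_leave", nrow = 7))
      expect_true(all(weekly[leave_wk == 0] == cdays))
    }
  }
})

test_that("the audit flags overloads, broken weekend pairs and missing cells", {
  h <- planning_horizon("2023-01-02", 28)
  cal <- build_availability(ft_staff, h, seed = 4)
  # hand-edit: make every day of week 1 available (6th+ day overload)
  cal_bad <- cal
  cal_bad["ft", 1:7] <- "available"
  rep1 <- audit_availability(cal_bad, ft_staff)
  expect_true(any(rep1$check == "week_overload"))
  expect_match(rep1$subject[rep1$check == "week_overload"][1], "week 1")
  # break a worked weekend pair
  wd <- wday_label(as.Date(colnames(cal)))
  sat <- which(wd == "Sat" & cal["ft", seq_along(wd)] == "available")[1]
  cal_pair <- cal
  cal_pair["ft", sat + 1] <- "off_contract"
  expect_true(any(audit_availability(cal_pair, ft_staff)$check ==
                    "weekend_pair"))
  # a missing staff-day in an externally supplied calendar
  cal_na <- cal
  cal_na["ft", 5] <- NA
  expect_true(any(audit_availability(cal_na, ft_staff)$check == "coverage"))
})

test_that("non-multiple-of-7 horizons are padded and truncated with a warning", {
  h <- planning_horizon("2023-01-02", 10)
  ws <- testthat::capture_warnings(cal <- build_availability(ft_staff, h,
                                                             seed = 5))
  expect_match(ws, "whole number of weeks", all = FALSE)
  expect_match(ws, "proportionally", all = FALSE)
  expect_equal(ncol(cal), 10)
})

test_that("either-day weekend mode marks one day per worked weekend", {
  h <- planning_horizon("2023-01-02", 28)
  rules <- contract_rules(weekend_mode = "either_day")
  cal <- build_availability(ft_staff, h, rules, seed = 6)
  wd <- wday_label(as.Date(colnames(cal)))
  expect_equal(sum(cal["ft", wd %in% c("Sat", "Sun")] == "available"), 2)
})
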