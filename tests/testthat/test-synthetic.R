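test_that("the case-study fixture is stable, verbatim and internally consistent", {
  inst <- cwtch_instance()
  expect_equal(sum(inst$demand), 31)
  expect_equal(unname(colSums(inst$demand)), c(4, 4, 5, 5, 5, 4, 4))
  expect_equal(inst$distances["kelly", "hospital_2"], 20)
  expect_equal(inst$distances["james", "hospital_1"], 44)
  expect_equal(inst$distances["laura", "hospital_3"], 36)
  expect_true(all(inst$distances[, "aa"] == 0))
  expect_equal(unname(rowSums(inst$distances)),
               c(50, 69, 50, 45, 59, 50, 64, 60))
  expect_equal(inst$staff$name,
               c("Kelly", "James", "Olivia", "Amelia", "Joseph", "Emily",
                 "Matthew", "Laura"))
  expect_equal(format(range(inst$horizon)), c("2019-10-14", "2019-10-20"))
  expect_true(all(inst$staff$capacity == 1))
  expect_true(all(inst$availability == "available"))
  # byte-stable across calls
  expect_identical(cwtch_instance(), inst)
})

test_that("the generator is deterministic per seed", {
  cfg <- generator_config(seed = 42, horizon_days = 14)
  a <- suppressWarnings(generate_instance(cfg))
  b <- suppressWarnings(generate_instance(cfg))
  expect_identical(a, b)
  c2 <- suppressWarnings(generate_instance(generator_config(seed = 43,
                                                            horizon_days = 14)))
  expect_false(identical(a$demand, c2$demand))
})

test_that("zero weekday means produce all-zero demand", {
  cfg <- generator_config(seed = 3, horizon_days = 14,
                          weekday_means = setNames(rep(0, 7),
                                                   c("Mon", "Tue", "Wed",
                                                     "Thu", "Fri", "Sat",
                                                     "Sun")),
                          weekday_min = setNames(rep(0, 7),
                                                 c("Mon", "Tue", "Wed",
                                                   "Thu", "Fri", "Sat",
                                                   "Sun")))
  inst <- suppressWarnings(generate_instance(cfg))
  expect_equal(sum(inst$demand), 0)
})

test_that("generated instances satisfy the validator by construction", {
  for (seed in c(2, 4, 6, 8)) {
    inst <- suppressWarnings(generate_instance(
      generator_config(seed = seed, horizon_days = 28)))
    expect_equal(nrow(validate_instance(inst)), 0)
    # exactly one zero-distance hospital (the home base) per staff member
    hosp <- inst$locations$id[inst$locations$kind == "hospital"]
    zeros <- rowSums(inst$distances[, hosp, drop = FALSE] == 0)
    expect_true(all(zeros == 1))
  }
})

test_that("sampled Monday demand matches its configured mean", {
  totals <- numeric(0)
  for (seed in 1:150) {
    inst <- suppressWarnings(generate_instance(
      generator_config(seed = seed, horizon_days = 28,
                       allow_infeasible = TRUE)))
    mon <- wday_label(inst$horizon) == "Mon"
    totals <- c(totals, colSums(inst$demand)[mon])
  }
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - 2.42), 3 * se)
})

test_that("history generation honours its floor and degenerate settings", {
  cfg <- generator_config(seed = 1, n_hospitals = 1)
  expect_error(generate_demand_history(cfg, n_days = 30), "at least 56")
  hist <- generate_demand_history(cfg, n_days = 56,
                                  coefficients = list(intercept = 2),
                                  noise_sd = 0)
  expect_true(all(hist$count == 2L))
  a <- generate_demand_history(cfg, n_days = 56)
  b <- generate_demand_history(cfg, n_days = 56)
  expect_identical(a, b)
})

test_that("the shipped extdata fixture matches the in-code instance", {
  dir <- system.file("extdata", "cwtch_week", package = "telerota")
  inst <- read_instance_dir(dir)
  ref <- cwtch_instance()
  expect_equal(inst$demand, ref$demand)
  expect_equal(inst$distances, ref$distances)
  pub <- read_rota_csv(file.path(dir, "rota_published.csv"), inst)
  expect_equal(nrow(pub$assignments), 31)
  m2 <- read_mileage_csv(file.path(dir, "mileage_objective2_published.csv"))
  expect_equal(m2$grand_total, 47)
})
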