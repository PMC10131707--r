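test_that("model dimensions follow the instance structure", {
  inst <- cwtch_instance()  # 8 staff x 4 locations x 7 days, all available
  m <- build_model(inst)
  expect_equal(m$n_variables, 8 * 4 * 7)
  expect_equal(m$n_coverage_constraints, 4 * 7)
  expect_equal(m$n_assignment_constraints, 8 * 7)
  # one unavailable staff-day elides one variable per location
  inst2 <- inst
  inst2$availability["kelly", 3] <- "on_leave"
  expect_equal(build_model(inst2)$n_variables, 8 * 4 * 7 - 4)
  # invalid instances are rejected with the report attached
  inst3 <- inst
  inst3$distances["kelly", "hospital_2"] <- -1
  err <- tryCatch(build_model(inst3), condition = function(e) e)
  expect_s3_class(err, "telerota_invalid_instance")
  expect_s3_class(err$report, "validation_report")
})

test_that("the case-study optimum is 31 assignments and its travel optimum 0", {
  inst <- cwtch_instance()
  res <- solve_rota(inst, "min_staffing")
  expect_equal(res$status, "optimal")
  expect_equal(res$objective_value, 31)
  expect_true(verify_rota(res$rota, inst)$feasible)
  # with full availability every hospital-day can be covered at zero miles
  res2 <- solve_rota(inst, "min_miles")
  expect_equal(res2$objective_value, 0)
  resl <- solve_rota(inst, "lexicographic")
  expect_equal(resl$objective_value, 31)
  expect_equal(resl$secondary_value, 0)
})

test_that("zero demand solves to an empty rota at objective 0", {
  inst <- cwtch_instance()
  inst$demand[] <- 0L
  for (mode in c("min_staffing", "min_miles", "lexicographic")) {
    res <- solve_rota(inst, mode)
    expect_equal(res$status, "optimal")
    expect_equal(res$objective_value, 0)
    expect_equal(nrow(res$rota$assignments), 0)
  }
})

test_that("branch-and-bound and exhaustive enumeration agree on toys", {
  for (seed in 1:25) {
    inst <- random_toy_instance(seed)
    for (mode in c("min_staffing", "min_miles", "lexicographic")) {
      a <- solve_rota(inst, mode)
      b <- brute_force_solve(inst, mode)
      expect_equal(a$status, b$status)
      if (a$status == "optimal") {
        expect_equal(a$objective_value, b$objective_value)
        if (mode == "lexicographic")
          expect_equal(a$secondary_value, b$secondary_value)
        expect_true(verify_rota(a$rota, inst)$feasible)
      }
    }
  }
})

test_that("a hand-checkable 2x2x2 toy matches the enumeration oracle", {
  ids <- c("near", "far")
  locs <- c("hospital_1", "hospital_2")
  staff <- staff_table(ids, contract = "full_time", capacity = 1,
                       home_base = c("hospital_1", "hospital_2"))
  lt <- location_table(locs)
  h <- planning_horizon("2023-01-02", 2)
  dm <- matrix(c(0, 12, 40, 0), 2, 2, dimnames = list(ids, locs))
  dd <- matrix(1L, 2, 2, dimnames = list(locs, format(h)))
  inst <- schedule_instance(staff, lt, h, dd, dm)
  a <- solve_rota(inst, "lexicographic")
  b <- brute_force_solve(inst, "lexicographic")
  expect_equal(a$objective_value, 4)  # unit demand everywhere, 2x2 days
  expect_equal(a$secondary_value, 0)  # each covers their home base
  expect_equal(b$objective_value, 4)
  expect_equal(b$secondary_value, 0)
})

test_that("infeasible toys are reported identically by both paths", {
  staff <- staff_table("solo", contract = "full_time", capacity = 1,
                       home_base = "hospital_1")
  lt <- location_table("hospital_1")
  h <- planning_horizon("2023-01-02", 1)
  dd <- matrix(3L, 1, 1, dimnames = list("hospital_1", format(h)))
  inst <- schedule_instance(staff, lt, h, dd)
  a <- solve_rota(inst, "min_staffing")
  b <- brute_force_solve(inst, "min_staffing")
  expect_equal(a$status, "infeasible")
  expect_equal(b$status, "infeasible")
  expect_equal(a$shortfall$shortfall, 2L)  # one capacity against demand 3
})

test_that("a forced distant assignment prices at that staff member's miles", {
  ids <- c("home", "away")
  staff <- staff_table(ids, contract = "full_time", capacity = 1,
                       home_base = c("hospital_1", "hospital_1"))
  lt <- location_table(c("hospital_1", "hospital_2"))
  h <- planning_horizon("2023-01-02", 1)
  dm <- matrix(c(0, 0, 25, 35), 2, 2,
               dimnames = list(ids, c("hospital_1", "hospital_2")))
  dd <- matrix(c(0L, 1L), 2, 1,
               dimnames = list(c("hospital_1", "hospital_2"), format(h)))
  av <- matrix(c("off_contract", "available"), 2, 1,
               dimnames = list(ids, format(h)))
  inst <- schedule_instance(staff, lt, h, dd, dm, av)
  res <- solve_rota(inst, "min_miles")
  expect_equal(res$objective_value, 35)
  expect_equal(brute_force_solve(inst, "min_miles")$objective_value, 35)
})

test_that("verify_rota recomputes the published totals and catches violations", {
  inst <- cwtch_instance()
  pub <- cwtch_rota()
  audit <- verify_rota(pub, inst)
  expect_true(audit$feasible)
  expect_equal(audit$total_assignments, 31)
  expect_equal(audit$total_miles, 416)
  # duplicate staff-day (two locations at once) is a violation
  dup <- pub
  dup$assignments <- rbind(dup$assignments,
                           data.frame(staff = "laura",
                                      date = as.Date("2019-10-17"),
                                      location = "hospital_1"))
  bad <- verify_rota(dup, inst)
  expect_false(bad$feasible)
  expect_true("multiple_locations" %in% bad$violations$check)
  # assignment on an unavailable day
  inst2 <- inst
  inst2$availability["kelly", 1] <- "on_leave"
  expect_true("unavailable" %in% verify_rota(pub, inst2)$violations$check)
})

test_that("with unit capacity and full availability the optimum is total demand", {
  for (seed in c(101, 202, 303)) {
    inst <- desk_instance(seed)
    inst$availability <- full_availability(inst$staff, inst$horizon)
    res <- solve_rota(inst, "min_staffing")
    if (res$status == "optimal")
      expect_equal(res$objective_value, sum(inst$demand))
  }
})

test_that("raising one demand cell never lowers the staffing optimum", {
  for (seed in 1:10) {
    inst <- random_toy_instance(seed)
    base <- solve_rota(inst, "min_staffing")
    if (base$status != "optimal") next
    set.seed(seed)
    l <- sample(nrow(inst$demand), 1); t <- sample(ncol(inst$demand), 1)
    inst$demand[l, t] <- inst$demand[l, t] + 1L
    bumped <- solve_rota(inst, "min_staffing")
    if (bumped$status == "optimal")
      expect_gte(bumped$objective_value, base$objective_value)
  }
})

test_that("lexicographic stage 2 keeps stage 1's optimum and dominates its miles", {
  for (seed in c(11, 22, 33, 44)) {
    inst <- desk_instance(seed)
    s1 <- solve_rota(inst, "min_staffing")
    lex <- solve_rota(inst, "lexicographic")
    if (s1$status != "optimal") {
      expect_equal(lex$status, s1$status)
      next
    }
    expect_equal(lex$objective_value, s1$objective_value)
    expect_lte(lex$secondary_value, s1$secondary_value)
  }
})

test_that("the tie-break seed changes rotas, never objective values", {
  inst <- cwtch_instance()
  r1 <- solve_rota(inst, "lexicographic", tie_break_seed = 1)
  r2 <- solve_rota(inst, "lexicographic", tie_break_seed = 2)
  expect_equal(r1$objective_value, r2$objective_value)
  expect_equal(r1$secondary_value, r2$secondary_value)
  r1b <- solve_rota(inst, "lexicographic", tie_break_seed = 1)
  expect_identical(r1$rota$assignments, r1b$rota$assignments)
})

test_that("oversized instances are refused by the enumeration oracle", {
  inst <- cwtch_instance()  # 224 variables
  expect_error(brute_force_solve(inst), "too large")
})

test_that("single-day travel optima agree with a Hungarian-assignment solution", {
  # with unit capacities, a one-day travel minimization is a linear sum
  # assignment of demand units to distinct staff; clue's LSAP solver is
  # an independent route to the same optimum
  for (seed in c(5, 17, 29)) {
    set.seed(seed)
    n_staff <- 6
    ids <- paste0("s", 1:n_staff)
    locs <- c("hospital_1", "hospital_2", "hospital_3")
    staff <- staff_table(ids, contract = "full_time", capacity = 1,
                         home_base = sample(locs, n_staff, replace = TRUE))
    lt <- location_table(locs)
    h <- planning_horizon("2023-01-02", 1)
    dm <- matrix(sample(5:40, n_staff * 3, replace = TRUE), n_staff, 3,
                 dimnames = list(ids, locs))
    dm[cbind(ids, staff$home_base)] <- 0
    d <- c(2L, 1L, 2L)
    dd <- matrix(d, 3, 1, dimnames = list(locs, format(h)))
    inst <- schedule_instance(staff, lt, h, dd, dm)
    res <- solve_rota(inst, "min_miles")
    # LSAP: columns = demand units (location repeated d_l times) padded
    # with zero-cost dummy columns up to n_staff
    jobs <- rep(seq_along(locs), d)
    cost <- cbind(dm[, jobs, drop = FALSE],
                  matrix(0, n_staff, n_staff - length(jobs)))
    lsap <- clue::solve_LSAP(cost)
    lsap_cost <- sum(cost[cbind(seq_len(n_staff), lsap)])
    expect_equal(res$objective_value, lsap_cost)
  }
})
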