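# transition matrices, cohort propagation, and discounted accrual

test_that("arm matrices have the published rows and structural invariants", {
  p <- default_params()
  v <- base_values(p)
  icd <- build_transition_matrix("ICD", v)
  expect_identical(icd$states,
                   c("WELL", "HOSPITALIZATION", "COMPLICATION", "REJECTION", "DEATH"))
  expect_equal(unname(icd$probs["HOSPITALIZATION", c("WELL", "DEATH")]),
               c(0.822, 0.178))
  expect_equal(unname(icd$probs["COMPLICATION", c("WELL", "REJECTION", "DEATH")]),
               c(0.768, 0.022, 0.210))
  expect_equal(unname(icd$probs["REJECTION", c("WELL", "DEATH")]),
               c(0.822, 0.178))
  expect_equal(unname(rowSums(icd$probs)), rep(1, 5), tolerance = 1e-12)
  expect_equal(unname(icd$probs["DEATH", ]), c(0, 0, 0, 0, 1))

  ph <- build_transition_matrix("PHARM", v)
  expect_identical(ph$states, c("WELL", "HOSPITALIZATION", "DEATH"))
  expect_equal(unname(ph$probs["HOSPITALIZATION", ]), c(0.716, 0, 0.284))
  expect_equal(unname(rowSums(ph$probs)), rep(1, 3), tolerance = 1e-12)

  # illustrative free values reproduce the documented WELL row
  v2 <- v
  v2[c("tp_well_compl_icd", "tp_well_hosp_icd", "tp_well_death_icd")] <-
    c(0.05, 0.05, 0.01)
  m2 <- build_transition_matrix("ICD", v2)
  expect_equal(unname(m2$probs["WELL", ]), c(0.89, 0.05, 0.05, 0, 0.01))

  # free params all zero: WELL absorbing alongside DEATH, still stochastic
  v3 <- v
  v3[c("tp_well_compl_icd", "tp_well_hosp_icd", "tp_well_death_icd")] <- 0
  m3 <- build_transition_matrix("ICD", v3)
  expect_equal(m3$probs["WELL", "WELL"], 1)
  expect_equal(unname(rowSums(m3$probs)), rep(1, 5))

  # infeasible free params error
  v4 <- v
  v4["tp_well_compl_icd"] <- 0.9
  v4["tp_well_hosp_icd"] <- 0.3
  expect_error(build_transition_matrix("ICD", v4), "exceed 1")
})

test_that("run_cohort: closed-form occupancy, conservation, stopping rules", {
  # identity chain: occupancy constant, stops at max_cycles
  P <- diag(2); dimnames(P) <- list(c("A", "DEATH"), c("A", "DEATH"))
  tm <- transition_matrix(P)
  tr <- run_cohort(tm, c(A = 0.7, DEATH = 0.3), max_cycles = 17)
  expect_equal(tr$n_cycles, 17)
  expect_true(all(abs(tr$occupancy[, "A"] - 0.7) < 1e-12))

  # survival chain: alive fraction is p^t exactly
  toy <- make_toy_two_state(0.9)
  tr2 <- run_cohort(toy$tm, "ALIVE", max_cycles = 50)
  expect_equal(unname(tr2$occupancy[, "ALIVE"]), 0.9^(0:tr2$n_cycles),
               tolerance = 1e-12)
  # newly dead each cycle is p^(t-1) * (1-p)
  expect_equal(tr2$entered_death[-1],
               0.9^(0:(tr2$n_cycles - 1)) * 0.1, tolerance = 1e-12)

  # absorption stopping: death occupancy reaches 1 - tol
  tr3 <- run_cohort(toy$tm, "ALIVE", max_cycles = 10000, absorb_tol = 1e-4)
  expect_gte(tr3$occupancy[tr3$n_cycles + 1, "DEATH"], 1 - 1e-4)
  expect_lt(tr3$n_cycles, 10000)

  expect_error(run_cohort(tm, c(A = 0.6, DEATH = 0.6)), "sum to 1")
  expect_error(
    transition_matrix(matrix(c(0.5, 0.2, 0, 1), 2, 2, byrow = TRUE,
                             dimnames = list(c("A", "B"), c("A", "B")))),
    "stochastic")
})

test_that("accrued QALYs match the geometric-series oracle", {
  # independent oracle: term-by-term summation of the discounted series
  toy <- make_toy_two_state(0.9, utility = 1, r_outcome = 0)
  r0 <- run_toy(toy)
  expect_equal(r0$discounted_qaly, 10, tolerance = 1e-6)
  expect_equal(r0$discounted_qaly, geom_sum(0.9, 0), tolerance = 1e-6)

  toy3 <- make_toy_two_state(0.9, utility = 1, r_outcome = 0.03)
  r3 <- run_toy(toy3)
  expect_equal(r3$discounted_qaly, 1 / (1 - 0.9 / 1.03), tolerance = 1e-6)
  expect_equal(r3$discounted_qaly, 7.923077, tolerance = 1e-6)

  # zero utilities give zero QALYs regardless of the trace
  z <- make_toy_two_state(0.9, utility = 0, cost = 100, r_cost = 0.06)
  expect_equal(run_toy(z)$discounted_qaly, 0)
  expect_equal(run_toy(z)$discounted_cost,
               100 / (1 - 0.9 / 1.06), tolerance = 1e-6 * 1000)
})

test_that("one-time death cost accrues on entry, discounted at the entry cycle", {
  toy <- make_toy_two_state(0.9)
  tr <- run_cohort(toy$tm, "ALIVE", max_cycles = 10000, absorb_tol = 1e-12)
  res <- accrue_outcomes(tr, c(ALIVE = 0), c(ALIVE = 0), death_cost = 1000,
                         dr_cost = 0.06)
  # oracle: sum over entry cycles t>=1 of 0.9^(t-1)*0.1*1000/1.06^t
  oracle <- sum(0.9^(0:5000) * 0.1 * 1000 / 1.06^(1:5001))
  expect_equal(res$discounted_cost, oracle, tolerance = 1e-9)
})

test_that("half-cycle correction halves first and last cycle state rewards", {
  toy <- make_toy_two_state(0.5)
  tr <- run_cohort(toy$tm, "ALIVE", max_cycles = 3)
  full <- accrue_outcomes(tr, c(ALIVE = 0), c(ALIVE = 1), dr_outcome = 0)
  half <- accrue_outcomes(tr, c(ALIVE = 0), c(ALIVE = 1), dr_outcome = 0,
                          half_cycle = TRUE)
  occ <- tr$occupancy[, "ALIVE"]
  expect_equal(full$discounted_qaly, sum(occ))
  expect_equal(half$discounted_qaly,
               unname(sum(occ) - 0.5 * occ[1] - 0.5 * occ[length(occ)]))
})

test_that("conservation, death monotonicity and discount monotonicity hold across random models", {
  for (seed in 1:20) {
    p <- random_valid_parameter_set(seed)
    for (arm in c("ICD", "PHARM")) {
      res <- run_arm(p, arm)
      occ <- res$trace$occupancy
      expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
      expect_true(all(diff(occ[, "DEATH"]) >= -1e-12))
      expect_gte(res$discounted_cost, 0)
      expect_true(res$discounted_qaly >= 0 &&
                    res$discounted_qaly <= res$trace$n_cycles + 1)
    }
  }
  # increasing a discount rate strictly decreases its positive total
  p <- default_params()
  lo <- run_arm(p, "ICD", dr_cost = 0.03, dr_outcome = 0.03)
  hi <- run_arm(p, "ICD", dr_cost = 0.09, dr_outcome = 0.09)
  expect_lt(hi$discounted_cost, lo$discounted_cost)
  expect_lt(hi$discounted_qaly, lo$discounted_qaly)
})

test_that("missing state rewards are contract errors", {
  toy <- make_toy_two_state(0.5)
  tr <- run_cohort(toy$tm, "ALIVE", max_cycles = 3)
  expect_error(accrue_outcomes(tr, c(WRONG = 1), c(ALIVE = 1)), "missing cost")
  expect_error(accrue_outcomes(tr, c(ALIVE = 1), c(WRONG = 1)), "missing utility")
})

test_that("trace export has the documented columns", {
  res <- run_arm(default_params(), "PHARM")
  tt <- trace_table(res)
  expect_true(all(c("cycle", "WELL", "HOSPITALIZATION", "DEATH", "entered_death",
                    "discounted_cost_increment", "discounted_qaly_increment")
                  %in% names(tt)))
  expect_equal(nrow(tt), res$trace$n_cycles + 1)
})
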