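test_that("discount factor follows the (1+r)^-t convention", {
  expect_identical(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03, tolerance = 1e-12)
  expect_equal(discount_factor(1, 0.03), 0.970874, tolerance = 1e-6)
  expect_identical(sum(discount_factor(0:39, 0)), 40)
  expect_error(discount_factor(-1, 0.03), "cycle_index")
  expect_error(discount_factor(1, -0.01), "rate")
})

test_that("transition_row_for selects rows, mixes OI, and sums to 1", {
  P <- base_P
  r <- transition_row_for(list(stage = "HIV", suppression = "suppressed"),
                          40, P)
  expect_equal(unname(r), c(0.946, 0.05, 0.004))
  r2 <- transition_row_for(list(stage = "AIDS", suppression = "suppressed"),
                           70, P)
  # 13% OI mixing of the two AIDS rows in the 65+ band
  expect_equal(r2[["death"]], 0.87 * 0.16 + 0.13 * 0.32, tolerance = 1e-12)
  for (st in list(list(stage = "HIV", suppression = "failed"),
                  list(stage = "AIDS", suppression = "failed"))) {
    r3 <- transition_row_for(st, 200, P)   # clamps to the 65+ band
    expect_equal(sum(r3), 1, tolerance = 1e-9)
  }
  Pm <- P
  Pm$transition_table <- Pm$transition_table[-1, ]
  expect_error(
    transition_row_for(list(stage = "HIV", suppression = "suppressed"),
                       36, Pm),
    "hiv_suppressed")
})

test_that("probability is conserved and death occupancy is monotone", {
  for (arm in c("TEST", "NO_TEST")) {
    out <- run_cohort(arm, base_P)
    st <- out$trace$states
    sums <- tapply(st$occupancy, st$cycle, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    dead <- st$occupancy[st$stage == "DEATH"]
    expect_true(all(diff(dead) >= -1e-12))
  }
})

test_that("degenerate worlds give closed-form totals", {
  # one fully alive undiscounted cycle with utility 1 everywhere
  P <- apply_overrides(base_P, list(discount_rate = 0, util_hiv = 1,
                                    util_aids_no_oi = 1, util_aids_oi = 1))
  P$transition_table$p_death <- 0
  P$transition_table$p_remain <-
    1 - P$transition_table$p_transition
  out <- run_cohort("NO_TEST", P, horizon = 1)
  expect_equal(out$total_discounted_qaly, 1, tolerance = 1e-12)

  # everyone dies after the first cycle
  P2 <- base_P
  P2$transition_table$p_death <- 1
  P2$transition_table$p_remain <- 0
  P2$transition_table$p_transition <- 0
  out2 <- run_cohort("NO_TEST", P2)
  first <- out2$trace$increments[1, ]
  expect_equal(out2$total_discounted_qaly, first$disc_qaly_inc,
               tolerance = 1e-12)
  expect_equal(out2$total_discounted_cost, first$disc_cost_inc,
               tolerance = 1e-12)
})

test_that("zero discounting makes totals equal undiscounted sums", {
  P <- apply_overrides(base_P, list(discount_rate = 0))
  out <- run_cohort("TEST", P)
  inc <- out$trace$increments
  expect_equal(out$total_discounted_cost, sum(inc$cost_inc),
               tolerance = 1e-9)
  expect_equal(out$total_discounted_qaly, sum(inc$qaly_inc),
               tolerance = 1e-9)
  expect_equal(out$total_discounted_cost, out$total_cost, tolerance = 1e-9)
})

test_that("two-cycle trace matches explicit matrix arithmetic", {
  # Reduced space: single class (none), no adverse events, no OI, NO_TEST.
  P <- reduced_params()
  out <- run_cohort("NO_TEST", P, horizon = 2, start_age = 36)

  e1 <- P$eff_dtg_none
  e2 <- with(P, adr_nrti * eff_pi_nrti + adr_pi * eff_pi_pi +
               adr_insti * eff_pi_insti +
               (1 - adr_nrti - adr_pi - adr_insti) * eff_pi_none)
  pH <- P$p_hiv_at_dx; pA <- P$p_aids_at_dx
  # cycle-0 occupancy after the suppression split
  occ0 <- c(HIV.S1 = pH * e1, HIV.F1 = pH * (1 - e1),
            AIDS.S1 = pA * e1, AIDS.F1 = pA * (1 - e1))
  # 35-44 band rows; OI off, so both AIDS contexts use the no-OI row
  Rs <- c(0.946, 0.05, 0.004); Rf <- c(0.944, 0.05, 0.006)
  A <- c(0.86, 0.07, 0.07)
  pre1 <- c(
    HIV.S1 = occ0[["HIV.S1"]] * Rs[1] + occ0[["AIDS.S1"]] * A[2],
    HIV.F1 = occ0[["HIV.F1"]] * Rf[1] + occ0[["AIDS.F1"]] * A[2],
    AIDS.S1 = occ0[["HIV.S1"]] * Rs[2] + occ0[["AIDS.S1"]] * A[1],
    AIDS.F1 = occ0[["HIV.F1"]] * Rf[2] + occ0[["AIDS.F1"]] * A[1])
  dead1 <- occ0[["HIV.S1"]] * Rs[3] + occ0[["HIV.F1"]] * Rf[3] +
    occ0[["AIDS.S1"]] * A[3] + occ0[["AIDS.F1"]] * A[3]
  # failure-triggered switch at the start of cycle 1
  occ1 <- c(HIV.S1 = pre1[["HIV.S1"]], HIV.S2 = e2 * pre1[["HIV.F1"]],
            HIV.F2 = (1 - e2) * pre1[["HIV.F1"]],
            AIDS.S1 = pre1[["AIDS.S1"]], AIDS.S2 = e2 * pre1[["AIDS.F1"]],
            AIDS.F2 = (1 - e2) * pre1[["AIDS.F1"]])

  st <- out$trace$states
  grab <- function(cyc, stage, line, supp) {
    sum(st$occupancy[st$cycle == cyc & st$stage == stage &
                       !is.na(st$line) & st$line == line &
                       st$suppression == supp])
  }
  expect_equal(grab(0, "HIV", 1, "suppressed"), occ0[["HIV.S1"]])
  expect_equal(grab(0, "HIV", 1, "failed"), occ0[["HIV.F1"]])
  expect_equal(grab(0, "AIDS", 1, "failed"), occ0[["AIDS.F1"]])
  expect_equal(grab(1, "HIV", 1, "suppressed"), occ1[["HIV.S1"]],
               tolerance = 1e-12)
  expect_equal(grab(1, "HIV", 2, "suppressed"), occ1[["HIV.S2"]],
               tolerance = 1e-12)
  expect_equal(grab(1, "HIV", 2, "failed"), occ1[["HIV.F2"]],
               tolerance = 1e-12)
  expect_equal(grab(1, "AIDS", 2, "suppressed"), occ1[["AIDS.S2"]],
               tolerance = 1e-12)
  expect_equal(st$occupancy[st$cycle == 1 & st$stage == "DEATH"], dead1,
               tolerance = 1e-12)

  # hand-computed reward increments (NO_TEST: no entry test; the cycle-1
  # switch charges the test on the switching mass)
  inc <- out$trace$increments
  c0 <- (occ0[["HIV.S1"]] + occ0[["HIV.F1"]]) * P$cost_dtg_hiv_first +
    (occ0[["AIDS.S1"]] + occ0[["AIDS.F1"]]) * P$cost_dtg_aids_first
  q0 <- (occ0[["HIV.S1"]] + occ0[["HIV.F1"]]) * P$util_hiv +
    (occ0[["AIDS.S1"]] + occ0[["AIDS.F1"]]) * P$util_aids_no_oi
  expect_equal(inc$cost_inc[1], c0, tolerance = 1e-12)
  expect_equal(inc$qaly_inc[1], q0, tolerance = 1e-12)
  c1 <- occ1[["HIV.S1"]] * P$cost_dtg_hiv_subseq +
    (occ1[["HIV.S2"]] + occ1[["HIV.F2"]]) * P$cost_pi_hiv_subseq +
    occ1[["AIDS.S1"]] * P$cost_dtg_aids_subseq +
    (occ1[["AIDS.S2"]] + occ1[["AIDS.F2"]]) * P$cost_pi_aids_subseq +
    (pre1[["HIV.F1"]] + pre1[["AIDS.F1"]]) * P$cost_drt
  expect_equal(inc$cost_inc[2], c1, tolerance = 1e-12)
  expect_equal(inc$disc_cost_inc[2], c1 / 1.03, tolerance = 1e-12)
})

test_that("half-cycle correction shrinks totals and keeps one-time costs", {
  full <- run_cohort("TEST", base_P, trace = FALSE)
  half <- run_cohort("TEST", base_P, half_cycle = TRUE, trace = FALSE)
  expect_lt(half$total_discounted_qaly, full$total_discounted_qaly)
  # the entry test cost must not be halved: the no-resistance-limit cost gap
  # stays exactly one test
  P <- no_resistance_params()
  r <- run_strategies(P, half_cycle = TRUE, trace = FALSE)
  expect_equal(r$TEST$total_discounted_cost - r$NO_TEST$total_discounted_cost,
               P$cost_drt, tolerance = 1e-9)
})

test_that("trace exports as tidy CSV", {
  out <- run_cohort("TEST", base_P, horizon = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  export_trace(out, f)
  df <- read.csv(f)
  expect_true(all(c("cycle", "stage", "occupancy", "cost_inc",
                    "disc_qaly_inc") %in% names(df)))
  expect_identical(sort(unique(df$cycle)), 0:2)
  expect_error(export_trace(run_cohort("TEST", base_P, trace = FALSE), f),
               "trace")
})
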