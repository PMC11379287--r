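test_that("baseline fixture transcribes the published values", {
  P <- base_P
  expect_identical(P$cost_drt, 1181.14)
  expect_identical(P$cost_dtg_hiv_first, 5486.33)
  expect_identical(P$cost_pi_aids_subseq, 10390.10)
  expect_identical(P$cost_pi_hiv_subseq, 5195.05)  # extra printed digit dropped
  expect_identical(c(P$util_hiv, P$util_aids_no_oi, P$util_aids_oi,
                     P$util_death),
                   c(0.76, 0.67, 0.58, 0))
  expect_identical(c(P$tdr_nrti, P$tdr_pi, P$tdr_insti),
                   c(0.03, 0.001, 0.001))  # 0.1% floor for PI/INSTI
  expect_identical(c(P$adr_nrti, P$adr_pi, P$adr_insti), c(0.34, 0.09, 0.01))
  expect_identical(c(P$oi_prob_failure, P$oi_prob_success), c(0.53, 0.13))
  expect_identical(P$eff_dtg_nrti, 0.82)  # table value over the 83% prose
  expect_identical(P$eff_pi_nrti, 0.72)   # table value over the 71% prose
  expect_identical(P$gdp_per_capita, 2746.4)
  expect_identical(P$discount_rate, 0.03)
  expect_identical(P$horizon_years, 40L)

  tt <- P$transition_table
  row <- function(ctx, band) tt[tt$context == ctx & tt$age_band == band, ]
  expect_equal(row("hiv_suppressed", "45-54")$p_death, 0.017)
  expect_equal(row("hiv_suppressed", "35-44")[, 3:5],
               data.frame(p_remain = 0.946, p_transition = 0.05,
                          p_death = 0.004),
               ignore_attr = TRUE)
  expect_equal(row("aids_no_oi", "65+")$p_death, 0.16)
})

test_that("all 16 transition rows are row-stochastic and the fixture validates", {
  tt <- base_P$transition_table
  expect_identical(nrow(tt), 16L)
  sums <- tt$p_remain + tt$p_transition + tt$p_death
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_identical(nrow(validate_parameters(base_P)), 0L)
})

test_that("with-OI death column equals twice the no-OI column as printed", {
  tt <- base_P$transition_table
  d_no <- tt$p_death[tt$context == "aids_no_oi"]
  d_oi <- tt$p_death[tt$context == "aids_oi"]
  expect_identical(d_oi, round(2 * d_no, 2))
  expect_identical(d_oi, c(0.14, 0.16, 0.22, 0.32))
})

test_that("validate_parameters reports violations as data", {
  P <- base_P
  P$transition_table$p_remain[1] <- P$transition_table$p_remain[1] + 0.05
  rep <- validate_parameters(P)
  expect_identical(nrow(rep), 1L)
  expect_match(rep$message, "row sums")

  P2 <- base_P
  P2$cost_drt <- -5
  rep2 <- validate_parameters(P2)  # nonnegativity + stale range bracket
  expect_true(all(rep2$parameter == "cost_drt"))
  expect_true(any(grepl("cost must be", rep2$message)))

  P3 <- base_P
  P3$p_aids_at_dx <- 0.3  # no longer complements p_hiv_at_dx
  expect_true("p_aids_at_dx" %in% validate_parameters(P3)$parameter)
})

test_that("uncertainty ranges bracket their points", {
  un <- base_P$uncertainty
  for (i in seq_len(nrow(un))) {
    pt <- base_P[[un$parameter[i]]]
    expect_true(un$low[i] <= pt && pt <= un$high[i], label = un$parameter[i])
  }
  expect_true(all(un$family[grepl("^cost_", un$parameter)] == "gamma"))
  expect_true(all(un$family[!grepl("^cost_", un$parameter)] == "beta"))
})

test_that("load_parameters inherits the baseline and rejects bad values", {
  expect_equal(load_parameters(NULL), base_P)
  expect_equal(load_parameters(list()), base_P)

  P <- load_parameters(list(discount_rate = 0))
  expect_identical(P$discount_rate, 0)
  P$discount_rate <- base_P$discount_rate
  expect_equal(P, base_P, ignore_attr = TRUE)

  expect_error(load_parameters(list(adverse_event_prob = 1.5)),
               "adverse_event_prob")
  expect_error(load_parameters(list(no_such_knob = 1)), "unknown parameter")
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", f)
  expect_error(load_parameters(f), "parse")
})

test_that("save/load round-trips a modified parameter set", {
  P <- apply_overrides(base_P, list(discount_rate = 0.05, cost_drt = 900,
                                    util_aids_oi = 0.5))
  f <- withr::local_tempfile(fileext = ".json")
  save_parameters(P, f)
  P2 <- load_parameters(f)
  expect_equal(P2, P, ignore_attr = TRUE)
})

test_that("scalar transition overrides propagate into the table", {
  P <- apply_overrides(base_P, list(p_hiv_to_aids_failed = 0.078))
  tt <- P$transition_table
  idx <- tt$context == "hiv_failed"
  expect_true(all(tt$p_transition[idx] == 0.078))
  sums <- tt$p_remain + tt$p_transition + tt$p_death
  expect_true(all(abs(sums - 1) < 1e-12))
  # untouched contexts keep their printed progression
  expect_true(all(tt$p_transition[tt$context == "hiv_suppressed"] == 0.05))

  P2 <- apply_overrides(base_P, list(p_aids_at_dx = 0.25))
  expect_identical(P2$p_hiv_at_dx, 0.75)
  expect_identical(P2$cohort$p_aids_at_dx, 0.25)
})

test_that("text-derived fixture applies the 1.56x failure progression", {
  P <- text_derived_fixture()
  tt <- P$transition_table
  expect_equal(unique(tt$p_transition[tt$context == "hiv_failed"]),
               1.56 * 0.05)
  expect_identical(nrow(validate_parameters(P)), 0L)
})

test_that("age bands clamp below 35 and above 65", {
  expect_identical(age_band(c(27, 36, 44.9, 45, 55, 64.9, 65, 200)),
                   c("35-44", "35-44", "35-44", "45-54", "55-64", "55-64",
                     "65+", "65+"))
})
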