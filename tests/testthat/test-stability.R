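test_that("CS-coefficient definition edge cases behave per definition", {
  x <- structured_cohort(300)
  # n_boot = 1 with a failing smallest proportion: subsample below 3p floor
  rep0 <- case_drop_bootstrap(x, drop_proportions = c(0.95), n_boot = 1,
                              seed = 1, min_rows = 20)
  expect_true(all(rep0$cs$cs == 0))
  expect_gt(rep0$n_skipped, 0)
})

test_that("stability report is reproducible and well-formed", {
  x <- structured_cohort(250)
  a <- case_drop_bootstrap(x, drop_proportions = c(0.1, 0.3), n_boot = 8,
                           seed = 42)
  b <- case_drop_bootstrap(x, drop_proportions = c(0.1, 0.3), n_boot = 8,
                           seed = 42)
  expect_identical(a$table, b$table)
  expect_identical(a$cs, b$cs)
  cors <- a$table$correlation
  expect_true(all(is.na(cors) | (cors >= -1 & cors <= 1)))
  # CS is one of the tested proportions or 0, and respects the run-max rule
  for (idx in a$cs$index) {
    cs <- a$cs$cs[a$cs$index == idx]
    expect_true(cs %in% c(0, 0.1, 0.3))
    if (cs == 0.3) {
      sub <- a$table[a$table$prop == 0.1 & a$table$index == idx, ]
      expect_gte(mean(!is.na(sub$correlation) & sub$correlation >= 0.7), 0.95)
    }
  }
})

test_that("interpretation flags follow the 0.25 / 0.5 rule", {
  expect_equal(symptomnet:::cs_interpretation(c(0, 0.2, 0.25, 0.45, 0.5, 0.75)),
               c("none", "none", "interpretable", "interpretable",
                 "preferred", "preferred"))
})

test_that("stronger samples give no worse subsample correlations (monotone in n)", {
  med_cor <- function(n) {
    x <- structured_cohort(n, seed = 31)
    rep <- case_drop_bootstrap(x, drop_proportions = 0.25, n_boot = 12,
                               seed = 7)
    median(rep$table$correlation[rep$table$index == "strength"], na.rm = TRUE)
  }
  ms <- vapply(c(200, 1000, 5000), med_cor, numeric(1))
  expect_true(all(diff(ms) >= -0.05))  # allow tiny Monte Carlo slack
})

test_that("identical columns give a strength-difference CI containing zero", {
  set.seed(11)
  a <- rbinom(400, 1, 0.5)
  b <- rbinom(400, 1, 0.45)
  x <- tibble::tibble(A = a, B = a, C = b,
                      D = rbinom(400, 1, 0.5))
  dt <- difference_bootstrap(x, items = c("A", "B", "C", "D"), n_boot = 40,
                             seed = 3, what = "strength")
  ab <- dt$differences[dt$differences$a == "A" & dt$differences$b == "B", ]
  # the two strengths are equal up to float noise from the near-singular
  # (duplicate-item) correlation matrix, so the CI straddles zero at the
  # numerical-noise scale
  expect_lte(ab$lower, 1e-4)
  expect_gte(ab$upper, -1e-4)
  expect_lt(abs(ab$estimate), 1e-4)
})

test_that("a dominant edge is significantly different from an absent one", {
  planted <- make_planted_network(4, c(2, 2), within = 0.7)
  x <- simulate_cohort(cohort_spec(5000, rep(0.5, 4), planted$correlation),
                       seed = 8)
  dt <- difference_bootstrap(x, n_boot = 60, seed = 5, what = "edges")
  d <- dt$differences
  pair <- d[d$a == "V1--V2" & d$b == "V1--V3", ]
  expect_true(pair$significant)
  expect_gt(pair$lower, 0)
  # determinism
  dt2 <- difference_bootstrap(x, n_boot = 60, seed = 5, what = "edges")
  expect_identical(dt$differences, dt2$differences)
  # CI sanity on all pairs
  expect_true(all(d$lower <= d$upper))
  expect_identical(d$significant, d$lower > 0 | d$upper < 0)
})
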