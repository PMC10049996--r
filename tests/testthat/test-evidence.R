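test_that("beta_from_or reproduces the published log-OR coefficients", {
  # (OR, published beta) pairs
  cases <- rbind(
    c(1.99, 0.688),   # insulin therapy
    c(0.39, -0.942),  # bariatric surgery
    c(1.45, 0.372),   # HbA1c
    c(0.70, -0.357),  # myopia
    c(0.37, -0.994),  # lipid-lowering < 3y
    c(0.80, -0.223),  # lipid-lowering > 3y
    c(1.19, 0.174),   # diabetes course
    c(1.25, 0.223),   # fasting plasma glucose
    c(0.67, -0.400),  # intensive glycemic control
    c(1.50, 0.405),   # hypertension
    c(1.73, 0.548),   # male gender
    c(1.22, 0.199),   # rural residence
    c(1.00, 0.000)    # no effect
  )
  expect_equal(beta_from_or(cases[, 1]), cases[, 2])
})

test_that("beta_from_or rejects non-positive odds ratios, naming the factor", {
  expect_error(beta_from_or(0), "positive")
  expect_error(beta_from_or(c(1.2, -3), factor_id = c("ok", "bad")), "bad")
})

test_that("beta_from_or is increasing and antisymmetric under reciprocals", {
  ors <- sort(exp(runif(50, log(0.1), log(10))))
  betas <- beta_from_or(ors)
  expect_true(all(diff(betas) >= 0))
  expect_equal(beta_from_or(1 / ors), -betas)
  # round trip within 3-decimal rounding error
  expect_true(all(abs(exp(betas) - ors) <= ors * (exp(5e-4) - 1) + 1e-12))
})

test_that("alpha_from_prevalence is the log-odds of the prevalence", {
  expect_equal(alpha_from_prevalence(0.5), 0)
  expect_equal(alpha_from_prevalence(0.278), log(0.278 / 0.722))
  expect_equal(round(alpha_from_prevalence(0.278), 4), -0.9544)
  expect_equal(alpha_from_prevalence(0.1), log(1 / 9))
  # strictly increasing, antisymmetric about 0.5
  p <- seq(0.01, 0.99, by = 0.01)
  a <- alpha_from_prevalence(p)
  expect_true(all(diff(a) > 0))
  expect_equal(a, -rev(a))
  expect_error(alpha_from_prevalence(0), "strictly inside")
  expect_error(alpha_from_prevalence(1), "strictly inside")
})

test_that("shipped evidence table is valid and flags only the smoking CI", {
  ev <- dr_evidence_table()
  expect_equal(nrow(ev), 13L)
  expect_setequal(
    unique(ev$factor_id),
    c("male", "bariatric", "myopia", "lipid_lowering", "fpg", "duration",
      "hba1c", "intensive_control", "hypertension", "insulin", "rural",
      "smoking")
  )
  expect_equal(ev$factor_id[ev$ci_inconsistent], "smoking")
  expect_true(all(ev$pooled_or > 0 & ev$ci_low > 0 & ev$ci_high >= ev$ci_low))
})

test_that("evidence validation rejects malformed tables", {
  ev <- dr_evidence_table()
  expect_error(validate_evidence(ev[0, ]), "empty")
  expect_error(validate_evidence(ev[, -4]), "missing columns")
  bad <- ev; bad$pooled_or[1] <- -1
  expect_error(validate_evidence(bad), "non-positive")
  dup <- rbind(ev, ev[1, ])
  expect_error(validate_evidence(dup), "duplicate")
  swapped <- ev; swapped$ci_high[2] <- swapped$ci_low[2] / 2
  expect_error(validate_evidence(swapped), "ci_high < ci_low")
})

test_that("derived mode computes ln(OR) betas and matches printed values except smoking", {
  cs <- build_coefficient_set(mode = "derived", prevalence = 0.278)
  b <- setNames(cs$betas$beta, paste(cs$betas$factor_id, cs$betas$level))
  expected <- c(
    "male present" = 0.548, "bariatric present" = -0.942,
    "myopia present" = -0.357, "lipid_lowering lt3y" = -0.994,
    "lipid_lowering gt3y" = -0.223, "fpg present" = 0.223,
    "duration present" = 0.174, "hba1c present" = 0.372,
    "intensive_control present" = -0.400, "hypertension present" = 0.405,
    "insulin present" = 0.688, "rural present" = 0.199
  )
  expect_equal(b[names(expected)], expected)
  expect_equal(unname(b["smoking present"]), round(log(0.68), 3))
  expect_equal(cs$alpha, log(0.278 / 0.722))
  # baseline levels carry zero coefficients, one per factor
  zero <- cs$betas[cs$betas$beta == 0, ]
  expect_setequal(zero$level[zero$factor_id != "lipid_lowering"], "absent")
  expect_equal(zero$level[zero$factor_id == "lipid_lowering"], "none")
  expect_equal(nrow(zero), 12L)
})

test_that("printed mode ships the canonical set and reconciliation flags exactly smoking and alpha", {
  cs <- build_coefficient_set(mode = "printed", prevalence = 0.278)
  expect_equal(cs$alpha, -0.949)
  expect_equal(cs$betas$beta[cs$betas$factor_id == "smoking" &
                               cs$betas$level == "present"], -0.083)
  expect_equal(cs$betas$beta[cs$betas$factor_id == "myopia" &
                               cs$betas$level == "present"], -0.357)
  flagged <- cs$reconciliation$term[cs$reconciliation$flagged]
  expect_setequal(flagged, c("smoking:present", "alpha"))
  # every other printed beta agrees with ln(OR) to 0.001
  ok <- cs$reconciliation[!cs$reconciliation$flagged, ]
  expect_true(all(abs(ok$printed - ok$derived) <= 0.001))
})

test_that("evidence and coefficient sets round-trip through CSV and JSON", {
  ev <- dr_evidence_table()
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_evidence(ev, csv)
  write_evidence(ev, js)
  expect_equal(read_evidence(csv)[names(ev)], ev)
  ev2 <- read_evidence(js)
  expect_equal(ev2[names(ev)], ev, ignore_attr = TRUE)

  cs <- build_coefficient_set()
  cj <- tempfile(fileext = ".json")
  write_coefficient_set(cs, cj)
  cs2 <- read_coefficient_set(cj)
  expect_equal(cs2$alpha, cs$alpha)
  expect_equal(cs2$prevalence, cs$prevalence)
  m <- merge(cs$betas, cs2$betas, by = c("factor_id", "level"))
  expect_equal(m$beta.x, m$beta.y)
})
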