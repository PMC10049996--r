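cs_printed <- build_coefficient_set()

test_that("the worked-example patient scores logit 1.177, P 0.764, LP 2.75", {
  r <- score_patient(example_patient(), cs_printed, rule = "lp_cutoff",
                     lp_cutoff = 2.24)
  expect_equal(r$logit, 1.177)
  expect_equal(r$probability, exp(1.177) / (1 + exp(1.177)))
  expect_equal(round(r$probability, 4), 0.7644)
  expect_equal(round(r$lp, 2), 2.75)
  expect_equal(r$risk_class, "high")
  # contribution bookkeeping: terms sum to the logit
  expect_equal(cs_printed$alpha + sum(r$contributions), r$logit)
  expect_equal(unname(r$contributions["bariatric"]), 0)
  expect_equal(unname(r$contributions["smoking"]), -0.083)
})

test_that("an all-baseline profile scores exactly the intercept", {
  factors <- unique(cs_printed$betas$factor_id)
  base <- setNames(ifelse(factors == "lipid_lowering", "none", "absent"),
                   factors)
  lg <- compute_logit(base, cs_printed)
  expect_equal(as.numeric(lg), cs_printed$alpha)
  expect_true(all(attr(lg, "contributions") == 0))
  expect_equal(probability_from_logit(lg),
               cs_printed$prevalence, tolerance = 0.01)
})

test_that("compute_logit matches a brute-force table-walk oracle on random profiles", {
  set.seed(11)
  for (mode in c("printed", "derived")) {
    cs <- build_coefficient_set(mode = mode)
    for (i in 1:25) {
      prof <- random_profile(cs)
      expect_equal(as.numeric(compute_logit(prof, cs)),
                   oracle_logit(prof, cs))
    }
  }
})

test_that("profile validation reports missing factors and unknown levels", {
  prof <- unclass(example_patient())
  expect_error(compute_logit(prof[-1], cs_printed), "missing factor")
  bad <- prof; bad["myopia"] <- "sometimes"
  expect_error(compute_logit(bad, cs_printed), "myopia='sometimes'")
  extra <- c(prof, coffee = "present")
  expect_error(compute_logit(extra, cs_printed), "unknown factor")
})

test_that("inverse logit is stable and relative risk is probability over prevalence", {
  expect_equal(probability_from_logit(0), 0.5)
  expect_equal(probability_from_logit(1.177), 0.7644080, tolerance = 1e-6)
  expect_equal(probability_from_logit(-1e6), 0)
  expect_equal(probability_from_logit(1e6), 1)
  expect_equal(relative_risk(0.5, 0.278), 0.5 / 0.278)
  expect_equal(relative_risk(0.278, 0.278), 1)
  expect_error(relative_risk(0.5, 0), "prevalence")
})

test_that("single-factor flips move logit, probability and LP in the beta's direction", {
  set.seed(21)
  nb <- cs_printed$betas[cs_printed$betas$beta != 0, ]
  for (i in seq_len(nrow(nb))) {
    prof <- random_profile(cs_printed)
    f <- nb$factor_id[i]
    lo <- prof; lo[f] <- baseline <- ifelse(f == "lipid_lowering", "none", "absent")
    hi <- prof; hi[f] <- nb$level[i]
    r_lo <- score_patient(lo, cs_printed)
    r_hi <- score_patient(hi, cs_printed)
    s <- sign(nb$beta[i])
    expect_equal(sign(r_hi$logit - r_lo$logit), s)
    expect_equal(sign(r_hi$probability - r_lo$probability), s)
    expect_equal(sign(r_hi$lp - r_lo$lp), s)
  }
})

test_that("logit, probability and LP rank patients identically", {
  set.seed(31)
  profs <- as.data.frame(t(replicate(40, random_profile(cs_printed))))
  scored <- score_patients(profs, cs_printed)
  expect_equal(order(scored$logit), order(scored$probability))
  expect_equal(order(scored$logit), order(scored$lp))
  # LP = P / p identity
  expect_equal(scored$lp, scored$probability / cs_printed$prevalence)
})

test_that("classification rules honor their boundary conventions", {
  mk <- function(p, lp) list(probability = p, lp = lp)
  expect_equal(classify(mk(0.5, 1), "p_half"), "high")
  expect_equal(classify(mk(0.4999, 1), "p_half"), "low")
  expect_equal(classify(mk(0.9, 2.24), "lp_cutoff", 2.24), "low")
  expect_equal(classify(mk(0.9, 2.2401), "lp_cutoff", 2.24), "high")
  expect_equal(classify(mk(0.9, 1.0), "lp_cutoff", 2.24), "low")
  expect_error(classify(mk(0.9, 1), "banana"), "arg")
  expect_error(classify(mk(0.9, 1), "lp_cutoff", -1), "positive")

  # p_half agrees with the sign of the logit everywhere
  set.seed(41)
  for (i in 1:30) {
    r <- score_patient(random_profile(cs_printed), cs_printed, rule = "p_half")
    expect_equal(r$risk_class == "high", r$logit >= 0)
  }
})

test_that("continuous glycemic columns are binarized at the configured thresholds", {
  expect_equal(binarize_fpg(c(6.0, 6.1, 6.2)), c("absent", "absent", "present"))
  expect_equal(binarize_hba1c(c(6.4, 6.5, 7.0)), c("absent", "present", "present"))
  ex <- as.list(unclass(example_patient()))
  df <- as.data.frame(ex[setdiff(names(ex), c("fpg", "hba1c"))])
  df$fpg_mmol_l <- 6.5
  df$hba1c_pct <- 7
  df$height_cm <- 170  # passthrough, no coefficient
  scored <- score_patients(df, cs_printed)
  expect_equal(scored$logit, 1.177)
})
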