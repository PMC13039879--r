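small_table <- function(seed = 21, n_per_group = c(ASD = 3, CON = 3, MHC = 3)) {
  simulate_cohort_features(generator_params(), n_per_group, seed = seed,
                           blocks = c(1, 3))
}

test_that("standardize centres and scales with the sample SD", {
  z <- standardize(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1))
  set.seed(31)
  x <- rnorm(100, 5, 3); x[c(4, 9)] <- NA
  z <- standardize(x)
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-12)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_true(all(is.na(z[c(4, 9)])))
  expect_equal(standardize(z), z, tolerance = 1e-12) # idempotent
  expect_error(standardize(rep(2, 10)), "zero-variance")
  expect_error(standardize(c(1, NA)), "2 non-missing")
})

test_that("aggregation produces per-condition cell means", {
  tab <- data.frame(
    subject_id = "a", group = "CON", age = 15, gender = "m",
    stimulus = rep(c("oddball", "standard"), each = 4),
    manipulation = rep(c("before", "after"), 4),
    block_direction = "forward",
    bps = c(1, 2, 3, 4, 5, 6, 7, 8), sepr = 1
  )
  agg <- aggregate_by_condition(tab)
  expect_lte(nrow(agg), 8) # at most 2 x 2 x 2 cells per subject
  cell <- agg[agg$stimulus == "oddball" & agg$manipulation == "before", ]
  expect_equal(cell$bps, mean(c(1, 3)))
  expect_true(all(agg$sepr == 1)) # constants aggregate to themselves
})

test_that("the trial-level LMM recovers structure and reports REML", {
  tab <- small_table()
  res <- fit_lmm(tab, "sepr")
  expect_s3_class(res, "lmm_result")
  expect_equal(res$fit_method, "REML")
  expect_true(all(c("stimulus:group:manipulation", "age", "gender") %in%
                    res$tests$term))
  expect_gte(res$vc[["sigma2_subject"]], 0)
  expect_gt(res$vc[["sigma2_residual"]], 0)
  expect_true(all(res$fixed$ci_lower < res$fixed$ci_upper))
  # outcome standardized across non-missing rows
  frame <- model.frame(res$fit)
  expect_equal(mean(frame$sepr), 0, tolerance = 1e-9)
  expect_equal(sd(frame$sepr), 1, tolerance = 1e-2)
})

test_that("aggregated-level models mirror the trial-level structure", {
  tab <- small_table(seed = 101)
  agg <- aggregate_by_condition(tab)
  expect_lte(nrow(agg), 9 * 8)
  res_agg <- fit_lmm(agg, "sepr")
  res_tr <- fit_lmm(tab, "sepr")
  ca <- marginal_contrast(res_agg, "stimulus", c("oddball", "standard"))
  ct <- marginal_contrast(res_tr, "stimulus", c("oddball", "standard"))
  # same direction of the stimulus effect on both analysis levels
  expect_gt(ca$delta, 0)
  expect_gt(ct$delta, 0)
})

test_that("duplicating every row leaves point estimates unchanged", {
  set.seed(41)
  cfg <- power_config(effect_beta = 0.4, group_sizes = c(ASD = 6, CON = 6, MHC = 6),
                      trials_per_subject = 20, reps = 1)
  tab <- oddpupil:::simulate_power_table(cfg)
  f <- y ~ group * manipulation + (1 | subject_id)
  # standardization is switched off: the sample-SD denominator (n - 1)
  # changes under row duplication, which would rescale the outcome
  r1 <- fit_lmm(tab, "y", formula_spec = f, standardize_outcome = FALSE)
  r2 <- fit_lmm(rbind(tab, tab), "y", formula_spec = f,
                standardize_outcome = FALSE)
  expect_equal(r1$fixed$estimate, r2$fixed$estimate, tolerance = 1e-6)
})

test_that("singular designs fail with the aliased term named", {
  set.seed(42)
  tab <- oddpupil:::simulate_power_table(
    power_config(group_sizes = c(ASD = 4, CON = 4, MHC = 4),
                 trials_per_subject = 10, reps = 1))
  tab$dup <- as.numeric(tab$group == "ASD") # aliased with the group dummy
  expect_error(
    fit_lmm(tab, "y", formula_spec = y ~ group + dup + (1 | subject_id)),
    "aliased.*dup")
})

test_that("unknown factor levels are rejected", {
  tab <- small_table()
  tab$group[1] <- "XXX"
  expect_error(fit_lmm(tab, "sepr"), "unknown level")
})

test_that("Nakagawa R2 follows the variance-component formula", {
  vc <- c(sigma2_fixed = 1, sigma2_subject = 1, sigma2_residual = 2)
  expect_equal(nakagawa_r2(vc), c(mR2 = 0.25, cR2 = 0.5))
  vc0 <- c(sigma2_fixed = 0.3, sigma2_subject = 0, sigma2_residual = 0.7)
  r2 <- nakagawa_r2(vc0)
  expect_equal(r2[["mR2"]], r2[["cR2"]]) # no random variance: mR2 = cR2
  vcf <- c(sigma2_fixed = 0, sigma2_subject = 0.5, sigma2_residual = 0.5)
  expect_equal(nakagawa_r2(vcf)[["mR2"]], 0)
})

test_that("R2 bounds hold on every fitted model", {
  tab <- small_table(seed = 51)
  for (oc in c("sepr", "bps", "mmn_amp", "p3a_amp")) {
    r2 <- fit_lmm(tab, oc)$r2
    expect_gte(r2[["mR2"]], 0)
    expect_lte(r2[["mR2"]], r2[["cR2"]])
    expect_lte(r2[["cR2"]], 1)
  }
})

test_that("marginal contrasts reduce to coefficient differences without interactions", {
  set.seed(61)
  cfg <- power_config(effect_beta = 0.5, group_sizes = c(ASD = 8, CON = 8, MHC = 8),
                      trials_per_subject = 30, reps = 1)
  tab <- oddpupil:::simulate_power_table(cfg)
  res <- fit_lmm(tab, "y", formula_spec = y ~ group + manipulation + (1 | subject_id))
  mc <- marginal_contrast(res, "group", c("ASD", "CON"))
  beta <- lme4::fixef(res$fit)
  expect_equal(mc$delta, unname(beta["groupASD"]), tolerance = 1e-9)
  self <- marginal_contrast(res, "group", c("ASD", "ASD"))
  expect_equal(self$delta, 0)
  expect_true(mc$ci95[1] <= mc$delta && mc$delta <= mc$ci95[2])
  expect_error(marginal_contrast(res, "group", c("ASD", "ZZZ")), "ZZZ")
  expect_error(marginal_contrast(res, "group", within = list(bogus = "x")),
               "bogus")
})

test_that("the subject random-intercept variance is recovered", {
  set.seed(71)
  cfg <- power_config(effect_beta = 0, group_sizes = c(ASD = 20, CON = 20, MHC = 20),
                      trials_per_subject = 100, icc = 0.3, reps = 1)
  tab <- oddpupil:::simulate_power_table(cfg)
  res <- fit_lmm(tab, "y", formula_spec = y ~ group * manipulation + (1 | subject_id),
                 standardize_outcome = FALSE)
  expect_equal(res$vc[["sigma2_subject"]], 0.3, tolerance = 0.35)
  expect_equal(res$vc[["sigma2_residual"]], 0.7, tolerance = 0.1)
})

test_that("pupil predictors enter ERP models and degenerate input fails", {
  tab <- small_table(seed = 81)
  res <- pupil_erp_model(tab, "mmn_amp", pupil_predictors = c("bps", "sepr"))
  expect_true(all(c("bps", "sepr") %in% res$fixed$term))
  resg <- pupil_erp_model(tab, "mmn_amp", pupil_predictors = "sepr",
                          group_interactions = TRUE)
  # interaction columns are named with the factor first (e.g. groupASD:sepr)
  expect_true(any(grepl("group[A-Z]+:sepr|sepr:group", resg$fixed$term)))
  tab$bps <- 0
  expect_error(pupil_erp_model(tab, "mmn_amp"), "zero-variance")
})

test_that("a generated SEPR-to-MMN coupling is recovered with the right sign", {
  # positive coupling enlarges the (negative) MMN component on trials with
  # larger pupil dilation, so the fitted SEPR slope on measured MMN
  # amplitude must be negative
  p <- generator_params(coupling_sepr_mmn_uv_per_mm = 20,
                        sepr_trial_sd_mm = 0.05)
  tab <- simulate_cohort_features(p, c(ASD = 4, CON = 4, MHC = 4), seed = 91,
                                  blocks = c(1, 3))
  res <- pupil_erp_model(tab, "mmn_amp", pupil_predictors = "sepr")
  slope <- res$fixed[res$fixed$term == "sepr", ]
  expect_lt(slope$estimate, 0)
  expect_lt(slope$ci_upper, 0)
})
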