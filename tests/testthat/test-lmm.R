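# Mixed-effects design construction, fitting, comparison, slope
# composition.

toy_dataset <- function(n_participants = 6, n_per = 60, slope_sd = 0.01,
                        cop_slope = -0.07, noise = 0.01, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(n_participants), function(i) {
    s_i <- cop_slope + rnorm(1, 0, slope_sd)
    cop <- runif(n_per, 0, 14)
    data.frame(
      participant = sprintf("P%02d", i),
      direction = "forward",
      cop_mag = cop,
      prop_pressure = 1 + s_i * cop + rnorm(n_per, 0, noise)
    )
  })
  do.call(rbind, rows)
}

test_that("design construction centres CoP and prunes single-level
          factors", {
  d <- toy_dataset()
  des <- build_lmm_design(d)
  expect_equal(mean(des$data$cop), 0, tolerance = 1e-12)
  expect_false("direction" %in% des$terms) # single level: dropped
  expect_error(build_lmm_design(d, include_cushion = TRUE), "cushion")

  d$cushion <- rep(c("air", "foam"), length.out = nrow(d))
  des2 <- build_lmm_design(d)
  expect_true("cushion" %in% des2$terms)
  expect_equal(levels(des2$data$cushion)[1], "air") # baseline
  expect_match(des2$fixed_formula, "cop:cushion")

  expect_error(build_lmm_design(d[0, ]), "participants")
})

test_that("baseline prediction at mean CoP equals the intercept", {
  d <- toy_dataset(4, 40)
  des <- build_lmm_design(d)
  fit <- fit_sip_lmm(des, "(1 + CoP)")
  intercept <- fit$fixed$estimate[fit$fixed$effect == "(Intercept)"]
  pred <- predict(fit$fit,
                  newdata = data.frame(participant = "new", cop = 0),
                  allow.new.levels = TRUE)
  expect_equal(unname(pred), intercept, tolerance = 1e-9)
})

test_that("the CoP fixed effect recovers the generating slope", {
  d <- toy_dataset(8, 80, slope_sd = 0.012, seed = 5)
  des <- build_lmm_design(d)
  fit <- fit_sip_lmm(des, "(1 + CoP)")
  cop <- fit$fixed[fit$fixed$effect == "cop", ]
  expect_lt(abs(cop$estimate - (-0.07)) / cop$std_error, 2)
  expect_true(cop$ci_low <= cop$estimate && cop$estimate <= cop$ci_high)
  expect_true(is.finite(fit$aic) && is.finite(fit$bic))
  expect_gt(cop$df, 1)
})

test_that("a zero CoP effect is covered by the CI in most seeded
          replicates", {
  covered <- 0L
  n_rep <- 50
  for (rep_i in seq_len(n_rep)) {
    d <- toy_dataset(5, 30, slope_sd = 0, cop_slope = 0, noise = 0.02,
                     seed = 1000 + rep_i)
    fit <- fit_sip_lmm(build_lmm_design(d), "(1 + CoP)")
    cop <- fit$fixed[fit$fixed$effect == "cop", ]
    if (cop$ci_low <= 0 && 0 <= cop$ci_high) covered <- covered + 1L
  }
  expect_gte(covered, 0.9 * n_rep)
})

test_that("model comparison ranks, reports ties stably, and rejects
          mismatched data", {
  fits <- study_lmm_fits()
  cmp <- compare_lmm_models(fits)
  expect_equal(cmp$label[1], "(1 + CoP + PR + CoP:PR)")
  expect_true(all(diff(cmp$aic) >= 0))
  # ranking invariant under input reordering
  cmp_rev <- compare_lmm_models(rev(fits))
  expect_equal(cmp_rev$label, cmp$label)

  # duplicated result: tie, stable input order
  dup <- compare_lmm_models(list(fits[[1]], fits[[1]]))
  expect_equal(dup$rank_aic, c(1L, 2L))

  expect_error(compare_lmm_models(list(fits[[1]])), "at least 2")

  other <- fit_sip_lmm(build_lmm_design(toy_dataset(4, 20)), "(1)")
  expect_error(compare_lmm_models(list(fits[[1]], other)), "differing")
})

test_that("total slopes compose the CoP estimate with direction
          interactions", {
  tab <- data.frame(
    effect = c("(Intercept)", "cop", "cop:directionleft",
               "cop:directionright"),
    estimate = c(0.59, -0.0685, -0.0307, -0.0297)
  )
  expect_equal(total_slope(tab, "forward"), -0.0685)
  expect_equal(total_slope(tab, "left"), -0.0992)
  expect_equal(total_slope(tab, "right"), -0.0982)
  expect_error(total_slope(tab[1:2, ], "left"), "missing term")
})

test_that("lateral interactions come out negative on a steeper-sideways
          cohort", {
  fits <- study_lmm_fits()
  best <- fits[["(1 + CoP + PR + CoP:PR)"]]
  il <- best$fixed$estimate[best$fixed$effect == "cop:directionleft"]
  ir <- best$fixed$estimate[best$fixed$effect == "cop:directionright"]
  expect_lt(il, 0)
  expect_lt(ir, 0)
})
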