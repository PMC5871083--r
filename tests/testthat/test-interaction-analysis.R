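test_that("lt transform is the natural log with optional offset", {
  expect_equal(lt_transform(1), 0)
  expect_equal(lt_transform(10), 2.302585, tolerance = 1e-6)
  expect_equal(lt_transform(0, offset = 1), 0)
  expect_error(lt_transform(0), "offset")
})

test_that("joint linear fit reproduces exact linear data and rejects degenerate input", {
  coag <- c(0.1, 0.5, 0.9, 1.3, 0.2, 0.7)
  comp <- c(0.3, 0.2, 0.8, 0.1, 0.9, 0.4)
  y <- 1 + 2 * coag
  fit <- suppressWarnings(fit_joint_linear(coag, comp, y))  # perfect fit
  expect_equal(fit$beta_coag$estimate, 2, tolerance = 1e-10)
  expect_equal(fit$beta_comp$estimate, 0, tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit$fit))), 1e-10)
  expect_true(fit$beta_coag$lower <= fit$beta_coag$estimate &&
                fit$beta_coag$estimate <= fit$beta_coag$upper)
  expect_error(fit_joint_linear(rep(1, 6), comp, y), "constant")
  expect_error(fit_joint_linear(coag, 2 * coag + 1, y), "collinear")
})

test_that("product-term p-value is invariant to affine rescaling of predictors", {
  d <- gen_cohort2(cohort2_config(n_patients = 60, seed = 8))
  sc <- pathway_scores(d)
  y <- lt_transform(d$SLEDAI)
  p1 <- test_interaction(sc$coagulation_score, sc$complement_score, y)$p_interaction
  p2 <- test_interaction(10 * sc$coagulation_score - 3,
                         0.2 * sc$complement_score + 7, y)$p_interaction
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("a product term collinear with a main effect is a degenerate design", {
  coag <- c(0, 0, 0, 1, 1, 1)
  comp <- c(2, 3, 4, 1, 1, 1)   # coag * comp == coag
  y <- c(1, 2, 3, 4, 5, 6)
  expect_error(test_interaction(coag, comp, y), "collinear")
})

test_that("median dichotomization sends ties low and reports its threshold", {
  g <- dichotomize(c(1, 2, 3, 4))
  expect_equal(attr(g, "threshold"), 2.5)
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  g2 <- dichotomize(c(1, 2, 2, 3))
  expect_equal(as.character(g2), c("low", "low", "low", "high"))
  expect_error(dichotomize(rep(5, 4)), "equal")
  sc <- pathway_scores(gen_cohort2(cohort2_config(n_patients = 112, seed = 6)))
  g3 <- dichotomize(sc$coagulation_score)
  ties <- sum(sc$coagulation_score == median(sc$coagulation_score))
  expect_lte(abs(sum(g3 == "high") - sum(g3 == "low")), max(ties, 1))
})

test_that("stratified table reproduces a hand-computed pooled-variance ANOVA", {
  # 2 patients per cell; LSD p-values from the pooled mean square error
  coag_g <- factor(c("low", "low", "high", "high", "low", "low", "high", "high"),
                   levels = c("low", "high"))
  comp_g <- factor(c("low", "low", "low", "low", "high", "high", "high", "high"),
                   levels = c("low", "high"))
  y <- c(1, 2, 2, 3, 3, 4, 6, 8)
  st <- suppressWarnings(stratified_means(coag_g, comp_g, y, route = "LSD"))
  expect_equal(st$cells$ltsledai_mean, c(1.5, 2.5, 3.5, 7.0))
  # hand ANOVA: SSW = 0.5 + 0.5 + 0.5 + 2 = 3.5 on 4 df -> MSE = 0.875
  mse <- 3.5 / 4
  se <- sqrt(mse * (1 / 2 + 1 / 2))
  p_ll_hl <- 2 * pt(-abs((1.5 - 2.5) / se), df = 4)
  expect_identical(st$route, "LSD")
  expect_equal(unname(st$row_col_p["row_low_comp"]), p_ll_hl, tolerance = 1e-10)
  p_lh_hh <- 2 * pt(-abs((3.5 - 7.0) / se), df = 4)
  expect_equal(unname(st$row_col_p["row_high_comp"]), p_lh_hh, tolerance = 1e-10)
})

test_that("stratified table handles the no-difference and separation limits", {
  g1 <- factor(rep(c("low", "high"), each = 4), levels = c("low", "high"))
  g2 <- factor(rep(c("low", "high", "low", "high"), each = 2),
               levels = c("low", "high"))
  same <- rep(2, 8)
  st <- suppressWarnings(stratified_means(g1, g2, same))
  expect_true(all(st$pairwise$p == 1))
  eps <- c(-1, 1, -1, 1, -1, 1, -1, 1) * 1e-3
  apart <- c(0, 0, 10, 10, 0, 0, 10, 10) + eps
  st2 <- suppressWarnings(stratified_means(g1, g2, apart))
  # low/low (near 0) vs low/high (near 10): separation drives p to 0
  expect_lt(unname(st2$row_col_p["col_low_coag"]), 1e-6)
  expect_error(
    stratified_means(factor(rep("low", 8), levels = c("low", "high")), g2, same),
    "empty")
})

test_that("cytokine subgroup moderation localizes the interaction to the high half", {
  pattern <- vapply(1:10, function(s) {
    d <- gen_cohort2(cohort2_config(n_patients = 1000, seed = 200 + s))
    sc <- pathway_scores(d)
    m <- subgroup_moderation(sc$coagulation_score, sc$complement_score,
                             sc$cytokine_score, lt_transform(d$SLEDAI))
    m$high$interaction$p_interaction < 0.05 &&
      m$low$interaction$p_interaction >= 0.05
  }, logical(1))
  expect_gte(mean(pattern), 0.8)
  # symmetric moderation: both halves significant at large n
  d <- gen_cohort2(cohort2_config(n_patients = 4000, seed = 31,
                                  beta_inter_high_cytokine = 0.5,
                                  beta_inter_low_cytokine = 0.5))
  sc <- pathway_scores(d)
  m <- subgroup_moderation(sc$coagulation_score, sc$complement_score,
                           sc$cytokine_score, lt_transform(d$SLEDAI))
  expect_lt(m$high$interaction$p_interaction, 0.05)
  expect_lt(m$low$interaction$p_interaction, 0.05)
  expect_error(subgroup_moderation(1:8, 1:8, rep(1, 8), 1:8), "equal")
})

test_that("pearson correlation matches hand computation and flags degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, -2 * x + 5)$r, -1)
  expect_equal(pearson(x, c(1, 3, 2, 4))$r, 0.8)
  expect_error(pearson(x, rep(1, 4)), "constant")
})

test_that("D-dimer and C4 behave as surrogates for their pathway scores", {
  for (s in 1:3) {
    d <- gen_cohort2(cohort2_config(n_patients = 112, seed = 40 + s))
    sc <- pathway_scores(d)
    expect_gt(pearson(d$`D-dimer`, sc$coagulation_score)$r, 0)
    expect_lt(pearson(d$C4, sc$complement_score)$r, 0)
  }
})

test_that("the surrogate pipeline runs end-to-end with D-dimer and C4 in place of the scores", {
  hits <- vapply(1:10, function(s) {
    d <- gen_cohort2(cohort2_config(n_patients = 1000, seed = 300 + s))
    sc <- pathway_scores(d)
    y <- lt_transform(d$SLEDAI)
    m <- subgroup_moderation(d$`D-dimer`, -d$C4, sc$cytokine_score, y)
    m$high$interaction$p_interaction < 0.05 &&
      m$low$interaction$p_interaction >= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})
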