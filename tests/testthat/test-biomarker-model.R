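test_that("quartile coding matches the clinical schemes, boundaries going low", {
  expect_equal(quartile_code(3.10, ddimer_scheme()), 4L)
  expect_equal(quartile_code(0.04, c4_scheme()), 4L)
  expect_equal(quartile_code(0.56, ddimer_scheme()), 1L)  # boundary-inclusive
  expect_equal(quartile_code(c(0.2, 0.57, 1.20, 1.21, 2.80, 2.81),
                             ddimer_scheme()),
               c(1L, 2L, 2L, 3L, 3L, 4L))
  expect_equal(quartile_code(c(0.05, 0.051, 0.12, 0.121, 0.20, 0.21),
                             c4_scheme()),
               c(4L, 3L, 3L, 2L, 2L, 1L))
  expect_error(quartile_code(-0.1, ddimer_scheme()), ">= 0")
  expect_error(quartile_scheme("x", c(1, 1, 2)), "ascending")
})

test_that("empirical quartiles use the linear-interpolation percentile definition", {
  sch <- estimate_quartiles(1:8, "toy")
  expect_equal(sch$cuts, c(2.75, 4.5, 6.25))
  expect_error(estimate_quartiles(rep(2, 10)), "distinct")
  expect_error(estimate_quartiles(1:5), "at least 8")
  # round-trip: data simulated from the built-in cuts give those cuts back
  d <- gen_cohort3(cohort3_config(n_patients = 4000, seed = 17))
  est <- estimate_quartiles(d$ddimer, "D-dimer")
  expect_equal(est$cuts, c(0.56, 1.20, 2.80), tolerance = 0.05)
})

test_that("linear predictor and probability reproduce the built-in equation", {
  eq <- ddc4_equation()
  expect_equal(linear_predictor(eq, 4, 4), 2.620, tolerance = 1e-12)
  expect_equal(linear_predictor(eq, 1, 1), -0.833, tolerance = 1e-12)
  expect_equal(linear_predictor(predictive_equation(0, 0, 0, 0), 2, 3), 0)
  expect_equal(round(predict_probability(eq, 4, 4), 3), 0.932)
  expect_equal(round(predict_probability(eq, 1, 1), 3), 0.303)
  expect_equal(plogis(0), 0.5)
  expect_error(linear_predictor(eq, 5, 1), "codes")
  expect_error(linear_predictor(eq, 1, 0), "codes")
})

test_that("cell probabilities are strictly increasing in each code and all distinct", {
  eq <- ddc4_equation()
  p <- outer(1:4, 1:4, function(d, c) predict_probability(eq, d, c))
  expect_true(all(apply(p, 1, diff) > 0))  # increasing in code_c
  expect_true(all(apply(p, 2, diff) > 0))  # increasing in code_d
  expect_equal(length(unique(round(as.vector(p), 6))), 16)
})

test_that("logistic fit recovers the generating equation and flags bad labels", {
  d <- gen_cohort3(cohort3_config(n_patients = 20000, seed = 1))
  f <- fit_equation(d)
  gen <- c(-1.612, 0.361, 0.325, 0.093)
  expect_true(all(abs(unlist(f$equation) - gen) <= 3 * f$se))
  expect_true(f$converged)
  expect_true(f$p_interaction >= 0 && f$p_interaction <= 1)

  all_pos <- d[1:100, ]; all_pos$active <- TRUE
  expect_error(fit_equation(all_pos), "both active and inactive")
  sep <- d[1:500, ]; sep$active <- sep$code_d >= 3
  expect_error(fit_equation(sep), "separation")
  expect_error(fit_equation(d[1:10, ]), "at least 20")
})

test_that("odds-ratio grid has a unit reference, matches analytic odds at large n", {
  eq <- ddc4_equation()
  d <- gen_cohort3(cohort3_config(n_patients = 50000, seed = 23))
  og <- or_grid(d)
  g <- og$grid
  expect_equal(g$or[g$code_d == 1 & g$code_c == 1], 1)
  expect_equal(sum(g$n), 50000)
  odds <- function(d_, c_) {
    p <- predict_probability(eq, d_, c_); p / (1 - p)
  }
  analytic <- odds(g$code_d, g$code_c) / odds(1, 1)
  nonref <- !(g$code_d == 1 & g$code_c == 1)
  expect_true(all(abs(log(g$or[nonref]) - log(analytic[nonref])) < 0.2))
  # positive coefficients make ORs non-decreasing along rows and columns
  m <- matrix(g$or, 4, 4, byrow = TRUE)  # rows: code_d, cols: code_c
  expect_true(all(apply(m, 1, diff) > -1e-9))
  expect_true(all(apply(m, 2, diff) > -1e-9))
  expect_lt(og$p_interaction, 0.05)
})

test_that("odds-ratio grid errors on an empty reference and reports empty cells as NA", {
  d <- gen_cohort3(cohort3_config(n_patients = 2000, seed = 29))
  expect_error(or_grid(d[!(d$code_d == 1 & d$code_c == 1), ]), "reference")
  sub <- d[!(d$code_d == 4 & d$code_c == 4), ]
  og <- or_grid(sub)
  expect_true(is.na(og$grid$or[og$grid$code_d == 4 & og$grid$code_c == 4]))
})

test_that("null labels give odds ratios near 1 across the grid", {
  d <- gen_cohort3(cohort3_config(n_patients = 20000, seed = 37))
  set.seed(1); d$active <- runif(nrow(d)) < 0.5   # independent of cells
  og <- or_grid(d)
  nonref <- !(og$grid$code_d == 1 & og$grid$code_c == 1)
  expect_true(all(abs(log(og$grid$or[nonref])) < 0.35))
})

test_that("rectangle-rule confusion counts match exhaustive hand enumeration", {
  rec <- toy_records()   # 4 active, 4 inactive, one patient per listed cell
  tab <- evaluate_rules(rec)
  row <- function(d, c) tab[tab$d_star == d & tab$c_star == c, ]
  # rule (3,3): positives are (3,3) and (4,4) -> TP 2, FP 0, FN 2, TN 4
  r <- row(3, 3)
  expect_equal(c(r$tp, r$fp, r$tn, r$fn), c(2, 0, 4, 2))
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$specificity, 1)
  expect_equal(r$npv, 4 / 6)
  # rule (2,3): adds (2,3) -> TP 3, FN 1
  r2 <- row(2, 3)
  expect_equal(c(r2$tp, r2$fp, r2$tn, r2$fn), c(3, 0, 4, 1))
  # all-inclusive rule
  r3 <- row(1, 1)
  expect_equal(r3$sensitivity, 1)
  expect_equal(r3$specificity, 0)
  expect_equal(r3$ppv, 0.5)          # prevalence of the toy cohort
  expect_equal(r3$npv, 0)            # degenerate denominator convention
  expect_true(r3$degenerate)
})

test_that("a dataset labeled exactly by a rectangle rule scores that rule perfectly", {
  d <- gen_cohort3(cohort3_config(n_patients = 500, seed = 41))
  d$active <- d$code_d >= 4 & d$code_c >= 4
  tab <- evaluate_rules(d)
  r <- tab[tab$d_star == 4 & tab$c_star == 4, ]
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_error(evaluate_rules(dplyr::mutate(d, active = FALSE)), "both")
})

test_that("probability-threshold mode ranks by P rather than the rectangle", {
  d <- gen_cohort3(cohort3_config(n_patients = 1000, seed = 43))
  tab <- evaluate_rules(d, rule = "probability")
  # sensitivity must now be monotone non-increasing in the cut-off
  expect_true(all(diff(tab$sensitivity) > -1e-9))  # rows ordered by desc cutoff
  expect_equal(tab$youden, tab$sensitivity + tab$specificity)
})
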