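#' Log-transform a SLEDAI score
#'
#' Natural logarithm of the SLEDAI disease-activity score (the continuous
#' outcome of the regression analyses). Cohorts that contain SLEDAI = 0
#' can enable an additive offset: `log(sledai + offset)`.
#'
#' The natural log is used because the group means of the transformed
#' outcome (roughly 1.6-2.9 across strata) correspond to ln of SLEDAI in
#' the 5-18 range; a base-10 transform would place them near 0.7-1.3.
#'
#' @param sledai Numeric vector of SLEDAI scores, >= 1 (or >= 0 with a
#'   positive `offset`).
#' @param offset Non-negative additive offset, default 0.
#' @return ltSLEDAI, a numeric vector.
#' @examples
#' lt_transform(1)            # 0
#' lt_transform(0, offset = 1) # 0
#' @export
lt_transform <- function(sledai, offset = 0) {
  if (offset < 0) abort("offset must be >= 0")
  if (any(sledai + offset <= 0, na.rm = TRUE)) {
    abort("SLEDAI + offset must be > 0; use offset = 1 for scores of 0")
  }
  log(sledai + offset)
}

#' Joint linear model of ltSLEDAI on the two pathway scores
#'
#' Ordinary least squares fit of `ltSLEDAI ~ coag + comp` with both
#' pathway scores entered together; 95% confidence intervals from the t
#' distribution.
#'
#' @param coag,comp Numeric pathway-score vectors.
#' @param ltsledai Numeric outcome vector (see [lt_transform()]).
#' @return A list of class `interaction_fit`: `beta_coag`, `beta_comp`
#'   (each a list with `estimate`, `lower`, `upper`, `p`), `n`, and the
#'   underlying `lm` fit. When fitted with a product term (see
#'   [test_interaction()]) also `beta_interaction` and `p_interaction`.
#' @export
fit_joint_linear <- function(coag, comp, ltsledai) {
  check_predictors(coag, comp, ltsledai)
  fit <- lm(ltsledai ~ coag + comp)
  wrap_linear_fit(fit, interaction = FALSE)
}

#' Product-term interaction test
#'
#' Fits `ltSLEDAI ~ coag + comp + coag:comp` and returns the fit with the
#' two-sided t-test p-value of the product-term coefficient. The p-value
#' is invariant to affine rescaling of either predictor.
#'
#' @inheritParams fit_joint_linear
#' @return An `interaction_fit` with `beta_interaction` and
#'   `p_interaction`.
#' @export
test_interaction <- function(coag, comp, ltsledai) {
  check_predictors(coag, comp, ltsledai)
  fit <- lm(ltsledai ~ coag * comp)
  if (anyNA(coef(fit))) {
    abort("degenerate design: the product term is collinear with the main effects")
  }
  wrap_linear_fit(fit, interaction = TRUE)
}

check_predictors <- function(coag, comp, ltsledai) {
  n <- length(ltsledai)
  if (length(coag) != n || length(comp) != n) {
    abort("coag, comp and ltsledai must have equal length")
  }
  if (n < 4) abort("need at least 4 observations")
  if (sd(coag) == 0 || sd(comp) == 0) {
    abort("constant predictor: both scores must vary")
  }
  r <- cor(coag, comp)
  if (abs(r) > 1 - 1e-12) abort("collinear predictors (|r| = 1)")
  invisible(TRUE)
}

wrap_linear_fit <- function(fit, interaction) {
  sm <- summary(fit)$coefficients
  ci <- confint(fit, level = 0.95)
  pull <- function(term) list(
    estimate = unname(sm[term, "Estimate"]),
    lower = unname(ci[term, 1]), upper = unname(ci[term, 2]),
    p = unname(sm[term, "Pr(>|t|)"])
  )
  out <- list(
    beta_coag = pull("coag"),
    beta_comp = pull("comp"),
    n = length(fit$residuals),
    fit = fit
  )
  if (interaction) {
    out$beta_interaction <- unname(sm["coag:comp", "Estimate"])
    out$p_interaction <- unname(sm["coag:comp", "Pr(>|t|)"])
  }
  structure(out, class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  fmt <- function(b, name) cat(sprintf(
    "  %s: beta = %.3f (95%% CI %.3f to %.3f), P = %.3g\n",
    name, b$estimate, b$lower, b$upper, b$p))
  cat("<interaction_fit> n =", x$n, "\n")
  fmt(x$beta_coag, "coagulation")
  fmt(x$beta_comp, "complement")
  if (!is.null(x$p_interaction)) {
    cat(sprintf("  interaction: beta = %.3f, P = %.3g\n",
                x$beta_interaction, x$p_interaction))
  }
  invisible(x)
}

#' Median dichotomization
#'
#' Splits scores at the sample median: `"high"` iff score > median, ties
#' assigned `"low"`.
#'
#' @param scores Numeric vector, n >= 2, not all equal.
#' @param method Only `"median"` is implemented.
#' @return A factor with levels `low`, `high` and attribute
#'   `"threshold"` (the median used).
#' @examples
#' dichotomize(c(1, 2, 2, 3))  # ties at the median go low
#' @export
dichotomize <- function(scores, method = "median") {
  method <- match.arg(method, "median")
  if (length(scores) < 2) abort("need at least 2 scores")
  if (length(unique(scores)) == 1L) {
    abort("all scores are equal; no median split is possible")
  }
  thr <- median(scores)
  labels <- factor(ifelse(scores > thr, "high", "low"),
                   levels = c("low", "high"))
  attr(labels, "threshold") <- thr
  labels
}

#' Stratified 2x2 comparison of ltSLEDAI
#'
#' Crosses the dichotomized coagulation and complement scores into four
#' cells and compares mean ltSLEDAI across them. Pairwise p-values use
#' the LSD test (pairwise t with the pooled ANOVA error) when Levene's
#' test across the four cells is non-significant at alpha = 0.05, and
#' Tamhane's T2 (pairwise Welch t with Sidak adjustment over the 6
#' comparisons) otherwise. The route taken is reported.
#'
#' When the pooled error is exactly 0 (all values identical within
#' cells), p is 1 for equal means and 0 for unequal means by convention.
#'
#' @param coag_group,comp_group Factors with levels `low`/`high` from
#'   [dichotomize()].
#' @param ltsledai Numeric outcome.
#' @param coag,comp Optional raw score vectors; when given, cell means
#'   and SDs of the scores are included as in the standard presentation.
#' @param route `"auto"` (default) selects LSD vs Tamhane T2 by Levene's
#'   test; `"LSD"` or `"TamhaneT2"` forces the respective procedure
#'   (useful when cell sizes are too small for the homogeneity test to
#'   be informative).
#' @return A list of class `stratified_table`: `cells` (tibble with
#'   `coag_group`, `comp_group`, `n`, means/SDs), `pairwise` (tibble of
#'   all 6 comparisons with p-values), `row_col_p` (the four
#'   within-row/within-column p-values), `route` (`"LSD"` or
#'   `"TamhaneT2"`), `levene_p`.
#' @export
stratified_means <- function(coag_group, comp_group, ltsledai,
                             coag = NULL, comp = NULL,
                             route = c("auto", "LSD", "TamhaneT2")) {
  route <- match.arg(route)
  cell <- interaction(coag_group, comp_group, sep = "/", lex.order = FALSE)
  lv <- c("low/low", "high/low", "low/high", "high/high")
  cell <- factor(as.character(cell), levels = lv)
  counts <- table(cell)
  if (any(counts == 0)) {
    abort(paste0("empty cell(s): ",
                 paste(names(counts)[counts == 0], collapse = ", ")))
  }
  msd <- function(v) {
    vapply(lv, function(l) {
      x <- v[cell == l]
      c(mean = mean(x), sd = if (length(x) > 1) sd(x) else 0)
    }, numeric(2))
  }
  lt_ms <- msd(ltsledai)
  cells <- tibble::tibble(
    cell = lv,
    coag_group = sub("/.*", "", lv),
    comp_group = sub(".*/", "", lv),
    n = as.integer(counts[lv]),
    ltsledai_mean = unname(lt_ms["mean", ]),
    ltsledai_sd = unname(lt_ms["sd", ])
  )
  if (!is.null(coag)) {
    ms <- msd(coag)
    cells$coag_mean <- unname(ms["mean", ])
    cells$coag_sd <- unname(ms["sd", ])
  }
  if (!is.null(comp)) {
    ms <- msd(comp)
    cells$comp_mean <- unname(ms["mean", ])
    cells$comp_sd <- unname(ms["sd", ])
  }

  # route: Levene (classical, centered at the mean) across the 4 cells
  within_var <- tapply(ltsledai, cell, var)
  if (all(within_var == 0, na.rm = TRUE)) {
    levene_p <- 1
  } else {
    levene_p <- car::leveneTest(ltsledai ~ cell, center = mean)[1, "Pr(>F)"]
  }
  if (route == "auto") {
    route <- if (levene_p >= 0.05) "LSD" else "TamhaneT2"
  }

  pairs <- utils::combn(lv, 2)
  N <- length(ltsledai)
  mse <- sum((counts[lv] - 1) * ifelse(is.na(within_var[lv]), 0,
                                       within_var[lv])) / (N - 4)
  pw <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    xa <- ltsledai[cell == a]; xb <- ltsledai[cell == b]
    diff <- mean(xa) - mean(xb)
    if (route == "LSD") {
      se <- sqrt(mse * (1 / length(xa) + 1 / length(xb)))
      if (se == 0) {
        p <- if (abs(diff) < 1e-12) 1 else 0
      } else {
        p <- 2 * pt(-abs(diff / se), df = N - 4)
      }
    } else {
      va <- var(xa) / length(xa); vb <- var(xb) / length(xb)
      se <- sqrt(va + vb)
      if (se == 0) {
        p <- if (abs(diff) < 1e-12) 1 else 0
      } else {
        df <- (va + vb)^2 /
          (va^2 / (length(xa) - 1) + vb^2 / (length(xb) - 1))
        p_raw <- 2 * pt(-abs(diff / se), df = df)
        p <- 1 - (1 - p_raw)^ncol(pairs)  # Sidak over the 6 comparisons
      }
    }
    tibble::tibble(cell_a = a, cell_b = b, diff = diff, p = min(p, 1))
  })
  pairwise <- dplyr::bind_rows(pw)
  getp <- function(a, b) {
    hit <- (pairwise$cell_a == a & pairwise$cell_b == b) |
      (pairwise$cell_a == b & pairwise$cell_b == a)
    pairwise$p[hit]
  }
  row_col_p <- c(
    row_high_comp = getp("low/high", "high/high"),
    row_low_comp = getp("low/low", "high/low"),
    col_high_coag = getp("high/low", "high/high"),
    col_low_coag = getp("low/low", "low/high")
  )
  structure(list(cells = cells, pairwise = pairwise,
                 row_col_p = row_col_p, route = route,
                 levene_p = unname(levene_p), n = N),
            class = "stratified_table")
}

#' @export
print.stratified_table <- function(x, ...) {
  cat("<stratified_table> n =", x$n, " route:", x$route,
      sprintf("(Levene P = %.3g)\n", x$levene_p))
  print(x$cells)
  invisible(x)
}

#' Cytokine-subgroup moderation analysis
#'
#' Splits patients at the median cytokine score (ties to the low group)
#' and repeats the full Part-2 pipeline — joint linear fit, product-term
#' interaction test, median dichotomization and the stratified 2x2 table
#' — within each inflammation half. Dichotomization thresholds are
#' recomputed within each subgroup.
#'
#' @param coag,comp,cytokine Numeric score vectors.
#' @param ltsledai Numeric outcome.
#' @return A list of class `moderation_result` with elements `high` and
#'   `low`, each containing `fit` (main effects), `interaction`
#'   (product-term fit), `table` ([stratified_means()] result) and `n`;
#'   plus `cytokine_threshold`.
#' @export
subgroup_moderation <- function(coag, comp, cytokine, ltsledai) {
  if (length(unique(cytokine)) == 1L) {
    abort("cytokine scores are all equal; no median split is possible")
  }
  if (length(ltsledai) < 8) abort("need at least 8 patients")
  grp <- dichotomize(cytokine)
  one <- function(keep) {
    if (sum(keep) < 4) abort("subgroup with fewer than 4 patients")
    co <- coag[keep]; cm <- comp[keep]; y <- ltsledai[keep]
    list(
      fit = fit_joint_linear(co, cm, y),
      interaction = test_interaction(co, cm, y),
      table = stratified_means(dichotomize(co), dichotomize(cm), y, co, cm),
      n = sum(keep)
    )
  }
  structure(list(
    high = one(grp == "high"),
    low = one(grp == "low"),
    cytokine_threshold = attr(grp, "threshold")
  ), class = "moderation_result")
}

#' Pearson correlation with t-based test
#'
#' @param x,y Numeric vectors of equal length, n >= 3, non-constant.
#' @return A tibble with `r`, `p` (two-sided) and `n`.
#' @examples
#' pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))  # r = 0.8
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("constant vector: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
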