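#' Quartile coding schemes for risk markers
#'
#' A quartile scheme turns a continuous marker into an ordinal risk code
#' 1-4, where 4 is always the highest-risk quartile. Intervals on the
#' concentration axis are left-open/right-closed, so a value exactly on a
#' cut point belongs to the lower concentration interval.
#'
#' For a `higher_is_risk` marker with cuts (q1, q2, q3): code 1 iff
#' v <= q1, ..., code 4 iff v > q3. For a `lower_is_risk` marker the
#' coding is reversed: code 4 iff v <= q1, ..., code 1 iff v > q3.
#'
#' `ddimer_scheme()` and `c4_scheme()` are the built-in clinical schemes:
#' plasma D-dimer (ug/mL, higher is risk) with cuts 0.56/1.20/2.80 and
#' serum C4 (mg/mL, lower is risk — complement consumption) with cuts
#' 0.05/0.12/0.20.
#'
#' @param marker Marker name.
#' @param cuts Three strictly ascending numeric cut points.
#' @param direction `"higher_is_risk"` or `"lower_is_risk"`.
#' @param units Optional unit string, checked by [read_cohort()].
#' @return An object of class `quartile_scheme`.
#' @examples
#' quartile_code(c(0.3, 0.56, 3.1), ddimer_scheme())
#' quartile_code(c(0.04, 0.2, 0.3), c4_scheme())
#' @export
quartile_scheme <- function(marker, cuts,
                            direction = c("higher_is_risk", "lower_is_risk"),
                            units = NULL) {
  direction <- match.arg(direction)
  cuts <- as.numeric(cuts)
  if (length(cuts) != 3L || anyNA(cuts)) abort("cuts must be 3 numbers")
  if (any(diff(cuts) <= 0)) abort("cut points must be strictly ascending")
  structure(list(marker = marker, cuts = cuts, direction = direction,
                 units = units),
            class = "quartile_scheme")
}

#' @rdname quartile_scheme
#' @export
ddimer_scheme <- function() {
  quartile_scheme("D-dimer", c(0.56, 1.20, 2.80), "higher_is_risk", "ug/mL")
}

#' @rdname quartile_scheme
#' @export
c4_scheme <- function() {
  quartile_scheme("C4", c(0.05, 0.12, 0.20), "lower_is_risk", "mg/mL")
}

#' @export
print.quartile_scheme <- function(x, ...) {
  cat("<quartile_scheme> ", x$marker,
      if (!is.null(x$units)) paste0(" (", x$units, ")"), "\n",
      "  cuts: ", paste(x$cuts, collapse = " / "),
      "  direction: ", x$direction, "\n", sep = "")
  invisible(x)
}

#' Apply a quartile scheme
#'
#' @param values Non-negative numeric marker values.
#' @param scheme A [quartile_scheme()].
#' @return Integer codes in 1-4 (4 = highest risk).
#' @export
quartile_code <- function(values, scheme) {
  stopifnot(inherits(scheme, "quartile_scheme"))
  values <- as.numeric(values)
  if (any(values < 0, na.rm = TRUE)) abort("marker values must be >= 0")
  above <- vapply(values, function(v) sum(v > scheme$cuts), integer(1))
  code <- if (scheme$direction == "higher_is_risk") 1L + above else 4L - above
  code[is.na(values)] <- NA_integer_
  code
}

#' Empirical quartile scheme from observed values
#'
#' Cut points at the 25th/50th/75th percentiles using the
#' linear-interpolation percentile definition ([stats::quantile()]
#' type 7).
#'
#' @param values Numeric marker values, n >= 8 with at least 4 distinct
#'   values.
#' @inheritParams quartile_scheme
#' @return A [quartile_scheme()].
#' @examples
#' estimate_quartiles(1:8, "toy")  # cuts 2.75 / 4.5 / 6.25
#' @export
estimate_quartiles <- function(values, marker = "marker",
                               direction = c("higher_is_risk",
                                             "lower_is_risk"),
                               units = NULL) {
  direction <- match.arg(direction)
  values <- values[!is.na(values)]
  if (length(values) < 8L) abort("need at least 8 observations")
  if (length(unique(values)) < 4L) {
    abort("need at least 4 distinct values to place quartile cuts")
  }
  cuts <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  quartile_scheme(marker, cuts, direction, units)
}

#' Predictive equations over quartile codes
#'
#' A logistic predictive equation over two ordinal quartile codes with
#' their product as interaction: z = b0 + b1*code_d + b2*code_c +
#' b3*code_d*code_c, P = 1 / (1 + exp(-z)).
#'
#' `ddc4_equation()` returns the built-in reference equation for lupus
#' activity from D-dimer and C4 quartile codes, with coefficients
#' (-1.612, 0.361, 0.325, 0.093). At the top-risk codes (4, 4) it gives
#' z = 2.620 and P = 0.932; at the lowest-risk codes (1, 1), P = 0.303.
#'
#' @param beta0,beta1,beta2,beta3 Intercept, D-dimer-code, C4-code and
#'   interaction coefficients.
#' @return An object of class `predictive_equation`.
#' @examples
#' eq <- ddc4_equation()
#' linear_predictor(eq, 4, 4)      # 2.620
#' predict_probability(eq, 4, 4)   # 0.932...
#' @export
predictive_equation <- function(beta0, beta1, beta2, beta3) {
  b <- c(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3)
  if (anyNA(b) || !is.numeric(b)) abort("coefficients must be numeric")
  structure(as.list(b), class = "predictive_equation")
}

#' @rdname predictive_equation
#' @export
ddc4_equation <- function() {
  predictive_equation(-1.612, 0.361, 0.325, 0.093)
}

#' @export
print.predictive_equation <- function(x, ...) {
  cat(sprintf(
    "<predictive_equation> z = %.3f + %.3f*code_d + %.3f*code_c + %.3f*code_d*code_c\n",
    x$beta0, x$beta1, x$beta2, x$beta3))
  invisible(x)
}

check_codes <- function(code_d, code_c) {
  ok <- function(k) is.numeric(k) && !anyNA(k) && all(k %in% 1:4)
  if (!ok(code_d) || !ok(code_c)) abort("quartile codes must be in {1, 2, 3, 4}")
}

#' Linear predictor and predicted probability
#'
#' @param eq A [predictive_equation()].
#' @param code_d,code_c Quartile codes in 1-4 (vectors recycle as usual).
#' @return `linear_predictor()`: the numeric z; `predict_probability()`:
#'   P = 1/(1+exp(-z)), strictly in (0, 1). Full precision is returned;
#'   round to 3 decimals for table display.
#' @export
linear_predictor <- function(eq, code_d, code_c) {
  stopifnot(inherits(eq, "predictive_equation"))
  check_codes(code_d, code_c)
  eq$beta0 + eq$beta1 * code_d + eq$beta2 * code_c +
    eq$beta3 * code_d * code_c
}

#' @rdname linear_predictor
#' @export
predict_probability <- function(eq, code_d, code_c) {
  plogis(linear_predictor(eq, code_d, code_c))
}

#' Fit the quartile-coded logistic interaction model
#'
#' Maximum-likelihood logistic regression of the binary activity label
#' on the two quartile codes (entered as ordinal 1-4) and their product.
#'
#' @param records Data frame with columns `code_d`, `code_c` and a
#'   logical/0-1 `active` column (or raw `ddimer`/`c4` columns plus
#'   `schemes` to code them).
#' @param schemes Optional list with elements `ddimer` and `c4`
#'   ([quartile_scheme()]s) used to code raw marker columns when code
#'   columns are absent.
#' @return A list of class `equation_fit`: `equation`
#'   (a [predictive_equation()]), `se`, `ci` (95% Wald), `p_interaction`,
#'   `converged`, `n`, and the underlying `glm` fit.
#' @export
fit_equation <- function(records, schemes = NULL) {
  records <- ensure_codes(records, schemes)
  active <- as.integer(records$active)
  if (length(unique(active)) < 2L) {
    abort("both active and inactive patients are required to fit")
  }
  if (nrow(records) < 20L) abort("need at least 20 records")
  d <- records$code_d
  c_ <- records$code_c
  check_codes(d, c_)
  fit <- suppressWarnings(
    glm(active ~ d + c_ + I(d * c_), family = binomial())
  )
  probs <- fitted(fit)
  if (any(probs > 1 - 1e-10) || any(probs < 1e-10)) {
    abort(paste0("complete or quasi-complete separation detected: fitted ",
                 "probabilities of 0 or 1; coefficients are not identified"))
  }
  b <- unname(coef(fit))
  se <- unname(sqrt(diag(vcov(fit))))
  z <- b / se
  ci <- cbind(lower = b - 1.96 * se, upper = b + 1.96 * se)
  structure(list(
    equation = predictive_equation(b[1], b[2], b[3], b[4]),
    se = setNames(se, c("beta0", "beta1", "beta2", "beta3")),
    ci = ci,
    p_interaction = 2 * pnorm(-abs(z[4])),
    converged = fit$converged,
    n = nrow(records),
    fit = fit
  ), class = "equation_fit")
}

ensure_codes <- function(records, schemes = NULL) {
  records <- tibble::as_tibble(records)
  if (!all(c("code_d", "code_c") %in% names(records))) {
    if (is.null(schemes)) {
      schemes <- list(ddimer = ddimer_scheme(), c4 = c4_scheme())
    }
    if (!all(c("ddimer", "c4") %in% names(records))) {
      abort("records need code_d/code_c columns or ddimer/c4 columns")
    }
    records$code_d <- quartile_code(records$ddimer, schemes$ddimer)
    records$code_c <- quartile_code(records$c4, schemes$c4)
  }
  if (!"active" %in% names(records) && "sledai" %in% names(records)) {
    records$active <- records$sledai >= 8
  }
  records
}

#' 16-cell odds-ratio grid
#'
#' Logistic regression of the activity label on 15 indicator variables
#' for the (D-dimer quartile x C4 quartile) cells, with the lowest-risk
#' cell (code_d = 1, code_c = 1) as reference (OR = 1). Odds ratios are
#' exponentiated coefficients with 95% Wald confidence intervals.
#' Cells with no patients are reported with `NA` odds ratios, never
#' silently dropped. The grid also carries the interaction p-value of
#' the coded model from [fit_equation()].
#'
#' @inheritParams fit_equation
#' @return A list of class `or_grid`: `grid` (tibble with `code_d`,
#'   `code_c`, `n`, `n_active`, `or`, `or_lower`, `or_upper`),
#'   `p_interaction`, `n`.
#' @export
or_grid <- function(records, schemes = NULL) {
  records <- ensure_codes(records, schemes)
  check_codes(records$code_d, records$code_c)
  active <- as.integer(records$active)
  if (length(unique(active)) < 2L) abort("both classes are required")
  cell <- factor(paste(records$code_d, records$code_c, sep = ":"),
                 levels = as.vector(outer(1:4, 1:4,
                                          function(d, c) paste(d, c, sep = ":"))))
  if (sum(cell == "1:1") == 0L) {
    abort("reference cell (code_d = 1, code_c = 1) is empty")
  }
  cell <- stats::relevel(cell, ref = "1:1")
  fit <- suppressWarnings(glm(active ~ cell, family = binomial()))
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  grid <- tidyr::expand_grid(code_d = 1:4, code_c = 1:4)
  key <- paste0("cell", grid$code_d, ":", grid$code_c)
  idx <- match(key, names(cf))
  or <- exp(cf[idx])
  lo <- exp(cf[idx] - 1.96 * se[idx])
  hi <- exp(cf[idx] + 1.96 * se[idx])
  ref <- grid$code_d == 1 & grid$code_c == 1
  or[ref] <- 1; lo[ref] <- 1; hi[ref] <- 1
  tab <- table(cell, active)
  counts <- as.data.frame.matrix(tab)
  ord <- match(paste(grid$code_d, grid$code_c, sep = ":"), rownames(counts))
  grid$n <- rowSums(counts)[ord]
  grid$n_active <- counts[ord, "1"]
  empty <- grid$n == 0
  or[empty] <- NA_real_; lo[empty] <- NA_real_; hi[empty] <- NA_real_
  grid$or <- unname(or); grid$or_lower <- unname(lo); grid$or_upper <- unname(hi)
  eqfit <- fit_equation(records)
  structure(list(grid = grid, p_interaction = eqfit$p_interaction,
                 n = nrow(records)),
            class = "or_grid")
}

#' Cut-off performance table for the predictive equation
#'
#' For every rectangle rule (d*, c*) in \{1..4\}^2 a patient is test
#' positive iff `code_d >= d*` and `code_c >= c*`; the row reports
#' sensitivity, specificity, PPV, NPV and the Youden index, together
#' with the equation's predicted probability P(d*, c*) at the rule's
#' minimum codes (the tabulated "cut-off"). The all-inclusive rule
#' (1, 1) classifies everyone positive: sensitivity 1, specificity 0,
#' PPV = prevalence, NPV degenerate.
#'
#' Positivity is defined by the rectangle rule, not by thresholding P:
#' the two agree only when the 16 cell probabilities are themselves
#' nested, which the reference coefficients do not guarantee across
#' rules. A probability-threshold mode is available via
#' `rule = "probability"`, where each row classifies positive iff
#' P(code_d, code_c) >= P(d*, c*).
#'
#' The Youden column follows the tabulated convention
#' sensitivity + specificity; subtract 1 for the conventional Youden J
#' (also returned as `youden_j`). A proportion whose denominator is 0
#' is reported as 0 and flagged in `degenerate`.
#'
#' @inheritParams fit_equation
#' @param eq A [predictive_equation()]; defaults to the built-in
#'   reference equation.
#' @param rule `"rectangle"` (default) or `"probability"`.
#' @return A tibble of class `performance_table` with one row per rule,
#'   ordered by decreasing cut-off probability: `d_star`, `c_star`,
#'   `cutoff`, `sensitivity`, `specificity`, `ppv`, `npv`, `youden`,
#'   `youden_j`, `tp`, `fp`, `tn`, `fn`, `degenerate`.
#' @export
evaluate_rules <- function(records, schemes = NULL, eq = ddc4_equation(),
                           rule = c("rectangle", "probability")) {
  rule <- match.arg(rule)
  records <- ensure_codes(records, schemes)
  check_codes(records$code_d, records$code_c)
  truth <- as.logical(records$active)
  if (!any(truth) || all(truth)) {
    abort("need both active and inactive patients to evaluate rules")
  }
  grid <- tidyr::expand_grid(d_star = 1:4, c_star = 1:4)
  p_obs <- predict_probability(eq, records$code_d, records$code_c)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    d_star <- grid$d_star[i]; c_star <- grid$c_star[i]
    cutoff <- predict_probability(eq, d_star, c_star)
    pos <- if (rule == "rectangle") {
      records$code_d >= d_star & records$code_c >= c_star
    } else {
      p_obs >= cutoff - 1e-12
    }
    tp <- sum(pos & truth); fp <- sum(pos & !truth)
    fn <- sum(!pos & truth); tn <- sum(!pos & !truth)
    safe <- function(num, den) if (den == 0) 0 else num / den
    sens <- safe(tp, tp + fn); spec <- safe(tn, tn + fp)
    tibble::tibble(
      d_star = d_star, c_star = c_star, cutoff = cutoff,
      sensitivity = sens, specificity = spec,
      ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn),
      youden = sens + spec, youden_j = sens + spec - 1,
      tp = tp, fp = fp, tn = tn, fn = fn,
      degenerate = (tp + fp == 0) || (tn + fn == 0)
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$cutoff))
  class(out) <- c("performance_table", class(out))
  out
}
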