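#' AUROC by the Mann-Whitney formulation
#'
#' Area under the ROC curve computed as the tie-corrected two-sample
#' U statistic: over all (positive, negative) pairs, a concordant pair
#' counts 1, a tied pair 1/2. The curve is built by sweeping every
#' distinct score threshold, so the trapezoidal area of the returned
#' curve equals the U-based AUROC exactly.
#'
#' @param scores Numeric marker values.
#' @param labels Binary labels (logical or 0/1); `TRUE`/1 = active.
#' @param direction `"higher_is_risk"` (default) or `"lower_is_risk"`;
#'   markers like C4 and C3, which fall with activity, use the latter.
#'   Flipping the orientation maps AUROC to 1 - AUROC.
#' @param marker Marker name carried into the result.
#' @return A list of class `roc_result`: `marker`, `auroc`, `curve`
#'   (tibble `fpr`, `tpr`, from (0,0) to (1,1), both non-decreasing),
#'   `n_pos`, `n_neg`, `direction`.
#' @examples
#' auroc(c(1, 3, 2, 4), c(0, 0, 1, 1))$auroc  # 0.875
#' @export
auroc <- function(scores, labels, direction = c("higher_is_risk",
                                                "lower_is_risk"),
                  marker = "marker") {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- complete.cases(scores, labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    abort("both classes must be present to compute an AUROC")
  }
  s <- if (direction == "higher_is_risk") scores else -scores
  if (length(unique(s)) == 1L) {
    warn("all scores are tied; AUROC is 0.5 by convention")
  }
  # tie-corrected U via midranks
  r <- rank(s, ties.method = "average")
  u <- sum(r[labels]) - n_pos * (n_pos + 1) / 2
  auc <- u / (n_pos * n_neg)
  # curve: sweep thresholds from +Inf down through each distinct score
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(labels & s >= t) / n_pos,
                     numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(!labels & s >= t) / n_neg,
                     numeric(1)))
  structure(list(
    marker = marker, auroc = auc,
    curve = tibble::tibble(fpr = fpr, tpr = tpr),
    n_pos = n_pos, n_neg = n_neg, direction = direction,
    scores = s, labels = labels
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s: AUROC = %.3f (n_pos = %d, n_neg = %d)\n",
              x$marker, x$auroc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Combined D-dimer + C4 risk score
#'
#' Scores each patient by the predictive equation's probability of
#' activity at the patient's quartile codes. Because the logistic is
#' strictly increasing, ranking by P is equivalent to ranking by z, and
#' the AUROC of the combination is invariant to that choice.
#'
#' @inheritParams fit_equation
#' @param eq A [predictive_equation()], default the built-in reference
#'   equation.
#' @return Numeric vector of per-patient predicted probabilities.
#' @export
combined_score <- function(records, eq = ddc4_equation(), schemes = NULL) {
  records <- ensure_codes(records, schemes)
  predict_probability(eq, records$code_d, records$code_c)
}

#' Paired AUROC comparison (DeLong test)
#'
#' Covariance-based z test for the difference between two AUROCs
#' computed on the same patients, using the placement-value estimator of
#' the variance of the paired difference. Two identical ROCs give
#' difference 0 and p = 1.
#'
#' @param roc_a,roc_b `roc_result` objects from [auroc()] built on the
#'   same patients in the same order.
#' @return A tibble with `auroc_a`, `auroc_b`, `difference`, `z`, `p`.
#' @export
compare_aurocs <- function(roc_a, roc_b) {
  stopifnot(inherits(roc_a, "roc_result"), inherits(roc_b, "roc_result"))
  if (roc_a$n_pos != roc_b$n_pos || roc_a$n_neg != roc_b$n_neg ||
      !identical(roc_a$labels, roc_b$labels)) {
    abort("the two ROCs must be computed on the same patients (paired)")
  }
  placements <- function(roc) {
    s <- roc$scores; lab <- roc$labels
    pos <- s[lab]; neg <- s[!lab]
    psi <- function(x, y) (sum(x > y) + 0.5 * sum(x == y)) / length(y)
    v10 <- vapply(pos, psi, numeric(1), y = neg)   # per-positive placement
    v01 <- vapply(neg, function(y) {
      (sum(pos > y) + 0.5 * sum(pos == y)) / length(pos)
    }, numeric(1))
    list(v10 = v10, v01 = v01)
  }
  pa <- placements(roc_a); pb <- placements(roc_b)
  m <- roc_a$n_pos; n <- roc_a$n_neg
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- roc_a$auroc - roc_b$auroc
  if (var_diff <= 0 || abs(diff) < 1e-15) {
    z <- 0
    p <- if (abs(diff) < 1e-15) 1 else NA_real_
    if (abs(diff) >= 1e-15) {
      z <- sign(diff) * Inf
      p <- 0
    }
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  tibble::tibble(auroc_a = roc_a$auroc, auroc_b = roc_b$auroc,
                 difference = diff, z = z, p = p)
}

#' @importFrom stats cov fitted
NULL
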