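# shared fixtures, built in code

# tiny clinical-record table with hand-assigned cells and labels
toy_records <- function() {
  tibble::tibble(
    patient_id = paste0("T", 1:8),
    code_d = c(1L, 2L, 3L, 4L, 4L, 1L, 2L, 3L),
    code_c = c(1L, 2L, 3L, 4L, 1L, 4L, 3L, 2L),
    active = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  )
}

# brute-force pairwise AUROC oracle (ties count 1/2)
auroc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# trapezoidal area under an ROC curve tibble (fpr, tpr)
trapezoid_area <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

expected_prevalence <- function(eq = ddc4_equation()) {
  g <- expand.grid(d = 1:4, c = 1:4)
  mean(predict_probability(eq, g$d, g$c))
}
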