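#' Max-normalize an analyte concentration matrix
#'
#' Rescales each analyte (column) by its maximum over patients, so that
#' the maximum normalized value of every analyte is exactly 1.
#' Normalization is computed over the analysis cohort only; it absorbs
#' assay units, which is what makes signed sums across analytes
#' comparable.
#'
#' @param x A numeric matrix or data frame, patients in rows, analytes in
#'   columns (columns named by analyte). Concentrations must be
#'   non-negative; `NA`s are allowed and propagate.
#' @return A numeric matrix of the same shape and dimnames, with each
#'   column divided by its maximum (computed over non-missing values).
#' @details An analyte whose maximum is 0 cannot be normalized; the error
#'   names the offending analyte. Negative concentrations are rejected.
#' @examples
#' normalize_analytes(cbind(a = c(2, 4), b = c(3, 3)))
#' @export
normalize_analytes <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) abort("concentrations must be numeric")
  if (nrow(m) < 1L) abort("need at least one patient (row)")
  if (any(m < 0, na.rm = TRUE)) {
    bad <- colnames(m)[apply(m < 0, 2, any, na.rm = TRUE)]
    abort(paste0("negative concentration(s) in analyte(s): ",
                 paste(bad %||% "<unnamed>", collapse = ", ")))
  }
  maxes <- apply(m, 2, function(col) {
    if (all(is.na(col))) NA_real_ else max(col, na.rm = TRUE)
  })
  zero <- !is.na(maxes) & maxes == 0
  if (any(zero)) {
    bad <- colnames(m)[zero] %||% which(zero)
    abort(paste0("analyte column(s) with all-zero values cannot be ",
                 "normalized: ", paste(bad, collapse = ", ")))
  }
  sweep(m, 2, maxes, "/")
}

#' Summary pathway score from a normalized panel
#'
#' The per-patient summary score for one pathway: the sum of the
#' pathway's max-normalized activator concentrations minus the sum of its
#' normalized inhibitor/de-activator concentrations. With k activators
#' and j inhibitors the score lies in `[-j, +k]`.
#'
#' @param normalized Matrix from [normalize_analytes()] (each column max
#'   is 1), columns named by analyte.
#' @param catalog Analyte catalog as from [default_catalog()].
#' @param pathway One of `"complement"`, `"coagulation"`, `"cytokine"`.
#' @param na_action `"error"` (default): a missing value for a catalogued
#'   analyte is a hard error. `"drop"`: the analyte is omitted from that
#'   patient's sum (no rescaling) and the returned vector carries an
#'   attribute `"dropped"` with the per-patient count of dropped terms.
#' @return Numeric vector of per-patient scores (named by rownames if
#'   present).
#' @examples
#' m <- normalize_analytes(cbind(C3a = c(1, 2), C4 = c(4, 2)))
#' compute_pathway_score(m, default_catalog(), "complement",
#'                       na_action = "drop")
#' @export
compute_pathway_score <- function(normalized, catalog, pathway,
                                  na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  validate_catalog(catalog)
  pathway <- match.arg(pathway, c("complement", "coagulation", "cytokine"))
  m <- as.matrix(normalized)
  cat_p <- catalog[catalog$pathway == pathway, ]
  present <- intersect(cat_p$analyte, colnames(m))
  if (length(present) == 0L) {
    abort(paste0("no catalogued analytes of pathway '", pathway,
                 "' present in the panel"))
  }
  sub <- m[, present, drop = FALSE]
  signs <- ifelse(cat_p$role[match(present, cat_p$analyte)] == "activator",
                  1, -1)
  if (anyNA(sub)) {
    if (na_action == "error") {
      bad <- colnames(sub)[apply(is.na(sub), 2, any)]
      abort(paste0("missing value(s) for analyte(s): ",
                   paste(bad, collapse = ", "),
                   "; set na_action = 'drop' to omit them per patient"))
    }
    dropped <- rowSums(is.na(sub))
    signed <- sweep(sub, 2, signs, "*")
    score <- rowSums(signed, na.rm = TRUE)
    attr(score, "dropped") <- dropped
    return(score)
  }
  drop(sub %*% signs)
}

#' All three pathway scores for an analyte panel
#'
#' Convenience wrapper: max-normalizes the panel once and computes the
#' coagulation, complement and cytokine summary scores per patient.
#'
#' @param panel Data frame with a `patient_id` column and one numeric
#'   column per analyte (names matching the catalog), or a numeric
#'   matrix with analyte column names.
#' @inheritParams compute_pathway_score
#' @return A tibble with columns `patient_id`, `coagulation_score`,
#'   `complement_score`, `cytokine_score`.
#' @examples
#' cfg <- cohort2_config(n_patients = 8, seed = 1)
#' pathway_scores(gen_cohort2(cfg))
#' @export
pathway_scores <- function(panel, catalog = default_catalog(),
                           na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  validate_catalog(catalog)
  if (is.data.frame(panel)) {
    ids <- if ("patient_id" %in% names(panel)) panel$patient_id
           else seq_len(nrow(panel))
    cols <- intersect(catalog$analyte, names(panel))
    m <- as.matrix(panel[cols])
  } else {
    ids <- rownames(panel) %||% seq_len(nrow(panel))
    cols <- intersect(catalog$analyte, colnames(panel))
    m <- panel[, cols, drop = FALSE]
  }
  if (length(cols) == 0L) abort("no catalogued analyte columns found")
  norm <- normalize_analytes(m)
  tibble::tibble(
    patient_id = ids,
    coagulation_score =
      as.numeric(compute_pathway_score(norm, catalog, "coagulation", na_action)),
    complement_score =
      as.numeric(compute_pathway_score(norm, catalog, "complement", na_action)),
    cytokine_score =
      as.numeric(compute_pathway_score(norm, catalog, "cytokine", na_action))
  )
}
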