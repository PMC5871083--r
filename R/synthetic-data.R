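#' Configuration for the ELISA-panel cohort simulator
#'
#' Defines the generating model for a cohort-II-style dataset: per-patient
#' latent pathway activations, lognormal analyte concentrations loading on
#' those latents with activator/inhibitor signs, and a log-scale SLEDAI
#' built from main effects plus a cytokine-moderated
#' coagulation-by-complement interaction.
#'
#' The generating model is a stand-in (the source cohort is observational
#' and its data-generating process is unknown); it is constructed so that
#' the structural claims the downstream analyses test — activator /
#' inhibitor signs, positive main effects, an interaction present only
#' under high inflammation — are literally true in the simulated data.
#'
#' Latents: A_coag, A_comp, A_cyt are iid standard normal. Analyte a of
#' pathway p has log-concentration
#' `log_mean + s_a * loading * A_p + log_sd * eps`, with `s_a = +1` for
#' activators and `-1` for inhibitors. ltSLEDAI =
#' `intercept + beta_coag*A_coag + beta_comp*A_comp + beta_inter*A_coag*A_comp + N(0, noise_sd)`
#' where `beta_inter` is `beta_inter_high_cytokine` for patients whose
#' observed cytokine summary score lies above its sample median and
#' `beta_inter_low_cytokine` otherwise — a hard switch on the same
#' measured quantity the median-split subgroup analysis conditions on,
#' so the generating subgroups are exactly the analysis subgroups.
#' SLEDAI
#' is `round(exp(ltSLEDAI))` floored at 1 so the log transform is always
#' defined.
#'
#' @param n_patients Number of patients (>= 4). Default 112, the size of
#'   the ELISA cohort being emulated.
#' @param seed Integer RNG seed.
#' @param analyte_catalog Catalog tibble as [default_catalog()].
#' @param intercept,beta_coag,beta_comp Main-effect parameters of the
#'   ltSLEDAI model. Defaults (2.1, 0.5, 0.4) put median SLEDAI near 10
#'   with both pathway effects positive.
#' @param beta_inter_high_cytokine,beta_inter_low_cytokine Interaction
#'   coefficient in the high / low inflammation half. Defaults (0.6, 0):
#'   the interaction exists only under excess inflammation.
#' @param noise_sd Residual SD of ltSLEDAI (> 0), default 0.45.
#' @param loading Loading of each log-concentration on its pathway
#'   latent, default 0.25. The default is deliberately mild so that the
#'   max-normalized concentrations — and hence the summary scores — are
#'   close to linear in the latent over its typical range; strong
#'   loadings make `exp(loading * A)` visibly convex, which misspecifies
#'   a linear main-effect model fitted to the scores.
#' @param log_sd Analyte-level lognormal noise SD, default 0.4 (~40%
#'   assay + biological CV).
#' @param log_mean Common log-scale mean concentration, default 0
#'   (absolute concentration scales are conventional; max-normalization
#'   removes them).
#' @return A list of class `cohort2_config`.
#' @export
cohort2_config <- function(n_patients = 112, seed = 1L,
                           analyte_catalog = default_catalog(),
                           intercept = 2.1, beta_coag = 0.5,
                           beta_comp = 0.4,
                           beta_inter_high_cytokine = 0.6,
                           beta_inter_low_cytokine = 0,
                           noise_sd = 0.45,
                           loading = 0.25, log_sd = 0.4, log_mean = 0) {
  if (n_patients < 4) abort("n_patients must be >= 4")
  if (noise_sd <= 0) abort("noise_sd must be > 0")
  validate_catalog(analyte_catalog)
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    analyte_catalog = analyte_catalog, intercept = intercept,
    beta_coag = beta_coag, beta_comp = beta_comp,
    beta_inter_high_cytokine = beta_inter_high_cytokine,
    beta_inter_low_cytokine = beta_inter_low_cytokine,
    noise_sd = noise_sd, loading = loading, log_sd = log_sd,
    log_mean = log_mean
  ), class = "cohort2_config")
}

#' Simulate an ELISA-panel cohort
#'
#' Draws a cohort from the generating model described in
#' [cohort2_config()]. Deterministic given the config (the seed lives in
#' the config).
#'
#' @param config A [cohort2_config()].
#' @return A tibble with `patient_id`, one concentration column per
#'   catalogued analyte, and `SLEDAI` (positive integer). The latent
#'   activations and the generated ltSLEDAI are attached as the
#'   `"latents"` attribute (a tibble) for parameter-recovery checks.
#' @examples
#' head(gen_cohort2(cohort2_config(n_patients = 8, seed = 42)))
#' @export
gen_cohort2 <- function(config) {
  stopifnot(inherits(config, "cohort2_config"))
  n <- config$n_patients
  cat <- config$analyte_catalog
  withr_seed(config$seed, {
    A <- list(coagulation = rnorm(n), complement = rnorm(n),
              cytokine = rnorm(n))
    conc <- vapply(seq_len(nrow(cat)), function(i) {
      s <- if (cat$role[i] == "activator") 1 else -1
      exp(config$log_mean + s * config$loading * A[[cat$pathway[i]]] +
            config$log_sd * rnorm(n))
    }, numeric(n))
    colnames(conc) <- cat$analyte
    cyt_cols <- cat$analyte[cat$pathway == "cytokine"]
    if (length(cyt_cols)) {
      cyt_score <- compute_pathway_score(
        normalize_analytes(conc[, cyt_cols, drop = FALSE]), cat, "cytokine")
      high_cyt <- cyt_score > median(cyt_score)
    } else {
      high_cyt <- A$cytokine > median(A$cytokine)
    }
    b3 <- ifelse(high_cyt, config$beta_inter_high_cytokine,
                 config$beta_inter_low_cytokine)
    lt <- config$intercept + config$beta_coag * A$coagulation +
      config$beta_comp * A$complement +
      b3 * A$coagulation * A$complement + rnorm(n, 0, config$noise_sd)
    sledai <- pmax(1L, as.integer(round(exp(lt))))
    out <- tibble::tibble(patient_id = sprintf("P%04d", seq_len(n)))
    out <- dplyr::bind_cols(out, tibble::as_tibble(conc))
    out$SLEDAI <- sledai
    attr(out, "latents") <- tibble::tibble(
      patient_id = out$patient_id,
      A_coag = A$coagulation, A_comp = A$complement,
      A_cyt = A$cytokine, high_cytokine = high_cyt, ltSLEDAI = lt
    )
    out
  })
}

#' Configuration for the clinical-record cohort simulator
#'
#' Defines a cohort-III-style generator: quartile codes for D-dimer and
#' C4 marginally uniform on \{1,2,3,4\} (optionally rank-correlated via a
#' Gaussian copula), continuous concentrations uniform within each code's
#' interval, and activity labels Bernoulli with probability given by a
#' [predictive_equation()] over the codes.
#'
#' The unbounded outer quartiles need finite sampling intervals: the
#' top D-dimer quartile draws from (2.80, 5.60] ug/mL and the bottom-risk
#' C4 quartile from (0.20, 0.40] mg/mL (twice the outermost cut).
#'
#' @param n_patients Number of patients (>= 1). Default 2025, the size of
#'   the clinical cohort being emulated.
#' @param seed Integer RNG seed.
#' @param equation A [predictive_equation()], default [ddc4_equation()].
#' @param quartile_cuts_ddimer,quartile_cuts_c4 Three strictly ascending
#'   cut points; defaults 0.56/1.20/2.80 ug/mL and 0.05/0.12/0.20 mg/mL.
#' @param code_correlation Rank correlation between the two codes in
#'   [-1, 1]; default 0 (independent codes).
#' @param cell_assignment `"random"` (codes drawn from the copula) or
#'   `"balanced"` (cycle deterministically through the 16 cells, one
#'   patient per cell when `n_patients` is 16).
#' @return A list of class `cohort3_config`.
#' @export
cohort3_config <- function(n_patients = 2025, seed = 1L,
                           equation = ddc4_equation(),
                           quartile_cuts_ddimer = c(0.56, 1.20, 2.80),
                           quartile_cuts_c4 = c(0.05, 0.12, 0.20),
                           code_correlation = 0,
                           cell_assignment = c("random", "balanced")) {
  cell_assignment <- match.arg(cell_assignment)
  if (n_patients < 1) abort("n_patients must be >= 1")
  stopifnot(inherits(equation, "predictive_equation"))
  for (cuts in list(quartile_cuts_ddimer, quartile_cuts_c4)) {
    if (length(cuts) != 3L || any(diff(cuts) <= 0)) {
      abort("quartile cut points must be 3 strictly ascending values")
    }
  }
  if (abs(code_correlation) > 1) abort("code_correlation must be in [-1, 1]")
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    equation = equation,
    quartile_cuts_ddimer = quartile_cuts_ddimer,
    quartile_cuts_c4 = quartile_cuts_c4,
    code_correlation = code_correlation,
    cell_assignment = cell_assignment
  ), class = "cohort3_config")
}

#' Simulate a clinical-record cohort
#'
#' Draws a cohort from the model in [cohort3_config()]. Besides D-dimer,
#' C4, their codes, SLEDAI and the activity flag, each record carries two
#' comparison markers for ROC work: serum C3 (mg/mL, lognormal, lower
#' when active) and anti-dsDNA positivity (Bernoulli, more frequent when
#' active). SLEDAI is drawn uniformly from 8..30 for active and 0..7 for
#' inactive patients, consistent with the activity threshold SLEDAI >= 8.
#'
#' @param config A [cohort3_config()].
#' @return A tibble with columns `patient_id`, `ddimer`, `c4`, `code_d`,
#'   `code_c`, `sledai`, `active`, `c3`, `anti_dsdna`.
#' @examples
#' head(gen_cohort3(cohort3_config(n_patients = 20, seed = 7)))
#' @export
gen_cohort3 <- function(config) {
  stopifnot(inherits(config, "cohort3_config"))
  n <- config$n_patients
  withr_seed(config$seed, {
    if (config$cell_assignment == "balanced") {
      cells <- tidyr::expand_grid(code_d = 1:4, code_c = 1:4)
      idx <- rep_len(seq_len(16L), n)
      code_d <- cells$code_d[idx]
      code_c <- cells$code_c[idx]
    } else {
      rho <- 2 * sin(pi * config$code_correlation / 6)  # rank -> Pearson
      z1 <- rnorm(n)
      z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * rnorm(n)
      code_d <- findInterval(pnorm(z1), c(0.25, 0.5, 0.75)) + 1L
      code_c <- findInterval(pnorm(z2), c(0.25, 0.5, 0.75)) + 1L
    }
    # uniform concentration within the code's interval
    bd <- c(0, config$quartile_cuts_ddimer, 2 * max(config$quartile_cuts_ddimer))
    bc <- c(0, config$quartile_cuts_c4, 2 * max(config$quartile_cuts_c4))
    ddimer <- runif(n, bd[code_d], bd[code_d + 1L])
    c4 <- runif(n, bc[5L - code_c], bc[6L - code_c])  # code 4 = lowest C4
    p <- predict_probability(config$equation, code_d, code_c)
    active <- runif(n) < p
    sledai <- ifelse(active,
                     sample(8:30, n, replace = TRUE),
                     sample(0:7, n, replace = TRUE))
    c3 <- rlnorm(n, meanlog = log(0.9) - 0.35 * active, sdlog = 0.25)
    anti_dsdna <- as.integer(runif(n) < ifelse(active, 0.55, 0.25))
    tibble::tibble(
      patient_id = sprintf("C%05d", seq_len(n)),
      ddimer = ddimer, c4 = c4,
      code_d = as.integer(code_d), code_c = as.integer(code_c),
      sledai = as.integer(sledai), active = active,
      c3 = c3, anti_dsdna = anti_dsdna
    )
  })
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
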