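#' Default analyte catalog
#'
#' The 21-analyte panel used throughout: seven serum complement analytes,
#' ten plasma coagulation analytes, three serum inflammatory cytokines,
#' with serum C4 (nephelometric) entering the complement pathway on the
#' inhibitor ("de-activator") side. An analyte's `role` determines the
#' sign with which its max-normalized concentration enters its pathway's
#' summary score: activators count `+1`, inhibitors `-1`.
#'
#' Activators rise with activation of their pathway; inhibitors and
#' de-activators fall. The defaults are:
#' \describe{
#'   \item{complement}{activators C3a, C4a, C5a, MASP2, C7; inhibitors
#'     C1q, FI, C4}
#'   \item{coagulation}{activators VWF, F7, TAT, FIB, F9, D-dimer;
#'     inhibitors PROS, F12, F13, ATIII}
#'   \item{cytokine}{TNF-RII, IL-6, IL-8, all activators}
#' }
#'
#' @return A tibble with columns `analyte`, `pathway`
#'   (`"complement"`, `"coagulation"` or `"cytokine"`) and `role`
#'   (`"activator"` or `"inhibitor"`).
#' @examples
#' default_catalog()
#' @export
default_catalog <- function() {
  tibble::tribble(
    ~analyte,  ~pathway,      ~role,
    "C3a",     "complement",  "activator",
    "C4a",     "complement",  "activator",
    "C5a",     "complement",  "activator",
    "MASP2",   "complement",  "activator",
    "C7",      "complement",  "activator",
    "C1q",     "complement",  "inhibitor",
    "FI",      "complement",  "inhibitor",
    "C4",      "complement",  "inhibitor",
    "VWF",     "coagulation", "activator",
    "F7",      "coagulation", "activator",
    "TAT",     "coagulation", "activator",
    "FIB",     "coagulation", "activator",
    "F9",      "coagulation", "activator",
    "D-dimer", "coagulation", "activator",
    "PROS",    "coagulation", "inhibitor",
    "F12",     "coagulation", "inhibitor",
    "F13",     "coagulation", "inhibitor",
    "ATIII",   "coagulation", "inhibitor",
    "TNF-RII", "cytokine",    "activator",
    "IL-6",    "cytokine",    "activator",
    "IL-8",    "cytokine",    "activator"
  )
}

validate_catalog <- function(catalog) {
  req <- c("analyte", "pathway", "role")
  if (!all(req %in% names(catalog))) {
    abort("catalog must have columns 'analyte', 'pathway', 'role'")
  }
  if (anyDuplicated(catalog$analyte)) {
    dup <- unique(catalog$analyte[duplicated(catalog$analyte)])
    abort(paste0("analyte(s) mapped more than once: ",
                 paste(dup, collapse = ", ")))
  }
  bad <- setdiff(unique(catalog$pathway),
                 c("complement", "coagulation", "cytokine"))
  if (length(bad)) {
    abort(paste0("unknown pathway(s): ", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(catalog$role), c("activator", "inhibitor"))
  if (length(bad)) {
    abort(paste0("unknown role(s): ", paste(bad, collapse = ", ")))
  }
  invisible(catalog)
}
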