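#' Read and validate a clinical cohort table
#'
#' Reads a CSV/TSV with a header row, applies an optional column-name
#' mapping, type-checks the fields and derives the binary activity flag
#' as SLEDAI >= 8. Rows failing validation are reported with their data
#' line numbers.
#'
#' Validation: `patient_id` must be unique; concentration columns must
#' be numeric and non-negative; `sledai` must be a non-negative integer.
#' Declared units for D-dimer (ug/mL) and C4 (mg/mL) must match the
#' quartile schemes in use, since the cut points are unit-specific; a
#' mismatch is a hard error.
#'
#' @param path Path to a CSV or TSV file (delimiter inferred from the
#'   extension, `.tsv`/`.tab` = tab).
#' @param mapping Named character vector mapping canonical names
#'   (`patient_id`, `sledai`, `ddimer`, `c4`, ...) to the file's column
#'   names, e.g. `c(sledai = "SLEDAI")`. Unmapped canonical names are
#'   looked up case-insensitively.
#' @param units Named character vector of declared units for marker
#'   columns, default `c(ddimer = "ug/mL", c4 = "mg/mL")`.
#' @param require Character vector of canonical columns that must be
#'   present, default `c("patient_id", "sledai")`.
#' @return A validated tibble with canonical column names, an `active`
#'   logical column when `sledai` is present, and attribute `"units"`.
#' @export
read_cohort <- function(path, mapping = NULL,
                        units = c(ddimer = "ug/mL", c4 = "mg/mL"),
                        require = c("patient_id", "sledai")) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  delim <- if (grepl("\\.(tsv|tab)$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  nm <- names(raw)
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  canon <- c("patient_id", "sledai", "ddimer", "c4", "c3", "anti_dsdna",
             "esr", "crp", "fib", "leukopenia", "thrombocytopenia")
  resolved <- list()
  for (cn in union(canon, names(mapping))) {
    if (!is.null(mapping) && cn %in% names(mapping)) {
      target <- mapping[[cn]]
      if (!(target %in% nm)) {
        abort(paste0("mapped column '", target, "' (for ", cn,
                     ") not found in ", path))
      }
    } else {
      target <- nm[match(norm(cn), norm(nm))]
    }
    if (!is.na(target) && target %in% nm) resolved[[cn]] <- target
  }
  missing_req <- setdiff(require, names(resolved))
  if (length(missing_req)) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_req, collapse = ", ")))
  }
  out <- tibble::as_tibble(raw[unlist(resolved)])
  names(out) <- names(resolved)

  if (anyDuplicated(out$patient_id)) {
    dup <- unique(out$patient_id[duplicated(out$patient_id)])
    abort(paste0("duplicate patient id(s): ", paste(dup, collapse = ", ")))
  }
  line_of <- function(i) i + 1L  # header is line 1
  for (col in intersect(c("ddimer", "c4", "c3", "esr", "crp", "fib"),
                        names(out))) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(!is.na(out[[col]]) & is.na(v))
    if (length(bad)) {
      abort(paste0("non-numeric ", col, " at line(s) ",
                   paste(line_of(bad), collapse = ", ")))
    }
    if (any(v < 0, na.rm = TRUE)) {
      bad <- which(v < 0)
      abort(paste0("negative ", col, " at line(s) ",
                   paste(line_of(bad), collapse = ", ")))
    }
    out[[col]] <- v
  }
  if ("sledai" %in% names(out)) {
    v <- suppressWarnings(as.numeric(out$sledai))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      abort(paste0("SLEDAI must be a non-negative integer; bad line(s) ",
                   paste(line_of(bad), collapse = ", ")))
    }
    out$sledai <- as.integer(v)
    out$active <- out$sledai >= 8L
  }
  expected <- c(ddimer = "ug/mL", c4 = "mg/mL")
  for (mk in intersect(names(expected), names(units))) {
    if (mk %in% names(out) && !identical(units[[mk]], expected[[mk]])) {
      abort(paste0("unit mismatch for ", mk, ": declared '", units[[mk]],
                   "', quartile cut points require '", expected[[mk]], "'"))
    }
  }
  attr(out, "units") <- units
  out
}

#' Write an analysis report
#'
#' Writes a machine-readable JSON report, TSV tables (including a
#' 16-row cut-off performance table when present) and a run log echoing
#' the configuration, its hash, the seed and the package version. Rerun
#' with the same results and seed produces byte-identical JSON.
#'
#' @param results A non-empty named list of stage results. Recognised
#'   elements get a TSV: `performance_table` (from [evaluate_rules()]),
#'   `or_grid` (from [or_grid()]), `scores`, `cells`.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed to record.
#' @param config Optional configuration list echoed into the log and
#'   hashed into every output.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, outdir, seed = NA_integer_,
                         config = list()) {
  if (length(results) == 0L) abort("empty results: nothing to write")
  if (is.null(names(results)) || any(names(results) == "")) {
    abort("results must be a named list")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) abort(paste0("cannot create directory: ", outdir))
  cfg_hash <- hash(list(config = config, seed = seed))
  meta <- list(seed = seed, config_hash = cfg_hash,
               package_version = as.character(packageVersion("lupuscc")))
  paths <- character(0)

  strip <- function(x) {
    if (inherits(x, "lm") || inherits(x, "glm")) return(NULL)
    if (is.list(x) && !is.data.frame(x)) {
      x <- x[!vapply(x, function(e) inherits(e, c("lm", "glm")),
                     logical(1))]
      return(lapply(x, strip))
    }
    x
  }
  json_path <- file.path(outdir, "report.json")
  jsonlite::write_json(
    c(list(meta = meta), lapply(unclass(results), strip)),
    json_path, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  paths <- c(paths, json_path)

  write_tsv_meta <- function(df, file) {
    p <- file.path(outdir, file)
    con <- file(p, "w")
    writeLines(paste0("# seed=", seed, " config_hash=", cfg_hash), con)
    close(con)
    readr::write_tsv(df, p, append = TRUE, col_names = TRUE)
    p
  }
  if (!is.null(results$performance_table)) {
    tab <- results$performance_table
    tab$cutoff <- round(tab$cutoff, 3)
    paths <- c(paths, write_tsv_meta(tab, "performance_table.tsv"))
  }
  if (!is.null(results$or_grid)) {
    paths <- c(paths, write_tsv_meta(results$or_grid$grid, "or_grid.tsv"))
  }
  for (nm in intersect(c("scores", "cells"), names(results))) {
    if (is.data.frame(results[[nm]])) {
      paths <- c(paths, write_tsv_meta(results[[nm]], paste0(nm, ".tsv")))
    }
  }
  log_path <- file.path(outdir, "run.log")
  writeLines(c(
    paste0("lupuscc ", meta$package_version),
    paste0("seed: ", seed),
    paste0("config_hash: ", cfg_hash),
    paste0("config: ", jsonlite::toJSON(config, auto_unbox = TRUE,
                                        digits = NA)),
    paste0("outputs: ", paste(basename(paths), collapse = ", "))
  ), log_path)
  paths <- c(paths, log_path)
  invisible(paths)
}
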