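# Case records, cohort container, tabular exchange format and validation.
#
# A cohort is a tibble with one row per patient specimen and a fixed column
# contract (see `cohort_columns()`).  "Unknown" is a first-class value (NA):
# the published marker tables have a different denominator for almost every
# marker, so missingness must survive a round trip through disk untouched and
# must never be coerced to "negative".

# ---- schema ----------------------------------------------------------------

# token sets for the categorical columns; NA (empty cell) = unknown everywhere
.enum_tokens <- list(
  group_truth          = c("HGBL", "BALL"),
  site                 = c("bone_marrow", "extramedullary"),
  cd45_vs_granulocytes = c("greater", "not_greater"),
  cd10_level           = c("bright_ge_hematogones", "not_bright", "negative"),
  cd20_vs_mature_b     = c("ge", "lt"),
  cd38_level           = c("bright_approx_hematogones", "not_bright"),
  tdt_flow             = c("positive", "negative"),
  cd34                 = c("positive", "negative"),
  surface_light_chain  = c("monotypic", "absent"),
  myeloid_markers      = c("positive", "negative"),
  tdt_ihc              = c("positive", "negative"),
  cyclin_d1            = c("positive", "negative")
)

.percent_cols <- c("myc_pct", "bcl6_pct", "bcl2_pct", "ki67_pct")

.flag_cols <- c("history_nhl", "myc_r", "bcl2_r", "bcl6_r", "ccnd1_r",
                "complex_karyotype", "ball_translocation",
                "tp53_mut", "kras_mut", "nras_mut")

#' Column contract of the cohort exchange format
#'
#' @return character vector of the column names, in file order.
#' @export
cohort_columns <- function() {
  c("case_id", "group_truth", "site", "history_nhl",
    "cd45_vs_granulocytes", "cd10_level", "cd20_vs_mature_b", "cd38_level",
    "tdt_flow", "cd34", "surface_light_chain", "myeloid_markers",
    "myc_pct", "bcl6_pct", "bcl2_pct", "tdt_ihc", "cyclin_d1", "ki67_pct",
    "myc_r", "bcl2_r", "bcl6_r", "ccnd1_r", "complex_karyotype",
    "ball_translocation", "tp53_mut", "kras_mut", "nras_mut")
}

#' Construct a cohort from a data frame
#'
#' Reorders/validates columns, coerces column types, and stamps provenance.
#' Missing columns are added as all-unknown except `case_id`, which is
#' mandatory.
#'
#' @param x data frame with at least a `case_id` column.
#' @param provenance one of `"fixture"`, `"synthetic"`, `"user"`.
#' @return a `blast_cohort` tibble.
#' @export
as_cohort <- function(x, provenance = "user") {
  provenance <- match.arg(provenance, c("fixture", "synthetic", "user"))
  if (!"case_id" %in% names(x)) {
    abort_blastscore("cohort must have a 'case_id' column", "cohort_schema")
  }
  x <- tibble::as_tibble(x)
  for (col in cohort_columns()) {
    if (!col %in% names(x)) x[[col]] <- NA
  }
  x <- x[, cohort_columns()]
  x$case_id <- as.character(x$case_id)
  for (col in names(.enum_tokens)) x[[col]] <- as.character(x[[col]])
  for (col in .percent_cols) x[[col]] <- as.numeric(x[[col]])
  for (col in .flag_cols) x[[col]] <- as.logical(x[[col]])
  validate_cohort(x)
  structure(x, class = c("blast_cohort", class(tibble::tibble())),
            provenance = provenance)
}

#' Validate a cohort against the column contract
#'
#' Checks case-id uniqueness, enum token validity and percent ranges.  Errors
#' name the offending case and column so malformed files are diagnosable.
#'
#' @param x cohort data frame.
#' @return `x`, invisibly, if valid.
#' @export
validate_cohort <- function(x) {
  dup <- x$case_id[duplicated(x$case_id)]
  if (length(dup) > 0) {
    abort_blastscore(
      paste0("duplicate case_id: ", paste(unique(dup), collapse = ", ")),
      "cohort_duplicate_id")
  }
  if (any(is.na(x$case_id)) || any(x$case_id == "")) {
    abort_blastscore("case_id must be non-empty for every row",
                     "cohort_schema")
  }
  for (col in names(.enum_tokens)) {
    vals <- x[[col]]
    bad <- !is.na(vals) & !(vals %in% .enum_tokens[[col]])
    if (any(bad)) {
      abort_blastscore(
        sprintf("invalid token '%s' in column '%s' (case %s); allowed: %s",
                vals[bad][1], col, x$case_id[bad][1],
                paste(.enum_tokens[[col]], collapse = ", ")),
        "cohort_bad_token")
    }
  }
  for (col in .percent_cols) {
    vals <- x[[col]]
    bad <- !is.na(vals) & (vals < 0 | vals > 100)
    if (any(bad)) {
      abort_blastscore(
        sprintf("percent out of range [0, 100] in column '%s' (case %s): %s",
                col, x$case_id[bad][1], vals[bad][1]),
        "cohort_bad_percent")
    }
  }
  invisible(x)
}

#' Cohort provenance
#' @param cohort a cohort.
#' @return `"fixture"`, `"synthetic"` or `"user"`.
#' @export
cohort_provenance <- function(cohort) {
  attr(cohort, "provenance") %||% "user"
}

# ---- readers / writers -----------------------------------------------------

#' Read a cohort from CSV or JSON
#'
#' CSV: UTF-8, comma separated, mandatory header, empty cell = unknown.
#' JSON: array of objects with the same keys; `null` or absent key = unknown.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @return a validated `blast_cohort`.
#' @export
read_cohort <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    abort_blastscore(paste0("file not found: ", path), "cohort_io")
  }
  if (format == "csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           na = "", progress = FALSE,
                           show_col_types = FALSE)
  } else {
    objs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(objs) == 0) objs <- data.frame(case_id = character())
    raw <- tibble::as_tibble(objs)
  }
  missing <- setdiff(cohort_columns(), names(raw))
  if (length(missing) > 0 && !"case_id" %in% names(raw)) {
    abort_blastscore("input lacks a 'case_id' column", "cohort_schema")
  }
  extra <- setdiff(names(raw), cohort_columns())
  if (length(extra) > 0) {
    abort_blastscore(
      paste0("unrecognized column(s): ", paste(extra, collapse = ", ")),
      "cohort_schema")
  }
  if (format == "csv") {
    # tolerate "TRUE"/"true" for flags; everything else is checked downstream
    for (col in intersect(.flag_cols, names(raw))) {
      v <- tolower(raw[[col]])
      bad <- !is.na(v) & !(v %in% c("true", "false"))
      if (any(bad)) {
        abort_blastscore(
          sprintf("invalid flag value '%s' in column '%s'", raw[[col]][bad][1], col),
          "cohort_bad_token")
      }
      raw[[col]] <- v == "true"
    }
    for (col in intersect(.percent_cols, names(raw))) {
      v <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- !is.na(raw[[col]]) & is.na(v)
      if (any(bad)) {
        abort_blastscore(
          sprintf("non-numeric percent '%s' in column '%s'", raw[[col]][bad][1], col),
          "cohort_bad_percent")
      }
      raw[[col]] <- v
    }
  }
  as_cohort(raw, provenance = "user")
}

#' Write a cohort to CSV or JSON
#'
#' `read_cohort(write_cohort(c))` reproduces `c` field for field; unknown
#' values are written as empty cells (CSV) or `null` (JSON).
#'
#' @param cohort cohort to write.
#' @param path destination path.
#' @param format `"csv"` or `"json"`; default inferred from the extension.
#' @export
write_cohort <- function(cohort, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  validate_cohort(cohort)
  out <- tibble::as_tibble(as.data.frame(cohort))[, cohort_columns()]
  if (format == "csv") {
    for (col in .flag_cols) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                           ifelse(out[[col]], "true", "false"))
    }
    readr::write_csv(out, path, na = "", progress = FALSE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# ---- TdT consolidation and per-system completeness -------------------------

#' Consolidated TdT call
#'
#' One TdT call per case for scoring: the flow-cytometry value when known,
#' else the immunohistochemistry value.  The two modalities agree in the
#' large majority of dual-tested cases; the rare discordant pattern
#' (weak/focal IHC positivity with negative flow) resolves to the flow call
#' and is flagged by [validate_for_system()].
#'
#' @param tdt_flow,tdt_ihc character vectors of `"positive"`/`"negative"`/NA.
#' @return character vector of consolidated calls (NA if neither is known).
#' @export
tdt_call <- function(tdt_flow, tdt_ihc) {
  ifelse(!is.na(tdt_flow), tdt_flow, tdt_ihc)
}

#' Per-case completeness report for a scoring system
#'
#' Lists which required inputs of the chosen system are unknown for each
#' case.  The six-point system needs the five flow criteria (CD45, CD10,
#' CD20, CD38, consolidated TdT) plus MYC evidence (IHC percent or
#' rearrangement status); the three-point system needs BCL6 percent, a TdT
#' call from either modality, and MYC evidence.
#'
#' @param cohort cohort (or any data frame with the cohort columns).
#' @param system `"six_point"` or `"three_point"`.
#' @return tibble: `case_id`, `system`, `scoreable`, `missing` (list-column
#'   of missing input names), `tdt_discordant` (both modalities known and
#'   disagreeing).
#' @export
validate_for_system <- function(cohort, system = c("six_point", "three_point")) {
  system <- match.arg(system)
  tdt <- tdt_call(cohort$tdt_flow, cohort$tdt_ihc)
  myc_known <- !is.na(cohort$myc_pct) | !is.na(cohort$myc_r)
  req <- if (system == "six_point") {
    list(cd45_vs_granulocytes = !is.na(cohort$cd45_vs_granulocytes),
         cd10_level           = !is.na(cohort$cd10_level),
         cd20_vs_mature_b     = !is.na(cohort$cd20_vs_mature_b),
         cd38_level           = !is.na(cohort$cd38_level),
         tdt                  = !is.na(tdt),
         myc                  = myc_known)
  } else {
    list(bcl6_pct = !is.na(cohort$bcl6_pct),
         tdt      = !is.na(tdt),
         myc      = myc_known)
  }
  known <- do.call(cbind, req)
  missing <- apply(known, 1, function(r) names(req)[!r], simplify = FALSE)
  tibble::tibble(
    case_id = cohort$case_id,
    system = system,
    scoreable = apply(known, 1, all),
    missing = missing,
    tdt_discordant = !is.na(cohort$tdt_flow) & !is.na(cohort$tdt_ihc) &
      cohort$tdt_flow != cohort$tdt_ihc
  )
}
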