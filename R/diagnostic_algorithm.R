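# Combined decision procedure for a blastoid B-cell neoplasm.
#
# Step order:
#   1. cyclin D1 positive or CCND1 rearranged -> mantle cell lymphoma; it is
#      excluded from the HGBL-vs-B-ALL differential up front.
#   2. CD34 positive (any subset of blasts) -> B-ALL, definitive; no score
#      can override it.
#   3. compute whichever of the two scores the available data support.
#   4. a single scoreable system whose total sits in its definitive band
#      decides on its own.
#   5. both systems scoreable and agreeing -> that shared call, firm.
#   6. disagreement (or a lone non-definitive score) -> correlate ancillary
#      clinical/genetic evidence: an unweighted signed tally over eight
#      features; ties stay indeterminate.
#   7. no scoreable system -> indeterminate.

# ancillary features and the diagnosis each one favors when present
.ancillary_features <- function() {
  tibble::tibble(
    feature = c("history_nhl", "myc_r", "complex_karyotype", "tp53_mut",
                "myeloid_markers", "kras_mut", "nras_mut",
                "ball_translocation"),
    direction = c(rep("favors_HGBL", 4), rep("favors_BALL", 4))
  )
}

# evidence tally for one case row; unknown features contribute nothing
.ancillary_tally <- function(case) {
  fired <- character(0)
  dirs <- character(0)
  for (i in seq_len(nrow(.ancillary_features()))) {
    f <- .ancillary_features()$feature[i]
    d <- .ancillary_features()$direction[i]
    v <- case[[f]]
    present <- if (f == "myeloid_markers") {
      !is.na(v) && v == "positive"
    } else {
      !is.na(v) && isTRUE(v)
    }
    if (present) {
      fired <- c(fired, f)
      dirs <- c(dirs, d)
    }
  }
  list(features = fired, directions = dirs,
       balance = sum(dirs == "favors_HGBL") - sum(dirs == "favors_BALL"))
}

#' Run the combined diagnostic algorithm on one case
#'
#' Every input yields a call; unknown fields are simply not used.  See the
#' package vignette for the full decision procedure.
#'
#' @param case one-row data frame with the cohort columns.
#' @return object of class `diagnostic_call`: list with `call` (one of
#'   `"HGBL"`, `"BALL"`, `"MCL_excluded"`, `"challenging_indeterminate"`),
#'   `pathway` (decision-step identifiers traversed), `six_result` /
#'   `three_result` (`score_result` or NULL), `ancillary_evidence`
#'   (data frame of fired features and directions) and `evidence_balance`.
#' @export
run_algorithm <- function(case) {
  case <- tibble::as_tibble(case)
  stopifnot(nrow(case) == 1)
  pathway <- character(0)
  finish <- function(call, six = NULL, three = NULL, anc = NULL) {
    structure(list(
      call = call, pathway = pathway,
      six_result = six, three_result = three,
      ancillary_evidence = if (is.null(anc)) {
        data.frame(feature = character(0), direction = character(0))
      } else {
        data.frame(feature = anc$features, direction = anc$directions)
      },
      evidence_balance = if (is.null(anc)) 0L else as.integer(anc$balance)
    ), class = "diagnostic_call")
  }

  # 1. mantle cell lymphoma exclusion
  if ((!is.na(case$cyclin_d1) && case$cyclin_d1 == "positive") ||
      isTRUE(case$ccnd1_r)) {
    pathway <- c(pathway, "mcl_exclusion")
    return(finish("MCL_excluded"))
  }
  # 2. CD34, even in a subset of blasts, is diagnostic of B-ALL
  if (!is.na(case$cd34) && case$cd34 == "positive") {
    pathway <- c(pathway, "cd34_definitive")
    return(finish("BALL"))
  }
  # 3. compute available scores
  pathway <- c(pathway, "scores_computed")
  six <- if (validate_for_system(case, "six_point")$scoreable)
    score_case(case, "six_point") else NULL
  three <- if (validate_for_system(case, "three_point")$scoreable)
    score_case(case, "three_point") else NULL

  if (is.null(six) && is.null(three)) {
    pathway <- c(pathway, "unscoreable")
    return(finish("challenging_indeterminate"))
  }
  if (xor(is.null(six), is.null(three))) {
    only <- if (is.null(six)) three else six
    if (only$definitive_band) {
      pathway <- c(pathway, "single_system_definitive")
      return(finish(only$favored, six, three))
    }
    # lone borderline score: fall back on ancillary correlation
    pathway <- c(pathway, "single_system_nondefinitive")
  } else if (six$favored == three$favored) {
    pathway <- c(pathway, "concordant_scores")
    return(finish(six$favored, six, three))
  } else {
    pathway <- c(pathway, "discordant_scores")
  }
  # 6. ancillary clinical/genetic correlation
  anc <- .ancillary_tally(case)
  if (anc$balance > 0) {
    pathway <- c(pathway, "ancillary_resolved")
    return(finish("HGBL", six, three, anc))
  }
  if (anc$balance < 0) {
    pathway <- c(pathway, "ancillary_resolved")
    return(finish("BALL", six, three, anc))
  }
  pathway <- c(pathway, "ancillary_tied")
  finish("challenging_indeterminate", six, three, anc)
}

#' @export
print.diagnostic_call <- function(x, ...) {
  cat(sprintf("<diagnostic call: %s via %s>\n", x$call,
              paste(x$pathway, collapse = " -> ")))
  invisible(x)
}

#' Classify every case of a cohort
#'
#' @param cohort cohort.
#' @return list with `calls` (tibble: `case_id`, `call`, `pathway`
#'   semicolon-joined, `six_total`, `three_total`, `evidence_balance`,
#'   `ancillary_features` semicolon-joined) and `summary` (named counts per
#'   call and per terminal pathway step; counts sum to the cohort size).
#' @export
classify_cohort <- function(cohort) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    dc <- run_algorithm(cohort[i, ])
    tibble::tibble(
      case_id = cohort$case_id[i],
      call = dc$call,
      pathway = paste(dc$pathway, collapse = ";"),
      six_total = if (is.null(dc$six_result)) NA_integer_
                  else dc$six_result$total,
      three_total = if (is.null(dc$three_result)) NA_integer_
                    else dc$three_result$total,
      evidence_balance = dc$evidence_balance,
      ancillary_features = paste(dc$ancillary_evidence$feature,
                                 collapse = ";"))
  })
  calls <- if (length(rows) == 0) {
    tibble::tibble(case_id = character(0), call = character(0),
                   pathway = character(0), six_total = integer(0),
                   three_total = integer(0), evidence_balance = integer(0),
                   ancillary_features = character(0))
  } else {
    dplyr::bind_rows(rows)
  }
  terminal <- vapply(strsplit(calls$pathway, ";"),
                     function(p) if (length(p)) p[length(p)] else NA_character_,
                     character(1))
  list(calls = calls,
       summary = list(
         n = nrow(calls),
         per_call = table(factor(calls$call,
                                 levels = c("HGBL", "BALL", "MCL_excluded",
                                            "challenging_indeterminate"))),
         per_terminal_step = if (nrow(calls)) table(terminal) else table(character(0))))
}
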