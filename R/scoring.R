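# The two additive scoring systems.
#
# Six-point (flow-cytometry focused), one point per criterion:
#   CD45 intensity > granulocytes; CD10 not bright (< hematogones, negativity
#   included); CD20 intensity >= mature B cells; CD38 bright (~ hematogones);
#   TdT negative; MYC overexpression (IHC >= 40%) and/or MYC rearrangement.
# A total of >= 3 favors blastoid HGBL, < 3 favors B-ALL.
#
# Three-point (IHC focused): BCL6 >= 30%, TdT negative, same MYC criterion.
# A total of >= 2 favors blastoid HGBL.
#
# Criteria live in a declarative table so the definitions can be amended
# without touching the scoring logic.

#' IHC percent-positive cutoffs used by the criteria
#' @return named numeric vector (`myc`, `bcl6`, `bcl2`, `cd10`).
#' @export
ihc_cutoffs <- function() {
  c(myc = 40, bcl6 = 30, bcl2 = 50, cd10 = 30)
}

#' MYC criterion: overexpression and/or rearrangement
#'
#' One point when MYC IHC is at or above the 40% cutoff, or a MYC
#' rearrangement is present by FISH/karyotype.  Rearrangement evidence alone
#' suffices when IHC was not performed (and vice versa).  Extra copies of
#' MYC without rearrangement do not count.
#'
#' @param myc_pct MYC IHC percent positive (0-100) or NA.
#' @param myc_r logical MYC rearrangement flag or NA.
#' @return 0/1 vector.
#' @export
#' @examples
#' myc_criterion(84, FALSE)  # 1
#' myc_criterion(NA, TRUE)   # 1
#' myc_criterion(39.9, FALSE) # 0
myc_criterion <- function(myc_pct, myc_r) {
  if (any(is.na(myc_pct) & is.na(myc_r))) {
    abort_blastscore(
      "MYC criterion incomputable: both myc_pct and myc_r are unknown",
      "score_incomputable")
  }
  .myc_points(myc_pct, myc_r)
}

# NA-tolerant internal form (NA when both inputs unknown)
.myc_points <- function(myc_pct, myc_r) {
  ihc_pos <- !is.na(myc_pct) & myc_pct >= ihc_cutoffs()[["myc"]]
  rearr <- !is.na(myc_r) & myc_r
  out <- as.integer(ihc_pos | rearr)
  out[is.na(myc_pct) & is.na(myc_r)] <- NA_integer_
  out
}

# per-criterion point functions, evaluated on cohort columns; return
# integer 0/1 with NA where the input is unknown
.criterion_defs <- function(system) {
  six <- list(
    cd45_gt_granulocytes = function(x)
      as.integer(x$cd45_vs_granulocytes == "greater"),
    # negativity is below hematogone level, so it satisfies "not bright"
    cd10_not_bright = function(x) {
      v <- as.integer(x$cd10_level %in% c("not_bright", "negative"))
      v[is.na(x$cd10_level)] <- NA_integer_
      v
    },
    cd20_ge_mature_b = function(x)
      as.integer(x$cd20_vs_mature_b == "ge"),
    cd38_bright = function(x)
      as.integer(x$cd38_level == "bright_approx_hematogones"),
    tdt_negative = function(x)
      as.integer(tdt_call(x$tdt_flow, x$tdt_ihc) == "negative"),
    myc_pos_or_r = function(x) .myc_points(x$myc_pct, x$myc_r)
  )
  three <- list(
    bcl6_pos = function(x) as.integer(x$bcl6_pct >= ihc_cutoffs()[["bcl6"]]),
    tdt_negative = six$tdt_negative,
    myc_pos_or_r = six$myc_pos_or_r
  )
  switch(system, six_point = six, three_point = three)
}

#' Criterion names of a scoring system, in stable order
#' @param system `"six_point"` or `"three_point"`.
#' @return character vector.
#' @export
criterion_names <- function(system = c("six_point", "three_point")) {
  names(.criterion_defs(match.arg(system)))
}

#' Favored diagnosis for a score total
#' @param total integer score total(s).
#' @param system scoring system.
#' @return `"HGBL"` or `"BALL"`.
#' @export
favored_call <- function(total, system = c("six_point", "three_point")) {
  system <- match.arg(system)
  thr <- if (system == "six_point") 3L else 2L
  ifelse(total >= thr, "HGBL", "BALL")
}

#' Is a score total in the "more definitive" band?
#'
#' Totals near the decision threshold are the ambiguous ones: a six-point
#' total of >= 4 or <= 2, or a three-point total of 3 or 0, is considered
#' more definitive for its side.
#'
#' @inheritParams favored_call
#' @return logical.
#' @export
definitive_band <- function(total, system = c("six_point", "three_point")) {
  system <- match.arg(system)
  if (system == "six_point") total >= 4L | total <= 2L else total %in% c(0L, 3L)
}

#' Score a single case
#'
#' @param case one-row data frame (or list coercible to one) with the cohort
#'   columns.
#' @param system `"six_point"` or `"three_point"`.
#' @return object of class `score_result`: list with `system`,
#'   `criterion_points` (named integer vector), `total`, `favored`,
#'   `definitive_band`.
#' @export
score_case <- function(case, system = c("six_point", "three_point")) {
  system <- match.arg(system)
  case <- tibble::as_tibble(case)
  stopifnot(nrow(case) == 1)
  defs <- .criterion_defs(system)
  pts <- vapply(defs, function(f) f(case), integer(1))
  if (anyNA(pts)) {
    abort_blastscore(
      sprintf("case %s not scoreable for %s: missing criterion input(s) %s",
              case$case_id %||% "<unnamed>", system,
              paste(names(pts)[is.na(pts)], collapse = ", ")),
      "score_incomputable")
  }
  total <- sum(pts)
  structure(
    list(system = system, criterion_points = pts, total = total,
         favored = favored_call(total, system),
         definitive_band = definitive_band(total, system)),
    class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<%s score: %d -> favors %s%s>\n", x$system, x$total, x$favored,
              if (x$definitive_band) " (definitive band)" else ""))
  print(x$criterion_points)
  invisible(x)
}

#' Six-point flow-cytometry-focused score
#'
#' @inheritParams score_case
#' @return `score_result`.
#' @export
six_point_score <- function(case) score_case(case, "six_point")

#' Three-point IHC-focused score
#'
#' @inheritParams score_case
#' @return `score_result`.
#' @export
three_point_score <- function(case) score_case(case, "three_point")

#' Score every case of a cohort
#'
#' Cases with incomplete input for the chosen system are reported with
#' `scoreable = FALSE` and NA scores, never silently dropped:
#' `sum(scoreable) + sum(!scoreable)` equals the cohort size.
#'
#' @param cohort cohort.
#' @param system `"six_point"` or `"three_point"`.
#' @return tibble: `case_id`, `system`, one 0/1 column per criterion,
#'   `total`, `favored`, `definitive_band`, `scoreable`.
#' @export
score_cohort <- function(cohort, system = c("six_point", "three_point")) {
  system <- match.arg(system)
  defs <- .criterion_defs(system)
  n <- nrow(cohort)
  out <- tibble::tibble(case_id = cohort$case_id, system = rep(system, n))
  if (n == 0) {
    for (nm in names(defs)) out[[nm]] <- integer(0)
    out$total <- integer(0)
    out$favored <- character(0)
    out$definitive_band <- logical(0)
    out$scoreable <- logical(0)
    return(out)
  }
  pts <- lapply(defs, function(f) f(cohort))
  for (nm in names(defs)) out[[nm]] <- pts[[nm]]
  mat <- do.call(cbind, pts)
  scoreable <- !apply(is.na(mat), 1, any)
  total <- ifelse(scoreable, rowSums(mat), NA_integer_)
  out$total <- as.integer(total)
  out$favored <- ifelse(scoreable, favored_call(total, system), NA_character_)
  out$definitive_band <- ifelse(scoreable, definitive_band(total, system), NA)
  out$scoreable <- scoreable
  # unscored criteria are left NA in the per-criterion columns on purpose
  out
}
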