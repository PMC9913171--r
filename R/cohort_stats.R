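# Diagnostic-performance metrics, between-system concordance, and 2x2
# Fisher exact group comparisons.

#' Diagnostic performance of predicted calls against gold labels
#'
#' Blastoid HGBL is conventionally the "positive" class, so PPV drops below
#' 100% whenever a B-ALL case scores into the HGBL range.
#'
#' @param predicted character vector of favored calls.
#' @param truth character vector of gold labels, same length, no NA.
#' @param positive label counted as the positive class (default `"HGBL"`).
#' @return object of class `performance_report`: `tp`, `fp`, `tn`, `fn`,
#'   fractions `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`
#'   (NA when a denominator is zero, never 0), and `rounded_pct`
#'   (nearest-integer percents, halves away from zero).
#' @export
performance <- function(predicted, truth, positive = "HGBL") {
  if (length(predicted) == 0) {
    abort_blastscore("performance() needs at least one prediction",
                     "stats_empty")
  }
  if (length(predicted) != length(truth) || any(is.na(truth))) {
    abort_blastscore("every prediction needs a known truth label",
                     "stats_truth")
  }
  tp <- sum(predicted == positive & truth == positive)
  fp <- sum(predicted == positive & truth != positive)
  tn <- sum(predicted != positive & truth != positive)
  fn <- sum(predicted != positive & truth == positive)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  metrics <- c(sensitivity = ratio(tp, tp + fn),
               specificity = ratio(tn, tn + fp),
               ppv = ratio(tp, tp + fp),
               npv = ratio(tn, tn + fn),
               accuracy = ratio(tp + tn, tp + fp + tn + fn))
  structure(
    c(list(tp = tp, fp = fp, tn = tn, fn = fn, positive = positive),
      as.list(metrics),
      list(rounded_pct = round_pct(100 * metrics))),
    class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance (positive = %s): tp %d fp %d tn %d fn %d>\n",
              x$positive, x$tp, x$fp, x$tn, x$fn))
  print(x$rounded_pct)
  invisible(x)
}

#' Concordance between the two scoring systems
#'
#' Compares favored diagnoses case by case over the subset scoreable in
#' both systems.  A case is *misleading* when either system's favored call
#' contradicts the gold label.
#'
#' @param six_results,three_results score tables from [score_cohort()].
#' @param truths named character vector (or tibble with `case_id`,
#'   `group_truth`) of gold labels.
#' @return object of class `concordance_report`: `n_compared`,
#'   `n_concordant`, `n_discordant`, `concordance_rate`, `n_misleading`,
#'   `misleading_ids`, `compared_ids`.
#' @export
concordance <- function(six_results, three_results, truths) {
  if (is.data.frame(truths)) {
    truths <- stats::setNames(truths$group_truth, truths$case_id)
  }
  six <- six_results[six_results$scoreable, c("case_id", "favored")]
  three <- three_results[three_results$scoreable, c("case_id", "favored")]
  both <- merge(six, three, by = "case_id", suffixes = c("_six", "_three"))
  if (nrow(both) == 0) {
    abort_blastscore("no case is scoreable in both systems", "stats_empty")
  }
  truth <- truths[both$case_id]
  agree <- both$favored_six == both$favored_three
  misleading <- both$favored_six != truth | both$favored_three != truth
  structure(list(
    n_compared = nrow(both),
    n_concordant = sum(agree),
    n_discordant = sum(!agree),
    concordance_rate = mean(agree),
    n_misleading = sum(misleading),
    misleading_ids = sort(both$case_id[misleading]),
    compared_ids = sort(both$case_id)
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "<concordance: %d/%d concordant (%s%%), %d discordant, %d misleading>\n",
    x$n_concordant, x$n_compared, round_pct(100 * x$concordance_rate),
    x$n_discordant, x$n_misleading))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability method: with margins fixed, the p-value is the sum of
#' hypergeometric probabilities of every table whose point probability does
#' not exceed that of the observed table (a small tolerance absorbs
#' floating-point ties).  This is the convention behind the p-values printed
#' in most clinical group-comparison tables; mid-p is not used.
#'
#' @param a,b group-1 positive and negative counts.
#' @param c,d group-2 positive and negative counts.
#' @return p-value in (0, 1]; degenerate margins (an all-zero row or column
#'   pair) return 1 with attribute `degenerate = TRUE`.
#' @export
#' @examples
#' fisher_exact(11, 14, 6, 35)  # ~0.018
fisher_exact <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort_blastscore("contingency counts must be non-negative integers",
                     "stats_contingency")
  }
  if (sum(counts) == 0) {
    abort_blastscore("contingency table must have at least one count",
                     "stats_contingency")
  }
  r1 <- a + b
  c1 <- a + c
  n <- sum(counts)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) {
    # one margin is degenerate: only one table is possible
    return(structure(1, degenerate = TRUE))
  }
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Compare marker prevalence between the two diagnosis groups
#'
#' Reproduces the layout of a published immunophenotype comparison table:
#' for each feature, positives/total per group over cases with known values
#' only (the published tables have a different denominator per marker), the
#' nearest-integer percent, and a two-sided Fisher exact p-value.
#'
#' @param cohort cohort with both truth groups represented.
#' @param features character vector of feature names; defaults to the full
#'   registry (see [feature_registry()]).
#' @return tibble: `feature`, `hgbl_pos`, `hgbl_n`, `hgbl_pct`, `ball_pos`,
#'   `ball_n`, `ball_pct`, `p_value`, `assessable`.
#' @export
group_compare <- function(cohort, features = feature_registry()$feature) {
  reg <- feature_registry()
  unknown <- setdiff(features, reg$feature)
  if (length(unknown) > 0) {
    abort_blastscore(paste0("unknown feature(s): ",
                            paste(unknown, collapse = ", ")),
                     "stats_feature")
  }
  groups <- cohort$group_truth
  if (!all(c("HGBL", "BALL") %in% groups)) {
    abort_blastscore("cohort must contain both HGBL and BALL cases",
                     "stats_groups")
  }
  rows <- lapply(features, function(f) {
    extract <- reg$extract[[match(f, reg$feature)]]
    v <- extract(cohort)  # logical: TRUE positive, FALSE negative, NA unknown
    cell <- function(grp) {
      vv <- v[groups == grp & !is.na(groups)]
      c(pos = sum(vv, na.rm = TRUE), n = sum(!is.na(vv)))
    }
    h <- cell("HGBL")
    b <- cell("BALL")
    assessable <- h[["n"]] > 0 && b[["n"]] > 0
    tibble::tibble(
      feature = f,
      hgbl_pos = h[["pos"]], hgbl_n = h[["n"]],
      hgbl_pct = if (h[["n"]] > 0) round_pct(100 * h[["pos"]] / h[["n"]]) else NA_real_,
      ball_pos = b[["pos"]], ball_n = b[["n"]],
      ball_pct = if (b[["n"]] > 0) round_pct(100 * b[["pos"]] / b[["n"]]) else NA_real_,
      p_value = if (assessable) {
        fisher_exact(h[["pos"]], h[["n"]] - h[["pos"]],
                     b[["pos"]], b[["n"]] - b[["pos"]])
      } else NA_real_,
      assessable = assessable)
  })
  dplyr::bind_rows(rows)
}

#' Feature registry for group comparisons
#'
#' Maps feature names to extractor functions returning a tri-state logical
#' per case (TRUE positive, FALSE negative, NA unknown).
#'
#' @return tibble with columns `feature` and `extract` (list of functions).
#' @export
feature_registry <- function() {
  enum_is <- function(col, val) function(x) {
    v <- x[[col]] == val
    v
  }
  pct_ge <- function(col, cut) function(x) x[[col]] >= cut
  flag <- function(col) function(x) x[[col]]
  tibble::tibble(
    feature = c("cd45_gt_granulocytes", "cd10_not_bright", "cd20_ge_mature_b",
                "cd38_bright", "cd34", "surface_light_chain", "tdt_negative",
                "myeloid_markers", "myc_ihc", "bcl2_ihc", "bcl6_ihc",
                "myc_r", "complex_karyotype", "ball_translocation",
                "tp53_mut", "kras_mut", "nras_mut"),
    extract = list(
      enum_is("cd45_vs_granulocytes", "greater"),
      function(x) {
        v <- x$cd10_level %in% c("not_bright", "negative")
        v[is.na(x$cd10_level)] <- NA
        v
      },
      enum_is("cd20_vs_mature_b", "ge"),
      enum_is("cd38_level", "bright_approx_hematogones"),
      enum_is("cd34", "positive"),
      enum_is("surface_light_chain", "monotypic"),
      function(x) tdt_call(x$tdt_flow, x$tdt_ihc) == "negative",
      enum_is("myeloid_markers", "positive"),
      pct_ge("myc_pct", ihc_cutoffs()[["myc"]]),
      pct_ge("bcl2_pct", ihc_cutoffs()[["bcl2"]]),
      pct_ge("bcl6_pct", ihc_cutoffs()[["bcl6"]]),
      flag("myc_r"), flag("complex_karyotype"), flag("ball_translocation"),
      flag("tp53_mut"), flag("kras_mut"), flag("nras_mut"))
  )
}

#' Full diagnostic-performance evaluation of a labelled cohort
#'
#' Scores the cohort with both systems and reports, against the gold
#' labels: per-system performance (each over its own scoreable cases),
#' the between-system concordance report, and the accuracy of a concordant
#' score (correct concordant calls / all concordant calls).
#'
#' @param cohort cohort whose `group_truth` is known for every scoreable case.
#' @param positive positive class label (default `"HGBL"`).
#' @return list: `six_performance`, `three_performance`, `concordance`,
#'   `concordant_subset` (list `n`, `n_correct`, `accuracy`), plus the two
#'   score tables (`six_scores`, `three_scores`).
#' @export
evaluate_cohort <- function(cohort, positive = "HGBL") {
  truth <- stats::setNames(cohort$group_truth, cohort$case_id)
  six <- score_cohort(cohort, "six_point")
  three <- score_cohort(cohort, "three_point")
  perf <- function(tbl) {
    keep <- tbl$scoreable
    if (any(is.na(truth[tbl$case_id[keep]]))) {
      abort_blastscore("scoreable case without a truth label", "stats_truth")
    }
    performance(tbl$favored[keep], truth[tbl$case_id[keep]], positive)
  }
  conc <- concordance(six, three, truth)
  joint <- merge(six[six$scoreable, c("case_id", "favored")],
                 three[three$scoreable, c("case_id", "favored")],
                 by = "case_id", suffixes = c("_six", "_three"))
  agree <- joint[joint$favored_six == joint$favored_three, ]
  n_correct <- sum(agree$favored_six == truth[agree$case_id])
  list(six_performance = perf(six),
       three_performance = perf(three),
       concordance = conc,
       concordant_subset = list(
         n = nrow(agree), n_correct = n_correct,
         accuracy = if (nrow(agree) > 0) n_correct / nrow(agree) else NA_real_),
       six_scores = six, three_scores = three)
}

#' TdT flow-vs-IHC modality agreement
#'
#' @param cohort cohort.
#' @return list: `n_dual` (cases with both modalities assessed),
#'   `n_concordant`, `rate` (NA when no dual-tested case exists).
#' @export
tdt_modality_concordance <- function(cohort) {
  dual <- !is.na(cohort$tdt_flow) & !is.na(cohort$tdt_ihc)
  n_dual <- sum(dual)
  n_conc <- sum(dual & cohort$tdt_flow == cohort$tdt_ihc, na.rm = TRUE)
  list(n_dual = n_dual, n_concordant = n_conc,
       rate = if (n_dual == 0) NA_real_ else n_conc / n_dual)
}
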