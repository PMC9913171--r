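# Seeded synthetic cohorts with the published marker prevalence structure,
# and a deterministic fixture cohort reconstructing the published score
# cross-tabulation.

# ---- cohort specification --------------------------------------------------

# feature names drawn per case by the generator (all Bernoulli probabilities)
.gen_features <- c(
  "cd45_gt_granulocytes", "cd10_not_bright", "cd20_ge_mature_b",
  "cd38_bright", "tdt_negative", "cd34_positive",
  "surface_light_chain_monotypic", "myeloid_markers_positive",
  "myc_ihc_positive", "bcl2_ihc_positive", "bcl6_ihc_positive",
  "myc_r", "bcl2_r", "bcl6_r", "ccnd1_r", "complex_karyotype",
  "ball_translocation", "tp53_mut", "kras_mut", "nras_mut",
  "history_nhl", "bone_marrow_site")

#' Default per-group feature prevalences
#'
#' Marginal probabilities taken from the published immunophenotype and
#' genetic comparison tables (percent columns), expressed as fractions.
#'
#' @return named list with elements `HGBL` and `BALL`, each a named numeric
#'   vector over the generator features.
#' @export
default_prevalences <- function() {
  list(
    HGBL = c(cd45_gt_granulocytes = 0.75, cd10_not_bright = 0.86,
             cd20_ge_mature_b = 0.72, cd38_bright = 0.70,
             tdt_negative = 0.83, cd34_positive = 0.00,
             surface_light_chain_monotypic = 0.75,
             myeloid_markers_positive = 0.00,
             myc_ihc_positive = 0.84, bcl2_ihc_positive = 0.85,
             bcl6_ihc_positive = 0.77,
             myc_r = 0.72, bcl2_r = 0.51, bcl6_r = 0.22, ccnd1_r = 0.00,
             complex_karyotype = 0.93, ball_translocation = 0.00,
             tp53_mut = 0.44, kras_mut = 0.00, nras_mut = 0.00,
             history_nhl = 0.33, bone_marrow_site = 0.31),
    BALL = c(cd45_gt_granulocytes = 0.23, cd10_not_bright = 0.58,
             cd20_ge_mature_b = 0.11, cd38_bright = 0.38,
             tdt_negative = 0.11, cd34_positive = 0.47,
             surface_light_chain_monotypic = 0.00,
             myeloid_markers_positive = 0.41,
             myc_ihc_positive = 0.24, bcl2_ihc_positive = 1.00,
             bcl6_ihc_positive = 0.16,
             myc_r = 0.00, bcl2_r = 0.00, bcl6_r = 0.00, ccnd1_r = 0.00,
             complex_karyotype = 0.46, ball_translocation = 0.57,
             tp53_mut = 0.15, kras_mut = 0.17, nras_mut = 0.22,
             history_nhl = 0.00, bone_marrow_site = 1.00))
}

#' Build a synthetic-cohort specification
#'
#' @param n_hgbl,n_ball group sizes (>= 0).
#' @param prevalence per-group feature prevalences, as from
#'   [default_prevalences()]; partial lists are completed with the defaults.
#' @param atypical_fraction named numeric (`HGBL`, `BALL`): probability that
#'   a case is "atypical", i.e. its `swap_features` are drawn from the
#'   *opposite* group's prevalences (an immunophenotype mimicking the other
#'   entity).  Default 0 for both.
#' @param swap_features features affected in atypical cases; defaults to the
#'   score-relevant markers.
#' @param seed integer root seed; per-case streams are derived from it by
#'   case index, so enlarging a cohort does not reshuffle existing cases.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hgbl, n_ball, prevalence = default_prevalences(),
                        atypical_fraction = c(HGBL = 0, BALL = 0),
                        swap_features = c("cd45_gt_granulocytes",
                                          "cd10_not_bright",
                                          "cd20_ge_mature_b", "cd38_bright",
                                          "tdt_negative", "myc_ihc_positive",
                                          "myc_r", "bcl6_ihc_positive"),
                        seed = 1L) {
  stopifnot(n_hgbl >= 0, n_ball >= 0)
  full <- default_prevalences()
  for (g in c("HGBL", "BALL")) {
    p <- prevalence[[g]] %||% numeric(0)
    unknown <- setdiff(names(p), .gen_features)
    if (length(unknown) > 0) {
      abort_blastscore(paste0("unknown prevalence feature(s): ",
                              paste(unknown, collapse = ", ")),
                       "spec_invalid")
    }
    full[[g]][names(p)] <- p
    if (any(full[[g]] < 0 | full[[g]] > 1)) {
      abort_blastscore(paste0("prevalence out of [0, 1] for group ", g),
                       "spec_invalid")
    }
  }
  af <- c(HGBL = 0, BALL = 0)
  af[names(atypical_fraction)] <- atypical_fraction
  if (any(af < 0 | af > 1)) {
    abort_blastscore("atypical_fraction out of [0, 1]", "spec_invalid")
  }
  stopifnot(all(swap_features %in% .gen_features))
  structure(list(n_hgbl = as.integer(n_hgbl), n_ball = as.integer(n_ball),
                 prevalence = full, atypical_fraction = af,
                 swap_features = swap_features, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Read a cohort specification from YAML
#' @param path YAML file with keys mirroring the [cohort_spec()] arguments.
#' @return `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) {
    abort_blastscore(paste0("spec file not found: ", path), "spec_io")
  }
  y <- tryCatch(yaml::read_yaml(path),
                error = function(e) abort_blastscore(
                  paste0("invalid YAML: ", conditionMessage(e)), "spec_io"))
  if (!is.list(y) || is.null(names(y)) || any(names(y) == "")) {
    abort_blastscore("spec file must be a YAML mapping of named keys",
                     "spec_invalid")
  }
  allowed <- c("n_hgbl", "n_ball", "prevalence", "atypical_fraction",
               "swap_features", "seed")
  unknown <- setdiff(names(y), allowed)
  if (length(unknown) > 0) {
    abort_blastscore(paste0("unknown spec key(s): ",
                            paste(unknown, collapse = ", ")), "spec_invalid")
  }
  args <- list(n_hgbl = y$n_hgbl %||% 0, n_ball = y$n_ball %||% 0)
  if (!is.null(y$prevalence)) {
    args$prevalence <- lapply(y$prevalence, function(p) unlist(p))
  }
  if (!is.null(y$atypical_fraction)) {
    args$atypical_fraction <- unlist(y$atypical_fraction)
  }
  if (!is.null(y$swap_features)) args$swap_features <- y$swap_features
  if (!is.null(y$seed)) args$seed <- y$seed
  do.call(cohort_spec, args)
}

# ---- generator -------------------------------------------------------------

# derived per-case seed, kept inside 32-bit integer range
.case_seed <- function(root, index) {
  as.integer((as.numeric(root) %% 2147483647 + 2654435761 * index) %% 2147483647)
}

#' Generate a seeded synthetic cohort
#'
#' One case at a time: each feature is an independent Bernoulli draw at its
#' group prevalence (atypical cases draw their `swap_features` from the
#' opposite group).  IHC percents are drawn uniformly above/below the
#' published positivity cutoff according to the Bernoulli outcome.  All
#' fields are emitted known; roughly 30% of cases get a second (IHC) TdT
#' call, concordant with flow.
#'
#' @param spec a [cohort_spec()].
#' @return `blast_cohort` with provenance `"synthetic"`; deterministic given
#'   `spec$seed`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c(rep("HGBL", spec$n_hgbl), rep("BALL", spec$n_ball))
  # stable per-group index so n changes do not reshuffle existing cases
  gidx <- c(seq_len(spec$n_hgbl), 500000L + seq_len(spec$n_ball))
  rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    other <- if (g == "HGBL") "BALL" else "HGBL"
    seed_i <- .case_seed(spec$seed, gidx[i])
    rows[[i]] <- withr::with_seed(seed_i, {
      atypical <- stats::runif(1) < spec$atypical_fraction[[g]]
      p <- spec$prevalence[[g]]
      if (atypical) {
        p[spec$swap_features] <- spec$prevalence[[other]][spec$swap_features]
      }
      draw <- stats::runif(length(.gen_features)) < p[.gen_features]
      names(draw) <- .gen_features
      u <- stats::runif(6)  # percent positions within the drawn band
      pct <- function(pos, cut, k) if (pos) cut + (100 - cut) * u[k] else cut * u[k]
      tibble::tibble(
        case_id = sprintf("S%s%05d", substr(g, 1, 1), gidx[i] %% 500000L),
        group_truth = g,
        site = if (draw[["bone_marrow_site"]]) "bone_marrow" else "extramedullary",
        history_nhl = draw[["history_nhl"]],
        cd45_vs_granulocytes = if (draw[["cd45_gt_granulocytes"]]) "greater" else "not_greater",
        cd10_level = if (draw[["cd10_not_bright"]]) "not_bright" else "bright_ge_hematogones",
        cd20_vs_mature_b = if (draw[["cd20_ge_mature_b"]]) "ge" else "lt",
        cd38_level = if (draw[["cd38_bright"]]) "bright_approx_hematogones" else "not_bright",
        tdt_flow = if (draw[["tdt_negative"]]) "negative" else "positive",
        cd34 = if (draw[["cd34_positive"]]) "positive" else "negative",
        surface_light_chain = if (draw[["surface_light_chain_monotypic"]]) "monotypic" else "absent",
        myeloid_markers = if (draw[["myeloid_markers_positive"]]) "positive" else "negative",
        myc_pct = pct(draw[["myc_ihc_positive"]], 40, 1),
        bcl6_pct = pct(draw[["bcl6_ihc_positive"]], 30, 2),
        bcl2_pct = pct(draw[["bcl2_ihc_positive"]], 50, 3),
        tdt_ihc = if (u[4] < 0.3) {
          if (draw[["tdt_negative"]]) "negative" else "positive"
        } else NA_character_,
        cyclin_d1 = "negative",
        ki67_pct = 50 + 50 * u[5],
        myc_r = draw[["myc_r"]],
        bcl2_r = draw[["bcl2_r"]],
        bcl6_r = draw[["bcl6_r"]],
        ccnd1_r = draw[["ccnd1_r"]],
        complex_karyotype = draw[["complex_karyotype"]],
        ball_translocation = draw[["ball_translocation"]],
        tp53_mut = draw[["tp53_mut"]],
        kras_mut = draw[["kras_mut"]],
        nras_mut = draw[["nras_mut"]])
    })
  }
  df <- if (length(rows) == 0) {
    tibble::tibble(case_id = character(0))
  } else {
    dplyr::bind_rows(rows)
  }
  as_cohort(df, provenance = "synthetic")
}

# ---- analytic score distribution (oracle for the simulator) ----------------

#' Criterion probabilities implied by feature prevalences
#'
#' The MYC criterion is satisfied by IHC overexpression and/or
#' rearrangement, so under feature independence its probability is
#' `1 - (1 - p_ihc) (1 - p_rearr)`.
#'
#' @param prevalence named numeric feature prevalences for one group.
#' @param system scoring system.
#' @return named numeric over the system's criteria, in stable order.
#' @export
criterion_prevalences <- function(prevalence,
                                  system = c("six_point", "three_point")) {
  system <- match.arg(system)
  myc <- 1 - (1 - prevalence[["myc_ihc_positive"]]) * (1 - prevalence[["myc_r"]])
  if (system == "six_point") {
    c(cd45_gt_granulocytes = prevalence[["cd45_gt_granulocytes"]],
      cd10_not_bright = prevalence[["cd10_not_bright"]],
      cd20_ge_mature_b = prevalence[["cd20_ge_mature_b"]],
      cd38_bright = prevalence[["cd38_bright"]],
      tdt_negative = prevalence[["tdt_negative"]],
      myc_pos_or_r = myc)
  } else {
    c(bcl6_pos = prevalence[["bcl6_ihc_positive"]],
      tdt_negative = prevalence[["tdt_negative"]],
      myc_pos_or_r = myc)
  }
}

#' Exact score-total distribution under criterion independence
#'
#' Enumerates all 2^k criterion patterns (k = 6 or 3) and accumulates their
#' probabilities by total.  Serves as the closed-form oracle against which
#' Monte-Carlo cohorts from [generate_cohort()] are validated.
#'
#' @param prev named numeric of per-criterion probabilities, in the order of
#'   [criterion_names()] (names are checked if present).
#' @param system scoring system.
#' @return numeric vector of probabilities named `"0"`..`"k"`; sums to 1.
#' @export
analytic_score_distribution <- function(prev,
                                        system = c("six_point", "three_point")) {
  system <- match.arg(system)
  k <- if (system == "six_point") 6L else 3L
  stopifnot(length(prev) == k, all(prev >= 0 & prev <= 1))
  if (!is.null(names(prev))) {
    stopifnot(identical(names(prev), criterion_names(system)))
  }
  patterns <- as.matrix(expand.grid(rep(list(0:1), k)))
  pr <- apply(patterns, 1, function(pat) {
    prod(ifelse(pat == 1, prev, 1 - prev))
  })
  totals <- rowSums(patterns)
  out <- vapply(0:k, function(t) sum(pr[totals == t]), numeric(1))
  stats::setNames(out, as.character(0:k))
}

# ---- fixture cohort --------------------------------------------------------

#' Deterministic fixture cohort reconstructing the published counts
#'
#' Builds 121 blastoid-HGBL plus 47 B-ALL case records, with no randomness,
#' such that running the pipeline reproduces the published structure:
#'
#' * 92 HGBL cases scoreable by the six-point system (33 bone marrow, 59
#'   extramedullary), all with total >= 3: 69 at >= 4 and 23 at exactly 3;
#' * 46 scoreable B-ALL cases: 40 at <= 2 and 6 at exactly 3, one of the
#'   six CD34-positive, the other five CD34-negative with myeloid marker
#'   expression (three carrying B-ALL-type translocations);
#' * a 101-case subset scoreable by both systems (64 HGBL with 59 three-point
#'   totals >= 2 and 5 below; 37 B-ALL partitioned 5/1/2/29 over the
#'   six-by-three score quadrants);
#' * a dual-modality TdT subtable of 23 HGBL (21 concordant, 2 IHC-positive/
#'   flow-negative) and 17 concordant B-ALL cases;
#' * exact marginal counts for CD45 (72/96 vs 11/47), myeloid markers
#'   (0/30 vs 19/46), CD34 (0/96 vs 22/47) and the mutation/karyotype
#'   denominators; remaining marginals are approximated (see the vignette).
#'
#' Cases outside the scoreable subsets carry unknowns in the corresponding
#' fields, so subset sizes emerge from [validate_for_system()] rather than
#' being tagged.  Criterion-level patterns, which are under-determined by
#' the totals, are laid out block-wise in the stable criterion order
#' (smallest pattern blocks first within each total) so rebuilds are
#' byte-identical.
#'
#' @return `blast_cohort` of 168 cases with provenance `"fixture"`.
#' @export
build_fixture_cohort <- function() {
  cohort <- dplyr::bind_rows(.fixture_hgbl(), .fixture_ball())
  out <- as_cohort(cohort, provenance = "fixture")
  .check_fixture(out)
  out
}

# blank case skeleton
.blank_cases <- function(ids, group) {
  df <- tibble::as_tibble(
    stats::setNames(rep(list(rep(NA, length(ids))), length(cohort_columns())),
                    cohort_columns()))
  df$case_id <- ids
  df$group_truth <- group
  df
}

.fixture_hgbl <- function() {
  n <- 121
  x <- .blank_cases(sprintf("H%03d", seq_len(n)), "HGBL")

  # six-point criterion patterns for the 92 scoreable cases, columns in the
  # stable criterion order; rows 1-23 total 6, 24-69 total 5, 70-92 total 3
  pat <- matrix(1L, nrow = 92, ncol = 6,
                dimnames = list(NULL, c("cd45", "cd10", "cd20", "cd38",
                                        "tdt", "myc")))
  pat[24:31, "cd45"] <- 0L
  pat[32:37, "cd10"] <- 0L
  pat[38:47, "cd20"] <- 0L
  pat[48:59, "cd38"] <- 0L
  pat[60:68, "tdt"] <- 0L
  pat[69, "myc"] <- 0L
  pat[70:85, c("cd45", "cd20", "cd38")] <- 0L
  pat[86:92, c("cd10", "tdt", "myc")] <- 0L

  sc <- 1:92
  x$cd45_vs_granulocytes[sc] <- ifelse(pat[, "cd45"] == 1, "greater", "not_greater")
  x$cd10_level[sc] <- ifelse(pat[, "cd10"] == 1, "not_bright", "bright_ge_hematogones")
  x$cd20_vs_mature_b[sc] <- ifelse(pat[, "cd20"] == 1, "ge", "lt")
  x$cd38_level[sc] <- ifelse(pat[, "cd38"] == 1, "bright_approx_hematogones", "not_bright")
  x$tdt_flow[sc] <- ifelse(pat[, "tdt"] == 1, "negative", "positive")
  # dual-modality TdT: cases 1-23; 1-2 are the discordant pair (weak IHC
  # positivity, negative flow), 3-23 concordant negative
  x$tdt_ihc[1:2] <- "positive"
  x$tdt_ihc[3:23] <- "negative"
  # MYC: criterion met except rows 69 and 86-92; cases 18-23 carry the
  # criterion by rearrangement alone (IHC not performed)
  myc_met <- pat[, "myc"] == 1
  x$myc_pct[sc] <- ifelse(myc_met, 80, 0)
  x$myc_pct[18:23] <- NA
  x$myc_pct[93:99] <- 0   # IHC-assessed outside the flow-scoreable set
  x$myc_r[sc] <- myc_met
  x$myc_r[93:95] <- TRUE
  x$myc_r[96:121] <- FALSE

  # four cases with flow assessed but CD20/TdT not evaluable (not scoreable)
  x$cd45_vs_granulocytes[93:96] <- "greater"
  x$cd10_level[93:96] <- "not_bright"
  x$cd38_level[93:95] <- "bright_approx_hematogones"
  x$cd38_level[96] <- "not_bright"

  x$cd34[1:96] <- "negative"
  x$surface_light_chain[1:72] <- "monotypic"
  x$surface_light_chain[73:96] <- "absent"
  x$myeloid_markers[1:30] <- "negative"

  # BCL6 IHC: known for the 64-case comparison subset (cases 1-59 and
  # 86-90) and for cases without complete flow panels; 72/93 positive
  x$bcl6_pct[1:49] <- 77
  x$bcl6_pct[50:59] <- 10
  x$bcl6_pct[86:90] <- 77
  x$bcl6_pct[93:110] <- 77
  x$bcl6_pct[111:121] <- 10

  x$bcl2_pct[1:98] <- 90
  x$bcl2_pct[99:115] <- 10
  x$ki67_pct[1:91] <- 90
  x$ki67_pct[92:121] <- 60
  x$cyclin_d1[] <- "negative"
  x$ccnd1_r[] <- FALSE
  x$bcl2_r[] <- c(rep(TRUE, 62), rep(FALSE, 59))
  x$bcl6_r[] <- c(rep(TRUE, 29), rep(FALSE, 92))

  x$site[] <- "extramedullary"
  x$site[c(1:33, 97:100)] <- "bone_marrow"
  x$history_nhl[] <- c(rep(TRUE, 40), rep(FALSE, 81))

  x$complex_karyotype[1:53] <- TRUE
  x$complex_karyotype[54:57] <- FALSE
  x$ball_translocation[1:57] <- FALSE
  x$tp53_mut[1:11] <- TRUE
  x$tp53_mut[12:25] <- FALSE
  x$kras_mut[1:25] <- FALSE
  x$nras_mut[1:25] <- FALSE
  x
}

.fixture_ball <- function() {
  n <- 47
  x <- .blank_cases(sprintf("B%03d", seq_len(n)), "BALL")

  pat <- matrix(0L, nrow = 46, ncol = 6,
                dimnames = list(NULL, c("cd45", "cd10", "cd20", "cd38",
                                        "tdt", "myc")))
  pat[1, c("cd38", "tdt", "myc")] <- 1L        # CD34+ case, score 3
  pat[2:6, c("cd45", "cd10", "cd38")] <- 1L    # CD34-/myeloid+ score-3 cases
  pat[7:8, c("cd38", "tdt")] <- 1L
  pat[9:10, c("cd10", "tdt")] <- 1L
  pat[11:18, c("cd10", "myc")] <- 1L
  pat[19:22, "cd10"] <- 1L
  pat[23:28, c("cd45", "cd38")] <- 1L
  pat[29:33, c("cd10", "cd20")] <- 1L
  pat[34:35, "cd38"] <- 1L
  pat[36:37, "cd10"] <- 1L
  pat[38:39, "cd38"] <- 1L

  sc <- 1:46
  x$cd45_vs_granulocytes[sc] <- ifelse(pat[, "cd45"] == 1, "greater", "not_greater")
  x$cd45_vs_granulocytes[47] <- "not_greater"
  x$cd10_level[sc] <- ifelse(pat[, "cd10"] == 1, "not_bright", "bright_ge_hematogones")
  x$cd10_level[47] <- "not_bright"
  x$cd20_vs_mature_b[sc] <- ifelse(pat[, "cd20"] == 1, "ge", "lt")
  x$cd38_level[sc] <- ifelse(pat[, "cd38"] == 1, "bright_approx_hematogones", "not_bright")
  x$cd38_level[47] <- "not_bright"
  x$tdt_flow[sc] <- ifelse(pat[, "tdt"] == 1, "negative", "positive")
  x$tdt_ihc[2:18] <- x$tdt_flow[2:18]  # 17 dual-tested, all concordant

  # MYC IHC assessed in the 37-case comparison subset; rearrangement status
  # known (negative) in 44
  x$myc_pct[1:37] <- ifelse(pat[1:37, "myc"] == 1, 80, 0)
  x$myc_r[4:47] <- FALSE

  # BCL6 IHC assessed in the same 37 cases; 6 positive
  x$bcl6_pct[1:37] <- 5
  x$bcl6_pct[c(7, 8, 19:22)] <- 77

  x$cd34[] <- "negative"
  x$cd34[c(1, 9:18, 23:33)] <- "positive"
  x$surface_light_chain[1:5] <- "absent"
  x$myeloid_markers[1:46] <- "negative"
  x$myeloid_markers[c(2:6, 9:22)] <- "positive"

  # translocations: BCR::ABL1 in seven CD34+ cases, MLL/TCF3-type in twenty
  # CD34- cases (three of them among the score-3 myeloid+ cases)
  x$ball_translocation[] <- FALSE
  x$ball_translocation[c(2:4, 7:15, 19:22, 34:44)] <- TRUE
  x$complex_karyotype[1:19] <- TRUE
  x$complex_karyotype[20:41] <- FALSE
  x$complex_karyotype[42:47] <- NA
  x$tp53_mut[2:7] <- TRUE
  x$tp53_mut[c(1, 8:41)] <- FALSE
  x$kras_mut[8:14] <- TRUE
  x$kras_mut[c(1:7, 15:41)] <- FALSE
  x$nras_mut[15:23] <- TRUE
  x$nras_mut[c(1:14, 24:41)] <- FALSE

  x$bcl2_pct[1:7] <- 90
  x$ki67_pct[1:37] <- 95
  x$cyclin_d1[] <- "negative"
  x$ccnd1_r[] <- FALSE
  x$bcl2_r[] <- FALSE
  x$bcl6_r[] <- FALSE
  x$site[] <- "bone_marrow"
  x$history_nhl[] <- FALSE
  x
}

# internal invariants of the fixture; violation is a construction bug
.check_fixture <- function(cohort) {
  six <- score_cohort(cohort, "six_point")
  three <- score_cohort(cohort, "three_point")
  hg <- cohort$group_truth == "HGBL"
  s6h <- six$scoreable & hg
  check <- function(ok, what) {
    if (!ok) abort_blastscore(paste0("fixture invariant violated: ", what),
                              "fixture_invariant")
  }
  check(sum(s6h) == 92, "92 six-point-scoreable HGBL cases")
  check(sum(six$total[s6h] >= 4) == 69 && sum(six$total[s6h] == 3) == 23,
        "HGBL six-point totals 69 at >=4 and 23 at 3")
  check(sum(cohort$site[s6h] == "bone_marrow") == 33,
        "33 bone-marrow cases among scoreable HGBL")
  s6b <- six$scoreable & !hg
  check(sum(s6b) == 46, "46 six-point-scoreable B-ALL cases")
  check(sum(six$total[s6b] == 3) == 6 && sum(six$total[s6b] <= 2) == 40,
        "B-ALL six-point totals 6 at 3 and 40 at <=2")
  joint <- six$scoreable & three$scoreable
  check(sum(joint & hg) == 64 && sum(joint & !hg) == 37,
        "joint comparison subset of 64 HGBL and 37 B-ALL")
  t3 <- three$total
  check(sum(joint & hg & t3 >= 2) == 59 && sum(joint & hg & t3 < 2) == 5,
        "HGBL three-point totals 59 at >=2 and 5 below")
  q <- table(six = six$total[joint & !hg] >= 3, three = t3[joint & !hg] >= 2)
  check(q["TRUE", "FALSE"] == 5 && q["TRUE", "TRUE"] == 1 &&
          q["FALSE", "TRUE"] == 2 && q["FALSE", "FALSE"] == 29,
        "B-ALL score quadrants 5/1/2/29")
  both_high <- joint & !hg & six$total >= 3 & t3 >= 2
  check(sum(cohort$cd34[both_high] == "positive", na.rm = TRUE) == 1,
        "the doubly misleading B-ALL case is CD34 positive")
  tdt <- tdt_modality_concordance(cohort)
  check(tdt$n_dual == 40 && tdt$n_concordant == 38,
        "TdT dual-modality subtable 38/40 concordant")
  invisible(cohort)
}
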