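# Fixtures built in code: single-case constructors and random cohorts.

# one-row case with every field unknown unless overridden
make_case <- function(case_id = "C1", ...) {
  x <- stats::setNames(rep(list(NA), length(cohort_columns())),
                       cohort_columns())
  x$case_id <- case_id
  over <- list(...)
  stopifnot(all(names(over) %in% cohort_columns()))
  x[names(over)] <- over
  tibble::as_tibble(x)
}

# prototypical blastoid-HGBL immunophenotype (scores 6 and 3 in the systems)
hgbl_case <- function(case_id = "H1", ...) {
  defaults <- list(
    group_truth = "HGBL", site = "extramedullary", history_nhl = TRUE,
    cd45_vs_granulocytes = "greater", cd10_level = "not_bright",
    cd20_vs_mature_b = "ge", cd38_level = "bright_approx_hematogones",
    tdt_flow = "negative", cd34 = "negative",
    surface_light_chain = "monotypic", myeloid_markers = "negative",
    myc_pct = 84, bcl6_pct = 77, bcl2_pct = 90, cyclin_d1 = "negative",
    ki67_pct = 95, myc_r = TRUE, ccnd1_r = FALSE, complex_karyotype = TRUE,
    ball_translocation = FALSE, tp53_mut = TRUE, kras_mut = FALSE,
    nras_mut = FALSE)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(make_case, c(list(case_id = case_id), defaults))
}

# prototypical B-ALL immunophenotype (scores 0 in both systems)
ball_case <- function(case_id = "B1", ...) {
  defaults <- list(
    group_truth = "BALL", site = "bone_marrow", history_nhl = FALSE,
    cd45_vs_granulocytes = "not_greater", cd10_level = "bright_ge_hematogones",
    cd20_vs_mature_b = "lt", cd38_level = "not_bright",
    tdt_flow = "positive", cd34 = "negative",
    surface_light_chain = "absent", myeloid_markers = "positive",
    myc_pct = 0, bcl6_pct = 0, bcl2_pct = 95, cyclin_d1 = "negative",
    ki67_pct = 90, myc_r = FALSE, ccnd1_r = FALSE, complex_karyotype = FALSE,
    ball_translocation = TRUE, tp53_mut = FALSE, kras_mut = FALSE,
    nras_mut = FALSE)
  over <- list(...)
  defaults[names(over)] <- over
  do.call(make_case, c(list(case_id = case_id), defaults))
}

# case realising a given six-point criterion pattern (0/1 vector in the
# stable criterion order); non-criterion fields stay unknown
pattern_case <- function(bits, case_id = "P1") {
  stopifnot(length(bits) == 6)
  make_case(
    case_id = case_id,
    cd45_vs_granulocytes = if (bits[1] == 1) "greater" else "not_greater",
    cd10_level = if (bits[2] == 1) "not_bright" else "bright_ge_hematogones",
    cd20_vs_mature_b = if (bits[3] == 1) "ge" else "lt",
    cd38_level = if (bits[4] == 1) "bright_approx_hematogones" else "not_bright",
    tdt_flow = if (bits[5] == 1) "negative" else "positive",
    myc_pct = if (bits[6] == 1) 80 else 0,
    myc_r = FALSE)
}

# random valid cohort (enum draws including unknown) for round-trip tests
random_cohort <- function(n, seed) {
  withr::with_seed(seed, {
    pick <- function(tokens) sample(c(tokens, NA), n, replace = TRUE)
    pct <- function() ifelse(stats::runif(n) < 0.2, NA,
                             round(stats::runif(n, 0, 100), 1))
    flag <- function() sample(c(TRUE, FALSE, NA), n, replace = TRUE)
    as_cohort(tibble::tibble(
      case_id = sprintf("R%04d", seq_len(n)),
      group_truth = pick(c("HGBL", "BALL")),
      site = pick(c("bone_marrow", "extramedullary")),
      history_nhl = flag(),
      cd45_vs_granulocytes = pick(c("greater", "not_greater")),
      cd10_level = pick(c("bright_ge_hematogones", "not_bright", "negative")),
      cd20_vs_mature_b = pick(c("ge", "lt")),
      cd38_level = pick(c("bright_approx_hematogones", "not_bright")),
      tdt_flow = pick(c("positive", "negative")),
      cd34 = pick(c("positive", "negative")),
      surface_light_chain = pick(c("monotypic", "absent")),
      myeloid_markers = pick(c("positive", "negative")),
      myc_pct = pct(), bcl6_pct = pct(), bcl2_pct = pct(),
      tdt_ihc = pick(c("positive", "negative")),
      cyclin_d1 = pick(c("positive", "negative")),
      ki67_pct = pct(),
      myc_r = flag(), bcl2_r = flag(), bcl6_r = flag(), ccnd1_r = flag(),
      complex_karyotype = flag(), ball_translocation = flag(),
      tp53_mut = flag(), kras_mut = flag(), nras_mut = flag()))
  })
}

# the fixture cohort is used across test files; build it once
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_fixture_cohort()
    cache
  }
})

# brute-force two-sided Fisher p-value: enumerate every table with the
# observed margins and sum the probabilities (binomial-coefficient form)
# of tables no more probable than the observed one
oracle_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  tab_prob <- function(x) {
    choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  }
  probs <- vapply(xs, tab_prob, numeric(1))
  min(1, sum(probs[probs <= tab_prob(a) * (1 + 1e-7)]))
}
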