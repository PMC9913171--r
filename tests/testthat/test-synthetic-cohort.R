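test_that("generation is deterministic and extends without reshuffling", {
  sp <- cohort_spec(n_hgbl = 30, n_ball = 20, seed = 5)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(cohort_provenance(a), "synthetic")

  # enlarging the cohort leaves the original cases untouched
  bigger <- generate_cohort(cohort_spec(n_hgbl = 35, n_ball = 25, seed = 5))
  expect_identical(as.data.frame(bigger[bigger$case_id %in% a$case_id, ]),
                   as.data.frame(a))
})

test_that("empty specifications give empty cohorts", {
  expect_equal(nrow(generate_cohort(cohort_spec(0, 0, seed = 1))), 0)
})

test_that("invalid specifications are rejected", {
  expect_error(cohort_spec(5, 5, prevalence = list(HGBL = c(myc_r = 1.2))),
               class = "spec_invalid")
  expect_error(cohort_spec(5, 5, prevalence = list(HGBL = c(nonsense = 0.5))),
               class = "spec_invalid")
  expect_error(cohort_spec(5, 5, atypical_fraction = c(HGBL = -0.1)),
               class = "spec_invalid")
})

test_that("empirical feature frequencies recover the specified prevalences", {
  n <- 5000
  co <- generate_cohort(cohort_spec(n_hgbl = n, n_ball = 0, seed = 104729))
  p <- default_prevalences()$HGBL
  emp <- c(
    cd45_gt_granulocytes = mean(co$cd45_vs_granulocytes == "greater"),
    cd10_not_bright = mean(co$cd10_level == "not_bright"),
    cd20_ge_mature_b = mean(co$cd20_vs_mature_b == "ge"),
    cd38_bright = mean(co$cd38_level == "bright_approx_hematogones"),
    tdt_negative = mean(tdt_call(co$tdt_flow, co$tdt_ihc) == "negative"),
    cd34_positive = mean(co$cd34 == "positive"),
    myc_ihc_positive = mean(co$myc_pct >= 40),
    bcl6_ihc_positive = mean(co$bcl6_pct >= 30),
    myc_r = mean(co$myc_r),
    complex_karyotype = mean(co$complex_karyotype),
    tp53_mut = mean(co$tp53_mut),
    bone_marrow_site = mean(co$site == "bone_marrow"))
  for (f in names(emp)) {
    half_band <- stats::qnorm(0.995) * sqrt(p[[f]] * (1 - p[[f]]) / n)
    expect_lt(abs(emp[[f]] - p[[f]]), max(half_band, 1e-12) + 1e-12,
              label = paste("frequency of", f))
  }
})

test_that("the analytic score distribution matches closed forms", {
  unit <- analytic_score_distribution(rep(1, 6), "six_point")
  expect_equal(unname(unit), c(rep(0, 6), 1))

  half <- analytic_score_distribution(rep(0.5, 6), "six_point")
  expect_equal(unname(half), dbinom(0:6, 6, 0.5))
  expect_equal(sum(half[as.character(3:6)]), 42 / 64)

  mixed <- analytic_score_distribution(c(0.2, 0.9, 0.5), "three_point")
  expect_equal(sum(mixed), 1)
})

test_that("Monte-Carlo score totals agree with the analytic distribution", {
  n <- 2000
  co <- generate_cohort(cohort_spec(n_hgbl = 0, n_ball = n, seed = 271828))
  six <- score_cohort(co, "six_point")
  expect_true(all(six$scoreable))  # synthetic cases are fully observed
  probs <- analytic_score_distribution(
    criterion_prevalences(default_prevalences()$BALL, "six_point"),
    "six_point")
  counts <- tabulate(six$total + 1L, nbins = 7)
  gof <- suppressWarnings(stats::chisq.test(counts, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("the atypical mixture pushes opposite-group cases across threshold", {
  base <- cohort_spec(n_hgbl = 0, n_ball = 1000, seed = 17)
  mixed <- cohort_spec(n_hgbl = 0, n_ball = 1000, seed = 17,
                       atypical_fraction = c(BALL = 0.1))
  n_high <- function(sp) {
    s <- score_cohort(generate_cohort(sp), "six_point")
    sum(s$total >= 3)
  }
  expect_gt(n_high(mixed), n_high(base))
})

test_that("the fixture cohort is deterministic to the byte", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(build_fixture_cohort(), p1)
  write_cohort(build_fixture_cohort(), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("the fixture satisfies the reconstructed study structure", {
  fx <- fixture_cohort()
  expect_equal(cohort_provenance(fx), "fixture")
  six <- score_cohort(fx, "six_point")
  three <- score_cohort(fx, "three_point")
  hg <- fx$group_truth == "HGBL"

  s6h <- six$scoreable & hg
  expect_equal(sum(s6h), 92)
  expect_equal(sum(six$total[s6h] >= 4), 69)
  expect_equal(sum(six$total[s6h] == 3), 23)
  expect_true(all(six$total[s6h] >= 3))
  expect_equal(sum(fx$site[s6h] == "bone_marrow"), 33)
  expect_equal(sum(fx$site[s6h] == "extramedullary"), 59)

  s6b <- six$scoreable & !hg
  expect_equal(sum(s6b), 46)
  expect_equal(sum(six$total[s6b] == 3), 6)
  expect_equal(sum(six$total[s6b] <= 2), 40)

  joint <- six$scoreable & three$scoreable
  expect_equal(sum(joint & hg), 64)
  expect_equal(sum(joint & !hg), 37)
  expect_equal(sum(joint & hg & three$total >= 2), 59)
  expect_equal(sum(joint & hg & three$total < 2), 5)
  quad <- table(six_high = six$total[joint & !hg] >= 3,
                three_high = three$total[joint & !hg] >= 2)
  expect_equal(unname(quad["TRUE", "FALSE"]), 5)
  expect_equal(unname(quad["TRUE", "TRUE"]), 1)
  expect_equal(unname(quad["FALSE", "TRUE"]), 2)
  expect_equal(unname(quad["FALSE", "FALSE"]), 29)

  # the doubly misleading B-ALL case is the CD34-positive one
  both_high <- joint & !hg & six$total >= 3 & three$total >= 2
  expect_equal(sum(both_high), 1)
  expect_equal(fx$cd34[both_high], "positive")
  # the other five score-3 B-ALL cases express myeloid antigens
  s3 <- s6b & six$total == 3 & !both_high
  expect_true(all(fx$cd34[s3] == "negative"))
  expect_true(all(fx$myeloid_markers[s3] == "positive"))
})

test_that("the bundled YAML spec loads and mirrors the defaults", {
  path <- system.file("extdata", "default_cohort_spec.yaml",
                      package = "blastscore")
  sp <- read_cohort_spec(path)
  expect_equal(sp$n_hgbl, 121L)
  expect_equal(sp$n_ball, 47L)
  expect_equal(sp$prevalence$HGBL[names(default_prevalences()$HGBL)],
               default_prevalences()$HGBL)
  expect_equal(sp$prevalence$BALL[names(default_prevalences()$BALL)],
               default_prevalences()$BALL)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("n_hgbl: 3\nunexpected_key: 1", bad)
  expect_error(read_cohort_spec(bad), class = "spec_invalid")
})
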