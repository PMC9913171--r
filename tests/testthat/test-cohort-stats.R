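test_that("Fisher exact reproduces published mutation-table p-values", {
  expect_equal(round(fisher_exact(11, 14, 6, 35), 3), 0.018)  # TP53
  expect_equal(round(fisher_exact(0, 25, 7, 34), 3), 0.039)   # KRAS
  expect_equal(round(fisher_exact(0, 25, 9, 32), 3), 0.011)   # NRAS
  expect_equal(fisher_exact(5, 5, 5, 5), 1)
})

test_that("Fisher exact agrees with enumeration and the stats oracle", {
  # exhaustive check against the brute-force oracle at small totals
  for (n in 1:14) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      expect_equal(as.numeric(fisher_exact(a, b, cc, d)),
                   oracle_fisher(a, b, cc, d))
    }
  }
  # random larger tables against the independent implementation in stats
  withr::with_seed(99, {
    for (i in 1:200) {
      t <- rmultinom(1, size = sample(4:120, 1), prob = runif(4, 0.05, 1))
      expect_equal(as.numeric(fisher_exact(t[1], t[2], t[3], t[4])),
                   stats::fisher.test(matrix(t, 2))$p.value,
                   tolerance = 1e-8)
    }
  })
})

test_that("Fisher exact is symmetric and flags degenerate margins", {
  withr::with_seed(3, {
    for (i in 1:50) {
      t <- sample(0:15, 4, replace = TRUE)
      if (sum(t) == 0) t[1] <- 1
      p <- fisher_exact(t[1], t[2], t[3], t[4])
      expect_equal(p, fisher_exact(t[3], t[4], t[1], t[2]))  # swap groups
      expect_equal(p, fisher_exact(t[2], t[1], t[4], t[3]))  # swap labels
      expect_gt(p, 0)
      expect_lte(p, 1)
    }
  })
  deg <- fisher_exact(0, 3, 0, 5)
  expect_equal(as.numeric(deg), 1)
  expect_true(attr(deg, "degenerate"))
  expect_error(fisher_exact(0, 0, 0, 0), class = "stats_contingency")
})

test_that("performance metrics follow their defining ratios", {
  perfect <- performance(rep(c("HGBL", "BALL"), each = 5),
                         rep(c("HGBL", "BALL"), each = 5))
  expect_equal(unname(perfect$rounded_pct), rep(100, 5))

  allpos <- performance(rep("HGBL", 20), rep(c("HGBL", "BALL"), each = 10))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$accuracy, 0.5)
  expect_true(is.na(allpos$npv))  # zero denominator reported NA, never 0

  withr::with_seed(21, {
    pred <- sample(c("HGBL", "BALL"), 60, replace = TRUE)
    truth <- sample(c("HGBL", "BALL"), 60, replace = TRUE)
    p <- performance(pred, truth)
    # sensitivity + false-negative rate = 1
    expect_equal(p$sensitivity + p$fn / (p$tp + p$fn), 1)
    # accuracy is the prevalence-weighted mean of sensitivity and specificity
    npos <- p$tp + p$fn
    nneg <- p$tn + p$fp
    expect_equal(p$accuracy,
                 (p$sensitivity * npos + p$specificity * nneg) / (npos + nneg))
  })
  expect_error(performance(character(0), character(0)), class = "stats_empty")
})

test_that("rounded percents print like the published tables", {
  expect_equal(round_pct(100 * 40 / 46), 87)
  expect_equal(round_pct(100 * 33 / 39), 85)
  expect_equal(round_pct(86.5), 87)   # halves away from zero
  expect_equal(round_pct(-86.5), -87)
})

test_that("between-system concordance counts agreements and misleads", {
  fx <- fixture_cohort()
  six <- score_cohort(fx, "six_point")
  three <- score_cohort(fx, "three_point")
  rep <- concordance(six, three, fx)
  expect_equal(rep$n_compared, 101)
  expect_equal(rep$n_discordant, 12)
  expect_equal(rep$n_misleading, 13)
  expect_equal(rep$n_concordant + rep$n_discordant, rep$n_compared)

  # identical favored calls give rate 1
  same <- concordance(six, six, fx)
  expect_equal(same$concordance_rate, 1)

  # hand-built four-case comparison with one disagreement
  mk <- function(favored) tibble::tibble(
    case_id = paste0("c", 1:4), favored = favored, scoreable = TRUE)
  hand <- concordance(mk(c("HGBL", "HGBL", "BALL", "BALL")),
                      mk(c("HGBL", "HGBL", "BALL", "HGBL")),
                      stats::setNames(rep("HGBL", 4), paste0("c", 1:4)))
  expect_equal(hand$concordance_rate, 0.75)

  none <- mk(c("HGBL", "HGBL", "BALL", "BALL"))
  none$scoreable <- FALSE
  expect_error(concordance(none, none, stats::setNames(rep("HGBL", 4),
                                                       paste0("c", 1:4))),
               class = "stats_empty")
})

test_that("group comparison reproduces per-marker fractions and denominators", {
  fx <- fixture_cohort()
  tbl <- group_compare(fx, c("cd45_gt_granulocytes", "myeloid_markers"))
  cd45 <- tbl[tbl$feature == "cd45_gt_granulocytes", ]
  expect_equal(cd45$hgbl_pct, 75)
  expect_equal(c(cd45$hgbl_pos, cd45$hgbl_n), c(72, 96))
  expect_equal(cd45$ball_pct, 23)
  expect_equal(c(cd45$ball_pos, cd45$ball_n), c(11, 47))
  mm <- tbl[tbl$feature == "myeloid_markers", ]
  expect_equal(c(mm$hgbl_pos, mm$hgbl_n, mm$ball_pos, mm$ball_n),
               c(0, 30, 19, 46))
  expect_lt(mm$p_value, 0.05)

  # a feature unknown everywhere is reported, not dropped
  blank <- dplyr::bind_rows(hgbl_case("h"), ball_case("b"))
  blank$kras_mut <- NA
  out <- group_compare(as_cohort(blank), "kras_mut")
  expect_false(out$assessable)
  expect_true(is.na(out$p_value))
})

test_that("TdT modality agreement counts dual-tested cases only", {
  expect_equal(tdt_modality_concordance(fixture_cohort()),
               list(n_dual = 40L, n_concordant = 38L, rate = 0.95))
  none <- as_cohort(make_case(tdt_flow = "negative"))
  expect_true(is.na(tdt_modality_concordance(none)$rate))
  one <- as_cohort(make_case(tdt_flow = "negative", tdt_ihc = "negative"))
  expect_equal(tdt_modality_concordance(one)$rate, 1)
})
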