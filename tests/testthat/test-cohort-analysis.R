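make_landscape <- function() {
  free_fitness(p = c(0.5, 0.3, 0.2), p_onc = c(0.9, 0.5, 0.1),
               p_pres = c(0.1, 0.5, 0.9), sigma_t = 4, sigma_i = 2,
               mutation = c("R175H", "R248Q", "Y220C"))
}

test_that("patient scoring maps landscape components onto cohorts", {
  fl <- make_landscape()
  cohort <- data.frame(patient_id = paste0("P", 1:4),
                       mutation = c("R175H", "R175H", "R248Q", "Y220C"),
                       time = c(1, 2, 3, 4), event = c(1, 1, 0, 1))
  free <- score_patients(cohort, fl, "free")
  intr <- score_patients(cohort, fl, "intrinsic")
  imm <- score_patients(cohort, fl, "immune")
  expect_equal(free$score, intr$score + imm$score)
  expect_equal(free$score[1], free$score[2])

  unk <- rbind(cohort, data.frame(patient_id = "P5", mutation = "X1Y",
                                  time = 1, event = 1))
  expect_warning(kept <- score_patients(unk, fl), "dropped")
  expect_equal(nrow(kept), 4L)
  expect_equal(attr(kept, "n_dropped"), 1L)

  # a patient with two scored mutations keeps the fitter one
  dup <- data.frame(patient_id = "P1", mutation = c("R175H", "Y220C"),
                    time = 1, event = 1)
  best <- score_patients(dup, fl, "free")
  expect_equal(nrow(best), 1L)
  expect_equal(best$score, max(fl$free[fl$mutation %in% dup$mutation]))
})

test_that("median split sends ties to the high group", {
  sp <- median_split(c(1, 2, 3, 4))
  expect_equal(sort(sp$low), 1:2)
  expect_equal(sort(sp$high), 3:4)

  sp2 <- median_split(c(1, 2, 2, 3))
  expect_equal(sp2$low, 1L)
  expect_equal(sort(sp2$high), 2:4)

  expect_error(median_split(c(5, 5)), "degenerate")
  expect_error(median_split(7), "at least 2")
})

test_that("Kaplan-Meier estimates match product-limit hand cases", {
  flat <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(flat$surv == 1))

  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  cens <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(cens$surv[cens$time == 1], 2 / 3)
  expect_equal(cens$surv[cens$time == 3], 0)

  # with no censoring the estimator equals the empirical survival function
  set.seed(6)
  t <- rexp(40)
  km2 <- kaplan_meier(t, rep(1, 40))
  emp <- vapply(km2$time, function(u) mean(t > u), 0)
  expect_equal(km2$surv, emp, tolerance = 1e-12)

  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "positive")
})

test_that("log-rank statistic matches a small-table oracle and survdiff", {
  same <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)

  # hand-checkable six-event table: all A events precede all B events
  lr <- logrank_test(c(1, 2, 3), c(1, 1, 1), c(4, 5, 6), c(1, 1, 1))
  sd <- survival::survdiff(survival::Surv(time, ev) ~ g, data.frame(
    time = 1:6, ev = 1, g = rep(c("a", "b"), each = 3)))
  expect_equal(lr$chisq, sd$chisq, tolerance = 1e-10)
  expect_equal(lr$observed_a, 3)
  expect_equal(lr$expected_a, 3 / 6 + 2 / 5 + 1 / 4, tolerance = 1e-12)

  # random censored data against the survival package implementation
  set.seed(13)
  for (i in 1:10) {
    na <- sample(5:30, 1); nb <- sample(5:30, 1)
    ta <- round(rexp(na, 0.5), 2) + 0.01; tb <- round(rexp(nb, 0.8), 2) + 0.01
    ea <- rbinom(na, 1, 0.7); eb <- rbinom(nb, 1, 0.7)
    if (sum(ea) + sum(eb) == 0) next
    lr <- logrank_test(ta, ea, tb, eb)
    sd <- survival::survdiff(survival::Surv(time, ev) ~ g, data.frame(
      time = c(ta, tb), ev = c(ea, eb),
      g = rep(c("a", "b"), c(na, nb))))
    expect_equal(lr$chisq, sd$chisq, tolerance = 1e-8)
  }

  expect_error(logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), "no events")
})

test_that("dataset comparison correlates shared-support frequencies", {
  a <- data.frame(mutation = c("m1", "m2", "m3"), count = c(50, 30, 20))
  ident <- dataset_comparison(a, a)
  expect_equal(ident$pearson_r, 1)
  expect_equal(ident$spearman_r, 1)
  expect_true(all(ident$shared$delta == 0))

  b <- data.frame(mutation = c("m1", "m2", "m3"), count = c(20, 30, 50))
  rev <- dataset_comparison(a, b)
  expect_equal(rev$pearson_r, -0.9285714286, tolerance = 1e-9)
  expect_equal(rev$spearman_r, -1)

  c_ <- data.frame(mutation = c("x1", "x2", "x3"), count = 1:3)
  expect_error(dataset_comparison(a, c_), "shared")
})

test_that("two-sided binomial enrichment uses the minlike convention", {
  expect_equal(binomial_enrichment(0, 10, 0.5), 2 / 1024)
  expect_equal(binomial_enrichment(1, 2, 0.5), 1)
  expect_equal(binomial_enrichment(2, 2, 0.5), 0.5)
  expect_error(binomial_enrichment(1, 2, 0), "strictly inside")
  expect_error(binomial_enrichment(3, 2, 0.5), "\\[0, n\\]")
})

test_that("Welch comparison behaves on hand cases and is antisymmetric", {
  same <- welch_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(3)
  a <- rnorm(4, 0, 1e-3)
  b <- 1 + rnorm(4, 0, 1e-3)
  expect_lt(welch_compare(a, b)$p, 0.01)

  x <- rnorm(10); y <- rnorm(12, 0.5)
  fwd <- welch_compare(x, y); bwd <- welch_compare(y, x)
  expect_equal(fwd$t, -bwd$t)
  expect_equal(fwd$p, bwd$p)
  expect_error(welch_compare(c(1, 1), c(1, 1)), "zero variance")
})

test_that("log-rank p falls with the hazard link strength", {
  li <- generate_landscape_inputs(100, 5000, seed = 14)
  median_p <- vapply(c(0, 0.5, 1, 2), function(beta) {
    ps <- vapply(1:15, function(s) {
      cfg <- synth_config(seed = 14, cohort_n = 120, beta = beta,
                          hazard_component = if (beta == 0) "none" else "free",
                          censor_rate = 0.2)
      fl <- free_fitness(li$p, li$p_onc, li$p_pres, 4, 2,
                         mutation = li$mutation)
      cohort <- generate_cohort(fl, cfg, seed = s * 100 + beta * 10)
      scored <- score_patients(cohort, fl)
      sp <- median_split(scored$score)
      logrank_test(scored$time[sp$low], scored$event[sp$low],
                   scored$time[sp$high], scored$event[sp$high])$p
    }, 0)
    median(ps)
  }, 0)
  expect_true(all(diff(median_p) <= 0))
  expect_gt(median_p[1], 0.05)
  expect_lt(median_p[4], 0.05)
})

test_that("survival weight scan finds the immune-linked regime", {
  li <- generate_landscape_inputs(150, 20000, sigma_t = 1, sigma_i = 5,
                                  seed = 40)
  fl <- free_fitness(li$p, li$p_onc, li$p_pres, 1, 5, mutation = li$mutation)
  cfg <- synth_config(seed = 40, cohort_n = 400, beta = 3,
                      hazard_component = "immune", censor_rate = 0.1)
  cohort <- generate_cohort(fl, cfg, seed = 41)
  scan <- survival_weight_scan(cohort, li$counts, li$p, li$p_onc, li$p_pres,
                               mutation = li$mutation,
                               lambda_grid = seq(0, 1, 0.1))
  expect_gte(attr(scan, "lambda_star"), 0.8)
  expect_false(any(scan$degenerate[-1]))
})

test_that("cohort CSV reader returns the expected columns", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cohort.csv")
  write.csv(data.frame(patient_id = "P1", mutation = "R175H",
                       time = 3.2, event = 1), path, row.names = FALSE)
  back <- read_cohort_csv(path)
  expect_equal(names(back), c("patient_id", "mutation", "time", "event"))
})
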