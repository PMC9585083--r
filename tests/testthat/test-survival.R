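test_that("NOTCH score is the per-patient mean of the four target genes", {
  coh <- tibble::tibble(patient_id = c("a", "b"),
                        hes1 = c(2, 1), hes2 = c(2, 2),
                        hey1 = c(2, 3), hey2 = c(2, 4))
  out <- notch_score(coh)
  expect_equal(out$notch_score, c(2, 2.5))

  withr::with_seed(3, {
    r <- tibble::tibble(patient_id = sprintf("p%02d", 1:20),
                        hes1 = rnorm(20), hes2 = rnorm(20),
                        hey1 = rnorm(20), hey2 = rnorm(20))
  })
  expect_equal(notch_score(r)$notch_score,
               rowMeans(cbind(r$hes1, r$hes2, r$hey1, r$hey2)))

  broken <- coh; broken$hey2[2] <- NA
  expect_error(notch_score(broken), "HEY2.*b")
  expect_error(notch_score(coh[, -2]), "hes1")
})

test_that("dichotomization uses a strict greater-than rule", {
  lab <- dichotomize(c(1, 2, 3, 4), "median")
  expect_equal(as.character(lab), c("low", "low", "high", "high"))
  expect_equal(attr(lab, "threshold"), 2.5)

  lab2 <- dichotomize(c(14.9, 15.0), threshold = 14.9)
  expect_equal(as.character(lab2), c("low", "high"))  # boundary value is low

  withr::with_seed(4, v <- rnorm(101))
  for (thr in c(-0.5, 0, 0.5)) {
    expect_equal(sum(dichotomize(v, thr) == "high"), sum(v > thr))
  }
})

test_that("four-group stratification records and re-applies thresholds", {
  withr::with_seed(5, {
    coh <- tibble::tibble(patient_id = sprintf("p%03d", 1:100),
                          hes1 = rnorm(100), hes2 = rnorm(100),
                          hey1 = rnorm(100), hey2 = rnorm(100),
                          ciita = rnorm(100, 14.9))
  })
  st <- stratify_four_groups(coh)
  expect_true(all(table(st$four_group) > 0))
  expect_equal(sum(table(st$four_group)), 100)
  thr <- strata_thresholds(st)
  # freezing the thresholds and re-applying reproduces the labels
  st2 <- stratify_four_groups(coh, notch_threshold = thr$notch,
                              ciita_threshold = thr$ciita)
  expect_equal(st2$four_group, st$four_group)

  # frozen thresholds from cohort A applied to cohort B depend only on B
  withr::with_seed(6, {
    cohB <- dplyr::mutate(coh, ciita = rnorm(100, 14.9))
  })
  stB <- stratify_four_groups(cohB, notch_threshold = thr$notch,
                              ciita_threshold = thr$ciita)
  expect_equal(as.character(stB$ciita_group),
               ifelse(cohB$ciita > thr$ciita, "high", "low"))

  # identical patients land in a single group
  same <- dplyr::mutate(coh, hes1 = 1, hes2 = 1, hey1 = 1, hey2 = 1,
                        ciita = 10)
  expect_equal(dplyr::n_distinct(stratify_four_groups(same)$four_group), 1L)
})

test_that("Kaplan-Meier reproduces the hand-computed product limit", {
  km <- kaplan_meier(tibble::tibble(time = c(1, 2, 3), event = 1))
  expect_equal(tidy(km)$survival, c(2 / 3, 1 / 3, 0))

  censored <- kaplan_meier(tibble::tibble(time = c(1, 2, 3), event = 0))
  expect_true(all(tidy(censored)$survival == 1))

  # estimator properties + agreement with the survival package on random data
  withr::with_seed(7, {
    d <- tibble::tibble(time = round(rexp(60, 0.3), 2) + 0.01,
                        event = rbinom(60, 1, 0.7))
  })
  steps <- tidy(kaplan_meier(d))
  expect_true(all(diff(steps$survival) <= 1e-12))
  expect_lte(max(steps$survival), 1)
  skip_if_not_installed("survival")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  sm <- summary(fit, times = steps$time)
  expect_equal(steps$survival, sm$surv, tolerance = 1e-12)
  expect_equal(steps$n_risk, sm$n.risk)
})

test_that("log-rank matches the hand-computed O/E/V table", {
  # group1 events at 1, 2; group2 events at 3, 4; no censoring:
  # O1 = 2, E1 = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9 = 17/36, X^2 = 49/17
  d <- tibble::tibble(time = c(1, 2, 3, 4), event = 1,
                      group = c("g1", "g1", "g2", "g2"))
  lr <- logrank_test(d)
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-12)
  expect_equal(lr$df, 1L)
  expect_equal(lr$p_value, pchisq(49 / 17, 1, lower.tail = FALSE))
  expect_equal(lr$table$observed, c(2, 2))
  expect_equal(lr$table$expected, c(5 / 6, 19 / 6), tolerance = 1e-12)

  # identical groups: statistic exactly 0
  d2 <- tibble::tibble(time = rep(c(1, 3, 7), 2), event = 1,
                       group = rep(c("a", "b"), each = 3))
  lr2 <- logrank_test(d2)
  expect_equal(lr2$statistic, 0)
  expect_equal(lr2$p_value, 1)

  expect_error(logrank_test(tibble::tibble(time = 1:4, event = 0,
                                           group = rep(c("a", "b"), 2))),
               "No events")
})

test_that("log-rank agrees with survival::survdiff on random 2- and 4-group data", {
  skip_if_not_installed("survival")
  for (seed in 1:5) {
    withr::with_seed(seed, {
      k <- sample(c(2, 4), 1)
      d <- tibble::tibble(time = rexp(40 * k, 0.2),
                          event = rbinom(40 * k, 1, 0.8),
                          group = rep(letters[1:k], each = 40))
    })
    lr <- logrank_test(d)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    expect_equal(lr$statistic, unname(sd$chisq), tolerance = 1e-8)
    expect_equal(lr$table$observed, unname(as.numeric(sd$obs)))
    expect_equal(lr$table$expected, unname(as.numeric(sd$exp)),
                 tolerance = 1e-8)
  }
})

test_that("log-rank p-values are uniform under the null", {
  pvals <- vapply(1:120, function(s) {
    withr::with_seed(1000 + s, {
      d <- tibble::tibble(time = rexp(80, 0.2),
                          event = rbinom(80, 1, 0.8),
                          group = rep(c("a", "b"), 40))
    })
    logrank_test(d)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("Fisher exact enumeration matches stats::fisher.test", {
  f <- fisher_enrichment(5, 5, 5, 5)
  expect_equal(f$odds_ratio, 1)
  expect_equal(f$p_value, 1)

  g <- fisher_enrichment(1, 9, 11, 3)
  ft <- stats::fisher.test(matrix(c(1, 11, 9, 3), 2))
  expect_equal(g$p_value, ft$p.value, tolerance = 1e-12)

  # boundary: empty off-diagonal cell gives infinite sample OR, finite p
  h <- fisher_enrichment(4, 0, 2, 6)
  expect_true(is.infinite(h$odds_ratio))
  expect_equal(h$p_value,
               stats::fisher.test(matrix(c(4, 2, 0, 6), 2))$p.value,
               tolerance = 1e-12)

  expect_error(fisher_enrichment(0, 0, 3, 4), "Degenerate")
  expect_error(fisher_enrichment(1.5, 2, 3, 4), "integers")
})
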