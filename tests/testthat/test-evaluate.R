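fx_risk <- function(stay, hours, scores) {
  data.frame(stay_id = stay, hour = hours, score = scores,
             stringsAsFactors = FALSE)
}

test_that("MAX-metric classification and lead time follow the alarm rules", {
  labels <- data.frame(
    stay_id = c("p1", "p2", "n1"),
    class = c("T72", "T72", "transient"),
    Tp = c(50, 50, NA), stringsAsFactors = FALSE)
  risk <- rbind(
    fx_risk("p1", c(30, 40, 45, 55), c(0.2, 0.66, 0.7, 0.9)),  # first alarm Tp-10
    fx_risk("p2", c(30, 40, 50, 62), c(0.1, 0.2, 0.3, 0.4)),   # never crosses
    fx_risk("n1", c(10, 20, 80), c(0.1, 0.4, 0.35))
  )
  ev <- max_metric(risk, labels, cutoff = 0.5)
  expect_equal(ev$predicted, c(TRUE, FALSE, FALSE))
  expect_equal(ev$lead_time[ev$stay_id == "p1"], 10)            # Tp - 40
  expect_true(is.na(ev$lead_time[ev$stay_id == "p2"]))
  ## late alarm inside (Tp, Tp+12] counts, with negative lead time
  risk3 <- fx_risk("p1", c(40, 55), c(0.2, 0.9))
  ev3 <- max_metric(risk3, labels[1, ], cutoff = 0.5)
  expect_true(ev3$predicted)
  expect_equal(ev3$lead_time, -5)
  ## a persistent stay with no admissible samples is an error
  expect_error(max_metric(fx_risk("n1", 1, 0.1), labels, 0.5), "no admissible")
})

test_that("auROC and auPR behave at the extremes", {
  ev <- data.frame(max_score = c(0.9, 0.8, 0.3, 0.2), truth = c(TRUE, TRUE, FALSE, FALSE))
  rp <- roc_pr(ev, n_boot = 0)
  expect_equal(rp$auroc, 1)
  expect_equal(rp$aupr, 1)
  expect_error(roc_pr(data.frame(max_score = 1, truth = TRUE), n_boot = 0),
               "both classes")
})

test_that("label-independent scores give a bootstrap interval covering 0.5", {
  set.seed(101)
  ev <- data.frame(max_score = runif(500), truth = runif(500) < 0.2)
  rp <- roc_pr(ev, n_boot = 300, seed = 2)
  expect_gt(0.5, rp$auroc_ci[1])
  expect_lt(0.5, rp$auroc_ci[2])
})

test_that("auROC equals the pairwise ranking probability on small cohorts", {
  set.seed(37)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    truth <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)   # heavy ties
    ev <- data.frame(max_score = scores, truth = truth)
    expect_equal(roc_pr(ev, n_boot = 0)$auroc, oracle_auroc(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("auROC is invariant under strictly monotone score transforms", {
  set.seed(43)
  scores <- runif(60)
  truth <- runif(60) < 0.3
  truth[1:2] <- c(TRUE, FALSE)
  a1 <- roc_pr(data.frame(max_score = scores, truth = truth), n_boot = 0)$auroc
  a2 <- roc_pr(data.frame(max_score = plogis(5 * scores - 2), truth = truth),
               n_boot = 0)$auroc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("auROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  scores <- round(runif(200), 2)
  truth <- runif(200) < 0.3
  truth[1:2] <- c(TRUE, FALSE)
  got <- roc_pr(data.frame(max_score = scores, truth = truth), n_boot = 0)$auroc
  want <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                         direction = "<")))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("standardized predictive values reproduce the closed form", {
  expect_equal(100 * standardized_ppv(0.9261, 0.8247, 0.10), 36.99,
               tolerance = 0.01)
  expect_equal(100 * standardized_ppv(0.7719, 0.8630, 0.10), 38.50,
               tolerance = 0.01)
  expect_equal(standardized_ppv(1, 1, 0.5), 1)
  expect_warning(out <- standardized_ppv(0, 1, 0.5), "undefined")
  expect_true(is.na(out))
  expect_equal(100 * standardized_npv(0.9261, 0.8247, 0.0570), 99.46,
               tolerance = 0.01)
})

test_that("confusion rates come from the 2x2 table and agree with the identities", {
  ev <- data.frame(
    truth = c(rep(TRUE, 4), rep(FALSE, 6)),
    predicted = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  r <- confusion_rates(ev)
  expect_equal(r$sensitivity, 0.75)
  expect_equal(r$specificity, 2 / 3)
  expect_equal(r$ppv, 0.6)
  expect_equal(r$f1, 2 * 0.6 * 0.75 / (0.6 + 0.75))
  ## count-based NPV equals the standardized form at the empirical prevalence
  expect_equal(r$npv, standardized_npv(r$sensitivity, r$specificity,
                                       r$prevalence), tolerance = 1e-12)
  expect_equal(r$ppv, standardized_ppv(r$sensitivity, r$specificity,
                                       r$prevalence), tolerance = 1e-12)
  all_right <- data.frame(truth = c(TRUE, FALSE), predicted = c(TRUE, FALSE))
  r2 <- confusion_rates(all_right)
  expect_equal(c(r2$sensitivity, r2$specificity, r2$ppv, r2$npv), rep(1, 4))
})

test_that("the average odds difference matches its definition", {
  ## identical performance in both groups: AOD 0
  ev <- data.frame(truth = rep(c(TRUE, FALSE), 10),
                   predicted = rep(c(TRUE, FALSE), 10))
  a <- average_odds_difference(ev, monitored = rep(c(TRUE, FALSE), each = 10))
  expect_equal(a$aod, 0)
  expect_true(a$fair)
  ## formula arithmetic: FPR 0.3 vs 0.1, TPR 0.5 vs 0.9
  mk_group <- function(n_pos, tpr, n_neg, fpr) {
    data.frame(truth = c(rep(TRUE, n_pos), rep(FALSE, n_neg)),
               predicted = c(rep(TRUE, round(n_pos * tpr)),
                             rep(FALSE, round(n_pos * (1 - tpr))),
                             rep(TRUE, round(n_neg * fpr)),
                             rep(FALSE, round(n_neg * (1 - fpr)))))
  }
  ev2 <- rbind(mk_group(10, 0.5, 10, 0.3), mk_group(10, 0.9, 10, 0.1))
  a2 <- average_odds_difference(ev2, monitored = rep(c(TRUE, FALSE), each = 20))
  expect_equal(a2$aod, -0.1, tolerance = 1e-12)
  expect_true(a2$fair)                       # boundary of the fairness band
  ## band flag fires outside [-0.1, 0.1]
  ev3 <- rbind(mk_group(10, 0.2, 10, 0.5), mk_group(10, 0.9, 10, 0.1))
  a3 <- average_odds_difference(ev3, monitored = rep(c(TRUE, FALSE), each = 20))
  expect_false(a3$fair)
  ## degenerate groups are flagged unreliable
  ev4 <- data.frame(truth = c(TRUE, TRUE, FALSE), predicted = TRUE)
  a4 <- average_odds_difference(ev4, monitored = c(TRUE, FALSE, FALSE))
  expect_false(a4$reliable)
})

test_that("the AOD matches a direct recount on random subgroup splits", {
  set.seed(67)
  for (rep in 1:40) {
    n <- sample(20:60, 1)
    truth <- runif(n) < 0.4
    pred <- runif(n) < 0.5
    mon <- runif(n) < 0.4
    if (!any(mon) || all(mon)) next
    ev <- data.frame(truth = truth, predicted = pred)
    got <- average_odds_difference(ev, mon)$aod
    expect_equal(got, oracle_aod(truth, pred, mon), tolerance = 1e-12)
  }
})
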