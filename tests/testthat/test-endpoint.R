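fake_stages <- function(stages, sid = "a") {
  data.frame(stay_id = sid, hour = seq_along(stages) - 1L, stage = stages,
             criterion = ifelse(stages == 3L, "scr", "none"),
             evaluable = TRUE, stringsAsFactors = FALSE)
}

test_that("severe events are the maximal stage-3 runs", {
  ev <- severe_events(fake_stages(c(2, 3, 3, 3, 2)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 1)
  expect_equal(ev$end, 4)
  expect_equal(ev$terminated_by, "recovery")
  expect_equal(nrow(severe_events(fake_stages(c(0, 1, 2, 2, 1)))), 0)
})

test_that("severe-event extraction matches a run-length-encoding oracle", {
  set.seed(59)
  for (rep in 1:500) {
    stages <- sample(0:3, sample(5:60, 1), replace = TRUE,
                     prob = c(.3, .2, .2, .3))
    got <- severe_events(fake_stages(stages))
    want <- oracle_runs(stages)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("events are truncated at RRT initiation and terminators are classified", {
  ## run 10..60, RRT at 40: classifiable event is the organic 30 h
  stages <- fake_stages(c(rep(0, 10), rep(3, 50)))
  ev <- severe_events(stages, rrt_start = 40)
  expect_equal(ev$start, 10)
  expect_equal(ev$end, 40)
  expect_equal(ev$terminated_by, "rrt")
  ## run reaching the end of a stay that ended in death
  ev2 <- severe_events(fake_stages(c(rep(0, 5), rep(3, 55))), died = TRUE)
  expect_equal(ev2$terminated_by, "death")
  ev3 <- severe_events(fake_stages(c(rep(0, 5), rep(3, 55))))
  expect_equal(ev3$terminated_by, "discharge")
})

test_that("persistence classes follow the endpoint rules with T72 precedence", {
  mk <- function(len, term) data.frame(stay_id = "a", start = 10, end = 10 + len,
                                       length = len, terminated_by = term)
  expect_equal(classify_persistence(mk(72, "recovery"))$class, "T72")
  expect_equal(classify_persistence(mk(50, "death"))$class, "D48")
  expect_equal(classify_persistence(mk(30, "rrt"))$class, "RRT24")
  expect_equal(classify_persistence(mk(40, "recovery"))$class, "transient")
  ## an 80-h event ending in death is primary endpoint, not D48
  expect_equal(classify_persistence(mk(80, "death"))$class, "T72")
  ## Tp is the first hour of the first qualifying event
  two <- rbind(mk(40, "recovery"), within(mk(75, "recovery"), start <- 60))
  cl <- classify_persistence(two)
  expect_equal(cl$class, "T72")
  expect_equal(cl$Tp, 60)
  ## cut-short events yield exclusions, not classes
  expect_equal(classify_persistence(mk(30, "death"))$exclusion$category, "imminence")
  expect_equal(classify_persistence(mk(20, "rrt"))$exclusion$rule,
               "RRT after less than 24 h of AKI stage 3")
  expect_equal(classify_persistence(mk(60, "discharge"))$exclusion$rule,
               "No measurement till 72nd hour")
  ## RRT without any organic stage 3 beforehand
  none <- mk(10, "recovery")[0, ]
  expect_equal(classify_persistence(none, has_rrt = TRUE)$exclusion$category,
               "imminence")
})

test_that("the exclusion cascade keeps exactly the engineered-clean stays", {
  ## 12 engineered stays: 5 clean (transient x2, T72, D48, RRT24), 7 excluded
  mk1 <- function(tpl, sid) {
    co <- worked_stay(tpl)
    co$events$stay_id <- sid
    co$statics$stay_id <- sid
    co$statics$patient_id <- paste0("p_", sid)
    co
  }
  parts <- list(
    mk1("transient", "c1"), mk1("T72", "c2"), mk1("D48", "c3"),
    mk1("RRT24", "c4"), mk1("transient", "c5"),
    mk1("excluded_demographic", "x1"), mk1("excluded_imminence_death", "x2"),
    mk1("excluded_imminence_rrt", "x3"), mk1("excluded_oliguria_start", "x4")
  )
  events <- do.call(rbind, lapply(parts, `[[`, "events"))
  statics <- do.call(rbind, lapply(parts, `[[`, "statics"))
  ## x5: giant height; x6: under 24 h of data; x7: never reaches stage 2
  tall <- mk1("transient", "x5"); tall$statics$height <- 210
  short <- list(events = fx_events("x6", c(0, 2, 4), "creatinine", c(1, 1, 1)),
                statics = fx_static("x6", L = 20))
  mild <- list(events = rbind(
    fx_events("x7", c(0, 12, 24, 48), "creatinine", c(1, 1.2, 1.3, 1.1)),
    fx_events("x7", seq(1, 71, 2), "urine_output", rep(190, 36))),
    statics = fx_static("x7", L = 72))
  events <- rbind(events, tall$events, short$events, mild$events)
  statics <- rbind(statics, tall$statics, short$statics, mild$statics)
  ev <- plausibility_filter(standardize_units(events))$events
  hm <- resample_hourly(ev, statics)
  adj <- adjudicate_cohort(hm, ev, statics)
  expect_setequal(adj$included, c("c1", "c2", "c3", "c4", "c5"))
  expect_equal(nrow(adj$exclusions), 7)
  expect_equal(sort(adj$exclusions$stay_id), paste0("x", 1:7))
  ## one first-matching rule per excluded stay, category order respected
  expect_equal(adj$exclusions$rule[adj$exclusions$stay_id == "x5"],
               "Height < 130 cm and > 200 cm")
  expect_equal(adj$exclusions$rule[adj$exclusions$stay_id == "x6"],
               "Less than 24 h of data")
  expect_equal(adj$exclusions$rule[adj$exclusions$stay_id == "x7"],
               "No hour at AKI stage 2 or 3")
  ## partition: included and excluded cover all stays exactly once
  expect_setequal(c(adj$included, adj$exclusions$stay_id), statics$stay_id)
  expect_length(intersect(adj$included, adj$exclusions$stay_id), 0)
})

test_that("per-hour labels cover stage >= 2 hours with the Tp window rules", {
  ## transient: every stage >= 2 hour is a negative sample
  stg <- fake_stages(c(rep(1, 5), rep(2, 10), rep(1, 5)))
  lab <- data.frame(stay_id = "a", class = "transient", Tp = NA_real_)
  s <- label_samples(stg, lab)
  expect_equal(nrow(s), 10)
  expect_true(all(s$label == 0))
  expect_setequal(s$hour, 5:14)
  ## persistent: [Tp - W, Tp + 12] positive, earlier stage >= 2 dropped,
  ## nothing after Tp + 12
  stages <- c(rep(0, 10), rep(2, 60), rep(3, 90))   # stage >= 2 from hour 10
  stg2 <- fake_stages(stages)
  lab2 <- data.frame(stay_id = "a", class = "T72", Tp = 70)
  s2 <- label_samples(stg2, lab2, window = 48)
  expect_true(all(s2$label == 1))
  expect_equal(min(s2$hour), 70 - 48)
  expect_equal(max(s2$hour), 70 + 12)
  ## stage-1 hours never emit samples
  s3 <- label_samples(fake_stages(rep(1, 30)),
                      data.frame(stay_id = "a", class = "transient", Tp = NA))
  expect_equal(nrow(s3), 0)
  expect_error(label_samples(stg, lab, window = 0), "positive")
})
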