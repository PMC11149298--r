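test_that("creatinine bands follow the KDIGO thresholds", {
  ## ratio exactly 2.0 meets the stage-2 band
  expect_equal(stage_scr(2.0, bscr = 1.0), 2L)
  ## 0.3 mg/dL rise within 48 h stages 1 even below 1.5x baseline
  expect_equal(stage_scr(c(0.8, 1.2), bscr = 1.0), c(0L, 1L))
  ## >= 3x baseline stages 3
  expect_equal(stage_scr(4.5, bscr = 1.0), 3L)
  ## >= 4.0 mg/dL stages 3 only with an acute qualifier
  expect_equal(stage_scr(c(4.2, 4.2), bscr = 3.5), c(0L, 0L))      # stable chronic
  expect_equal(stage_scr(c(3.8, 4.2), bscr = 3.5), c(0L, 3L))      # acute rise
  ## switchable rise criterion
  expect_equal(stage_scr(c(0.8, 1.2), bscr = 1.0, use_rise = FALSE), c(0L, 0L))
  expect_error(stage_scr(1, bscr = 0), "positive")
})

test_that("urine-output bands follow the trailing-window rules", {
  ## 0.4 ml/kg/h for 8 h after ample normal flow: stage 1, not yet stage 2
  f <- c(rep(1.2, 24), rep(0.4, 8))
  s <- stage_uo(f)$stage
  expect_equal(s[32], 1L)          # hour 31: 6-h mean 0.4, 12-h mean 0.67
  ## 0.2 for 26 h: stage 3 once the 24-h mean drops below 0.3
  f <- c(rep(1.2, 24), rep(0.2, 26))
  s <- stage_uo(f)$stage
  expect_equal(s[24 + 24], 3L)     # hour 47 = 24th hour of the run
  ## zero output for 12 h: anuria band
  f <- c(rep(1.0, 24), rep(0, 12))
  out <- stage_uo(f)
  expect_equal(out$stage[36], 3L)
  expect_true(out$anuric[36])
  ## insufficient coverage is not evaluable
  expect_true(all(is.na(stage_uo(rep(NA_real_, 30))$stage)))
})

test_that("baseline creatinine follows the nadir rules", {
  ## RRT stay: minimum before RRT initiation only
  st <- fx_static("a", L = 120)
  ev <- rbind(
    fx_events("a", c(5, 20, 60, 80), "creatinine", c(1.4, 1.2, 0.9, 0.8)),
    fx_events("a", 50, "rrt", 1)
  )
  b <- baseline_scr(standardize_units(ev), st)
  expect_equal(b$bscr, 1.2)
  expect_equal(b$provenance, "pre-RRT nadir")
  ## two non-RRT stays of one patient pool their nadir
  st2 <- rbind(fx_static("s1", patient_id = "p", L = 96),
               fx_static("s2", patient_id = "p", L = 96))
  ev2 <- rbind(fx_events("s1", c(1, 10), "creatinine", c(1.1, 1.3)),
               fx_events("s2", c(2, 12), "creatinine", c(0.8, 1.0)))
  b2 <- baseline_scr(standardize_units(ev2), st2)
  expect_equal(b2$bscr, c(0.8, 0.8))
  ## a sibling RRT stay is excluded from the pool
  ev3 <- rbind(ev2, fx_events("s2", 1, "rrt", 1))
  b3 <- baseline_scr(standardize_units(ev3), st2)
  expect_equal(b3$bscr[b3$stay_id == "s1"], 1.1)
})

test_that("baseline matches an exhaustive minimum over the rule's windows", {
  set.seed(23)
  for (rep in 1:15) {
    n_stays <- sample(2:4, 1)
    st <- do.call(rbind, lapply(seq_len(n_stays), function(i) {
      fx_static(paste0("s", i), patient_id = "p", L = 100)
    }))
    ev <- do.call(rbind, lapply(seq_len(n_stays), function(i) {
      e <- fx_events(paste0("s", i), sort(sample(0:99, 6)), "creatinine",
                     round(runif(6, 0.5, 3), 2))
      if (runif(1) < 0.4) e <- rbind(e, fx_events(paste0("s", i),
                                                  sample(20:80, 1), "rrt", 1))
      e
    }))
    ev <- standardize_units(ev)
    b <- baseline_scr(ev, st)
    rrt_h <- rrt_start_hours(ev, st)
    for (k in seq_len(n_stays)) {
      sid <- st$stay_id[k]
      scr <- ev[ev$variable == "creatinine", ]
      h <- as.numeric(difftime(scr$time, fx_time(0), units = "hours"))
      if (!is.na(rrt_h[sid])) {
        expected <- suppressWarnings(
          min(scr$value[scr$stay_id == sid & h < rrt_h[sid]]))
        if (!is.finite(expected)) expected <- NA_real_
      } else {
        pool <- st$stay_id[is.na(rrt_h[st$stay_id])]
        expected <- min(scr$value[scr$stay_id %in% pool])
      }
      expect_equal(b$bscr[b$stay_id == sid], expected)
    }
  }
})

test_that("the hourly stage is the maximum of the criteria with RRT dominance", {
  st <- fx_static("a", L = 60)
  ## creatinine stage 1 while urine output reaches stage 2
  ev <- rbind(
    fx_events("a", c(0, 24), "creatinine", c(1.0, 1.6)),
    fx_events("a", seq(1, 59, 2), "urine_output",
              c(rep(200, 12), rep(60, 18)))   # 1.25 then 0.375 ml/kg/h
  )
  hm <- resample_hourly(standardize_units(ev), st)
  ss <- stage_hourly(hm, bscr = 1.0, rrt_start = NA)
  h40 <- which(ss$hour == 40)
  expect_equal(ss$scr_stage[h40], 1L)
  expect_equal(ss$uo_stage[h40], 2L)
  expect_equal(ss$stage[h40], 2L)
  expect_equal(ss$criterion[h40], "uo")
  ## RRT forces stage 3 whatever the other criteria say
  ss2 <- stage_hourly(hm, bscr = 1.0, rrt_start = 45)
  expect_true(all(ss2$stage[ss2$hour >= 45] == 3L))
  expect_true(all(ss2$criterion[ss2$hour >= 45] == "rrt"))
  expect_equal(ss2$stage[ss2$hour < 45], ss$stage[ss$hour < 45])
})

test_that("raising a creatinine value never lowers any hour's stage", {
  set.seed(31)
  for (rep in 1:10) {
    s <- runif(72, 0.5, 5)
    s[sample(72, 20)] <- NA
    base <- stage_scr(s, bscr = 1.0)
    i <- sample(which(!is.na(s)), 1)
    s2 <- s
    s2[i] <- s2[i] + runif(1, 0.1, 2)
    bumped <- stage_scr(s2, bscr = 1.0)
    ok <- !is.na(base) & !is.na(bumped)
    expect_true(all(bumped[ok] >= base[ok]))
  }
})

test_that("staging equals the brute-force per-hour oracle on random stays", {
  set.seed(47)
  specs <- variable_specs()
  for (rep in 1:30) {
    L <- sample(30:140, 1)
    with_rrt <- runif(1) < 0.3
    ev <- standardize_units(fx_random_stay("r", L = L, with_rrt = with_rrt))
    st <- fx_static("r", L = L)
    hm <- resample_hourly(ev, st, specs)
    b <- baseline_scr(ev, st)
    rrt <- rrt_start_hours(ev, st)
    got <- stage_hourly(hm, b$bscr, rrt_start = unname(rrt["r"]))
    want <- oracle_stage_stay(ev, st, b$bscr, rrt["r"])
    expect_equal(got$stage, want$stage)
    expect_equal(got$criterion, want$criterion)
    expect_equal(got$evaluable, want$evaluable)
  }
})
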