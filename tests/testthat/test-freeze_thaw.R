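# Freeze-thaw pipeline: frozen detection, baseline, ice content, rate,
# end-to-end processing and summaries.

test_that("detect_frozen uses an inclusive threshold", {
  expect_false(any(detect_frozen(rep(20, 5))))
  expect_true(detect_frozen(0))       # boundary included
  expect_false(detect_frozen(0.01))
  expect_true(detect_frozen(-3, freezing_point = -2))
  # chamber ramp 20 -> -16 at 3 deg C/step: first sub-zero level is -1,
  # the 8th level (index arithmetic on the staircase)
  ramp <- seq(20, -16, by = -3)
  fr <- detect_frozen(ramp)
  expect_equal(which(fr)[1], 8L)
  expect_true(all(fr[8:length(ramp)]))
  expect_false(any(fr[1:7]))
})

test_that("baseline_theta0 averages the trailing pre-freeze window", {
  m <- table2_models$juniperus
  s <- series_from_theta(c(44, 45, 46, 40, 35),
                         c(5, 3, 1, -1, -2), m)
  expect_equal(baseline_theta0(s, m), 45, tolerance = 1e-9)
  # constant pre-freeze water content
  s2 <- series_from_theta(rep(45, 4), c(5, 4, -1, -1), m)
  expect_equal(baseline_theta0(s2, m), 45, tolerance = 1e-9)
  # window wider than available pre-freeze samples: use what exists
  s3 <- series_from_theta(c(44, 40), c(2, -1), m)
  expect_equal(baseline_theta0(s3, m), 44, tolerance = 1e-9)
  # frozen from the first sample -> instructive error
  s4 <- series_from_theta(c(40, 38), c(-5, -6), m)
  expect_error(baseline_theta0(s4, m), "supply theta0")
})

test_that("ice_content applies the density ratio and clamp rule", {
  expect_equal(as.numeric(ice_content(45, 45)), 0)
  expect_equal(as.numeric(ice_content(45, 30, 0.917)), 13.755)
  # direct arithmetic oracle on a grid
  th0 <- 45
  thx <- seq(0, 45, by = 5)
  expect_equal(as.numeric(ice_content(th0, thx, 0.9)), (th0 - thx) * 0.9)
  # theta_x above baseline clamps to 0 and counts
  d <- ice_content(45, c(30, 46, 47))
  expect_equal(as.numeric(d), c(13.755, 0, 0))
  expect_equal(attr(d, "n_clamped"), 2L)
  d2 <- ice_content(45, 46, clamp_negative = FALSE)
  expect_lt(as.numeric(d2), 0)
  expect_error(ice_content(45, 120), "\\[0, 100\\]")
})

test_that("freeze_thaw_rate is a forward difference in %/min", {
  t0 <- as.POSIXct("2019-01-01", tz = "UTC")
  expect_equal(freeze_thaw_rate(t0 + c(0, 60, 120), rep(7, 3)), c(0, 0, 0))
  expect_equal(freeze_thaw_rate(t0 + c(0, 60), c(10, 12)), c(2, 0))
  # field cadence: 10-min sampling, thawing branch
  expect_equal(freeze_thaw_rate(t0 + c(0, 600), c(12, 10)), c(0.2, 0))
  # nonuniform spacing handled per-interval
  expect_equal(freeze_thaw_rate(c(0, 60, 180), c(0, 3, 6)),
               c(3, 1.5, 0))
  # absolute value: the multiset of interval rates is invariant under time
  # reversal of the delta series (the terminal-zero padding shifts ends)
  set.seed(5)
  d <- stats::runif(20, 0, 40)
  ts <- seq(0, by = 120, length.out = 20)
  expect_equal(sort(freeze_thaw_rate(ts, d)),
               sort(freeze_thaw_rate(ts, rev(d))))
  expect_true(all(freeze_thaw_rate(ts, d) >= 0))
  expect_error(freeze_thaw_rate(c(0, 0, 60), c(1, 2, 3)), "duplicate")
})

test_that("process_series handles never-frozen and single-sample series", {
  m <- table2_models$juniperus
  s <- series_from_theta(rep(45, 6), rep(10, 6), m)
  rec <- process_series(s, m)
  expect_true(all(rec$delta_pct == 0))
  expect_true(all(rec$sigma_pct_per_min == 0))
  expect_false(any(rec$frozen))

  s1 <- series_from_theta(45, 10, m)
  rec1 <- process_series(s1, m)
  expect_equal(nrow(rec1), 1L)
  expect_equal(rec1$delta_pct, 0)

  # frozen from the start requires explicit theta0
  sf <- series_from_theta(c(40, 38), c(-5, -6), m)
  expect_error(process_series(sf, m), "supply theta0")
  recf <- process_series(sf, m, theta0 = 45)
  expect_equal(recf$delta_pct, (45 - c(40, 38)) * 0.917, tolerance = 1e-9)
})

test_that("process_series tracks a chamber freeze-thaw shape", {
  m <- table2_models$juniperus
  cfg <- pipeline_config()
  sim <- simulate_readings(simulation_config(noise_sd_v = 0), m)
  rec <- process_series(sim$readings, m, cfg)
  peak <- max(rec$delta_pct)
  expect_gt(peak, 20)
  ipeak <- which.max(rec$delta_pct)
  # rises during cooling, plateaus at depth, falls during warming
  cool <- rec$delta_pct[1:ipeak]
  expect_true(all(diff(cool) >= -1e-9))
  tail_delta <- rec$delta_pct[(ipeak + 1):nrow(rec)]
  expect_lt(min(tail_delta), 0.05 * peak)
  # conservation for every in-episode record (no clamping triggered)
  expect_equal(attr(rec, "n_clamped"), 0L)
  th0 <- attr(rec, "baselines")$theta0[1]
  active <- rec$delta_pct > 0
  expect_equal(rec$delta_pct[active] / cfg$density_ratio +
                 rec$theta_pct[active], rep(th0, sum(active)),
               tolerance = 1e-9)
  # bound
  expect_true(all(rec$delta_pct <= th0 * cfg$density_ratio + 1e-9))
  expect_true(all(rec$sigma_pct_per_min >= 0))
})

test_that("pipeline re-baselines at each new freeze episode", {
  m <- table2_models$juniperus
  # two freeze events separated by a complete thaw at a different baseline
  theta <- c(45, 45, 45, 30, 30, 45, 42, 42, 42, 30, 30)
  temp <- c(5, 4, 3, -2, -3, 5, 6, 5, 4, -1, -2)
  s <- series_from_theta(theta, temp, m)
  rec <- process_series(s, m)
  b <- attr(rec, "baselines")
  expect_equal(nrow(b), 2L)
  expect_equal(b$theta0, c(45, 42), tolerance = 1e-9)
  expect_equal(rec$delta_pct[4], (45 - 30) * 0.917, tolerance = 1e-9)
  expect_equal(rec$delta_pct[10], (42 - 30) * 0.917, tolerance = 1e-9)
  # thawed stretch between episodes reports no ice
  expect_equal(rec$delta_pct[6:9], rep(0, 4))
})

test_that("summarize_rates reports mean/sd/min/max with n-1 sd", {
  s <- summarize_rates(rep(3, 5))
  expect_equal(s$mean, 3)
  expect_equal(s$sd, 0)
  expect_equal(s$min, 3)
  expect_equal(s$max, 3)
  s2 <- summarize_rates(c(0, 2))
  expect_equal(s2$mean, 1)
  expect_equal(s2$sd, sqrt(2))
  expect_equal(s2$min, 0)
  expect_equal(s2$max, 2)
  expect_error(summarize_rates(1), "insufficient data")
  # emitted JSON carries the four summary keys
  path <- withr::local_tempfile(fileext = ".json")
  write_summary_json(s2, path)
  obj <- jsonlite::fromJSON(path)
  expect_true(all(c("mean", "sd", "min", "max") %in% names(obj)))
  expect_equal(obj$labels$sd, "Standard Deviation")
})
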