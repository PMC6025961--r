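test_that("detect_events handles the canonical threshold-crossing cases", {
  # always below: empty table
  expect_equal(nrow(detect_events(rep(1, 20), 100, 12)), 0)
  # below until frame 10, >= threshold for frames 10-30, below at 31
  tr <- c(rep(0, 9), rep(150, 21), rep(0, 10))
  ev <- detect_events(tr, 100, 12)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_frames, 21L)
  expect_equal(ev$dwell_min, 252)          # 21 frames x 12 min
  expect_equal(ev$t_on, 9 * 12)
  expect_equal(ev$t_off, 30 * 12)
  expect_false(ev$censored)
  # above at the first frame: censored
  ev2 <- detect_events(c(150, 150, 0, 0), 100, 12)
  expect_true(ev2$censored[1])
  expect_true(is.na(ev2$t_on[1]))
  # running past the last frame: censored, no t_off
  ev3 <- detect_events(c(0, 0, 150, 150), 100, 12)
  expect_true(ev3$censored[1])
  expect_true(is.na(ev3$t_off[1]))
})

test_that("detect_events matches a brute-force frame scan on random traces", {
  set.seed(123)
  for (i in 1:1000) {
    tr <- random_trace(200)
    ev <- detect_events(tr, threshold = 1, frame_interval = 12)
    bf <- brute_force_events(tr, 1, 12)
    expect_equal(nrow(ev), nrow(bf))
    if (nrow(bf)) {
      starts <- ifelse(bf$start == 1L, NA_real_, (bf$start - 1) * 12)
      ends <- ifelse(bf$end == 200L, NA_real_, bf$end * 12)
      expect_equal(ev$t_on, starts)
      expect_equal(ev$t_off, ends)
      expect_equal(ev$censored, bf$censored)
      expect_equal(ev$n_frames, bf$end - bf$start + 1L)
    }
  }
})

test_that("dwell_min is exactly n_frames times the frame interval", {
  set.seed(77)
  for (i in 1:200) {
    tr <- random_trace(120)
    ev <- detect_events(tr, 1, 12)
    unc <- ev[!ev$censored, ]
    expect_identical(unc$dwell_min, unc$n_frames * 12)
  }
})

test_that("events_per_100hr counts all onsets per observed time", {
  tr <- c(0, 150, 150, 0, 0, 150, 0)
  ev <- detect_events(tr, 100, 12)
  expect_equal(events_per_100hr(ev, 250), 2 / 250 * 100)
  expect_equal(events_per_100hr(list(ev, ev[0, ]), 250), 0.8)
  expect_equal(events_per_100hr(ev[0, ], 10), 0)
  expect_error(events_per_100hr(ev, 0), "> 0")
})

test_that("dwell_summary excludes censored events and applies the correction", {
  ev <- tibble::tibble(lineage_id = 1L, t_on = c(0, 100, 500, NA),
                       t_off = c(120, 340, 860, NA),
                       n_frames = c(10L, 20L, 30L, 5L),
                       dwell_min = c(120, 240, 360, NA),
                       censored = c(FALSE, FALSE, FALSE, TRUE))
  dw <- dwell_summary(ev)
  expect_equal(dw$mean_min, 240)
  expect_equal(dw$sd_min, 120)
  expect_equal(dw$n, 3)
  expect_equal(dw$n_censored, 1)
  expect_equal(dwell_summary(ev, correction_min = 6)$mean_min, 246)
  # single event: sd flagged as NA
  dw1 <- dwell_summary(ev[1, ])
  expect_equal(dw1$mean_min, 120)
  expect_true(is.na(dw1$sd_min))
  # all censored: documented error with the censored count
  expect_error(dwell_summary(ev[4, ]), "censored")
})

test_that("elongation_rate is exact on deterministic growth curves", {
  expect_equal(elongation_rate(rep(3, 10), 12)$rate_pct_per_hr, 0)
  # doubling per hour: 100 %/hr by definition
  L <- 2 * 2^((0:10) * 12 / 60)
  expect_equal(elongation_rate(L, 12)$rate_pct_per_hr, 100, tolerance = 1e-9)
  # closed form for slope 0.5/hr
  L2 <- exp((0:6) * (0.5 / 60) * 12)
  est <- elongation_rate(L2, 12)
  expect_equal(est$rate_pct_per_hr, 100 * (exp(0.5) - 1), tolerance = 1e-6)
  expect_equal(est$r2, 1)
})

test_that("elongation_rate is invariant to length rescaling and rejects bad input", {
  set.seed(3)
  L <- 3 * exp(0.008 * (0:8) * 12 + rnorm(9, 0, 0.01))
  a <- elongation_rate(L, 12)$rate_pct_per_hr
  b <- elongation_rate(L * 1000, 12)$rate_pct_per_hr   # um -> nm
  expect_equal(a, b, tolerance = 1e-12)
  expect_error(elongation_rate(c(3, 4), 12), ">= 3")
  expect_error(elongation_rate(c(3, 4, -1), 12), "positive")
  expect_error(elongation_rate(c(3, 5.9, 2.9, 3.4), 12), "division")
})

test_that("reporter_correlation computes both coefficients and guards input", {
  expect_equal(reporter_correlation(1:10, (1:10) * 3 + 2)$pearson, 1)
  expect_equal(reporter_correlation(1:10, -(1:10))$pearson, -1)
  expect_equal(reporter_correlation(1:10, -(1:10))$spearman, -1)
  expect_error(reporter_correlation(1:5, rep(1, 5)), "zero variance")
  expect_error(reporter_correlation(1:2, 2:1), "at least 3")
})

test_that("shared-state reporters correlate positively, more so with less noise", {
  set.seed(11)
  state <- rbinom(300, 1, 0.3)
  make <- function(sigma) {
    x <- 100 + 900 * state + rnorm(300, 0, sigma)
    y <- 120 + 800 * state + rnorm(300, 0, sigma)
    reporter_correlation(x, y)$pearson
  }
  lo_noise <- make(50); hi_noise <- make(600)
  expect_gt(lo_noise, 0)
  expect_gt(hi_noise, 0)
  expect_gt(lo_noise, hi_noise)
})

test_that("per_state_growth splits windows by >= 50% event overlap", {
  # two synthetic cells with known growth, one inside an event
  mk <- function(id, r, frames) data.frame(
    cell_id = id, parent_id = NA_integer_, channel_id = 1L,
    frame = frames, t_min = (frames - 1) * 12,
    length_um = 3 * exp(r * (frames - min(frames)) * 12),
    f_sucC = 0, f_alsS = 0, state_sucC = 0L, state_alsS = 0L, fate = "live")
  lin <- rbind(mk(1L, log(1.74) / 60, 1:10),                 # 74 %/hr
               mk(2L, log(1.63) / 60, 1:10))                 # 63 %/hr
  ev <- tibble::tibble(lineage_id = 2L, t_on = 0, t_off = 120,
                       n_frames = 10L, dwell_min = 120, censored = FALSE)
  ps <- per_state_growth(lin, ev, 12)
  expect_equal(ps$state_on$n, 1)
  expect_equal(ps$state_off$n, 1)
  expect_equal(ps$state_on$mean, 63, tolerance = 1e-6)
  expect_equal(ps$state_off$mean, 74, tolerance = 1e-6)
  # no events: on class absent
  ps2 <- per_state_growth(lin, ev[0, ], 12)
  expect_null(ps2$state_on)
  expect_equal(ps2$state_off$n, 2)
})
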