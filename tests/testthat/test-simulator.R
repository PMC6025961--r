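test_that("parameter and scenario validation enforce the model invariants", {
  expect_error(switch_params(k_on_sucC = -1), "non-negative")
  expect_error(switch_params(penalty_alsS = 1.4), "\\[0, 1\\]")
  expect_error(switch_params(h_alsS = 0.5), "h_alsS")
  expect_error(switch_params(y_acetoin = 0), "y_acetoin")
  expect_error(switch_params(nonsense = 1), "unknown parameter")
  expect_error(scenario_config("batch", duration = 100, frame_interval = 30),
               "divide")
  expect_error(scenario_config("mother_machine", channel_capacity = 0),
               "channel_capacity")
  expect_error(scenario_config("batch", initial_env = list(acetate = -2)),
               ">= 0")
  cfg <- scenario_config("batch", comK_null = TRUE)
  expect_equal(metaswitch:::.effective_params(switch_params(), cfg)$k_on_sucC, 0)
})

test_that("batch with zero tracked cells leaves the environment constant", {
  cfg <- scenario_config("batch", duration = 120, frame_interval = 30,
                         seed = 1, n_sample = 0)
  run <- simulate_batch(switch_params(), cfg)
  env <- run$environment
  for (col in c("biomass", "glucose_mM", "malate_mM", "acetate_mM", "acetoin_mM"))
    expect_equal(env[[col]], rep(env[[col]][1], nrow(env)))
})

test_that("batch acetate rises then falls once, acetoin never decreases", {
  run <- simulate_batch(switch_params(),
                        scenario_config("batch", duration = 960,
                                        frame_interval = 30, seed = 5))
  e <- run$environment
  ph <- detect_phases(e[, c("t_min", "acetate_mM")])
  expect_equal(ph$n_production_runs, 1)
  expect_equal(ph$n_consumption_runs, 1)
  expect_true(all(diff(e$acetoin_mM) >= 0))
  expect_gt(max(e$acetate_mM), 5)
})

test_that("closed-run acetate bookkeeping balances exactly", {
  for (seed in c(2, 8)) {
    run <- simulate_batch(switch_params(),
                          scenario_config("batch", duration = 600,
                                          frame_interval = 30, seed = seed,
                                          n_sample = 300))
    e <- run$environment
    prod <- utils::tail(e$cum_acetate_produced, 1)
    cons <- utils::tail(e$cum_acetate_consumed, 1)
    expect_equal(prod - cons, utils::tail(e$acetate_mM, 1) - e$acetate_mM[1],
                 tolerance = 1e-10)
    expect_equal(utils::tail(e$acetoin_mM, 1) - e$acetoin_mM[1],
                 switch_params()$y_acetoin * cons, tolerance = 1e-10)
  }
})

test_that("comK knockout strongly reduces peak acetate at matched seed", {
  cfg <- scenario_config("batch", duration = 960, frame_interval = 30, seed = 3)
  wt <- simulate_batch(switch_params(), cfg)
  cfg$comK_null <- TRUE
  ko <- simulate_batch(switch_params(), cfg)
  expect_lt(max(ko$environment$acetate_mM), max(wt$environment$acetate_mM))
  expect_lt(max(ko$environment$acetate_mM), 0.5 * max(wt$environment$acetate_mM))
})

test_that("simulations are bit-identical under the same seed and config", {
  cfg <- scenario_config("batch", duration = 240, frame_interval = 30,
                         seed = 17, n_sample = 100)
  a <- simulate_batch(switch_params(), cfg)
  b <- simulate_batch(switch_params(), cfg)
  expect_identical(a$environment, b$environment)
  expect_identical(a$snapshots, b$snapshots)
  cfgm <- scenario_config("mother_machine", duration = 240, seed = 17,
                          n_channels = 4)
  expect_identical(simulate_mother_machine(switch_params(), cfgm),
                   simulate_mother_machine(switch_params(), cfgm))
})

test_that("mother machine keeps one mother record per channel per frame", {
  cfg <- scenario_config("mother_machine", duration = 480, seed = 2,
                         n_channels = 5, channel_capacity = 3)
  lin <- simulate_mother_machine(switch_params(), cfg)
  n_frames <- 480 / 12 + 1
  per_channel <- table(lin$channel_id[!duplicated(paste(lin$channel_id, lin$frame))])
  expect_true(all(per_channel == n_frames))
  expect_setequal(unique(lin$channel_id), 1:5)
  # zero channels: empty table with the full dialect
  empty <- simulate_mother_machine(switch_params(),
                                   scenario_config("mother_machine",
                                                   duration = 60, n_channels = 0))
  expect_equal(nrow(empty), 0)
  expect_named(empty, metaswitch:::.lineage_cols)
})

test_that("absorbing off-states produce no activation events", {
  p <- switch_params(k_on_sucC = 0, k0_alsS = 0, kmax_alsS = 0)
  cfg <- scenario_config("mother_machine", duration = 960, seed = 4,
                         n_channels = 10, channel_capacity = 2,
                         media_condition = list(acetate = 20, quorum = 1))
  lin <- simulate_mother_machine(p, cfg)
  expect_true(all(lin$state_sucC == 0))
  expect_true(all(lin$state_alsS == 0))
  for (tr in mother_traces(lin, "state_sucC"))
    expect_equal(nrow(detect_events(tr, 0.5, 12)), 0)
})

test_that("mother-machine on-episodes have the configured exponential mean", {
  p <- switch_params(k_on_sucC = 1 / 252, k_off_sucC = 1 / 252,
                     k0_alsS = 0, kmax_alsS = 0)
  cfg <- scenario_config("mother_machine", duration = 4200, seed = 31,
                         n_channels = 50, channel_capacity = 1)
  lin <- simulate_mother_machine(p, cfg)
  traces <- mother_traces(lin, "state_sucC")
  ev <- dplyr::bind_rows(lapply(seq_along(traces), function(i)
    detect_events(traces[[i]], 0.5, 12, lineage_id = i)))
  dw <- dwell_summary(ev, correction_min = 6)
  expect_gt(dw$n, 300)
  expect_lt(abs(dw$mean_min - 252) / 252, 0.10)
})

test_that("on-state occupancy converges to k_on / (k_on + k_off)", {
  k_on <- 1 / 300; k_off <- 1 / 252
  p <- switch_params(k_on_sucC = k_on, k_off_sucC = k_off,
                     k0_alsS = 0, kmax_alsS = 0)
  cfg <- scenario_config("mother_machine", duration = 4200, seed = 13,
                         n_channels = 145, channel_capacity = 1)
  lin <- simulate_mother_machine(p, cfg)
  expect_gt(145 * 4200 / 60, 1e4)            # cell-hours observed
  occ <- vapply(mother_traces(lin, "state_sucC"), mean, numeric(1))
  se <- stats::sd(occ) / sqrt(length(occ))
  expect_lt(abs(mean(occ) - k_on / (k_on + k_off)), 3 * se)
})

test_that("alsS occupancy is zero without acetate or basal activation", {
  p <- switch_params(k0_alsS = 0)
  cfg <- scenario_config("mother_machine", duration = 960, seed = 6,
                         n_channels = 10, channel_capacity = 2,
                         media_condition = list(acetate = 0, quorum = 1))
  lin <- simulate_mother_machine(p, cfg)
  expect_true(all(lin$state_alsS == 0))
})

test_that("alsS steady-state occupancy increases with ambient acetate", {
  p <- switch_params()
  occ <- vapply(c(0, 10, 20), function(a) {
    per_seed <- vapply(1:10, function(s) {
      cfg <- scenario_config("mother_machine", duration = 1200, seed = 200 + s,
                             n_channels = 20, channel_capacity = 2,
                             media_condition = list(acetate = a, quorum = 1))
      mean(simulate_mother_machine(p, cfg)$state_alsS)
    }, numeric(1))
    mean(per_seed)
  }, numeric(1))
  expect_true(all(diff(occ) > 0))
})

test_that("deterministic pad limit gives exact doublings", {
  # division every 60 min over 180 min: 2^3 live cells from one founder
  p <- deterministic_params()
  cfg <- scenario_config("pad", duration = 180, frame_interval = 60, seed = 1,
                         n_founders = 1, initial_env = list(acetate = 0))
  # founder must start at half the division length for exact timing
  run <- simulate_pad(p, cfg)
  lin <- run$lineage
  final <- lin[lin$frame == max(lin$frame), ]
  expect_equal(nrow(final), 8)
  expect_true(all(final$fate == "live"))
  # genealogy: 8 leaves, depth 3, binary throughout
  tree <- build_genealogy(lin)
  expect_equal(sum(tree$nodes$n_daughters == 0), 8)
  expect_true(all(tree$nodes$n_daughters %in% c(0L, 2L)))
})

test_that("division disabled yields one undivided lineage", {
  p <- deterministic_params(L_div = Inf)
  cfg <- scenario_config("pad", duration = 120, frame_interval = 60, seed = 1,
                         n_founders = 1)
  lin <- simulate_pad(p, cfg)$lineage
  expect_equal(unique(lin$cell_id), 1L)
  expect_true(all(is.na(lin$parent_id)))
})

test_that("pad growth recovers as alsS+ cells detoxify acetate", {
  cfg <- scenario_config("pad", duration = 1320, frame_interval = 12, seed = 2)
  run <- simulate_pad(switch_params(), cfg)
  e <- run$environment
  expect_lt(utils::tail(e$acetate_mM, 1), e$acetate_mM[1])
  rates <- cell_cycle_rates(run$lineage, 12)
  early <- rates$rate_pct_per_hr[rates$t_last <= 120]
  late <- rates$rate_pct_per_hr[rates$t_first >= 1200]
  expect_gt(mean(late), mean(early))
  # with detox disabled the environment does not recover
  cfg$alsS_null <- TRUE
  run0 <- simulate_pad(switch_params(), cfg)
  expect_gte(utils::tail(run0$environment$acetate_mM, 1), e$acetate_mM[1])
})

test_that("reporter_update follows exact stable-reporter dynamics", {
  p <- switch_params()
  # off state with zero production stays at zero
  p0 <- switch_params(beta_off = 0)
  st <- list(sucC_state = FALSE, alsS_state = FALSE, F_sucC = 0, F_alsS = 0)
  expect_equal(reporter_update(st, 100, p0)$F_sucC, 0)
  # on-state steady state is beta_on / r
  r <- p$r_base * p$penalty_sucC
  st_on <- list(sucC_state = TRUE, alsS_state = FALSE,
                F_sucC = p$beta_on / r, F_alsS = 0)
  expect_equal(reporter_update(st_on, 50, p)$F_sucC, p$beta_on / r,
               tolerance = 1e-12)
  # decay after switch-off matches the closed form with e-folding 1/r
  r_off <- p$r_base
  st_hi <- list(sucC_state = FALSE, alsS_state = FALSE,
                F_sucC = 5000, F_alsS = 0)
  for (dt in c(10, 60, 300)) {
    got <- reporter_update(st_hi, dt, p, growth_rate = r_off)$F_sucC
    want <- p$beta_off / r_off + (5000 - p$beta_off / r_off) * exp(-r_off * dt)
    expect_equal(got, want, tolerance = 1e-6)
  }
})
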