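test_that("figure-ground segregation: figure bursts, surround stays silent", {
  r <- fg_seg_full()
  val <- function(layer, region, channel)
    r$count[r$layer == layer & r$region == region & r$channel == channel]
  expect_equal(val(1, "figure", "1"), 12)       # driven layer-1 burst
  expect_equal(val(1, "ground", "1"), 0)
  expect_equal(val(2, "figure", "1"), 12)       # layer 2 follows its drive
  expect_equal(val(2, "ground", "1"), 0)
  expect_equal(val(2, "ground", "2"), 0)        # complement channel quiescent
  expect_equal(attr(r, "modulation_index"),
               val(2, "figure", "avg") - val(2, "ground", "avg"))
  expect_gt(attr(r, "modulation_index"), 0)
})

test_that("identical drive to both channels gives zero modulation", {
  # degenerate control: figure indistinguishable from ground
  u <- make_uniform_mask(16)
  net <- network_config(N = 16)
  sch <- build_schedule(list(stim_event(1, u, 0, Inf, net$w_input),
                             stim_event(2, u, 0, Inf, net$w_input)),
                        duration_ms = 60)
  r <- run_network(sch, net)
  f <- region_spec(16, 4, "figure")
  g <- region_spec(16, 4, "ground")
  expect_equal(modulation_index(count_spikes(r, f, c(0, 50)),
                                count_spikes(r, g, c(0, 50))), 0)
})

test_that("masking weakens figure-ground modulation; controls are SOA-independent", {
  cfg <- experiment_config(N = 32, fig_size = 8, n_seeds = 3,
                           soa_fg = c(3, 10))
  pm <- run_fg_masking(cfg, "pattern")
  s <- attr(pm, "summary")
  nm <- attr(pm, "controls")$NM
  expect_true(all(s$mi < nm$mi))
  expect_true(all(s$mi_sem > 0))                  # pattern masks vary by seed
  expect_true(all(c("repeat_id", "mask_seed") %in% names(pm)))
  expect_true(all(!is.na(pm$mask_seed)))          # seed traceability
  # the no-mask control does not depend on the SOA grid
  cfg2 <- experiment_config(N = 32, fig_size = 8, n_seeds = 3,
                            soa_fg = c(5, 20, 50))
  pm2 <- run_fg_masking(cfg2, "pattern")
  expect_identical(attr(pm2, "controls")$NM, nm)
  um <- run_fg_masking(cfg, "uniform")
  expect_true(all(is.na(attr(um, "summary")$mi_sem) |
                    attr(um, "summary")$mi_sem == 0))
})

test_that("pattern-mask SEM shrinks roughly like one over the square root of n", {
  base <- function(n) experiment_config(N = 32, fig_size = 8, n_seeds = n,
                                        soa_fg = 3)
  s20 <- attr(run_fg_masking(base(20), "pattern"), "summary")$mi_sem
  s5 <- attr(run_fg_masking(base(5), "pattern"), "summary")$mi_sem
  expect_gt(s5 / s20, 1.0)
  expect_lt(s5 / s20, 4.5)
})

test_that("the surround mask alone evokes no central response", {
  cfg <- full_config()
  pair <- make_metacontrast_pair(cfg$N, cfg$fig_size)
  net <- network_config(N = cfg$N, inhibition = "both", excitation = "both")
  sch <- build_schedule(list(
    stim_event(1, pair$mask, 0, 50, cfg$w_input),
    stim_event(2, pair$mask, 50, cfg$off_pulse_ms, cfg$w_input)),
    duration_ms = 110)
  r <- run_network(sch, net)
  fig <- region_spec(cfg$N, cfg$fig_size, "figure")
  expect_equal(count_spikes(r, fig, c(0, 100)), 0)
  expect_equal(count_spikes(r, fig, c(0, 100), layer = 1, channels = 1L), 0)
})

test_that("metacontrast suppression is strongest near mask transitions", {
  m <- meta_accept()
  for (dm in c(50, 100)) {
    s <- m[m$mask_dur == dm, ]
    # layer 1 is essentially unaffected by the mask
    ctrl_l1 <- attr(m, "controls")["l1", "25"]
    expect_true(all(abs(s$response_l1 - ctrl_l1) <= 1))
    # strong suppression somewhere, recovery at the extremes of the sweep
    expect_gt(max(s$suppression), 30)
    expect_lt(abs(s$suppression[which.max(s$soa)]), 5)
    d <- attr(m, "dips")[[sprintf("t25_m%d", dm)]]
    d <- d[order(-d$suppression), ]
    # the deepest dips sit one target-duration from a mask transition
    expect_equal(d$gap_ms[1:2], c(25, 25))
  }
})

test_that("repetition masking dips at intermediate SOA and recovers fully", {
  rr <- repetition_runs()
  rn <- rr$normal
  expect_equal(rn$normalized[rn$soa == 300], 1, tolerance = 0.05)
  dip <- attr(rn, "dip")
  expect_true(dip$soa %in% c(20, 30, 50))         # intermediate, not extreme
  expect_lt(dip$normalized, 0.7)
  # the shortest SOA barely suppresses (repetition masking's signature)
  expect_gt(rn$normalized[rn$soa == 10], 0.8)
  # a higher-contrast second target shallows the dip
  expect_lt(attr(rr$high, "dip")$suppression_pct, dip$suppression_pct)
})

test_that("repetition SOAs below the target duration are rejected", {
  cfg <- experiment_config(N = 16, fig_size = 4, soa_rep = c(5, 20))
  expect_error(run_repetition(cfg), "SOA")
})
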