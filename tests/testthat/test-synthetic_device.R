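test_that("capture model validates probabilities and rejects unknown mouths", {
  cm <- capture_model()
  expect_error(simulate_capture(cm, 10, mouth_um = 7), "mouth")
  expect_error(capture_model(list(`6` = list(p_none = 0.5, p_single = 0.6,
                                             p_multiple = 0.1))), "sum to 1")
  # deterministic capture
  all_single <- capture_model(list(`6` = list(p_none = 0, p_single = 1,
                                              p_multiple = 0)))
  expect_true(all(simulate_capture(all_single, 50, seed = 1) == "single"))
})

test_that("capture draws hit the configured single fraction and reproduce under a seed", {
  cm <- capture_model()
  occ <- simulate_capture(cm, 10000, seed = 42)
  frac <- mean(occ == "single")
  se <- sqrt(0.842 * (1 - 0.842) / 10000)
  expect_lt(abs(frac - 0.842), 3 * se)
  expect_identical(occ, simulate_capture(cm, 10000, seed = 42))
})

test_that("sampled cells follow the population model", {
  pop <- population_model("g", 0.0864, cv_strain = 0.35)
  cells <- sample_cells(pop, 20000, seed = 7)
  se <- 0.0864 * 0.35 / sqrt(20000)
  expect_lt(abs(mean(cells$true_strain) - 0.0864), 3 * se)
  expect_identical(cells, sample_cells(pop, 20000, seed = 7))
  # zero-variance population: identical cells
  det <- population_model("d", 0.1, cv_strain = 0, sd_length_um = 0,
                          p_broken = 0)
  cd <- sample_cells(det, 5, seed = 1)
  expect_true(all(cd$true_strain == 0.1))
  expect_true(all(cd$init_length_um == 16))
  expect_error(population_model("g", -1), "positive")
  expect_error(sample_cells(pop, 0), "positive")
})

test_that("stretch traces have the exact sampling grid and recover truth", {
  cfg <- controller_config()
  cell <- data.frame(cell_id = "x", group = "g", true_strain = 0.09,
                     init_length_um = 16, broken = FALSE)
  # noise-free, instantaneous response: exact recovery
  tr <- simulate_stretch_trace(cell, cfg, noise_sd_um = 0, tau_s = 1e-12)
  expect_equal(nrow(tr), 501)  # 50 fps x 10 s inclusive
  expect_equal(strain_from_trace(tr)$strain, 0.09, tolerance = 1e-12)
  # finite tau: closed-form shortfall exp(-duration/tau)
  tr2 <- simulate_stretch_trace(cell, cfg, noise_sd_um = 0, tau_s = 2)
  expect_equal(strain_from_trace(tr2)$strain, 0.09 * (1 - exp(-5)),
               tolerance = 1e-12)
})

test_that("frame noise biases the min/max strain upward as the MC oracle predicts", {
  cfg <- controller_config()
  cell <- data.frame(cell_id = "x", group = "g", true_strain = 0.0864,
                     init_length_um = 16, broken = FALSE)
  set.seed(55)
  rec <- replicate(100, strain_from_trace(
    simulate_stretch_trace(cell, cfg, noise_sd_um = 0.05, tau_s = 2))$strain)
  bias <- mean(rec) - 0.0864 * (1 - exp(-5))
  # positive and of the order of 2 * noise_sd * sqrt(2 log n_frames) / L0
  expect_gt(bias, 0)
  expect_lt(bias, 2 * 0.05 * sqrt(2 * log(501)) / 16)
})

test_that("broken cells emit collapsing traces caught by QC", {
  cfg <- controller_config()
  cell <- data.frame(cell_id = "x", group = "g", true_strain = 0.09,
                     init_length_um = 16, broken = TRUE)
  tr <- simulate_stretch_trace(cell, cfg, noise_sd_um = 0, tau_s = 2,
                               seed = 3)
  res <- analyze_traces(tr, 17.6)
  expect_equal(res$qc_flag, "broken")
})

test_that("controller cycles obey the state machine and count bookkeeping", {
  cfg <- controller_config()
  cap <- capture_model()
  pop <- population_model("g", 0.0864)
  expect_error(run_cycles(cfg, cap, pop, 1, n_ports = 5), "unreachable")
  log <- run_cycles(cfg, cap, pop, n_cycles = 30, seed = 17,
                    emit_traces = FALSE)
  by_cycle <- split(log$events, log$events$cycle)
  for (ev in by_cycle) {
    expect_equal(ev$state, c("capture", "stretch", "release"))
    expect_true(all(diff(ev$time_s) > 0))
    # stretch phase lasts exactly the configured duration
    expect_equal(ev$time_s[3] - ev$time_s[2], cfg$stretch_duration_s)
  }
  expect_equal(sum(log$measured), sum(log$occupancy$occupancy == "single"))
  # full release: no carry-over occupancy between cycles
  expect_identical(log, run_cycles(cfg, cap, pop, n_cycles = 30, seed = 17,
                                   emit_traces = FALSE))
})

test_that("deterministic capture saturates every port each cycle", {
  cfg <- controller_config(capture_count_threshold = 20)
  all_single <- capture_model(list(`6` = list(p_none = 0, p_single = 1,
                                              p_multiple = 0)))
  pop <- population_model("g", 0.0864, p_broken = 0)
  log <- run_cycles(cfg, all_single, pop, n_cycles = 5, seed = 2)
  expect_true(all(log$measured == 20))
  expect_equal(length(unique(log$traces$cell_id)), 100)
  # release efficiency 1: occupancy cleared each cycle (re-draw fills all)
  expect_equal(sum(log$occupancy$occupancy != "single"), 0)
})

test_that("measured totals match the analytic expectation over many cycles", {
  cfg <- controller_config(capture_count_threshold = 1,
                           max_capture_attempts = 1)
  cap <- capture_model()
  pop <- population_model("g", 0.0864)
  n_cycles <- 100
  log <- run_cycles(cfg, cap, pop, n_cycles = n_cycles, seed = 23,
                    emit_traces = FALSE)
  # one draw per cycle across 20 ports, full release: Binomial(2000, 0.842)
  expected <- n_cycles * 20 * 0.842
  se <- sqrt(n_cycles * 20 * 0.842 * (1 - 0.842))
  expect_lt(abs(sum(log$measured) - expected), 3 * se)
})

test_that("end-to-end recovery is exact for noise-free instantaneous response", {
  pa <- population_model("normal", 0.0864, noise_sd_um = 0, tau_s = 1e-12,
                         p_broken = 0)
  pb <- population_model("treated", 0.1013, noise_sd_um = 0, tau_s = 1e-12,
                         p_broken = 0)
  # zero-variance populations: recovery must be exact, not just unbiased
  pa0 <- population_model("normal", 0.0864, cv_strain = 0, noise_sd_um = 0,
                          tau_s = 1e-12, p_broken = 0)
  pb0 <- population_model("treated", 0.1013, cv_strain = 0, noise_sd_um = 0,
                          tau_s = 1e-12, p_broken = 0)
  rec0 <- end_to_end_recovery(pa0, pb0, n_per_group = 20, seed = 9)
  expect_equal(rec0$groups[[1]]$minmax$mean_strain, 0.0864, tolerance = 1e-12)
  expect_equal(rec0$groups[[2]]$minmax$mean_strain, 0.1013, tolerance = 1e-12)
  expect_equal(rec0$groups[[1]]$minmax$mean_modulus, 203.7, tolerance = 1e-9)
  # dispersed populations: recovered sample mean within sampling error
  rec <- end_to_end_recovery(pa, pb, n_per_group = 400, seed = 9)
  for (g in rec$groups) {
    expect_lt(abs(g$minmax$mean_strain - g$truth_mean_strain),
              4 * g$minmax$se_strain)
  }
  # identical groups: recovered difference consistent with zero
  rec2 <- end_to_end_recovery(pa, pa, n_per_group = 40, seed = 9)
  expect_lt(abs(rec2$groups[[1]]$minmax$mean_strain -
                rec2$groups[[2]]$minmax$mean_strain),
            3 * (rec2$groups[[1]]$minmax$se_strain +
                 rec2$groups[[2]]$minmax$se_strain))
})
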