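# dF/F0 normalization, spike detection against simulator truth, per-ROI
# statistics, synchrony, and the NMDA/AMPA ratio.

flat_trace_set <- function(f, n = 300, rate = 5) {
  structure(list(time_s = (seq_len(n) - 1) / rate,
                 F = matrix(f, nrow = 1, ncol = n,
                            dimnames = list("roi001", NULL)),
                 frame_rate_hz = rate),
            class = "trace_set")
}

test_that("dF/F0 basics: constant trace, direct formula, scale invariance", {
  tr <- flat_trace_set(100)
  expect_true(all(compute_dff(tr) == 0))
  # transient peak: F0 = 100, F = 300 -> dF/F0 = 2
  tr2 <- flat_trace_set(100)
  tr2$F[1, 150] <- 300
  expect_equal(unname(compute_dff(tr2)[1, 150]), 2.0)
  # multiplying a trace by 5 leaves dF/F0 unchanged
  tr5 <- tr2
  tr5$F <- tr5$F * 5
  expect_equal(compute_dff(tr5), compute_dff(tr2))
  trz <- flat_trace_set(0)
  expect_error(compute_dff(trz), "baseline")
})

test_that("noiseless simulated spikes are recovered exactly", {
  cfg <- sim_calcium_config(n_rois = 6, duration_s = 180, noise_sd = 0,
                            cell_rate_per_min = 2, sync_rate_per_min = 0,
                            amp_mean = 1, amp_sd = 0, decay_tau_s = 1,
                            min_separation_s = 8, seed = 41)
  sim <- simulate_calcium_traces(cfg)
  dff <- compute_dff(sim$traces)
  sp <- detect_spikes(dff, cfg$frame_rate_hz)
  for (roi in names(sim$truth$spike_times)) {
    expect_equal(sp$times[[roi]], sim$truth$spike_times[[roi]],
                 tolerance = 0.21)
    expect_equal(length(sp$times[[roi]]),
                 length(sim$truth$spike_times[[roi]]))
    if (length(sp$amplitudes[[roi]]) > 0) {
      expect_equal(sp$amplitudes[[roi]], sim$truth$spike_amplitudes[[roi]],
                   tolerance = 0.02)
    }
  }
})

test_that("flat traces yield zero events; close peaks collapse to one", {
  dff <- matrix(0, nrow = 2, ncol = 200, dimnames = list(c("a", "b"), NULL))
  sp <- detect_spikes(dff, 5)
  expect_equal(lengths(sp$times), c(a = 0L, b = 0L))
  # two peaks 0.4 s apart with 1 s refractory: only the larger survives
  dff2 <- matrix(0, nrow = 1, ncol = 100, dimnames = list("a", NULL))
  dff2[1, 50] <- 1.0
  dff2[1, 52] <- 0.6          # 0.4 s later at 5 Hz
  sp2 <- detect_spikes(dff2, 5, refractory_s = 1)
  expect_equal(length(sp2$times[["a"]]), 1L)
  expect_equal(sp2$amplitudes[["a"]], 1.0)
})

test_that("spike statistics follow the stated formulas", {
  sp <- structure(list(
    times = list(a = c(10, 50), b = numeric(0), c = seq(10, 170, 20)),
    amplitudes = list(a = c(1, 3), b = numeric(0), c = rep(1, 9)),
    duration_s = 120), class = "spike_train_set")
  st <- spike_statistics(sp)
  expect_equal(st$amplitude[st$roi == "a"], 2.0)
  expect_equal(st$frequency_per_min[st$roi == "a"], 1.0)
  expect_true(is.na(st$amplitude[st$roi == "b"]))
  expect_equal(st$frequency_per_min[st$roi == "b"], 0)
  # 9 events in 180 s -> 3 per minute
  sp$duration_s <- 180
  st2 <- spike_statistics(sp)
  expect_equal(st2$frequency_per_min[st2$roi == "c"], 3.0)
})

test_that("synchrony counts co-firing windows and is monotone", {
  sp <- structure(list(
    times = list(a = c(10, 40), b = c(10, 40), c = c(10, 40)),
    amplitudes = list(a = c(1, 1), b = c(1, 1), c = c(1, 1)),
    duration_s = 60), class = "spike_train_set")
  sy <- synchronous_firing_rate(sp, participation = 1.0)
  expect_equal(sy$n_events, 2L)
  expect_equal(sy$rate_per_min, 2.0)
  expect_equal(sy$sync_event_times, c(10, 40))
  # monotone non-increasing in participation
  sp2 <- sp
  sp2$times$c <- c(10.1, 80)
  r_low <- synchronous_firing_rate(sp2, participation = 0.1)$rate_per_min
  r_mid <- synchronous_firing_rate(sp2, participation = 0.7)$rate_per_min
  r_hi <- synchronous_firing_rate(sp2, participation = 1.0)$rate_per_min
  expect_true(r_low >= r_mid && r_mid >= r_hi)
  expect_error(synchronous_firing_rate(sp, participation = 0), "participation")
})

test_that("independent sparse trains produce (almost) no synchrony", {
  cfg <- sim_calcium_config(n_rois = 10, duration_s = 180, noise_sd = 0,
                            cell_rate_per_min = 1, sync_rate_per_min = 0,
                            amp_sd = 0.1, seed = 8)
  sim <- simulate_calcium_traces(cfg)
  sp <- detect_spikes(compute_dff(sim$traces), cfg$frame_rate_hz)
  sy <- synchronous_firing_rate(sp, participation = 0.8)
  expect_lte(sy$n_events, 1L)
})

test_that("planted network events are recovered at the planted rate", {
  cfg <- sim_calcium_config(n_rois = 8, duration_s = 120, noise_sd = 0,
                            cell_rate_per_min = 0, sync_rate_per_min = 5,
                            sync_participation = 1, amp_sd = 0.1, seed = 14)
  sim <- simulate_calcium_traces(cfg)
  sp <- detect_spikes(compute_dff(sim$traces), cfg$frame_rate_hz)
  sy <- synchronous_firing_rate(sp, participation = 1.0)
  expect_lte(abs(sy$n_events - length(sim$truth$sync_event_times)), 1)
})

test_that("halving a recording conserves events and doubles the rate", {
  sp <- structure(list(
    times = list(a = c(10, 100), b = c(10, 100)),
    amplitudes = list(a = c(1, 1), b = c(1, 1)),
    duration_s = 120), class = "spike_train_set")
  st <- spike_statistics(sp)
  expect_equal(st$frequency_per_min, c(1, 1))
  first <- structure(list(times = lapply(sp$times, function(x) x[x < 60]),
                          amplitudes = lapply(sp$amplitudes, `[`, 1),
                          duration_s = 60), class = "spike_train_set")
  second <- structure(list(times = lapply(sp$times, function(x) x[x >= 60]),
                           amplitudes = lapply(sp$amplitudes, `[`, 2),
                           duration_s = 60), class = "spike_train_set")
  n_total <- sum(lengths(first$times)) + sum(lengths(second$times))
  expect_equal(n_total, sum(lengths(sp$times)))
  expect_equal(spike_statistics(first)$frequency_per_min, c(1, 1) * 2 / 2 * 1)
})

test_that("NMDA/AMPA ratio reads 20 ms post-onset over the AMPA peak", {
  t_s <- seq(0, 0.1, by = 5e-4)
  # +40 mV: NMDA-like slow biexponential; -70 mV: fast AMPA transient
  onset <- 0.01
  i40 <- ifelse(t_s >= onset,
                60 * (exp(-(t_s - onset) / 0.05) -
                        exp(-(t_s - onset) / 0.004)), 0)
  i70 <- ifelse(t_s >= onset,
                -60 * (exp(-(t_s - onset) / 0.008) -
                         exp(-(t_s - onset) / 0.001)), 0)
  pair <- list(trace_plus40 = data.frame(time_s = t_s, current_pA = i40),
               trace_minus70 = data.frame(time_s = t_s, current_pA = i70),
               onset_s = onset)
  got <- nmda_ampa_ratio(pair)
  # closed-form oracle at the same read-outs
  nmda <- 60 * (exp(-0.02 / 0.05) - exp(-0.02 / 0.004))
  tpk <- log(0.008 / 0.001) / (1 / 0.001 - 1 / 0.008)
  ampa <- 60 * (exp(-tpk / 0.008) - exp(-tpk / 0.001))
  expect_equal(got, nmda / ampa, tolerance = 0.01)
  # trivial ratio: 30 pA read-out over 60 pA peak
  pair2 <- list(
    trace_plus40 = data.frame(time_s = c(0, 0.02, 0.04),
                              current_pA = c(0, 30, 30)),
    trace_minus70 = data.frame(time_s = c(0, 0.01, 0.04),
                               current_pA = c(0, -60, 0)),
    onset_s = 0)
  expect_equal(nmda_ampa_ratio(pair2), 0.5)
  # zero NMDA component
  pair3 <- pair2
  pair3$trace_plus40$current_pA <- c(0, 0, 0)
  expect_equal(nmda_ampa_ratio(pair3), 0)
  pair4 <- pair2
  pair4$trace_minus70$current_pA <- c(0, 0, 0)
  expect_error(nmda_ampa_ratio(pair4), "zero")
})
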