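test_that("SNR decays as a power law anchored at the noise floor", {
  expect_equal(snr(80), 1)
  expect_equal(snr(40), 4)
  r <- seq(5, 2000, by = 5)
  s <- snr(r)
  expect_true(all(diff(s) < 0))
  expect_lt(snr(1e6), 1e-6)
  # coincident points clip at r_min instead of diverging
  expect_equal(snr(0), snr(spike_detector_config()$r_min))
})

test_that("strong, noiseless spikes are always detected", {
  cfg <- spike_detector_config(cv = 0)
  spikes <- data.frame(time_ms = seq(10, 500, by = 10), neuron = 1)
  d <- matrix(10, 1, 1)  # a(r) = 64 >> theta
  set.seed(2)
  ev <- detect_crossings(spikes, d, cfg, duration_ms = 500,
                         noise_events = FALSE)
  expect_equal(nrow(ev), nrow(spikes))
  expect_true(all(ev$amplitude > cfg$threshold))
})

test_that("a spike at exactly threshold amplitude is detected half the time", {
  cfg <- spike_detector_config(cv = 0)
  r_at_theta <- 80 / sqrt(4)  # a(r) = 4 = theta
  spikes <- data.frame(time_ms = seq_len(1e4), neuron = 1)
  set.seed(3)
  ev <- detect_crossings(spikes, matrix(r_at_theta, 1, 1), cfg,
                         duration_ms = 1e4 + 1, noise_events = FALSE)
  p_hat <- nrow(ev) / 1e4
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("noise-event counts follow the Gaussian-tail Poisson oracle", {
  cfg <- spike_detector_config()
  n_ch <- 5000
  d <- matrix(1e6, n_ch, 1)  # neurons effectively invisible
  set.seed(4)
  ev <- detect_crossings(data.frame(time_ms = numeric(0),
                                    neuron = integer(0)),
                         d, cfg, duration_ms = 1000)
  expected <- 30000 * pnorm(4, lower.tail = FALSE)  # ~0.95 per channel-second
  counts <- tabulate(ev$channel, nbins = n_ch)
  se <- sqrt(expected / n_ch)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  expect_true(all(ev$amplitude > cfg$threshold))
})

test_that("collision sampling masks the smaller of coincident events only", {
  cfg <- spike_detector_config()
  iso <- data.frame(time_ms = c(10, 50), channel = c(1, 1),
                    neuron = c(1, 1), amplitude = c(5, 6))
  expect_equal(nrow(sample_collisions(iso, cfg)), 2)
  coinc <- data.frame(time_ms = c(20, 20), channel = 1, neuron = 1:2,
                      amplitude = c(5, 7))
  set.seed(6)
  out <- sample_collisions(coinc, cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$amplitude, 7)
  apart <- data.frame(time_ms = c(20, 21), channel = 1, neuron = 1:2,
                      amplitude = c(5, 7))
  expect_equal(nrow(sample_collisions(apart, cfg)), 2)
})

test_that("collision sampling never adds events and is skippable", {
  cfg <- spike_detector_config()
  set.seed(7)
  ev <- data.frame(time_ms = sort(runif(200, 0, 100)),
                   channel = sample(1:4, 200, TRUE),
                   neuron = sample(1:20, 200, TRUE),
                   amplitude = 4 + rexp(200))
  ev <- ev[order(ev$channel, ev$time_ms), ]
  out <- sample_collisions(ev, cfg)
  expect_lte(nrow(out), nrow(ev))
  expect_true(all(paste(out$time_ms, out$channel) %in%
                    paste(ev$time_ms, ev$channel)))
  # tau_c = 0 disables collisions entirely
  cfg0 <- spike_detector_config(collision_window_ms = 0)
  expect_identical(sample_collisions(ev, cfg0), ev)
})

test_that("sorted output keeps only units above the sortable-SNR cutoff", {
  cfg <- spike_detector_config()
  # unit 1 at SNR 7 (sortable), unit 2 at SNR 5 (MUA only)
  d <- matrix(c(80 / sqrt(7), 80 / sqrt(5)), nrow = 1)
  spikes <- data.frame(time_ms = rep(seq(10, 200, by = 10), 2),
                       neuron = rep(1:2, each = 20))
  set.seed(8)
  ev <- detect_crossings(spikes, d, cfg, duration_ms = 210,
                         noise_events = FALSE)
  mua <- emit_spikes(ev, d, cfg, "mua")
  srt <- emit_spikes(ev, d, cfg, "sorted")
  expect_true(all(srt$unit == 1))
  expect_true(any(ev$neuron == 2))        # unit 2 was detected...
  expect_false(2 %in% srt$unit)           # ...but never sorted
  expect_gt(nrow(mua), nrow(srt))
  expect_true(all(mua$amplitude > cfg$threshold))
})

test_that("noise events appear in MUA but never in sorted output", {
  cfg <- spike_detector_config()
  d <- matrix(1e5, 3, 1)
  set.seed(9)
  ev <- detect_crossings(data.frame(time_ms = numeric(0),
                                    neuron = integer(0)),
                         d, cfg, duration_ms = 20000)
  expect_gt(nrow(ev), 0)
  expect_gt(nrow(emit_spikes(ev, d, cfg, "mua")), 0)
  expect_equal(nrow(emit_spikes(ev, d, cfg, "sorted")), 0)
})

test_that("sorted output deduplicates one spike seen on several channels", {
  cfg <- spike_detector_config(cv = 0)
  d <- matrix(c(20, 25), nrow = 2)  # both channels see unit 1 loudly
  spikes <- data.frame(time_ms = c(10, 30), neuron = 1)
  set.seed(10)
  ev <- detect_crossings(spikes, d, cfg, duration_ms = 40,
                         noise_events = FALSE)
  expect_equal(nrow(ev), 4)  # 2 spikes x 2 channels
  srt <- emit_spikes(ev, d, cfg, "sorted")
  expect_equal(nrow(srt), 2)
  expect_equal(srt$time_ms, c(10, 30))
})
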