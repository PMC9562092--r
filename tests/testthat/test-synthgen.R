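test_that("event table reflects the configured block design", {
  cfg <- synth_config()
  gen <- generate_recording(cfg, seed = 7)
  expect_equal(nrow(gen$events), 4 * 40)
  expect_true(all(table(gen$events$condition) == 40))
  expect_equal(dim(gen$recording$data),
               c(32, 4 * 40 * round(6.5 * 250)))
  # onsets are strictly increasing and trial-spaced within a block
  d <- diff(gen$events$onset_s[gen$events$block == 2])
  expect_true(all(abs(d - 6.5) < 1e-12))
})

test_that("noise-free epochs reproduce the planted template exactly", {
  cfg <- small_config(noise_scale = 0, coupling_spec = no_coupling())
  gen <- generate_recording(cfg, seed = 1)
  ep <- epoch_recording(gen$recording, gen$events, 0, cfg$trial_dur)
  for (b in seq_len(cfg$n_blocks)) {
    cond <- cfg$condition_labels[b]
    sel <- which(ep$condition == cond)
    avg <- colMeans(ep$data[sel, , , drop = FALSE], dims = 1)
    expect_equal(avg, gen$truth$erp_templates[cond, , ], tolerance = 0,
                 ignore_attr = TRUE)
  }
})

test_that("planted coupling shows up at the planted cross-correlation lag", {
  cfg <- synth_config(
    channel_labels = montage_channels(19), trials_per_block = 31,
    n_blocks = 1, condition_labels = "None", trial_dur = 6.5,
    coupling_spec = tibble::tibble(source = "Cz", target = "Pz",
                                   lag = 5L, gain = 1),
    coupling_gain_jitter = 0,
    p2_amplitudes = c(None = 0), p2_latency = c(None = 180),
    p3_amplitude = 0, n3_amplitude = 0,
    rt_mean = c(None = 496), valence_shift = c(None = 0)
  )
  gen <- generate_recording(cfg, seed = 3)   # ~200 s of signal
  x <- gen$recording$data["Cz", ]
  y <- gen$recording$data["Pz", ]
  # direct-summation cross-correlation over lags -20..20
  lags <- -20:20
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(x[1:(length(x) - k)] * y[(1 + k):length(y)])
    else sum(x[(1 - k):length(x)] * y[1:(length(y) + k)])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 5)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- small_config(trials_per_block = 3)
  a <- generate_recording(cfg, seed = 11)
  b <- generate_recording(cfg, seed = 11)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$events, b$events)
  expect_identical(a$truth$coupling, b$truth$coupling)
})

test_that("background spectrum follows the configured 1/f slope", {
  for (expo in c(0.5, 1, 1.5)) {
    cfg <- synth_config(channel_labels = montage_channels(19),
                        trials_per_block = 10, n_blocks = 1,
                        condition_labels = "None",
                        noise_exponent = expo, coupling_spec = no_coupling(),
                        p2_amplitudes = c(None = 0), p2_latency = c(None = 180),
                        p3_amplitude = 0, n3_amplitude = 0,
                        rt_mean = c(None = 496), valence_shift = c(None = 0))
    gen <- generate_recording(cfg, seed = 5)
    sp <- stats::spec.pgram(stats::ts(gen$recording$data[1, ], frequency = 250),
                            spans = 15, plot = FALSE)
    sel <- sp$freq >= 1 & sp$freq <= 40
    slope <- unname(stats::coef(stats::lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2])
    expect_lt(abs(slope + expo), 0.3)
  }
})

test_that("behavioral accuracy tracks the designated metric at the target correlation", {
  cfg0 <- synth_config(accuracy_metric_corr = 0)
  set.seed(99)
  metric <- rnorm(64)
  beh <- generate_behavior(cfg0, metric, seed = 1)
  expect_lt(abs(cor(beh$correct, metric)), 0.35)

  cfgn <- synth_config(accuracy_metric_corr = -0.9)
  neg <- vapply(1:100, function(s) {
    set.seed(s + 500)
    m <- rnorm(64)
    b <- generate_behavior(cfgn, m, seed = s)
    cor(b$correct, m) < 0
  }, logical(1))
  expect_gte(sum(neg), 99)

  expect_equal(nrow(generate_behavior(cfg0, numeric(0))), 0)
  expect_error(synth_config(accuracy_metric_corr = 1), "strictly inside")
  expect_true(all(beh$correct >= 0 & beh$correct <= 40))
  expect_true(all(beh$rt_ms > 0))
})

test_that("valence scores are clipped to the 1-9 scale and detect planted shifts", {
  cfg <- synth_config()
  val <- generate_valence(cfg, seed = 4)
  expect_true(all(val$pre >= 1 & val$pre <= 9))
  expect_true(all(val$post >= 1 & val$post <= 9))
  h <- dplyr::filter(val, condition == "H")
  res <- paired_ttest(h$pre, h$post)
  expect_lt(res$p, 0.05)
  expect_equal(res$effect_direction, 1L)
  q <- dplyr::filter(val, condition == "Q")
  expect_equal(paired_ttest(q$pre, q$post)$effect_direction, -1L)

  # a zero-shift condition rejects at roughly the nominal rate
  rej <- vapply(1:400, function(s) {
    v <- generate_valence(cfg, n_subjects = 16, seed = 10000 + s)
    none <- dplyr::filter(v, condition == "None")
    paired_ttest(none$pre, none$post)$p <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})
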