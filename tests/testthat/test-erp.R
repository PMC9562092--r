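test_that("epoch averaging reproduces templates and cancels opposite trials", {
  cfg <- small_config(trials_per_block = 4, noise_scale = 0,
                      coupling_spec = no_coupling())
  gen <- generate_recording(cfg, seed = 1)
  ep <- epoch_recording(gen$recording, gen$events, 0, cfg$trial_dur)
  wav <- average_epochs(ep, "H", "FPz")
  chan <- match("FPz", cfg$channel_labels)
  expect_equal(wav$values, gen$truth$erp_templates["H", chan, ])
  expect_equal(wav$n_trials, 4)

  # (x, -x) averages to zero
  x <- matrix(rnorm(3 * 100), 3, 100)
  dat <- array(0, dim = c(2, 3, 100))
  dat[1, , ] <- x
  dat[2, , ] <- -x
  ep2 <- eeg_epochs(dat, 100, 0, 1, c("a", "a"), c("c1", "c2", "c3"))
  expect_equal(average_epochs(ep2, "a", "c2")$values, rep(0, 100))
  expect_error(average_epochs(ep2, "zzz", "c1"), "No kept trials")
})

test_that("averaging residual shrinks like sigma over sqrt(n)", {
  template <- sin(seq(0, pi, length.out = 200))
  ratios <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 25
    trials <- matrix(rep(template, each = n), n, 200) +
      matrix(rnorm(n * 200), n, 200)
    res <- colMeans(trials) - template
    sqrt(mean(res^2)) * sqrt(n)   # should concentrate near sigma = 1
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("component measurement finds planted extrema with tie-breaks", {
  fs <- 250
  t_ms <- (0:249) / fs * 1000
  bump <- 5 * exp(-((t_ms - 180) / 20)^2 / 2)
  m <- measure_component(bump, "P2", fs = fs)
  expect_equal(m$amplitude, 5, tolerance = 1e-6)
  expect_lt(abs(m$latency_ms - 180), 1000 / fs + 1e-9)

  flat <- rep(0, 250)
  mf <- measure_component(flat, "P2", fs = fs)
  expect_equal(mf$amplitude, 0)
  expect_equal(mf$latency_ms, t_ms[min(which(t_ms >= 150))])

  two <- rep(0, 250)
  two[c(45, 60)] <- 3   # equal peaks at 176 and 236 ms
  mt <- measure_component(two, "P2", fs = fs)
  expect_equal(mt$latency_ms, t_ms[45])

  neg <- -bump
  mn <- measure_component(neg, "N2", window_ms = c(150, 275), fs = fs)
  expect_equal(mn$amplitude, -5, tolerance = 1e-6)
  expect_error(measure_component(bump, "P2", window_ms = c(1100, 1200), fs = fs),
               "no samples")
})

test_that("measurement is invariant to adding trials equal to the mean", {
  ep <- planted_p2_epochs(c(a = 3, b = 6), n_trials = 10, seed = 2)
  base <- measure_component(average_epochs(ep, "a", "FPz"), "P2")
  mean_wave <- average_epochs(ep, "a", "FPz")$values
  extra <- array(0, dim = c(dim(ep$data)[1] + 1, dim(ep$data)[2], dim(ep$data)[3]))
  extra[seq_len(dim(ep$data)[1]), , ] <- ep$data
  extra[dim(extra)[1], , ] <- matrix(mean_wave, dim(ep$data)[2], dim(ep$data)[3],
                                     byrow = TRUE)
  ep3 <- eeg_epochs(extra, ep$fs, ep$tmin, ep$tmax, c(ep$condition, "a"),
                    ep$labels)
  again <- measure_component(average_epochs(ep3, "a", "FPz"), "P2")
  expect_equal(again$amplitude, base$amplitude)
  expect_equal(again$latency_ms, base$latency_ms)
})

test_that("pointwise ANOVA F matches a from-scratch sum-of-squares oracle", {
  set.seed(3)
  ep <- planted_p2_epochs(c(a = 2, b = 5, c = 8), n_trials = 12, seed = 3)
  res <- pointwise_anova(ep, "FPz", alpha = 0.05)
  ch <- match("FPz", ep$labels)
  for (tp in c(10, 45, 120, 200)) {
    groups <- split(ep$data[, ch, tp], ep$condition)
    ow <- stats::oneway.test(vals ~ g,
                             data = data.frame(vals = unlist(groups),
                                               g = rep(names(groups), lengths(groups))),
                             var.equal = TRUE)
    expect_equal(res$f[tp], unname(ow$statistic), tolerance = 1e-10)
    expect_equal(res$p[tp], unname(ow$p.value), tolerance = 1e-10)
  }
})

test_that("pointwise ANOVA recovers the planted effect window and is calibrated", {
  hits <- vapply(1:3, function(s) {
    ep <- planted_p2_epochs(c(a = 2, b = 5, c = 8, d = 11), n_trials = 40,
                            seed = 300 + s)
    res <- pointwise_anova(ep, "FPz", alpha = 0.05, min_run_ms = 20)
    any(res$intervals$start_ms <= 230 & res$intervals$end_ms >= 130)
  }, logical(1))
  expect_true(all(hits))

  # identical generators: about alpha of timepoints flagged
  fracs <- vapply(1:20, function(s) {
    ep <- planted_p2_epochs(c(a = 0, b = 0, c = 0), n_trials = 15,
                            seed = 600 + s)
    res <- pointwise_anova(ep, "Cz", alpha = 0.05, min_run_ms = 0)
    mean(res$p <= 0.05)
  }, numeric(1))
  expect_gt(mean(fracs), 0.02)
  expect_lt(mean(fracs), 0.09)

  one <- planted_p2_epochs(c(a = 1), n_trials = 5, seed = 4)
  expect_error(pointwise_anova(one, "FPz"), ">= 2 conditions")
})
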