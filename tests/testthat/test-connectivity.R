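test_that("Welch auto-spectra are flat for white noise and peak at a planted tone", {
  set.seed(1)
  x <- rbind(rnorm(60000))   # 240 s at 250 Hz -> ~479 segments
  cs <- cross_spectra(x, fs = 250, seg_len_s = 1)
  expect_equal(cs$delta_f, 1)
  auto <- Re(cs$S[1, 1, ])
  sel <- cs$freqs >= 1 & cs$freqs <= 40
  expect_lt(max(auto[sel]) / min(auto[sel]), 3)

  tone <- rbind(sin(2 * pi * 10 * (0:19999) / 250) + 0.5 * rnorm(20000))
  cst <- cross_spectra(tone, fs = 250, seg_len_s = 1)
  expect_equal(cst$freqs[which.max(Re(cst$S[1, 1, ]))], 10)
  expect_error(cross_spectra(rbind(rnorm(100)), fs = 250, seg_len_s = 10),
               "shorter")
})

test_that("cross-spectra are Hermitian with nonnegative real diagonal", {
  set.seed(2)
  cs <- cross_spectra(matrix(rnorm(4 * 5000), 4), fs = 250)
  for (f in c(1, 5, 20)) {
    S <- cs$S[, , f]
    expect_identical(S, Conj(t(S)))
    expect_true(all(Re(diag(S)) >= 0))
    expect_true(all(Im(diag(S)) == 0))
  }
})

test_that("coherency is unity on the diagonal and small for independent channels", {
  set.seed(3)
  x <- matrix(rnorm(3 * 100000), 3)   # ~ 799 segments
  K <- coherency(cross_spectra(x, fs = 250))
  expect_true(all(abs(Mod(K$K[1, 1, ]) - 1) < 1e-9))
  sel <- K$freqs >= 1 & K$freqs <= 40
  expect_lt(max(Mod(K$K[1, 2, sel])), 0.2)
  # identical channels: coherence magnitude 1 everywhere
  y <- x[1, ]
  K2 <- coherency(cross_spectra(rbind(y, y), fs = 250))
  expect_true(all(abs(Mod(K2$K[1, 2, ]) - 1) < 1e-6))
})

test_that("a pure delay gives near-unit coherence with a linear phase slope", {
  d <- delayed_pair(100000, lag = 5, snr = 100, seed = 4)
  K <- coherency(cross_spectra(d, fs = 250))
  sel <- which(K$freqs >= 8 & K$freqs <= 13)
  expect_true(all(Mod(K$K[1, 2, sel]) > 0.9))
  ph <- Arg(K$K[1, 2, sel])
  slopes <- diff(ph)
  slopes <- atan2(sin(slopes), cos(slopes))   # unwrap bin-to-bin
  expect_equal(mean(slopes), 2 * pi * 5 / 250, tolerance = 0.05)
})

test_that("PSI has the planted direction, exact antisymmetry and null cases", {
  # identical channels: real coherency, zero PSI
  set.seed(5)
  y <- rnorm(30000)
  K <- coherency(cross_spectra(rbind(y, y), fs = 250))
  expect_true(all(psi(K, "alpha")$psi == 0))

  pos <- vapply(1:10, function(s) {
    d <- delayed_pair(30000, lag = 5, snr = 1, seed = 40 + s)
    K <- coherency(cross_spectra(d, fs = 250))
    psi(K, "alpha")$psi[1, 2] > 0
  }, logical(1))
  expect_gte(sum(pos), 9)

  d <- delayed_pair(30000, lag = 5, snr = 1, seed = 6)
  K <- coherency(cross_spectra(d, fs = 250))
  for (b in names(eeg_bands())) {
    P <- psi(K, b)$psi
    expect_identical(P, -t(P))       # antisymmetry is exact
    expect_true(all(diag(P) == 0))
  }
  # swapping the channels negates the matrix
  Ks <- coherency(cross_spectra(d[c(2, 1), ], fs = 250))
  expect_equal(psi(Ks, "beta")$psi[1, 2], -psi(K, "beta")$psi[1, 2],
               tolerance = 1e-12)
  expect_error(psi(K, c(4, 4.5)), "fewer than 2")
})

test_that("PSI equals the naive frequency-pair oracle and ignores common gain", {
  set.seed(7)
  x <- matrix(rnorm(5 * 20000), 5)
  x[3, ] <- x[3, ] + c(rep(0, 7), x[1, 1:19993])
  cs <- cross_spectra(x, fs = 250)
  K <- coherency(cs)
  for (b in c("delta", "theta", "gamma")) {
    P <- psi(K, b)$psi
    band <- eeg_bands()[[b]]
    for (i in 1:5) {
      for (j in 1:5) {
        expect_equal(P[i, j],
                     oracle_psi_pair(K$K, K$freqs, K$delta_f, band, i, j),
                     tolerance = 1e-12)
      }
    }
  }
  # common gain on both channels leaves PSI unchanged
  xg <- x
  xg[1, ] <- 3 * xg[1, ]
  xg[3, ] <- 3 * xg[3, ]
  Kg <- coherency(cross_spectra(xg, fs = 250))
  expect_equal(psi(Kg, "theta")$psi[1, 3], psi(K, "theta")$psi[1, 3],
               tolerance = 1e-10)
})

test_that("positive-part adjacency keeps one direction per pair", {
  P <- matrix(0, 2, 2)
  expect_true(all(psi_to_adjacency(P) == 0))
  P[1, 2] <- 0.3
  P[2, 1] <- -0.3
  W <- psi_to_adjacency(P)
  expect_equal(W[1, 2], 0.3)
  expect_equal(W[2, 1], 0)
  set.seed(8)
  M <- matrix(rnorm(36), 6)
  A <- psi_to_adjacency(M - t(M))
  expect_true(all(A * t(A) == 0))   # no reciprocal pair survives
  expect_true(all(diag(A) == 0))
})

test_that("epoched input pools segments within trials", {
  cfg <- small_config(trials_per_block = 4)
  gen <- generate_recording(cfg, seed = 9)
  ep <- suppressMessages(preprocess(gen$recording, gen$events,
                                    filter_method = "fft"))
  cs <- cross_spectra(ep, seg_len_s = 1)
  # 3.5 s epochs at 50% overlap -> 6 segments per kept trial
  expect_equal(cs$n_segments, sum(ep$kept) * 6)
  adj <- connectivity_adjacency(ep, bands = c("theta", "alpha"))
  expect_named(adj, c("theta", "alpha"))
  expect_true(all(adj$theta >= 0))
})
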