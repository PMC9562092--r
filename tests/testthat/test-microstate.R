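test_that("GFP equals the RMS of average-referenced electrode values", {
  expect_equal(gfp(matrix(c(1, -1), 2, 1))$values, 1)
  expect_equal(gfp(matrix(c(2, -1, -1), 3, 1))$values, sqrt(2))
  # constant map carries no field after re-referencing
  expect_warning(g <- gfp(matrix(5, 4, 1)), "re-referencing")
  expect_equal(g$values, 0)
  # oracle: direct RMS on random average-referenced maps
  set.seed(1)
  u <- matrix(rnorm(8 * 20), 8, 20)
  u <- sweep(u, 2, colMeans(u))
  expect_equal(gfp(u)$values, apply(u, 2, function(v) sqrt(mean(v^2))))
})

test_that("GFP peaks are strict local maxima thinned by separation", {
  expect_equal(gfp_peaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  # two peaks 4 ms apart at 1000 Hz: only the larger survives 10 ms spacing
  v <- c(0, 1, 0, 0, 2, 0)
  expect_equal(gfp_peaks(v, min_separation_ms = 10, fs = 1000), 5L)
  expect_equal(gfp_peaks(v, min_separation_ms = 0, fs = 1000), c(2L, 5L))
  expect_length(gfp_peaks(1:10), 0)
  expect_length(gfp_peaks(rep(1, 10)), 0)
})

test_that("T-AAHC recovers planted templates and trivial solutions", {
  tpl <- orthogonal_templates(32, 3, seed = 2)
  for (s in 1:3) {
    sim <- template_maps(tpl, 60, noise_sd = 0.1 / sqrt(32), seed = s)
    sol <- taahc(sim$maps, k_min = 3, k_max = 3)[["K=3"]]
    co <- abs(eegdecide:::spatial_correlation(sol$templates, tpl))
    # each planted template recovered by some cluster
    expect_true(all(apply(co, 2, max) >= 0.95))
  }
  # K = number of maps: every map its own cluster, perfect fit
  m <- matrix(rnorm(5 * 8), 5, 8)
  sol <- taahc(m, k_min = 5, k_max = 5)[["K=5"]]
  expect_equal(sol$gev, 1)
  # identical maps collapse to one cluster with perfect fit
  same <- matrix(rep(rnorm(8), each = 6), 6, 8)
  sol1 <- taahc(same, k_min = 1, k_max = 1)[["K=1"]]
  expect_equal(sol1$gev, 1, tolerance = 1e-12)
  expect_error(taahc(m, k_min = 2, k_max = 10), "cannot exceed")
})

test_that("GEV is non-decreasing in K for nested solutions", {
  tpl <- orthogonal_templates(19, 4, seed = 5)
  sim <- template_maps(tpl, 50, noise_sd = 0.15 / sqrt(19), seed = 6)
  sols <- taahc(sim$maps, k_min = 2, k_max = 8)
  gevs <- vapply(sols, function(s) s$gev, numeric(1))  # ascending K
  expect_true(all(diff(gevs) >= -1e-10))
})

test_that("CV criterion matches its closed form and selects the planted K", {
  expect_equal(cv_criterion(1, 32, 4), (31 / 27)^2)
  expect_equal(cv_criterion(0, 32, 5), 0)
  expect_error(cv_criterion(1, 6, 5), "n_channels")
  tpl <- orthogonal_templates(32, 3, seed = 7)
  hits <- vapply(1:5, function(s) {
    sim <- template_maps(tpl, 60, noise_sd = 0.1 / sqrt(32), seed = 100 + s)
    select_k(taahc(sim$maps, k_min = 2, k_max = 8)) == 3
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("backfitting segments planted sequences and ignores global scale", {
  tpl <- orthogonal_templates(16, 3, seed = 8)
  # two templates concatenated in time -> exactly 2 segments
  erp <- cbind(matrix(tpl[1, ], 16, 10), matrix(tpl[2, ], 16, 10))
  bf <- backfit(erp, tpl[1:2, ], fs = 100)
  expect_equal(nrow(bf$segment_table), 2)
  expect_equal(bf$segment_table$template, c(1L, 2L))
  # scaling the waveform changes nothing
  bf2 <- backfit(3.7 * erp, tpl[1:2, ], fs = 100)
  expect_identical(bf$labels, bf2$labels)
  # single template scaled over time -> one segment
  ramp <- matrix(tpl[3, ], 16, 20) * rep(seq(0.2, 2, length.out = 20), each = 16)
  expect_equal(nrow(backfit(ramp, tpl, fs = 100)$segment_table), 1)
  # noisy planted 3-state sequence recovered >= 90%
  set.seed(9)
  lab <- rep(1:3, each = 40)
  noisy <- t(tpl[lab, ] + matrix(rnorm(120 * 16, sd = 0.2 / sqrt(16)), 120, 16))
  bf3 <- backfit(noisy, tpl)
  expect_gte(mean(bf3$labels == lab), 0.9)
})

test_that("template matching pairs shared maps across conditions", {
  tpl <- orthogonal_templates(32, 6, seed = 10)
  solA <- eegdecide:::new_microstate_solution(6, tpl, 1:6, 1, 0, 0, "sensitive")
  # identical sets: identity matching at correlation 1
  m <- match_across_conditions(list(A = solA, B = solA))
  expect_equal(m$ref_template, m$template)
  expect_true(all(m$correlation > 1 - 1e-12))
  # permuted set: permutation recovered
  perm <- c(3, 1, 6, 2, 5, 4)
  solB <- eegdecide:::new_microstate_solution(6, tpl[perm, ], 1:6, 1, 0, 0, "sensitive")
  m2 <- match_across_conditions(list(A = solA, B = solB))
  expect_equal(m2$template[match(1:6, m2$ref_template)], match(1:6, perm))
  # sets sharing 3 of 6 templates: the shared pairs are the top matches
  set.seed(11)
  other <- orthogonal_templates(32, 6, seed = 12)
  mixed <- rbind(tpl[1:3, ], other[4:6, ])
  solC <- eegdecide:::new_microstate_solution(6, mixed, 1:6, 1, 0, 0, "sensitive")
  m3 <- match_across_conditions(list(A = solA, B = solC))
  top3 <- dplyr::arrange(m3, dplyr::desc(correlation))[1:3, ]
  expect_setequal(top3$ref_template, 1:3)
  expect_true(all(top3$correlation > 0.95))
})

test_that("the full per-condition microstate analysis runs end to end", {
  cfg <- small_config(trials_per_block = 8, coupling_spec = no_coupling())
  gen <- generate_recording(cfg, seed = 13)
  ep <- suppressMessages(preprocess(gen$recording, gen$events,
                                    filter_method = "fft"))
  sel <- ep$kept & ep$condition == "H"
  grand <- colSums(ep$data[sel, , , drop = FALSE], dims = 1) / sum(sel)
  res <- microstate_analysis(grand, fs = ep$fs, k_max = 6,
                             channel_labels = ep$labels)
  expect_true(res$k_opt >= 2 && res$k_opt <= 6)
  expect_equal(ncol(res$solution$templates), 19)
  expect_true(all(abs(sqrt(rowSums(res$solution$templates^2)) - 1) < 1e-9))
  # segments tile the analyzed window
  seg <- res$segmentation$segment_table
  expect_equal(seg$start_ms[1], 0)
  expect_equal(nrow(seg), sum(rle(res$segmentation$labels)$lengths > 0))
})
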