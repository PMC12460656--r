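make_tep <- function(k = 1, noise = 0, n_trials = 3, n_channels = 4,
                     seed = 1, ...) {
  gen_tep(tep_spec(k = k, trial_noise_rms = noise, n_trials = n_trials, ...),
          n_channels, 250, seed = seed)
}

test_that("trial averaging baseline-corrects and average-references", {
  t <- make_tep(k = 1, noise = 0, n_trials = 1, freqs = 9, damping = 70,
                latencies = 25, amplitudes = 6)
  ev <- trial_average(t)
  # single trial: the trial itself, after the two corrections
  raw <- t$data[1, , ]
  bidx <- t$times >= -250 & t$times < -5
  manual <- raw - rowMeans(raw[, bidx])
  manual <- sweep(manual, 2, colMeans(manual))
  expect_equal(unclass(ev), manual, ignore_attr = TRUE)
  # channel mean is zero at every time point after average reference
  expect_lt(max(abs(colMeans(ev))), 1e-12)
})

test_that("average referencing is idempotent", {
  t <- make_tep(k = 2, noise = 2, n_trials = 5, freqs = c(8, 18),
                damping = c(50, 60), latencies = c(20, 60),
                amplitudes = c(5, 3), seed = 3)
  ev <- trial_average(t)
  again <- sweep(ev, 2, colMeans(ev))
  expect_equal(unclass(again), unclass(ev), ignore_attr = TRUE)
})

test_that("noise-only averages obey the averaging law", {
  t <- make_tep(k = 0, noise = 4, n_trials = 500, seed = 5)
  ev <- trial_average(t)
  expect_lt(sqrt(mean(ev^2)), 1.5 * 4 / sqrt(500))
})

test_that("rank-1 evoked data yields one component matching the source", {
  n_ch <- 4; fs <- 250
  times <- seq(-250, 499, by = 1000 / fs)
  topo <- c(0.5, -0.5, 0.5, -0.5)
  wave <- ifelse(times >= 20, exp(-(times - 20) / 60) *
                   cos(2 * pi * 11 * (times - 20) / 1000), 0)
  evoked <- outer(topo, wave)
  evoked <- sweep(evoked, 2, colMeans(evoked))
  attr(evoked, "times") <- times
  cm <- pca_components(evoked, pcist_params())
  expect_equal(cm$n_retained, 1L)
  y <- cm$timecourses[1, ]
  # reproduces the generating waveform up to sign
  cors <- abs(stats::cor(y, wave))
  expect_gt(cors, 0.999)
})

test_that("component bookkeeping follows the variance and SNR rules", {
  n_ch <- 6; fs <- 250
  times <- seq(-250, 499, by = 1000 / fs)
  ridx <- times >= 0 & times < 300
  # two orthogonal sources with 80% / 20% of response energy
  t1 <- ifelse(times >= 10, sin(2 * pi * 9 * times / 1000), 0)
  t2 <- ifelse(times >= 10, sin(2 * pi * 23 * times / 1000), 0)
  q <- qr.Q(qr(matrix(rnorm(n_ch * 2), n_ch)))  # orthonormal topographies
  e1 <- outer(q[, 1], t1); e2 <- outer(q[, 2], t2)
  s1 <- sqrt(sum(e1[, ridx]^2)); s2 <- sqrt(sum(e2[, ridx]^2))
  evoked <- e1 / s1 * sqrt(0.8) + e2 / s2 * sqrt(0.2)
  attr(evoked, "times") <- times
  cm <- pca_components(evoked, pcist_params(variance_retained = 0.99))
  expect_equal(cm$n_retained, 2L)
  # 80% retention needs only the dominant source
  cm1 <- pca_components(evoked, pcist_params(variance_retained = 0.75))
  expect_equal(cm1$n_retained, 1L)
  # zero matrix: nothing retained
  z <- matrix(0, n_ch, length(times)); attr(z, "times") <- times
  expect_equal(pca_components(z, pcist_params())$n_retained, 0L)
})

test_that("distance matrices are exact pointwise differences", {
  expect_equal(distance_matrix(c(0, 1)), matrix(c(0, 1, 1, 0), 2))
  expect_equal(distance_matrix(rep(2, 5)), matrix(0, 5, 5))
  d <- distance_matrix(c(0, 2, 1))
  expect_equal(d[1, 2], 2); expect_equal(d[1, 3], 1); expect_equal(d[2, 3], 1)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})

test_that("state-transition counts match hand-evaluated cases", {
  expect_equal(nst(rep(1, 10), 0.5), 0)
  # 4x4 matrix: each reference column sees exactly one transition
  expect_equal(nst(c(0, 0, 1, 1), 0.5), 1)
  y <- c(0.3, -0.1, 0.8, 0.2, -0.4)
  expect_equal(nst(y, max(distance_matrix(y)) + 1), 0)
})

test_that("grid NST evaluation agrees with the direct definition", {
  set.seed(71)
  for (rep in 1:20) {
    y <- rnorm(sample(5:40, 1))
    eps <- sort(c(0, runif(8, 0, max(distance_matrix(y)) * 1.1)))
    direct <- vapply(eps, function(e) nst(y, e), numeric(1))
    expect_equal(dreamcomplexity:::nst_grid(y, eps), direct)
    # beyond the largest distance no transition survives
    expect_equal(nst(y, max(distance_matrix(y))), 0)
  }
})

test_that("threshold optimization prefers response structure", {
  p <- pcist_params(epsilon_grid_size = 50)
  step <- c(rep(0, 30), rep(1, 30))
  flat <- rep(0, 50)
  opt <- optimize_epsilon(flat, step, p)
  expect_gt(opt$objective, 0)
  expect_lt(opt$epsilon, 1)
  # identical segments: weighted difference cannot be positive
  seg <- rnorm(40)
  opt2 <- optimize_epsilon(seg, seg, pcist_params(k_weight = 1.2))
  expect_lte(opt2$objective, 0)
  # scaling both segments scales the threshold, not the objective
  opt3 <- optimize_epsilon(flat * 10, step * 10, p)
  expect_equal(opt3$objective, opt$objective)
  expect_equal(opt3$epsilon, opt$epsilon * 10)
})

test_that("the index is invariant to global amplitude scaling", {
  t <- make_tep(k = 8, noise = 4, n_trials = 20, n_channels = 8, seed = 11)
  r1 <- pcist(t)
  t2 <- t; t2$data <- t$data * 2
  r2 <- pcist(t2)
  expect_identical(r1$n_components_retained, r2$n_components_retained)
  expect_equal(r1$value, r2$value, tolerance = 1e-9)
  t3 <- t; t3$data <- t$data * 0.137
  r3 <- pcist(t3)
  expect_identical(r1$n_components_retained, r3$n_components_retained)
  expect_equal(r1$value, r3$value, tolerance = 1e-9)
})

test_that("a structured response scores far above the pure-noise floor", {
  # matched seeds: same background noise with and without the evoked part
  ratios <- vapply(1:6, function(s) {
    v0 <- pcist(gen_tep(tep_spec(k = 0, n_trials = 30), 8, 250, seed = s))$value
    v8 <- pcist(gen_tep(tep_spec(k = 8, n_trials = 30), 8, 250, seed = s))$value
    v0 / v8
  }, numeric(1))
  expect_true(all(ratios < 0.4))
  expect_lt(median(ratios), 0.35)
})

test_that("zero-input trial sets yield a zero index", {
  sp <- tep_spec(k = 0, trial_noise_rms = 0, n_trials = 2)
  t <- gen_tep(sp, 3, 250, seed = 1)
  r <- pcist(t)
  expect_equal(r$value, 0)
  expect_equal(r$n_components_retained, 0L)
  expect_equal(nrow(r$per_component), 0L)
})

test_that("GMFP measures across-channel dispersion", {
  ev <- matrix(1, 4, 10)
  expect_equal(gmfp(ev), rep(0, 10))
  two <- rbind(3, -3)
  expect_equal(gmfp(matrix(two, 2, 5)), rep(3 * sqrt(2), 5))
  # peak latency of a single-component evoked response
  t <- make_tep(k = 1, noise = 0, n_trials = 1, n_channels = 6, freqs = 10,
                damping = 40, latencies = 80, amplitudes = 6)
  g <- gmfp(trial_average(t))
  peak_ms <- t$times[which.max(g)]
  expect_lt(abs(peak_ms - 80), 10 + 25)  # within half a cycle of onset
  expect_error(gmfp(matrix(1, 1, 10)), ">= 2 channels")
})

test_that("inter-trial phase coherence behaves at its extremes", {
  # identical trials: perfect coherence
  t <- make_tep(k = 1, noise = 0, n_trials = 5, n_channels = 3, freqs = 10,
                damping = 100, latencies = 10, amplitudes = 5)
  co <- itpc(t, band = c(8, 12))
  post <- co[, t$times > 50 & t$times < 300]
  expect_true(all(post > 0.999))
  # independent noise: coherence near the Rayleigh expectation
  tn <- make_tep(k = 0, noise = 4, n_trials = 200, n_channels = 2, seed = 9)
  cn <- itpc(tn, band = c(8, 12))
  expect_lt(mean(cn), 0.15)
  # phase-locked evoked + noise: post-stimulus exceeds pre-stimulus
  tm <- make_tep(k = 1, noise = 3, n_trials = 60, n_channels = 4, freqs = 10,
                 damping = 150, latencies = 20, amplitudes = 8, seed = 10)
  cm <- itpc(tm, band = c(8, 12))
  pre <- rowMeans(cm[, tm$times < -50])
  post <- rowMeans(cm[, tm$times > 50 & tm$times < 300])
  expect_true(all(post > pre))
})
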