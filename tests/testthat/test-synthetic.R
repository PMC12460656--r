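test_that("spontaneous generator is seed-deterministic and validates input", {
  p <- state_profile("wake_eo")
  expect_identical(gen_spontaneous(p, 4, 10, 250, seed = 7),
                   gen_spontaneous(p, 4, 10, 250, seed = 7))
  expect_error(gen_spontaneous(p, 0, 10, 250, seed = 1), "positive")
  expect_error(gen_spontaneous(p, 4, 3, 250, seed = 1), ">= 5")
  expect_error(gen_spontaneous(p, 4, 10, 50, seed = 1), ">= 100")
})

test_that("a silent profile produces an all-zero recording", {
  silent <- state_profile("quiet",
                          band_powers = c(delta = 0, theta = 0, alpha = 0, beta = 0),
                          one_over_f_exponent = 1, broadband_rms = 0)
  e <- gen_spontaneous(silent, 3, 10, 250, seed = 1)
  expect_true(all(e$data == 0))
})

test_that("recordings are cut into floor(duration/5) five-second epochs", {
  p <- state_profile("sedation")
  e <- gen_spontaneous(p, 2, 23, 250, seed = 2)
  expect_equal(dim(e$data), c(4L, 2L, 1250L))
})

test_that("default profiles encode the stated spectral contrasts", {
  eo <- state_profile("wake_eo"); ec <- state_profile("wake_ec")
  sed <- state_profile("sedation")
  expect_gt(sed$band_powers[["delta"]], eo$band_powers[["delta"]])
  expect_gt(ec$band_powers[["alpha"]], eo$band_powers[["alpha"]])
  expect_equal(eo$broadband_rms, ec$broadband_rms)
})

test_that("eyes-closed profiles carry more alpha-band power than eyes-open", {
  # Welch-style band power via per-epoch periodograms, matched broadband rms
  band_power <- function(e, lo, hi) {
    d <- dim(e$data); fs <- e$fs
    freqs <- seq(0, fs / 2, length.out = d[3] / 2 + 1)
    sel <- freqs >= lo & freqs <= hi
    tot <- 0
    for (ep in seq_len(d[1])) for (ch in seq_len(d[2])) {
      sp <- Mod(fft(e$data[ep, ch, ]))^2
      tot <- tot + sum(sp[seq_along(freqs)][sel])
    }
    tot / (d[1] * d[2])
  }
  wins <- 0L
  for (s in 1:50) {
    eo <- gen_spontaneous(state_profile("wake_eo"), 4, 10, 250, seed = s)
    ec <- gen_spontaneous(state_profile("wake_ec"), 4, 10, 250, seed = 1000 + s)
    if (band_power(ec, 8, 12) > band_power(eo, 8, 12)) wins <- wins + 1L
  }
  expect_gte(wins, 45)
})

test_that("TMS trial generator is deterministic and enforces latency bounds", {
  sp <- tep_spec(k = 2, freqs = c(10, 20), damping = c(50, 80),
                 latencies = c(20, 100), amplitudes = c(5, 3), n_trials = 5)
  expect_identical(gen_tep(sp, 4, 250, seed = 3), gen_tep(sp, 4, 250, seed = 3))
  bad <- tep_spec(k = 1, freqs = 10, damping = 50, latencies = 600,
                  amplitudes = 5, n_trials = 2)
  expect_error(gen_tep(bad, 4, 250, seed = 1), "latency")
  expect_error(gen_tep(sp, 4, 250, epoch_window = c(100, 500), seed = 1),
               "negative to positive")
})

test_that("noiseless single-component trials are identical with silent baseline", {
  sp <- tep_spec(k = 1, freqs = 8, damping = 60, latencies = 30,
                 amplitudes = 5, trial_noise_rms = 0, n_trials = 4)
  t <- gen_tep(sp, 3, 250, seed = 2)
  expect_equal(t$data[1, , ], t$data[2, , ])
  expect_equal(t$data[1, , ], t$data[4, , ])
  baseline <- t$data[, , t$times < 0]
  expect_true(all(baseline == 0))
})

test_that("noise-only trial averages shrink like one over root n", {
  sp <- tep_spec(k = 0, trial_noise_rms = 4, n_trials = 500)
  t <- gen_tep(sp, 3, 250, seed = 6)
  avg <- apply(t$data, c(2, 3), mean)
  expect_lt(sqrt(mean(avg^2)), 4 / 10)
  # baseline of the average is statistically centered on zero; per-trial
  # baseline means are independent, so they calibrate the standard error
  trial_means <- apply(t$data[, , t$times < 0], 1, mean)
  se <- sd(trial_means) / sqrt(length(trial_means))
  base_mean <- mean(avg[, t$times < 0])
  expect_lt(abs(base_mean), 3 * se + 1e-12)
})

test_that("report generator reproduces the packaged cohort layout", {
  rep52 <- gen_reports(seed = 4)
  expect_equal(nrow(rep52), 52L)
  expect_equal(length(unique(rep52$participant_id)), 20L)
  counts <- table(table(rep52$participant_id))
  expect_equal(as.integer(counts[c("3", "2", "1")]), c(14L, 4L, 2L))
  tab <- tabulate_reports(rep52)
  expect_equal(tab$q1$n, c(1L, 28L, 2L, 9L, 12L))
  expect_equal(tab$q2$n, c(8L, 22L, 4L, 18L))
  expect_equal(tab$class$n, c(24L, 23L, 5L))
  # deterministic under seed, different under another seed
  expect_identical(gen_reports(seed = 4), rep52)
  expect_false(identical(gen_reports(seed = 5), rep52))
})

test_that("degenerate marginals force a single report", {
  m <- report_marginals(
    q1_counts = c(nothing = 0, no_info = 0, white = 0, vague = 0, vivid = 1),
    q2_counts = c(no = 0, no_info = 0, maybe = 0, yes = 1),
    class_totals = c(experience = 1, no_information = 0, no_experience = 0))
  r <- gen_reports(m, participants = 1L, seed = 1)
  expect_equal(as.character(r$q1), "vivid")
  expect_equal(as.character(r$q2), "yes")
})

test_that("infeasible marginals fail loudly, naming the violated total", {
  expect_error(report_marginals(q2_counts = c(no = 9, no_info = 22, maybe = 4,
                                              yes = 18)),
               "totals differ")
  expect_error(gen_reports(participants = rep(3L, 10)), "sum to 30")
})

test_that("the reconstructed joint table reproduces every marginal exactly", {
  tab <- fixture_joint_table()
  m <- report_marginals()
  expect_equal(unname(rowSums(tab)), unname(m$q1_counts))
  expect_equal(unname(colSums(tab)), unname(m$q2_counts))
  expect_equal(sum(tab), 52)
  # class totals under the default rule
  rule <- classification_rule()
  cls <- c(experience = 0L, no_information = 0L, no_experience = 0L)
  for (i in rownames(tab)) for (j in colnames(tab)) {
    cls[rule[i, j]] <- cls[rule[i, j]] + tab[i, j]
  }
  expect_equal(unname(cls), unname(m$class_totals))
  # arithmetic consequence: exactly 3 detail-positive reports with Q2 = no
  expect_equal(sum(tab[c("white", "vague", "vivid"), "no"]), 3L)
})

test_that("joint-table search recovers margins of random feasible tables", {
  rule <- classification_rule()
  set.seed(61)
  for (rep in 1:10) {
    raw <- matrix(rpois(20, 3), 5, 4,
                  dimnames = list(dreamcomplexity:::q1_levels(),
                                  dreamcomplexity:::q2_levels()))
    cls <- c(experience = 0L, no_information = 0L, no_experience = 0L)
    for (i in rownames(raw)) for (j in colnames(raw)) {
      cls[rule[i, j]] <- cls[rule[i, j]] + raw[i, j]
    }
    m <- report_marginals(q1_counts = rowSums(raw), q2_counts = colSums(raw),
                          class_totals = cls)
    sol <- fixture_joint_table(m, rule)
    expect_equal(rowSums(sol), rowSums(raw))
    expect_equal(colSums(sol), colSums(raw))
  }
})

test_that("epoch containers round-trip bit-exactly", {
  e <- gen_spontaneous(state_profile("wake_eo"), 3, 10, 250, seed = 1)
  f <- tempfile(fileext = ".epochs")
  write_epochs(e, f)
  e2 <- read_epoch_container(f)
  expect_identical(e$data, e2$data)
  expect_identical(e$fs, e2$fs)
  t <- gen_tep(tep_spec(k = 2, freqs = c(10, 20), damping = c(50, 60),
                        latencies = c(20, 40), amplitudes = c(4, 2),
                        n_trials = 3), 2, 250, seed = 2)
  f2 <- tempfile(fileext = ".epochs")
  write_epochs(t, f2)
  t2 <- read_epoch_container(f2)
  expect_identical(t$data, t2$data)
  expect_identical(t$times, t2$times)
})
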